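isolate,enzyme,topt_c,topt_se,tsmax_c,tsmax_se
Acinetobacter,BG,36.0,1.9,18.2,2.4
Acinetobacter,LAP,37.7,0.6,24.45,0.6
Acinetobacter,PHOS,37.55,2.1,18.85,2.6
Bacillus,LAP,60.7,2.5,40.25,1.5
Bacillus,PHOS,48.05,1,27.95,0.7
Citrobacter,BG,38.1,0.7,22.6,0.8
Citrobacter,LAP,39.7,0.6,24.55,0.6
Citrobacter,PHOS,47.95,0.9,27.95,0.7
Comamonas,BG,39.1,2.5,19.0,3.1
Comamonas,LAP,40.6,0.7,24.55,0.8
Enterobacter,BG,33.5,0.6,19.8,0.7
Enterobacter,LAP,40.0,0.4,25.25,0.5
Enterobacter,PHOS,46.85,0.5,28.25,0.4
Flaviobacterium,BG,38.4,0.5,23.2,0.6
Flaviobacterium,LAP,39.4,0.8,23.85,0.9
Flaviobacterium,PHOS,41.85,2.2,23.25,2.3
Pseudomonas,BG,39.0,2.6,19.1,3.2
Pseudomonas,LAP,41.4,1.1,23.25,1.1
Pseudomonas,PHOS,40.45,2.7,18.55,3.1
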