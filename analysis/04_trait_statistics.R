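#!/usr/bin/env Rscript
# Step 4: trait-level statistics.  Variance partitioning of the thermal
# traits across isolate and enzyme, Holm-adjusted pairwise Z-tests with
# compact letter groupings, trait correlations, and the fraction of
# activation-energy relationships that change between fitting windows.

library(thermotrait)

traits <- read.csv("results/traits.csv")
ea <- read.csv("results/ea_profile.csv")

for (resp in c("dCp", "topt_c", "tsmax_c")) {
  ap <- anova_partition(traits, resp)
  print(ap)
}
ap_ea <- anova_partition(ea, "E_A", factors = c("window", "isolate", "enzyme"))
print(ap_ea)

pw_dcp <- pairwise_z(traits, "dCp")
letters <- compact_letter_display(pw_dcp)
message("\ncompact letters for dCp within each enzyme:")
print(letters)

message(sprintf("\nR^2(Topt, TSmax) simulated: %.2f; published table: %.2f",
                trait_correlation(traits, "topt_c", "tsmax_c"),
                trait_correlation(table1_fixture(), "topt_c", "tsmax_c")))
message(sprintf("R^2(dCp, Topt) = %.2f, R^2(dCp, TSmax) = %.2f",
                trait_correlation(traits, "dCp", "topt_c"),
                trait_correlation(traits, "dCp", "tsmax_c")))

pw_ea <- lapply(split(ea, ea$window), function(d) pairwise_z(d, "E_A"))
rc1 <- relationship_change(pw_ea[["4-25"]], pw_ea[["4-35"]])
rc2 <- relationship_change(pw_ea[["4-35"]], pw_ea[["4-60"]])
message(sprintf("EA relationships changed: %.1f%% (4-25 vs 4-35), %.1f%% (4-35 vs 4-60)",
                100 * rc1$fraction_changed, 100 * rc2$fraction_changed))
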