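test_that("Holm adjustment matches the hand-worked step-down and its invariants", {
  expect_equal(holm_adjust(0.5), 0.5)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # order invariance
  set.seed(1)
  p <- runif(7)
  ord <- sample(7)
  expect_equal(holm_adjust(p)[ord], holm_adjust(p[ord]))
  # dominance: p_raw <= p_holm <= m * p_raw (capped at 1)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= pmin(1, 7 * p)))
})

toy_traits <- function() {
  data.frame(isolate = rep(c("A", "B", "C"), 2),
             enzyme = rep(c("BG", "LAP"), each = 3),
             dCp = c(-4000, -4002, -9000, -3000, -3001, -3002),
             dCp_se = c(1, 1, 1, 1000, 1000, 1000))
}

test_that("pairwise Z-tests match the normal-tail oracle within families", {
  pw <- pairwise_z(toy_traits(), "dCp")
  expect_s3_class(pw, "tt_pairwise")
  expect_equal(nrow(pw), 6)  # 3 pairs per enzyme family
  # hand value: diff 2, se 1 and 1 -> z = sqrt(2), p = 0.1573
  r <- pw[pw$family == "BG" & pw$member1 == "A" & pw$member2 == "B", ]
  expect_equal(abs(r$z), sqrt(2), tolerance = 1e-9)
  expect_equal(r$p_raw, 2 * pnorm(-sqrt(2)), tolerance = 1e-12)
  expect_equal(r$p_raw, 0.1573, tolerance = 1e-4)
  # brute-force oracle on every row
  expect_equal(pw$p_raw, 2 * pnorm(-abs(pw$diff / pw$se_diff)),
               tolerance = 1e-9)
  expect_true(all(pw$p_holm >= pw$p_raw))
  # large separations with tiny SE are significant after Holm
  expect_true(all(pw$significant[pw$family == "BG" & pw$member2 == "C"]))
  expect_false(any(pw$significant[pw$family == "LAP"]))
})

test_that("pairwise Z edge cases: equal estimates, zero SEs, single pairs", {
  tr <- data.frame(isolate = c("A", "B"), enzyme = "BG",
                   dCp = c(-5, -5), dCp_se = c(0, 0))
  pw <- pairwise_z(tr, "dCp")
  expect_equal(pw$p_raw, 1)
  expect_equal(pw$p_holm, pw$p_raw)  # family of one pair
  tr$dCp <- c(-5, -6)
  expect_warning(pw2 <- pairwise_z(tr, "dCp"), "zero joint SE")
  expect_true(pw2$significant)
})

test_that("variance partitioning recovers known decompositions", {
  # response depends only on isolate
  tr <- data.frame(isolate = rep(c("A", "B"), each = 2),
                   enzyme = rep(c("BG", "LAP"), 2),
                   y = c(5, 5, 9, 9))
  ap <- anova_partition(tr, "y")
  expect_equal(ap$table$pct_explained_mean[ap$table$factor == "isolate"], 100)
  expect_equal(ap$table$pct_explained_mean[ap$table$factor == "enzyme"], 0)

  # balanced 2x2 additive: isolate effect +-2, enzyme effect +-1 -> 80/20
  tr2 <- data.frame(isolate = rep(c("A", "B"), each = 2),
                    enzyme = rep(c("BG", "LAP"), 2),
                    y = c(2 + 1, 2 - 1, -2 + 1, -2 - 1))
  ap2 <- anova_partition(tr2, "y")
  expect_equal(ap2$table$pct_explained_mean,
               c(80, 20), tolerance = 1e-9)
  expect_false(ap2$order_sensitive)  # balanced: orders agree

  # row permutation leaves the SS unchanged
  perm <- tr2[c(3, 1, 4, 2), ]
  expect_equal(anova_partition(perm, "y")$table$ss_mean, ap2$table$ss_mean)

  expect_warning(anova_partition(data.frame(isolate = "A", enzyme = c("BG", "LAP"),
                                            y = c(1, 2)), "y"),
                 "single-level")
  # percent-of-explained sums to 100
  expect_equal(sum(ap2$table$pct_explained_mean), 100, tolerance = 1e-9)
})

test_that("trait correlation handles identity, degeneracy, and the published table", {
  tr <- data.frame(x = 1:10, y = 1:10, z = rep(2, 10))
  expect_equal(trait_correlation(tr, "x", "y"), 1)
  expect_warning(r0 <- trait_correlation(tr, "x", "z"), "zero variance")
  expect_true(is.na(r0))
  expect_error(trait_correlation(tr[1:2, ], "x", "y"), "3 complete rows")
  fx <- table1_fixture()
  r2 <- trait_correlation(fx, "topt_c", "tsmax_c")
  expect_equal(r2, 0.820, tolerance = 0.005)
})

test_that("relationship change counts flag flips and is symmetric", {
  pw <- function(sig) {
    structure(data.frame(family = "F", member1 = c("A", "A", "B", "C"),
                         member2 = c("B", "C", "C", "D"),
                         significant = sig),
              class = c("tt_pairwise", "data.frame"))
  }
  a <- pw(c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(relationship_change(a, a)$fraction_changed, 0)
  b <- pw(c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(relationship_change(a, b)$fraction_changed, 1)
  c1 <- pw(c(TRUE, FALSE, TRUE, TRUE))  # one of four flips
  expect_equal(relationship_change(a, c1)$fraction_changed, 0.25)
  expect_equal(relationship_change(a, c1)$fraction_changed,
               relationship_change(c1, a)$fraction_changed)
  bad <- pw(c(TRUE, FALSE, TRUE, FALSE))
  bad$member2[4] <- "E"
  expect_error(relationship_change(a, bad), "do not match")
})

test_that("compact letters encode exactly the non-significant sharing", {
  base <- data.frame(family = "F", member1 = c("m1", "m1", "m2"),
                     member2 = c("m2", "m3", "m3"),
                     estimate1 = c(3, 3, 2), estimate2 = c(2, 1, 1))
  mk <- function(sig) {
    d <- base
    d$significant <- sig
    structure(d, class = c("tt_pairwise", "data.frame"))
  }
  none <- compact_letter_display(mk(c(FALSE, FALSE, FALSE)))
  expect_equal(unique(none$letters), "a")
  all_sig <- compact_letter_display(mk(c(TRUE, TRUE, TRUE)))
  expect_equal(sort(all_sig$letters), c("a", "b", "c"))
  # only (m1, m3) significant -> a / ab / b
  mid <- compact_letter_display(mk(c(FALSE, TRUE, FALSE)))
  expect_equal(mid$letters[match(c("m1", "m2", "m3"), mid$member)],
               c("a", "ab", "b"))
})
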