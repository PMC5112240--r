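#' Holm step-down multiple-testing adjustment
#'
#' Wrapper over [stats::p.adjust()] with `method = "holm"`, with input
#' validation: sort ascending, multiply the i-th smallest p by
#' `m - i + 1`, enforce monotonicity, cap at 1, return in input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))
#' @export
holm_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "holm")
}

#' Pairwise approximate Z-tests on a trait matrix
#'
#' For every pair of combinations within a comparison family, computes
#' \eqn{Z = (\theta_1 - \theta_2)/\sqrt{se_1^2 + se_2^2}} with a two-sided
#' normal p-value, then applies the Holm adjustment within each family.
#' The standard errors come from the model-fit covariance (or the trait
#' Monte Carlo), not from pooled replicate variance.  The default family
#' compares isolates sharing one enzyme (within-panel comparisons); the
#' `"within_isolate"` family compares enzymes sharing one isolate, and
#' `"all"` treats every pair as one family.
#'
#' Degenerate SEs: two members with zero SE and equal estimates get
#' `p = 1` by convention; zero joint SE with unequal estimates is flagged
#' significant with a warning.
#'
#' @param traits Data frame with columns `isolate`, `enzyme`, the response,
#'   and its standard error.
#' @param response Name of the estimate column.
#' @param se Name of the SE column (default `paste0(response, "_se")`).
#' @param family `"within_enzyme"`, `"within_isolate"` or `"all"`.
#' @param alpha Significance level for the adjusted flags (default 0.05).
#' @return A data frame of class `tt_pairwise` with one row per pair:
#'   `family`, `member1`, `member2`, `estimate1`, `estimate2`, `diff`,
#'   `se_diff`, `z`, `p_raw`, `p_holm`, `significant`.  The response and
#'   alpha are kept as attributes.
#' @export
pairwise_z <- function(traits, response, se = paste0(response, "_se"),
                       family = c("within_enzyme", "within_isolate", "all"),
                       alpha = 0.05) {
  family <- match.arg(family)
  for (col in c(response, se)) {
    if (!col %in% names(traits)) stop("missing column: ", col, call. = FALSE)
  }
  if (any(traits[[se]] < 0, na.rm = TRUE)) {
    stop("standard errors must be nonnegative", call. = FALSE)
  }
  traits <- traits[!is.na(traits[[response]]), , drop = FALSE]
  grouping <- switch(family,
                     within_enzyme = traits$enzyme,
                     within_isolate = traits$isolate,
                     all = rep("all", nrow(traits)))
  member <- switch(family,
                   within_enzyme = traits$isolate,
                   within_isolate = traits$enzyme,
                   all = paste(traits$isolate, traits$enzyme, sep = ":"))
  rows <- list()
  for (fam in unique(grouping)) {
    idx <- which(grouping == fam)
    if (length(idx) < 2) next
    cmb <- utils::combn(idx, 2)
    est <- traits[[response]]
    ses <- traits[[se]]
    d <- est[cmb[1, ]] - est[cmb[2, ]]
    se_d <- sqrt(ses[cmb[1, ]]^2 + ses[cmb[2, ]]^2)
    z <- ifelse(se_d > 0, d / se_d, ifelse(d == 0, 0, Inf * sign(d)))
    if (any(se_d == 0 & d != 0)) {
      warning("zero joint SE with unequal estimates: flagged significant",
              call. = FALSE)
    }
    p_raw <- ifelse(is.infinite(z), 0, 2 * stats::pnorm(-abs(z)))
    rows[[fam]] <- data.frame(
      family = fam, member1 = member[cmb[1, ]], member2 = member[cmb[2, ]],
      estimate1 = est[cmb[1, ]], estimate2 = est[cmb[2, ]],
      diff = d, se_diff = se_d, z = z, p_raw = p_raw,
      p_holm = holm_adjust(p_raw), row.names = NULL)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(family = character(), member1 = character(),
                      member2 = character(), estimate1 = numeric(),
                      estimate2 = numeric(), diff = numeric(),
                      se_diff = numeric(), z = numeric(), p_raw = numeric(),
                      p_holm = numeric())
  }
  out$significant <- out$p_holm < alpha
  rownames(out) <- NULL
  structure(out, response = response, alpha = alpha,
            class = c("tt_pairwise", "data.frame"))
}

#' Variance partitioning of a trait across design factors
#'
#' Decomposes a trait over main effects (default isolate and enzyme) with a
#' sequential-sum-of-squares linear model, reporting each factor's SS as a
#' percentage of the summed factor SS ("of explained") and of the total SS.
#' The trait matrix is typically unbalanced (missing combinations), so the
#' sequential SS depend on factor order: both orders are computed, their
#' mean reported, and a divergence above 1 percentage point flagged in the
#' `order_sensitive` field.
#'
#' @param traits Trait data frame.
#' @param response Name of the response column.
#' @param factors Character vector of factor columns (default
#'   `c("isolate", "enzyme")`).  Factors with a single observed level are
#'   dropped with a warning.
#' @return A list of class `tt_anova`: `table` (per-factor SS and
#'   percentages under both orders plus their mean), `ss_residual`,
#'   `ss_total`, `order_sensitive`.
#' @export
anova_partition <- function(traits, response, factors = c("isolate", "enzyme")) {
  dat <- traits[!is.na(traits[[response]]), , drop = FALSE]
  keep <- vapply(factors, function(f) length(unique(dat[[f]])) > 1, logical(1))
  if (any(!keep)) {
    warning("dropping single-level factor(s): ",
            paste(factors[!keep], collapse = ", "), call. = FALSE)
    factors <- factors[keep]
  }
  if (length(factors) == 0) stop("no usable factors", call. = FALSE)
  for (f in factors) dat[[f]] <- factor(dat[[f]])

  seq_ss <- function(ord) {
    fml <- stats::as.formula(paste(response, "~", paste(ord, collapse = " + ")))
    tab <- suppressWarnings(stats::anova(stats::lm(fml, data = dat)))
    ss <- tab[["Sum Sq"]]
    names(ss) <- rownames(tab)
    ss
  }
  ord1 <- factors
  ord2 <- rev(factors)
  ss1 <- seq_ss(ord1)
  ss2 <- seq_ss(ord2)
  ss_res <- unname(ss1["Residuals"])
  f1 <- ss1[factors]
  f2 <- ss2[factors]
  ss_total <- sum(f1) + ss_res
  pct_expl <- function(ss) 100 * ss / sum(ss)
  tab <- data.frame(
    factor = factors,
    ss_order1 = unname(f1), ss_order2 = unname(f2),
    ss_mean = unname((f1 + f2) / 2),
    pct_explained_order1 = unname(pct_expl(f1)),
    pct_explained_order2 = unname(pct_expl(f2)),
    pct_explained_mean = unname((pct_expl(f1) + pct_expl(f2)) / 2),
    pct_total_order1 = unname(100 * f1 / ss_total),
    pct_total_order2 = unname(100 * f2 / (sum(f2) + ss_res)),
    row.names = NULL)
  order_sensitive <- any(abs(tab$pct_explained_order1 -
                               tab$pct_explained_order2) > 1)
  structure(list(response = response, table = tab, ss_residual = ss_res,
                 ss_total = ss_total, order_sensitive = order_sensitive),
            class = "tt_anova")
}

#' @export
print.tt_anova <- function(x, ...) {
  cat("Variance partition for", x$response,
      if (x$order_sensitive) "(sequential-SS order sensitive)" else "", "\n")
  print(x$table[, c("factor", "ss_mean", "pct_explained_mean")], digits = 4)
  invisible(x)
}

#' Squared Pearson correlation between two traits
#'
#' Computed over the rows where both traits are present; requires at least
#' three complete rows.  A zero-variance trait yields `NA` with a warning
#' (the correlation is undefined).
#'
#' @param traits Trait data frame.
#' @param x,y Column names.
#' @return The squared Pearson correlation.
#' @export
trait_correlation <- function(traits, x, y) {
  ok <- stats::complete.cases(traits[[x]], traits[[y]])
  if (sum(ok) < 3) stop("need at least 3 complete rows", call. = FALSE)
  xv <- traits[[x]][ok]
  yv <- traits[[y]][ok]
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(xv, yv)^2
}

#' Fraction of pairwise relationships that change between two analyses
#'
#' Given two [pairwise_z()] results over the identical pair universe
#' (e.g. activation energies fitted over two temperature windows), reports
#' the fraction of pairs whose Holm-adjusted significance flag differs.
#' Symmetric in its arguments.
#'
#' @param a,b `tt_pairwise` data frames covering identical pair sets.
#' @return A list: `n_pairs`, `n_changed`, `fraction_changed`.
#' @export
relationship_change <- function(a, b) {
  key <- function(d) paste(d$family, d$member1, d$member2, sep = "|")
  ka <- key(a)
  kb <- key(b)
  if (length(ka) != length(kb) || !setequal(ka, kb) || anyDuplicated(ka)) {
    stop("pair sets do not match", call. = FALSE)
  }
  changed <- a$significant != b$significant[match(ka, kb)]
  list(n_pairs = length(ka), n_changed = sum(changed),
       fraction_changed = mean(changed))
}

#' Compact letter display for pairwise-test results
#'
#' Assigns letters so that two members share a letter if and only if they
#' are not significantly different (as used on grouped bar panels).
#' Members are inserted in descending order of estimate (ties broken by
#' label); a member joins an existing letter group when compatible with
#' all its members, otherwise starts a new letter, and a final absorption
#' pass adds each member to every other group it is compatible with.
#'
#' @param pairwise A `tt_pairwise` result from [pairwise_z()].
#' @return A data frame with `family`, `member`, `estimate`, `letters`.
#' @export
compact_letter_display <- function(pairwise) {
  out <- list()
  for (fam in unique(pairwise$family)) {
    pw <- pairwise[pairwise$family == fam, , drop = FALSE]
    members <- unique(c(pw$member1, pw$member2))
    est <- c(pw$estimate1, pw$estimate2)[match(members,
                                               c(pw$member1, pw$member2))]
    ord <- order(-est, members)
    members <- members[ord]
    est <- est[ord]
    sig <- function(m1, m2) {
      hit <- (pw$member1 == m1 & pw$member2 == m2) |
        (pw$member1 == m2 & pw$member2 == m1)
      any(pw$significant[hit])
    }
    groups <- list()
    for (m in members) {
      placed <- FALSE
      for (gi in seq_along(groups)) {
        if (!any(vapply(groups[[gi]], function(g) sig(m, g), logical(1)))) {
          groups[[gi]] <- c(groups[[gi]], m)
          placed <- TRUE
          break
        }
      }
      if (!placed) groups[[length(groups) + 1]] <- m
    }
    # absorption: a member belongs to every group it is compatible with
    for (gi in seq_along(groups)) {
      for (m in setdiff(members, groups[[gi]])) {
        if (!any(vapply(groups[[gi]], function(g) sig(m, g), logical(1)))) {
          groups[[gi]] <- c(groups[[gi]], m)
        }
      }
    }
    letter_of <- letters[seq_along(groups)]
    lett <- vapply(members, function(m) {
      paste0(letter_of[vapply(groups, function(g) m %in% g, logical(1))],
             collapse = "")
    }, character(1))
    out[[fam]] <- data.frame(family = fam, member = members, estimate = est,
                             letters = lett, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
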