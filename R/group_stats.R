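#' Bin larva scores for chi-squared testing
#'
#' The statistical workflow is nonparametric: continuous scores are reduced
#' to bin counts before testing, because activity and visual responses are
#' not normally distributed. Built-in schemes:
#' \describe{
#'   \item{`activity_quartiles`}{0-25, 25-50, 50-75, 75-100 percent active;
#'     bins are upper-open except the last, so a larva at exactly 25 falls
#'     in the second bin.}
#'   \item{`eo_terciles`}{visual responses `<0`, `0-10`, `>10` percentage
#'     points; the middle bin is closed on both ends, so 0 and 10 are
#'     middle, 10.01 is top.}
#'   \item{`sign`}{positive vs non-positive (E-O of exactly 0 counts as
#'     non-positive, consistent with the tercile placement of 0).}
#' }
#'
#' @param values Numeric scores (finite; in [0, 100] for the quartile
#'   scheme).
#' @param scheme Binning scheme, or `"custom"` with explicit `edges`.
#' @param edges For `scheme = "custom"`: breakpoints passed to [cut()]
#'   (right-closed).
#' @return An object of class `binned_counts`: named integer vector of
#'   counts with attributes `scheme` and `labels`.
#' @examples
#' bin_scores(c(10, 25, 60, 99), "activity_quartiles")
#' bin_scores(c(-5, 0, 10, 10.01), "eo_terciles")
#' @export
bin_scores <- function(values, scheme = c("activity_quartiles", "eo_terciles",
                                          "sign", "custom"), edges = NULL) {
  scheme <- match.arg(scheme)
  if (any(!is.finite(values))) stop("domain error: values must be finite")
  counts <- switch(scheme,
    activity_quartiles = {
      if (any(values < 0 | values > 100))
        stop("domain error: activity must be in [0, 100]")
      idx <- findInterval(values, c(0, 25, 50, 75), rightmost.closed = FALSE)
      labs <- c("0-25%", "25-50%", "50-75%", "75-100%")
      tabulate_bins(idx, labs)
    },
    eo_terciles = {
      idx <- ifelse(values < 0, 1L, ifelse(values <= 10, 2L, 3L))
      tabulate_bins(idx, c("<0%", "0-10%", ">10%"))
    },
    sign = {
      idx <- ifelse(values > 0, 1L, 2L)
      tabulate_bins(idx, c("positive", "non-positive"))
    },
    custom = {
      if (is.null(edges)) stop("custom scheme needs edges")
      f <- cut(values, edges, include.lowest = TRUE)
      if (anyNA(f)) stop("domain error: value outside custom edges")
      stats::setNames(as.integer(table(f)), levels(f))
    })
  structure(counts, scheme = scheme, labels = names(counts),
            class = "binned_counts")
}

tabulate_bins <- function(idx, labels) {
  stats::setNames(tabulate(idx, nbins = length(labels)), labels)
}

#' @export
print.binned_counts <- function(x, ...) {
  cat(sprintf("binned_counts (%s):\n", attr(x, "scheme")))
  print(stats::setNames(as.integer(x), attr(x, "labels")))
  invisible(x)
}

#' Chi-squared homogeneity test between two groups of binned counts
#'
#' Pearson chi-squared on the 2 x k contingency table of a treatment group
#' against its control, with expected counts from the pooled margins and no
#' continuity correction. Bins empty in *both* groups are pruned first (they
#' carry no information and would make expected counts 0/0); a bin empty in
#' only one group is kept, since that asymmetry is signal. Degrees of
#' freedom: `(k - 1)` after pruning.
#'
#' @param counts_a,counts_b Aligned bin-count vectors (same scheme) for the
#'   two groups.
#' @param n_comparisons Number of comparisons in the contrast family, for
#'   the Bonferroni-adjusted significance call (default 1).
#' @param alpha Base significance level(s) checked after adjustment.
#' @return An object of class `group_comparison`: list with `chi2`, `dof`,
#'   `p`, `n_comparisons`, `bonferroni_alpha` (0.05/n), and `significant_at`
#'   (`"none"`, `"0.05/n"`, or `"0.01/n"`).
#' @examples
#' chi2_homogeneity(c(10, 0), c(0, 10))  # chi2 = 20, p ~ 7.7e-6
#' @export
chi2_homogeneity <- function(counts_a, counts_b, n_comparisons = 1,
                             alpha = c(0.05, 0.01)) {
  a <- as.integer(counts_a); b <- as.integer(counts_b)
  if (length(a) != length(b)) stop("bin count vectors must align")
  if (sum(a) == 0 || sum(b) == 0)
    stop("invalid test: a group has zero total count")
  keep <- (a + b) > 0                     # prune bins empty in both groups
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2) stop("invalid test: fewer than 2 informative bins")
  tab <- rbind(a, b)
  test <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  comparison(unname(test$statistic), unname(test$parameter),
             unname(test$p.value), n_comparisons, alpha)
}

#' Chi-squared test of E-O values against the 50-50 null
#'
#' If larvae do not respond to the visual stimulus, E-O values are expected
#' to be 50% positive and 50% negative. This goodness-of-fit test compares
#' the observed (positive, non-positive) counts to equal expected counts
#' `(n/2, n/2)` with 1 degree of freedom. An E-O of exactly 0 counts as
#' non-positive.
#'
#' @param eo Vector of valid E-O values.
#' @inheritParams chi2_homogeneity
#' @return A `group_comparison`.
#' @examples
#' chi2_5050(c(rep(5, 20)))   # 20 positive, 0 non-positive: chi2 = 20
#' @export
chi2_5050 <- function(eo, n_comparisons = 1, alpha = c(0.05, 0.01)) {
  eo <- eo[!is.na(eo)]
  if (length(eo) < 1) stop("invalid test: no valid E-O values")
  obs <- c(sum(eo > 0), sum(eo <= 0))
  test <- suppressWarnings(stats::chisq.test(obs, p = c(0.5, 0.5),
                                             correct = FALSE))
  comparison(unname(test$statistic), 1L, unname(test$p.value),
             n_comparisons, alpha)
}

comparison <- function(chi2, dof, p, n_comparisons, alpha) {
  thr <- sort(alpha) / n_comparisons      # strictest first
  sig <- "none"
  if (p < max(thr)) sig <- sprintf("%.2f/n", max(alpha))
  if (p < min(thr)) sig <- sprintf("%.2f/n", min(alpha))
  structure(list(chi2 = chi2, dof = dof, p = p,
                 n_comparisons = n_comparisons,
                 bonferroni_alpha = max(alpha) / n_comparisons,
                 significant_at = sig),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("chi-squared = %.4g, dof = %d, p = %.3g (alpha_bonf = %.3g, %s)\n",
              x$chi2, x$dof, x$p, x$bonferroni_alpha, x$significant_at))
  invisible(x)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Base significance level.
#' @param n_comparisons Number of comparisons in the family.
#' @return `alpha / n_comparisons`.
#' @examples
#' bonferroni(0.05, 6)   # 0.00833...
#' @export
bonferroni <- function(alpha, n_comparisons) {
  if (n_comparisons < 1) stop("domain error: n_comparisons must be >= 1")
  if (alpha <= 0 || alpha > 1) stop("domain error: alpha must be in (0, 1]")
  alpha / n_comparisons
}

#' Median p-value across repeat experiments
#'
#' When an experiment is repeated on separate days, each day is tested
#' against its own internal control and the *median* of the per-day p-values
#' is the reported significance — robust to a single outlying day while
#' preserving independence of samples within each test. Missing entries
#' (contrasts not run on a given day) are dropped.
#'
#' @param p Vector of p-values, possibly with NAs.
#' @return The median p, or `NA` if no finite p-values remain.
#' @examples
#' median_p(c(9e-4, 9e-6, 0.04))   # 9e-4
#' @export
median_p <- function(p) {
  p <- p[is.finite(p)]
  if (length(p) == 0) return(NA_real_)
  stats::median(p)
}

#' Convert a mass concentration to micromolar
#'
#' @param mass_conc_mg_l Mass concentration in mg/L.
#' @param formula_weight Molar mass in g/mol.
#' @return Concentration in uM: `1000 * mass_conc / formula_weight`.
#' @examples
#' molar_from_mass(160, 261.3)   # tricaine: 160 mg/L is 612 uM
#' @export
molar_from_mass <- function(mass_conc_mg_l, formula_weight) {
  if (mass_conc_mg_l <= 0 || formula_weight <= 0)
    stop("domain error: inputs must be positive")
  1000 * mass_conc_mg_l / formula_weight
}

#' Run the binned contrast battery between treatment groups and a control
#'
#' Applies the full statistical workflow to a scored experiment: for each
#' treatment group vs the control group, a quartile-binned activity contrast
#' and a tercile-binned E-O contrast, each Bonferroni-corrected for the
#' number of treatment groups; plus a 50-50 sign test of each group's E-O
#' values.
#'
#' @param scores A [score_larvae()] table (or [simulate_scores()] output
#'   with a `group` column supplied via `group_map`).
#' @param group_map Data.frame (`plate`, `row`, `group`).
#' @param control Label of the control group.
#' @param metric Activity value used for binning: `"headline"` or
#'   `"overall"` (see [summarize_group()]).
#' @param alpha Significance levels for the Bonferroni calls.
#' @return Data.frame with one row per (group, contrast): `group`,
#'   `contrast` (`activity`, `eo`, `eo_5050`), `chi2`, `dof`, `p`,
#'   `n_comparisons`, `bonferroni_alpha`, `significant_at`.
#' @export
stats_report <- function(scores, group_map, control,
                         metric = c("headline", "overall"),
                         alpha = c(0.05, 0.01)) {
  metric <- match.arg(metric)
  sc <- merge(scores, group_map, by = c("plate", "row"), sort = FALSE)
  if (!control %in% sc$group) stop(sprintf("control group '%s' not found", control))
  treatments <- setdiff(unique(group_map$group), control)
  ncmp <- max(1L, length(treatments))
  act <- if (metric == "headline") sc$activity_headline else sc$activity
  ctrl_act <- bin_scores(act[sc$group == control & !is.na(act)],
                         "activity_quartiles")
  ctrl_eo <- sc$eo[sc$group == control & sc$eo_valid]
  rows <- list()
  add <- function(group, contrast, cmp) {
    rows[[length(rows) + 1]] <<- data.frame(
      group = group, contrast = contrast, chi2 = cmp$chi2, dof = cmp$dof,
      p = cmp$p, n_comparisons = cmp$n_comparisons,
      bonferroni_alpha = cmp$bonferroni_alpha,
      significant_at = cmp$significant_at, stringsAsFactors = FALSE)
  }
  add(control, "eo_5050", chi2_5050(ctrl_eo, ncmp, alpha))
  for (g in treatments) {
    ga <- act[sc$group == g & !is.na(act)]
    add(g, "activity",
        chi2_homogeneity(bin_scores(ga, "activity_quartiles"), ctrl_act,
                         ncmp, alpha))
    ge <- sc$eo[sc$group == g & sc$eo_valid]
    if (length(ge) > 0 && length(ctrl_eo) > 0) {
      add(g, "eo",
          chi2_homogeneity(bin_scores(ge, "eo_terciles"),
                           bin_scores(ctrl_eo, "eo_terciles"), ncmp, alpha))
      add(g, "eo_5050", chi2_5050(ge, ncmp, alpha))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median-p summary across an experiment set
#'
#' Combines per-experiment [stats_report()] tables (one per repeat day) into
#' the reported per-contrast median p-values.
#'
#' @param reports List of [stats_report()] data.frames, one per experiment.
#' @return Data.frame: `group`, `contrast`, `n_experiments`, `median_p`.
#' @export
experiment_set_summary <- function(reports) {
  all <- do.call(rbind, Map(function(r, i) {
    r$experiment <- i
    r
  }, reports, seq_along(reports)))
  key <- interaction(all$group, all$contrast, drop = TRUE)
  first <- !duplicated(key)
  out <- data.frame(group = all$group[first], contrast = all$contrast[first],
                    stringsAsFactors = FALSE)
  out$n_experiments <- as.vector(tapply(all$p, key, function(p)
    sum(is.finite(p))))[key[first]]
  out$median_p <- as.vector(tapply(all$p, key, median_p))[key[first]]
  rownames(out) <- NULL
  out
}
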