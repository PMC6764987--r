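#' Activity percentage from per-interval movement flags
#'
#' Activity is "larval movement per interval" (lmpi): the percentage of
#' scored frame intervals in which the larva's thresholded difference area
#' reached the movement cutoff.
#'
#' @param move Vector of 0/1 movement flags (NAs dropped).
#' @return Percentage in [0, 100].
#' @export
activity_percent <- function(move) {
  move <- move[!is.na(move)]
  if (length(move) == 0) stop("undefined score: no scored intervals")
  100 * sum(move) / length(move)
}

#' E-O visual-response statistic
#'
#' The optomotor response measure: the mean percentage of intervals spent in
#' the upper half of the well during even stimulus periods (lines moving up;
#' periods 4, 6, 8, 10, 12 in the standard schedule) minus the mean during
#' odd stimulus periods (lines moving down; 3, 5, 7, 9, 11). Positive values
#' indicate stimulus-following; a blind larva's expected E-O is 0.
#'
#' @param periods Integer period ids of the supplied values (stimulus
#'   periods only).
#' @param up_pct Percentage of intervals "up" in each period (NA when no
#'   position was defined in that period).
#' @return E-O in percentage points, in [-100, 100]; `NA` when either the
#'   even or the odd side has no defined period.
#' @examples
#' eo_statistic(3:12, c(20, 80, 30, 70, 40, 60, 10, 90, 0, 100))
#' @export
eo_statistic <- function(periods, up_pct) {
  ok <- !is.na(up_pct)
  periods <- periods[ok]; up_pct <- up_pct[ok]
  even <- periods %% 2 == 0
  if (!any(even) || !any(!even)) return(NA_real_)
  mean(up_pct[even]) - mean(up_pct[!even])
}

#' Per-well, per-period activity and location scores
#'
#' Aggregates the detection results into one row per (well, period):
#' activity percentage over the period's intervals and the percentage of
#' intervals with the larva in the upper half of the well. Intervals flagged
#' invalid and acclimation intervals (period 0) are excluded; the up%%
#' denominator counts only intervals with a defined centroid.
#'
#' @param results A [run_detection()] results table.
#' @param carry_forward When `TRUE`, intervals without a defined position
#'   inherit the larva's last known up/down state within the well (off by
#'   default; the default excludes undefined intervals from denominators).
#' @return Data.frame: `plate`, `row`, `col`, `period`, `stimulus`,
#'   `n_intervals`, `activity`, `n_up_defined`, `up_pct`.
#' @export
period_scores <- function(results, carry_forward = FALSE) {
  res <- results[results$valid & results$period >= 1L, , drop = FALSE]
  if (nrow(res) == 0) stop("undefined score: no valid scored intervals")
  if (carry_forward) {
    res <- res[order(res$plate, res$row, res$col, res$frame_pair), ]
    wid <- paste(res$plate, res$row, res$col)
    res$up <- stats::ave(res$up, wid, FUN = fill_forward)
  }
  key <- interaction(res$plate, res$row, res$col, res$period, drop = TRUE)
  first <- !duplicated(key)
  out <- data.frame(plate = res$plate[first], row = res$row[first],
                    col = res$col[first], period = res$period[first],
                    stimulus = res$stimulus[first], stringsAsFactors = FALSE)
  out$n_intervals <- as.vector(tapply(res$move, key, length))[key[first]]
  agg <- function(x, f) as.vector(tapply(x, key, f))[key[first]]
  out$n_intervals <- agg(res$move, length)
  out$activity <- agg(res$move, function(m) 100 * mean(m))
  out$n_up_defined <- agg(res$up, function(u) sum(!is.na(u)))
  out$up_pct <- agg(res$up, function(u)
    if (all(is.na(u))) NA_real_ else 100 * mean(u, na.rm = TRUE))
  out <- out[order(out$plate, out$row, out$col, out$period), ]
  rownames(out) <- NULL
  out
}

fill_forward <- function(x) {
  if (all(is.na(x))) return(x)
  idx <- cumsum(!is.na(x))
  filled <- c(NA, x[!is.na(x)])[idx + 1L]
  filled
}

#' Score every larva in a detection results table
#'
#' Produces one score row per well: overall activity, headline activity (the
#' first 10-minute period after acclimation, the assay's reference activity
#' window), and the E-O visual response over the stimulus periods. Larvae
#' whose overall activity falls below `activity_floor` are flagged
#' `eo_valid = FALSE` — too few position fixes for a reliable vision
#' measurement (the assay's 5%% activity threshold).
#'
#' @param results A [run_detection()] results table.
#' @param schedule The `period_schedule` used for the recording.
#' @param activity_floor Minimum overall activity (%%) for a valid E-O
#'   (default 5). Applied per larva.
#' @param carry_forward Passed to [period_scores()].
#' @return Data.frame: `plate`, `row`, `col`, `n_intervals`, `activity`,
#'   `activity_headline`, `eo`, `eo_valid`.
#' @export
score_larvae <- function(results, schedule, activity_floor = 5,
                         carry_forward = FALSE) {
  ps <- period_scores(results, carry_forward = carry_forward)
  key <- interaction(ps$plate, ps$row, ps$col, drop = TRUE)
  first <- !duplicated(key)
  out <- data.frame(plate = ps$plate[first], row = ps$row[first],
                    col = ps$col[first])
  split_idx <- split(seq_len(nrow(ps)), key)
  ord <- match(levels(key), key[first])  # split() returns level order
  stats_per <- lapply(split_idx, function(ii) {
    p <- ps[ii, ]
    total_n <- sum(p$n_intervals)
    act <- sum(p$activity * p$n_intervals) / total_n
    head_act <- if (any(p$period == 1L)) p$activity[p$period == 1L][1] else NA_real_
    stim <- p[p$stimulus != "none", ]
    eo <- if (nrow(stim) > 0) eo_statistic(stim$period, stim$up_pct) else NA_real_
    c(n = total_n, activity = act, headline = head_act, eo = eo)
  })
  m <- do.call(rbind, stats_per)
  # reorder from level order back to first-appearance order
  lev_of_first <- as.character(key[first])
  m <- m[match(lev_of_first, names(split_idx)), , drop = FALSE]
  out$n_intervals <- as.integer(m[, "n"])
  out$activity <- m[, "activity"]
  out$activity_headline <- m[, "headline"]
  out$eo <- m[, "eo"]
  out$eo_valid <- !is.na(out$eo) & out$activity >= activity_floor
  out <- out[order(out$plate, out$row, out$col), ]
  rownames(out) <- NULL
  out
}

#' Group-level summary of larva scores
#'
#' Means and standard errors of activity and E-O per treatment group, with n
#' counting only larvae valid for the respective metric (all scored larvae
#' for activity; `eo_valid` larvae for E-O). SEM is the sample SD divided by
#' `sqrt(n)` and is `NA` for a single larva.
#'
#' @param scores A [score_larvae()] table.
#' @param group_map Data.frame (`plate`, `row`, `group`) mapping rows to
#'   treatment labels, e.g. from [assign_row_groups()].
#' @param metric Which activity value to summarize: `"headline"` (first
#'   period after acclimation, the assay's reference) or `"overall"`.
#' @return Data.frame: `group`, `n`, `mean_activity`, `sem_activity`,
#'   `n_eo`, `mean_eo`, `sem_eo`.
#' @export
summarize_group <- function(scores, group_map,
                            metric = c("headline", "overall")) {
  metric <- match.arg(metric)
  sc <- merge(scores, group_map, by = c("plate", "row"), sort = FALSE)
  if (nrow(sc) == 0) stop("undefined summary: no larvae matched the group map")
  act <- if (metric == "headline") sc$activity_headline else sc$activity
  sem <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
  groups <- unique(group_map$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    a <- act[sc$group == g & !is.na(act)]
    e <- sc$eo[sc$group == g & sc$eo_valid]
    if (length(a) == 0 && length(e) == 0)
      stop(sprintf("undefined summary: group '%s' is empty", g))
    data.frame(group = g, n = length(a),
               mean_activity = if (length(a)) mean(a) else NA_real_,
               sem_activity = sem(a),
               n_eo = length(e),
               mean_eo = if (length(e)) mean(e) else NA_real_,
               sem_eo = sem(e), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-period group means (row-averaged time courses)
#'
#' The assay's stable readout is the row/group average: individual larvae are
#' highly variable, but averaging 12 or more larvae gives reproducible
#' activity and position time courses. Returns per-group, per-period means of
#' activity and up%%, suitable for plotting.
#'
#' @inheritParams summarize_group
#' @param results A [run_detection()] results table.
#' @param schedule The recording's `period_schedule`.
#' @return Data.frame: `group`, `period`, `stimulus`, `n`, `mean_activity`,
#'   `mean_up_pct`.
#' @export
group_period_means <- function(results, schedule, group_map) {
  ps <- period_scores(results)
  ps <- merge(ps, group_map, by = c("plate", "row"), sort = FALSE)
  key <- interaction(ps$group, ps$period, drop = TRUE)
  first <- !duplicated(key)
  out <- data.frame(group = ps$group[first], period = ps$period[first],
                    stimulus = ps$stimulus[first], stringsAsFactors = FALSE)
  agg <- function(x, f) as.vector(tapply(x, key, f))[key[first]]
  out$n <- agg(ps$activity, length)
  out$mean_activity <- agg(ps$activity, mean)
  out$mean_up_pct <- agg(ps$up_pct, function(u) mean(u, na.rm = TRUE))
  out <- out[order(out$group, out$period), ]
  rownames(out) <- NULL
  out
}
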