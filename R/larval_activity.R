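#' @title Larval activity, habituation and thigmotaxis phenotyping
#' @name larval_activity
#' @description
#' Per-larva statistics from 1 Hz activity exports over an 80-minute
#' light/dark protocol followed by a tapping (startle habituation) block, with
#' the quality-control exclusions and the subsampled permutation test used for
#' cross-clutch genotype comparisons.
NULL

#' Default experimental protocol timeline
#'
#' 5 min habituation, 25 min baseline, three 10-min dark blocks alternating
#' with two 10-min light blocks, 10 min re-habituation, then 30 mechanical
#' taps at 1 Hz. All blocks are half-open minute intervals `[start, end)`.
#'
#' @param tap_count Number of taps (default 30).
#' @return List of class `protocol_timeline` with `habituation`, `baseline`,
#'   `dark_blocks`, `light_blocks` (each `c(start, end)` in minutes),
#'   `tap_times_s` (tap onset seconds) and `total_min`.
#' @export
default_protocol <- function(tap_count = 30L) {
  tap_start <- 90L * 60L  # after 10 min re-habituation following the blocks
  structure(list(
    habituation = c(0, 5),
    baseline = c(5, 30),
    dark_blocks = list(c(30, 40), c(50, 60), c(70, 80)),
    light_blocks = list(c(40, 50), c(60, 70)),
    tap_times_s = tap_start + seq_len(tap_count) - 1L,
    total_min = 91L
  ), class = "protocol_timeline")
}

block_minutes <- function(blocks) {
  unlist(lapply(blocks, function(b) seq(b[1], b[2] - 1L)))
}

minute_means <- function(activity, time_s) {
  minute <- floor(time_s / 60)
  tapply(activity, minute, mean)
}

#' Interval mean activity (baseline, dark, light)
#'
#' Activity is averaged per minute first, then per interval; the dark and
#' light means pool their respective blocks. Minutes missing inside an
#' interval raise a QC flag and the mean is taken over available minutes.
#'
#' @param activity Numeric vector of per-second activity (%delta pixels).
#' @param time_s Integer seconds since recording start, aligned to `activity`.
#' @param timeline A [default_protocol()] timeline.
#' @return List with `mean_baseline`, `mean_dark`, `mean_light`, `qc_flags`.
#' @export
interval_means <- function(activity, time_s, timeline = default_protocol()) {
  mm <- minute_means(activity, time_s)
  have <- as.numeric(names(mm))
  take <- function(mins, flag) {
    present <- mins %in% have
    flags <- if (all(present)) character() else flag
    list(mean = mean(mm[as.character(mins[present])]), flags = flags)
  }
  b <- take(seq(timeline$baseline[1], timeline$baseline[2] - 1L),
            "missing_minutes_baseline")
  d <- take(block_minutes(timeline$dark_blocks), "missing_minutes_dark")
  l <- take(block_minutes(timeline$light_blocks), "missing_minutes_light")
  list(mean_baseline = b$mean, mean_dark = d$mean, mean_light = l$mean,
       qc_flags = c(b$flags, d$flags, l$flags))
}

#' Light/dark transition responses
#'
#' For each transition, the difference between the mean activity of the first
#' minute after and the last minute before the stimulus; differences are then
#' averaged across same-type transitions. Light-to-dark (LD) transitions occur
#' at each dark-block start, dark-to-light (DL) at each light-block start.
#'
#' @inheritParams interval_means
#' @return List with `ld_transition` and `dl_transition` (%delta pixels).
#' @export
transition_response <- function(activity, time_s,
                                timeline = default_protocol()) {
  mm <- minute_means(activity, time_s)
  at <- function(m) mm[[as.character(m)]]
  diffs <- function(starts) {
    vapply(starts, function(s) at(s) - at(s - 1L), numeric(1))
  }
  ld <- diffs(vapply(timeline$dark_blocks, `[`, numeric(1), 1L))
  dl <- diffs(vapply(timeline$light_blocks, `[`, numeric(1), 1L))
  list(ld_transition = mean(ld), dl_transition = mean(dl))
}

#' Tap (startle habituation) response statistics
#'
#' The per-tap response is the activity in the 1-second bin starting at each
#' tap (taps are 1 s apart, so windows tile exactly). Reports the response to
#' tap 1, the mean response over taps 3-5 and taps 21-30, and the
#' responsiveness drops `act1 - mean(3-5)` and `act1 - mean(21-30)`. Larvae
#' with zero response to all of the first three taps are flagged as low
#' responders (excluded from downstream statistics).
#'
#' @inheritParams interval_means
#' @param tap_times_s Tap onset seconds (>= 10 taps expected; default timeline
#'   delivers 30 at 1 Hz).
#' @return List with `act1_tap`, `mean_tap_3_5`, `mean_tap_21_30`,
#'   `diff_3_5_vs_1`, `diff_21_30_vs_1`, `low_responder`.
#' @export
tapping_response <- function(activity, time_s,
                             tap_times_s = default_protocol()$tap_times_s) {
  resp <- activity[match(tap_times_s, time_s)]
  if (anyNA(resp)) stop("activity missing at tap times", call. = FALSE)
  list(
    act1_tap = resp[1],
    mean_tap_3_5 = mean(resp[3:5]),
    mean_tap_21_30 = mean(resp[21:30]),
    diff_3_5_vs_1 = resp[1] - mean(resp[3:5]),
    diff_21_30_vs_1 = resp[1] - mean(resp[21:30]),
    low_responder = all(resp[1:3] == 0)
  )
}

#' Thigmotaxis (periphery preference) per condition
#'
#' Per minute, the periphery share of total distance moved (TDM),
#' `100 * periphery / (center + periphery)`; the per-larva value for each
#' condition (baseline, dark, light) is the median across that condition's
#' minutes of movement (zone activity > 0 in the minute). QC: larvae whose
#' per-minute total activity and total TDM correlate at Pearson r < 0.9 are
#' flagged `tracking_mismatch`; conditions with fewer than 3 minutes of
#' movement are flagged `low_movement` and excluded.
#'
#' @param zones data.frame with columns `minute`, `zone` (`center`/
#'   `periphery`), `tdm_mm`, `activity_pct` for one larva.
#' @param timeline A [default_protocol()] timeline.
#' @param min_moving_minutes Minimum movement minutes per condition (default 3).
#' @param r_threshold Pearson threshold for the activity/TDM tracking check.
#' @return List with `thigmotaxis` (named B/D/L, percent or `NA`) and
#'   `qc_flags`.
#' @export
thigmotaxis <- function(zones, timeline = default_protocol(),
                        min_moving_minutes = 3L, r_threshold = 0.9) {
  stopifnot(all(c("minute", "zone", "tdm_mm", "activity_pct") %in% names(zones)))
  per_min <- function(col) {
    tapply(zones[[col]], list(zones$minute, zones$zone), sum)
  }
  tdm <- per_min("tdm_mm")
  act <- per_min("activity_pct")
  minutes <- as.numeric(rownames(tdm))
  tot_tdm <- rowSums(tdm, na.rm = TRUE)
  tot_act <- rowSums(act, na.rm = TRUE)

  qc <- character()
  r <- suppressWarnings(stats::cor(tot_act, tot_tdm))
  if (is.na(r) || r < r_threshold) qc <- c(qc, "tracking_mismatch")

  share <- 100 * tdm[, "periphery"] / (tdm[, "periphery"] + tdm[, "center"])
  moving <- tot_act > 0
  conds <- list(
    B = seq(timeline$baseline[1], timeline$baseline[2] - 1L),
    D = block_minutes(timeline$dark_blocks),
    L = block_minutes(timeline$light_blocks)
  )
  out <- vapply(names(conds), function(cn) {
    sel <- minutes %in% conds[[cn]] & moving & !is.na(share)
    if (sum(sel) < min_moving_minutes) return(NA_real_)
    stats::median(share[sel])
  }, numeric(1))
  if (anyNA(out)) qc <- c(qc, "low_movement")
  list(thigmotaxis = out, qc_flags = qc)
}

#' Per-larva summary over the full protocol
#'
#' Convenience wrapper running [interval_means()], [transition_response()],
#' [tapping_response()] and [thigmotaxis()] for one larva.
#'
#' @inheritParams interval_means
#' @param zones Per-larva zone data.frame (see [thigmotaxis()]); optional.
#' @return One-row data.frame of all summary features plus a `qc_flags`
#'   comma-separated string and `low_responder` flag.
#' @export
larva_summary <- function(activity, time_s, zones = NULL,
                          timeline = default_protocol()) {
  im <- interval_means(activity, time_s, timeline)
  tr <- transition_response(activity, time_s, timeline)
  tp <- tapping_response(activity, time_s, timeline$tap_times_s)
  th <- if (!is.null(zones)) thigmotaxis(zones, timeline) else
    list(thigmotaxis = c(B = NA_real_, D = NA_real_, L = NA_real_),
         qc_flags = character())
  data.frame(
    mean_baseline = im$mean_baseline, mean_dark = im$mean_dark,
    mean_light = im$mean_light,
    ld_transition = tr$ld_transition, dl_transition = tr$dl_transition,
    act1_tap = tp$act1_tap, mean_tap_3_5 = tp$mean_tap_3_5,
    mean_tap_21_30 = tp$mean_tap_21_30,
    diff_3_5_vs_1 = tp$diff_3_5_vs_1, diff_21_30_vs_1 = tp$diff_21_30_vs_1,
    thigmotaxis_b = th$thigmotaxis[["B"]], thigmotaxis_d = th$thigmotaxis[["D"]],
    thigmotaxis_l = th$thigmotaxis[["L"]],
    low_responder = tp$low_responder,
    qc_flags = paste(c(im$qc_flags, th$qc_flags), collapse = ",")
  )
}

#' Subsampled permutation genotype test (median p)
#'
#' Each permutation draws `subsample` observations per genotype (without
#' replacement when the group is at least that large, with replacement
#' otherwise), runs a two-sided Wilcoxon rank-sum test, and the median of the
#' permutation p-values is returned. Used for cross-replicate genotype
#' comparisons where clutch sizes vary.
#'
#' @param a,b Numeric observation vectors for the two genotypes (non-empty).
#' @param n_perm Number of permutations (default 100).
#' @param subsample Observations drawn per genotype (default 10).
#' @param seed Integer RNG seed (required).
#' @return Median p-value across permutations.
#' @export
permutation_genotype_test <- function(a, b, n_perm = 100L, subsample = 10L,
                                      seed) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both genotypes need at least one observation", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  draw <- function(x) sample(x, subsample, replace = length(x) < subsample)
  ps <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    wilcoxon_ranksum(draw(a), draw(b))
  }, numeric(1)))
  stats::median(ps)
}

#' Permutation tests of every genotype against a reference
#'
#' Loops [permutation_genotype_test()] over each non-reference genotype
#' versus the reference (WT by default), one feature at a time.
#'
#' @param values Numeric feature values, one per larva.
#' @param genotype Genotype label per larva.
#' @param reference Reference genotype (default `"WT"`; must be present).
#' @param seed Integer RNG seed (required).
#' @inheritParams permutation_genotype_test
#' @return data.frame with `genotype`, `n`, `n_ref`, `median_p`.
#' @export
genotype_feature_tests <- function(values, genotype, reference = "WT",
                                   n_perm = 100L, subsample = 10L, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (!reference %in% genotype) {
    stop(sprintf("reference genotype '%s' absent", reference), call. = FALSE)
  }
  ref_vals <- values[genotype == reference]
  others <- setdiff(unique(genotype), reference)
  out <- lapply(seq_along(others), function(i) {
    g_vals <- values[genotype == others[i]]
    data.frame(genotype = others[i], n = length(g_vals),
               n_ref = length(ref_vals),
               median_p = permutation_genotype_test(
                 ref_vals, g_vals, n_perm = n_perm, subsample = subsample,
                 seed = child_seed(seed, i)))
  })
  do.call(rbind, out)
}

#' Percent change of a feature median versus WT
#'
#' `100 * (median_del - median_wt) / median_wt`; when the WT median is zero
#' the denominator is replaced by the supplied category-wise fallback floor
#' (the minimum nonzero WT median of that feature category across founders).
#'
#' @param wt,del Numeric observation vectors (or precomputed medians of
#'   length 1).
#' @param fallback_floor Positive denominator used when `median(wt)` is 0.
#' @return Percent change.
#' @export
percent_change_vs_wt <- function(wt, del, fallback_floor = NULL) {
  mw <- stats::median(wt)
  md <- stats::median(del)
  denom <- mw
  if (denom == 0) {
    if (is.null(fallback_floor) || fallback_floor == 0) {
      stop("WT median is 0 and no nonzero fallback floor provided",
           call. = FALSE)
    }
    denom <- fallback_floor
  }
  100 * (md - mw) / denom
}

#' Trial-level genotype count filter
#'
#' Applied after all larva-level exclusions: a trial (clutch) is dropped when
#' any genotype retains fewer than `min_per_genotype` larvae.
#'
#' @param genotype Vector of genotype labels of the retained larvae.
#' @param min_per_genotype Minimum larvae per genotype (default 3).
#' @param genotypes_expected Genotypes that must be present (default the
#'   observed ones).
#' @return `TRUE` when the trial passes.
#' @export
trial_passes_counts <- function(genotype, min_per_genotype = 3L,
                                genotypes_expected = unique(genotype)) {
  counts <- table(factor(genotype, levels = genotypes_expected))
  all(counts >= min_per_genotype)
}
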