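#' @title Fish-pair trajectory metrics
#' @name social_behavior
#' @description
#' Locomotion, anxiety and social metrics from tracked positions of a fish
#' pair in a circular arena: speed, absolute tangential and normal
#' acceleration, distance traveled, periphery occupancy, normalized distance
#' to the arena center, ratio-in-front (leadership), polarization and
#' neighbor distance, plus the homotypic/heterotypic comparison scheme.
NULL

#' Circular arena geometry
#'
#' @param center Numeric `c(x, y)` center (cm).
#' @param radius Arena radius R (cm), > 0.
#' @param periphery_inner_fraction Inner edge of the periphery ring as a
#'   fraction of R (default 0.8: the ring from 0.8 R to the wall).
#' @return List of class `arena`.
#' @export
arena <- function(center = c(0, 0), radius, periphery_inner_fraction = 0.8) {
  stopifnot_scalar_number(radius, "radius", min = 1e-12)
  stopifnot_scalar_number(periphery_inner_fraction, "periphery_inner_fraction",
                          min = 1e-12, max = 1 - 1e-12)
  structure(list(center = center, radius = radius,
                 periphery_inner_fraction = periphery_inner_fraction),
            class = "arena")
}

gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  # reflect-pad so endpoints are smoothed against themselves
  xp <- c(x[rev(seq_len(half) + 1L)], x, x[n - seq_len(half)])
  stats::filter(xp, k, sides = 2)[half + seq_len(n)]
}

#' Linear interpolation of short tracking gaps
#'
#' Missing frames are linearly interpolated per axis when the gap spans at
#' most `max_gap` frames; longer gaps are left missing and excluded from all
#' frame-wise statistics downstream.
#'
#' @param positions n x 2 matrix of (x, y) positions, `NA` for lost frames.
#' @param max_gap Longest gap (frames) to interpolate (default 5).
#' @return Positions with short gaps filled.
#' @export
interpolate_gaps <- function(positions, max_gap = 5L) {
  miss <- is.na(positions[, 1]) | is.na(positions[, 2])
  if (!any(miss)) return(positions)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- positions
  for (j in which(r$values)) {
    if (r$lengths[j] > max_gap) next
    i0 <- starts[j] - 1L; i1 <- ends[j] + 1L
    if (i0 < 1L || i1 > nrow(positions)) next  # gap touches an edge
    idx <- starts[j]:ends[j]
    for (ax in 1:2) {
      out[idx, ax] <- stats::approx(c(i0, i1), positions[c(i0, i1), ax],
                                    xout = idx)$y
    }
  }
  out
}

#' Per-frame kinematics of one fish
#'
#' Velocity by central differences and acceleration by second differences on
#' (optionally Gaussian-smoothed) positions. The acceleration is decomposed
#' along the unit velocity: the tangential component (speeding up/slowing
#' down) and the normal component (turning); absolute values are reported.
#' Frames with speed below `heading_threshold` have undefined heading and
#' undefined components.
#'
#' @param positions n x 2 matrix of (x, y) positions in cm (n >= 3).
#' @param fps Frames per second.
#' @param sigma Gaussian position-smoothing SD in frames (default 1; 0
#'   disables smoothing).
#' @param heading_threshold Minimum speed (cm/s) for a defined heading
#'   (default 0.1).
#' @return data.frame per frame: `vx`, `vy`, `speed`, `abs_tangential_accel`,
#'   `abs_normal_accel`, `heading_defined`. First and last frames have `NA`
#'   derivatives.
#' @export
kinematics <- function(positions, fps, sigma = 1,
                       heading_threshold = 0.1) {
  ok <- stats::complete.cases(positions)
  if (!any(ok)) stop("all frames missing", call. = FALSE)
  if (nrow(positions) < 3L) stop("need >= 3 frames", call. = FALSE)
  dt <- 1 / fps
  p <- positions
  p[, 1] <- gaussian_smooth(p[, 1], sigma)
  p[, 2] <- gaussian_smooth(p[, 2], sigma)
  n <- nrow(p)
  idx <- 2:(n - 1)
  v <- matrix(NA_real_, n, 2)
  a <- matrix(NA_real_, n, 2)
  v[idx, ] <- (p[idx + 1L, ] - p[idx - 1L, ]) / (2 * dt)
  a[idx, ] <- (p[idx + 1L, ] - 2 * p[idx, ] + p[idx - 1L, ]) / dt^2
  speed <- sqrt(rowSums(v^2))
  defined <- !is.na(speed) & speed >= heading_threshold
  ux <- ifelse(defined, v[, 1] / speed, NA_real_)
  uy <- ifelse(defined, v[, 2] / speed, NA_real_)
  at <- a[, 1] * ux + a[, 2] * uy
  anx <- a[, 1] - at * ux
  any_ <- a[, 2] - at * uy
  data.frame(
    vx = v[, 1], vy = v[, 2], speed = speed,
    abs_tangential_accel = abs(at),
    abs_normal_accel = sqrt(anx^2 + any_^2),
    heading_defined = defined
  )
}

#' Distance traveled (cm)
#'
#' Sum of frame-to-frame displacements over consecutive tracked frames.
#'
#' @param positions n x 2 position matrix.
#' @return Total path length in cm.
#' @export
distance_traveled <- function(positions) {
  d <- diff(positions)
  sum(sqrt(rowSums(d^2)), na.rm = TRUE)
}

#' Periphery occupancy and normalized distance to origin
#'
#' The normalized distance to the arena center is r/R per frame (0 = center,
#' 1 = wall), with r clamped at R to absorb tracking jitter. A frame counts as
#' periphery when r >= `periphery_inner_fraction * R` (inclusive).
#'
#' @param positions n x 2 position matrix (cm).
#' @param arena An [arena()].
#' @return List with `time_in_periphery` (frame count), `in_periphery`
#'   (logical per frame) and `norm_dist_origin` (numeric per frame).
#' @export
periphery_and_origin <- function(positions, arena) {
  dx <- positions[, 1] - arena$center[1]
  dy <- positions[, 2] - arena$center[2]
  r <- pmin(sqrt(dx^2 + dy^2), arena$radius)
  peri <- r >= arena$periphery_inner_fraction * arena$radius
  list(time_in_periphery = sum(peri, na.rm = TRUE),
       in_periphery = peri,
       norm_dist_origin = r / arena$radius)
}

#' Ratio in front (leadership)
#'
#' The proportion of counted frames in which the other fish lies in the focal
#' fish's frontal half-plane: dot(unit heading, other - focal) > 0. Low values
#' mean the focal fish is mostly in front, i.e. leads. Frames without a
#' defined focal heading (or with either fish missing) are dropped from the
#' denominator.
#'
#' @param focal_positions,other_positions n x 2 position matrices (cm).
#' @param fps Frames per second.
#' @param sigma Position smoothing for the heading (see [kinematics()]).
#' @param heading_threshold Minimum focal speed for a defined heading.
#' @return Proportion in \[0, 1\], or `NA` when no frame qualifies.
#' @export
ratio_in_front <- function(focal_positions, other_positions, fps, sigma = 1,
                           heading_threshold = 0.1) {
  k <- kinematics(focal_positions, fps, sigma, heading_threshold)
  dx <- other_positions[, 1] - focal_positions[, 1]
  dy <- other_positions[, 2] - focal_positions[, 2]
  use <- k$heading_defined & !is.na(dx) & !is.na(dy)
  if (!any(use, na.rm = TRUE)) return(NA_real_)
  dot <- k$vx * dx + k$vy * dy  # same sign as unit-heading dot product
  mean(dot[which(use)] > 0)
}

#' Polarization order parameter of a pair
#'
#' Per frame, the magnitude of the mean of the two unit velocity vectors:
#' 1 for identical headings, 0 for antiparallel ones. Frames where either
#' heading is undefined are dropped. Returns the per-frame series and its
#' median.
#'
#' @param kin1,kin2 Per-fish kinematics (from [kinematics()]).
#' @return List with `series` (per-frame polarization) and `median`.
#' @export
polarization <- function(kin1, kin2) {
  u1x <- kin1$vx / kin1$speed; u1y <- kin1$vy / kin1$speed
  u2x <- kin2$vx / kin2$speed; u2y <- kin2$vy / kin2$speed
  ok <- kin1$heading_defined & kin2$heading_defined
  pol <- sqrt(((u1x + u2x) / 2)^2 + ((u1y + u2y) / 2)^2)
  pol[!ok | is.na(ok)] <- NA_real_
  list(series = pol, median = stats::median(pol, na.rm = TRUE))
}

#' Neighbor distance
#'
#' Median Euclidean distance between the two fish across frames where both
#' are tracked.
#'
#' @param positions1,positions2 n x 2 position matrices (cm).
#' @return Median distance (cm).
#' @export
neighbor_distance <- function(positions1, positions2) {
  d <- sqrt(rowSums((positions1 - positions2)^2))
  if (all(is.na(d))) stop("no frame with both fish present", call. = FALSE)
  stats::median(d, na.rm = TRUE)
}

#' All metrics for one tracked pair
#'
#' @param pair A trajectory pair: list with `positions` (list of two n x 2
#'   matrices), `fps`, `genotypes` (length-2, `Het`/`Del`), `arena` (an
#'   [arena()]), and optionally `pair_id`. [gen_pair_trajectories()] returns
#'   this shape.
#' @param sigma Position smoothing SD in frames (default 1).
#' @return data.frame with one row per fish carrying individual metrics
#'   (means of per-frame quantities; `time_in_periphery` in frames,
#'   `periphery_fraction` as a proportion) plus pair-level `polarization`
#'   (median) and `neighbor_distance` replicated on both rows, and
#'   `pair_type` among `HetHet`, `HetDel`, `DelDel`.
#' @export
pair_metrics <- function(pair, sigma = 1) {
  stopifnot(length(pair$positions) == 2L)
  p1 <- interpolate_gaps(pair$positions[[1]])
  p2 <- interpolate_gaps(pair$positions[[2]])
  k1 <- kinematics(p1, pair$fps, sigma)
  k2 <- kinematics(p2, pair$fps, sigma)
  pol <- polarization(k1, k2)
  nd <- neighbor_distance(p1, p2)
  gt <- pair$genotypes
  pt <- c(HetHet = "HetHet", HetDel = "HetDel", DelHet = "HetDel",
          DelDel = "DelDel")[[paste(gt, collapse = "")]]
  one <- function(p, k, pother, genotype, fish_id) {
    po <- periphery_and_origin(p, pair$arena)
    data.frame(
      pair_id = pair$pair_id %||% NA_character_,
      fish_id = fish_id, genotype = genotype, pair_type = pt,
      speed = mean(k$speed, na.rm = TRUE),
      abs_normal_accel = mean(k$abs_normal_accel[k$heading_defined],
                              na.rm = TRUE),
      abs_tangential_accel = mean(k$abs_tangential_accel[k$heading_defined],
                                  na.rm = TRUE),
      distance_traveled = distance_traveled(p),
      time_in_periphery = po$time_in_periphery,
      periphery_fraction = mean(po$in_periphery, na.rm = TRUE),
      norm_dist_origin = mean(po$norm_dist_origin, na.rm = TRUE),
      ratio_in_front = ratio_in_front(p, pother, pair$fps, sigma),
      polarization = pol$median,
      neighbor_distance = nd
    )
  }
  rbind(one(p1, k1, p2, gt[1], 1L), one(p2, k2, p1, gt[2], 2L))
}

INDIVIDUAL_METRICS <- c("speed", "abs_normal_accel", "abs_tangential_accel",
                        "distance_traveled", "time_in_periphery",
                        "norm_dist_origin")
PAIR_METRICS <- c("polarization", "neighbor_distance")

#' Genotype comparisons across pairs
#'
#' Implements the comparison scheme for pair experiments. For individual
#' metrics (speed, accelerations, distance traveled, periphery time,
#' normalized distance to origin): homotypic pairs (HetHet, DelDel)
#' contribute the two-fish average as a single observation, compared between
#' genotypes (comparison `S`); within heterotypic HetDel pairs each fish
#' contributes its own value labeled by genotype (comparison `D`).
#' Ratio-in-front is kept per fish in both schemes. Pair metrics
#' (polarization, neighbor distance) are compared between pair types:
#' HetHet vs HetDel (`HM`) and HetHet vs DelDel (`HD`). All comparisons use
#' two-sided Wilcoxon rank-sum tests; groups with fewer than 2 observations
#' skip the comparison with a warning.
#'
#' @param metrics data.frame of per-fish rows as returned by [pair_metrics()]
#'   (rows from multiple pairs bound together; `pair_id` must identify pairs).
#' @return data.frame with `metric`, `comparison` (`S`, `D`, `HM`, `HD`),
#'   `n_a`, `n_b`, `median_a`, `median_b`, `p`.
#' @export
pair_comparison <- function(metrics) {
  rows <- list()
  add <- function(metric, comparison, a, b) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) {
      warning(sprintf("skipping %s/%s: group with < 2 observations",
                      metric, comparison), call. = FALSE)
      return()
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, comparison = comparison,
      n_a = length(a), n_b = length(b),
      median_a = stats::median(a), median_b = stats::median(b),
      p = wilcoxon_ranksum(a, b))
  }
  homo <- metrics[metrics$pair_type %in% c("HetHet", "DelDel"), ]
  hetero <- metrics[metrics$pair_type == "HetDel", ]
  for (m in c(INDIVIDUAL_METRICS, "ratio_in_front")) {
    if (m == "ratio_in_front") {
      # kept per fish to preserve the leadership asymmetry
      a <- homo[homo$pair_type == "HetHet", m]
      b <- homo[homo$pair_type == "DelDel", m]
    } else {
      avg <- tapply(homo[[m]], homo$pair_id, mean)
      type_by_pair <- tapply(homo$pair_type, homo$pair_id,
                             function(x) x[[1]])
      a <- avg[type_by_pair == "HetHet"]
      b <- avg[type_by_pair == "DelDel"]
    }
    add(m, "S", a, b)
    add(m, "D",
        hetero[hetero$genotype == "Het", m],
        hetero[hetero$genotype == "Del", m])
  }
  pair_level <- metrics[!duplicated(metrics$pair_id), ]
  for (m in PAIR_METRICS) {
    hh <- pair_level[pair_level$pair_type == "HetHet", m]
    add(m, "HM", hh, pair_level[pair_level$pair_type == "HetDel", m])
    add(m, "HD", hh, pair_level[pair_level$pair_type == "DelDel", m])
  }
  do.call(rbind, rows)
}
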