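# Fixture builders and independent oracles used across the test files.

# PSI table with exact per-group means (no noise): group_means is a named list
# event_id -> numeric vector over groups; every group gets `n_per_group`
# samples with identical PSI.
toy_psi_table <- function(group_means,
                          groups = c("Neural", paste0("T", 1:5)),
                          n_per_group = 2L, length_nt = 20L,
                          quality = "OK") {
  samples <- paste0(rep(groups, each = n_per_group), "_",
                    seq_len(n_per_group))
  sample_group <- rep(groups, each = n_per_group)
  psi <- t(vapply(group_means, function(mu) {
    mu[match(sample_group, groups)]
  }, numeric(length(samples))))
  qual <- matrix(quality, nrow(psi), ncol(psi))
  qual[is.na(psi)] <- "N"
  colnames(psi) <- colnames(qual) <- samples
  events <- data.frame(event_id = names(group_means),
                       gene_id = paste0("g_", names(group_means)),
                       exon_length_nt = length_nt)
  list(table = psi_table(events, psi, qual),
       config = data.frame(sample = samples, group = sample_group,
                           excluded = ""))
}

# Independent brute-force reimplementation of the tissue-enrichment caller
# (plain loops, no shared code path).
brute_call <- function(table, config, params, target) {
  qlv <- c(N = 0, VLOW = 1, LOW = 2, OK = 3, SOUND = 4)
  res <- list()
  for (i in seq_len(nrow(table$psi))) {
    gmeans <- c(); gnames <- c()
    for (g in unique(config$group)) {
      excl <- strsplit(config$excluded[config$group == g][1], ",")[[1]]
      if (g != target && target %in% excl) next
      vals <- c()
      for (s in config$sample[config$group == g]) {
        q <- table$quality[i, s]
        if (qlv[[q]] >= qlv[[params$min_quality]] && !is.na(table$psi[i, s])) {
          vals <- c(vals, table$psi[i, s])
        }
      }
      if (length(vals) >= params$min_rep) {
        gmeans <- c(gmeans, mean(vals)); gnames <- c(gnames, g)
      }
    }
    names(gmeans) <- gnames
    if (length(gmeans) < params$n_groups || !target %in% gnames) next
    others <- gmeans[names(gmeans) != target]
    dpt <- gmeans[[target]] - mean(others)
    pooled <- c()
    for (g in names(others)) {
      for (s in config$sample[config$group == g]) {
        q <- table$quality[i, s]
        if (qlv[[q]] >= qlv[[params$min_quality]] && !is.na(table$psi[i, s])) {
          pooled <- c(pooled, table$psi[i, s])
        }
      }
    }
    dpg <- gmeans[[target]] - mean(pooled)
    called <- abs(dpt) >= params$min_dpsi && abs(dpg) >= params$min_dpsi_glob
    if (params$require_positive) called <- called && dpt > 0
    res[[table$events$event_id[i]]] <- called
  }
  res
}

# Exhaustive hypergeometric enumeration of the two-sided Fisher p for a 2x2
# table: sum of probabilities of all tables (same margins) no more probable
# than the observed one.
enum_fisher_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(a_range, r1, r2, c1)
  p_obs <- dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Activity trace with one constant level per minute over the full protocol
# (including the tap block span).
step_trace <- function(levels_by_minute, total_min = 91L) {
  stopifnot(length(levels_by_minute) == total_min)
  data.frame(time_s = 0:(total_min * 60L - 1L),
             activity = rep(levels_by_minute, each = 60L))
}

# Per-larva zone table with a fixed periphery TDM share per minute.
zone_fixture <- function(periphery_share, tdm_total = 10,
                         activity_total = 5, minutes = 0:90) {
  data.frame(
    minute = rep(minutes, 2L),
    zone = rep(c("periphery", "center"), each = length(minutes)),
    tdm_mm = c(rep(tdm_total * periphery_share, length(minutes)),
               rep(tdm_total * (1 - periphery_share), length(minutes))),
    activity_pct = rep(activity_total / 2, 2L * length(minutes)))
}

# Uniform circular motion positions.
circle_positions <- function(v, r, fps, n) {
  omega <- v / r
  t <- (seq_len(n) - 1L) / fps
  cbind(r * cos(omega * t), r * sin(omega * t))
}

# Brute-force running-sum enrichment score: explicit prefix loop computing
# the weighted hit CDF minus the miss CDF at every position.
brute_es <- function(scores, set, weight = 1, positive_only = FALSE) {
  ord <- order(scores, names(scores), decreasing = c(TRUE, FALSE),
               method = "radix")
  scores <- scores[ord]
  inset <- names(scores) %in% set
  N <- length(scores)
  denom <- sum(abs(scores[inset])^weight)
  n_miss <- N - sum(inset)
  dev <- numeric(N)
  for (i in seq_len(N)) {
    hits <- sum(abs(scores[seq_len(i)][inset[seq_len(i)]])^weight) / denom
    miss <- sum(!inset[seq_len(i)]) / n_miss
    dev[i] <- hits - miss
  }
  if (positive_only) return(max(dev))
  if (max(dev) >= -min(dev)) max(dev) else min(dev)
}

rotate2 <- function(pos, angle) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  pos %*% t(R)
}
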