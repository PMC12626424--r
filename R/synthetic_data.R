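#' @title Seeded synthetic-data generators
#' @name synthetic_data
#' @description
#' Generators producing inputs with the statistical structure each analysis
#' stage assumes: PSI tables with planted neural-enriched events, larval
#' activity experiments with genotype effect multipliers, fish-pair
#' trajectories with a tunable leader-follower coupling, and negative-
#' binomial count matrices with planted pathway shifts. Every generator is
#' deterministic in the configuration (including its seed), with one RNG
#' stream per generated entity (event/larva/fish/gene) so that subsetting
#' entities never changes the others.
NULL

#' Simulation configuration
#'
#' @param seed Master RNG seed (integer).
#' @param n_events Number of splicing events for [gen_psi_table()].
#' @param n_tissue_groups Number of tissue groups (first is `Neural`).
#' @param n_samples_per_group Samples per tissue group.
#' @param neural_fraction Proportion of events planted as neural-enriched.
#' @param dpsi_effect Planted PSI enrichment of neural events (PSI units).
#' @param coverage_dropout Per-cell probability of insufficient coverage (`N`).
#' @param n_larvae_per_genotype Larvae per genotype for
#'   [gen_activity_experiment()].
#' @param tap_count Taps in the startle block (default 30).
#' @param fps Trajectory frame rate (default 30).
#' @param arena_radius_cm Arena radius (default 21: a 42 cm diameter tank).
#' @param follow_gain Leader-follower coupling for
#'   [gen_pair_trajectories()], >= 0 (0 = independent fish).
#' @param n_frames Trajectory frames (default 18000: 10 min at 30 fps).
#' @param n_genes,n_lines Genes and deletion lines for
#'   [gen_expression_counts()].
#' @param pathway_shift Planted log2 shift of the pathway gene set.
#' @param dispersion Negative-binomial dispersion (1/size).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_events = 60L, n_tissue_groups = 6L,
                       n_samples_per_group = 3L, neural_fraction = 0.25,
                       dpsi_effect = 40, coverage_dropout = 0.05,
                       n_larvae_per_genotype = 12L, tap_count = 30L,
                       fps = 30, arena_radius_cm = 21, follow_gain = 0,
                       n_frames = 18000L, n_genes = 2000L, n_lines = 6L,
                       pathway_shift = 0, dispersion = 0.1) {
  stopifnot_scalar_number(seed, "seed", min = 0, max = 2^31 - 1)
  for (nm in c("n_events", "n_tissue_groups", "n_samples_per_group",
               "n_larvae_per_genotype", "tap_count", "n_frames",
               "n_genes", "n_lines")) {
    stopifnot_scalar_number(get(nm), nm, min = 1)
  }
  stopifnot_scalar_number(neural_fraction, "neural_fraction", 0, 1)
  stopifnot_scalar_number(coverage_dropout, "coverage_dropout", 0, 1)
  stopifnot_scalar_number(fps, "fps", min = 1e-9)
  stopifnot_scalar_number(arena_radius_cm, "arena_radius_cm", min = 1e-9)
  stopifnot_scalar_number(follow_gain, "follow_gain", min = 0)
  stopifnot_scalar_number(dispersion, "dispersion", min = 1e-9)
  structure(as.list(environment())[c(
    "seed", "n_events", "n_tissue_groups", "n_samples_per_group",
    "neural_fraction", "dpsi_effect", "coverage_dropout",
    "n_larvae_per_genotype", "tap_count", "fps", "arena_radius_cm",
    "follow_gain", "n_frames", "n_genes", "n_lines", "pathway_shift",
    "dispersion")], class = "sim_config")
}

OK_QUALITIES <- c("VLOW", "LOW", "OK", "SOUND")

#' Generate a PSI table with planted neural-enriched events
#'
#' Events are split into planted neural-enriched events (neural-group PSI
#' equals the other-tissue base plus `dpsi_effect`), non-enriched events, and
#' a low-coverage class (covered in fewer tissue groups than the default
#' eligibility requires). Per-cell quality codes are sampled with probability
#' `coverage_dropout` of insufficient coverage.
#'
#' @param config A [sim_config()].
#' @param psi_noise_sd Per-cell PSI noise SD (default 2).
#' @param low_coverage_fraction Fraction of events planted as low-coverage
#'   (default 0.1).
#' @return List with `table` (a [psi_table()]), `config_table` (sample-to-
#'   group data.frame with empty `excluded` column), and `truth` (data.frame
#'   `event_id`, `label` in `neural`/`null`/`low_coverage`).
#' @export
gen_psi_table <- function(config, psi_noise_sd = 2,
                          low_coverage_fraction = 0.1) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_tissue_groups < 5L) {
    warning("fewer than 5 tissue groups: default calling parameters ",
            "(n_groups = 5) will return no eligible event", call. = FALSE)
  }
  groups <- c("Neural",
              paste0("Tissue", seq_len(config$n_tissue_groups - 1L)))
  samples <- paste0(rep(groups, each = config$n_samples_per_group), "_",
                    seq_len(config$n_samples_per_group))
  sample_group <- rep(groups, each = config$n_samples_per_group)
  n <- config$n_events
  label <- character(n)
  psi <- matrix(NA_real_, n, length(samples))
  qual <- matrix("N", n, length(samples))
  lengths_nt <- integer(n)
  for (i in seq_len(n)) {
    # everything about event i, including its class, comes from its own
    # stream, so generating more events never changes earlier ones
    e <- with_seed(child_seed(config$seed, i), {
      u <- stats::runif(1)
      lab <- if (u < low_coverage_fraction) "low_coverage"
             else if (u < low_coverage_fraction +
                        (1 - low_coverage_fraction) * config$neural_fraction)
               "neural"
             else "null"
      len <- sample(c(sample(3:27, 1), sample(28:51, 1), sample(52:300, 1)),
                    1)
      base <- stats::runif(1, 5, 55)
      mu <- rep(base, length(samples))
      if (lab == "neural") {
        mu[sample_group == "Neural"] <-
          min(base + config$dpsi_effect, 100)
      }
      x <- pmin(100, pmax(0, mu + stats::rnorm(length(samples),
                                               sd = psi_noise_sd)))
      q <- sample(OK_QUALITIES, length(samples), replace = TRUE)
      drop <- stats::runif(length(samples)) < config$coverage_dropout
      if (lab == "low_coverage") {
        # additionally uncovered outside 2 tissue groups: too few for
        # default eligibility
        keep_groups <- sample(groups, min(2L, length(groups)))
        drop <- drop | !(sample_group %in% keep_groups)
      }
      q[drop] <- "N"
      x[drop] <- NA_real_
      list(lab = lab, len = len, x = x, q = q)
    })
    label[i] <- e$lab
    lengths_nt[i] <- e$len
    psi[i, ] <- e$x
    qual[i, ] <- e$q
  }
  ids <- sprintf("EV%04d", seq_len(n))
  events <- data.frame(event_id = ids, gene_id = sprintf("G%04d", seq_len(n)),
                       exon_length_nt = lengths_nt)
  colnames(psi) <- colnames(qual) <- samples
  list(
    table = psi_table(events, psi, qual),
    config_table = data.frame(sample = samples, group = sample_group,
                              excluded = ""),
    truth = data.frame(event_id = ids, label = label)
  )
}

#' Generate a larval activity experiment
#'
#' Per-larva 1 Hz activity over the full protocol (habituation, baseline,
#' three dark / two light blocks, re-habituation, taps), with zero-inflated
#' gamma noise per second, plus per-minute per-zone distance series. Genotype
#' effects are injected as multipliers on the baseline level, the dark-light
#' transition amplitude, and the tap response decay.
#'
#' @param config A [sim_config()].
#' @param baseline_mult,transition_mult Named multipliers per genotype
#'   (`WT`, `Het`, `Del`) on the light-period activity level and on the
#'   dark-minus-light gap.
#' @param tap_decay Named per-genotype per-tap geometric decay of the startle
#'   response (1 = no habituation).
#' @param light_level Mean light/baseline activity (%delta pixels; default 10).
#' @param dark_gap Dark-minus-light activity gap before multipliers
#'   (default 5).
#' @param tap_amp Response to tap 1 (default 20).
#' @param periphery_bias Expected periphery share of distance moved
#'   (default 0.65).
#' @param zero_inflation Probability of an immobile second (default 0.3).
#' @return List with `traces` (larva_id, genotype, time_s, activity),
#'   `zones` (larva_id, genotype, minute, zone, tdm_mm, activity_pct) and
#'   `protocol`.
#' @export
gen_activity_experiment <- function(config,
                                    baseline_mult = c(WT = 1, Het = 1, Del = 1),
                                    transition_mult = c(WT = 1, Het = 1, Del = 1),
                                    tap_decay = c(WT = 0.85, Het = 0.85, Del = 0.85),
                                    light_level = 10, dark_gap = 5,
                                    tap_amp = 20, periphery_bias = 0.65,
                                    zero_inflation = 0.3) {
  stopifnot(inherits(config, "sim_config"))
  protocol <- default_protocol(config$tap_count)
  n_sec <- protocol$total_min * 60L
  time_s <- seq_len(n_sec) - 1L
  minute <- floor(time_s / 60)
  dark_min <- block_minutes(protocol$dark_blocks)
  genos <- rep(c("WT", "Het", "Del"), each = config$n_larvae_per_genotype)
  shape <- 2

  traces <- vector("list", length(genos))
  zones <- vector("list", length(genos))
  for (i in seq_along(genos)) {
    g <- genos[i]
    sim <- with_seed(child_seed(config$seed, 1000L + i), {
      level <- rep(light_level * baseline_mult[[g]], n_sec)
      level[minute %in% dark_min] <- light_level * baseline_mult[[g]] +
        dark_gap * transition_mult[[g]]
      zero <- stats::runif(n_sec) < zero_inflation
      act <- ifelse(zero, 0,
                    stats::rgamma(n_sec, shape = shape,
                                  scale = level / ((1 - zero_inflation) * shape)))
      taps <- match(protocol$tap_times_s, time_s)
      act[taps] <- tap_amp * tap_decay[[g]]^(seq_along(taps) - 1L) *
        (1 + 0.05 * stats::rnorm(length(taps)))
      act <- pmax(act, 0)
      mm <- tapply(act, minute, mean)
      tdm <- 50 * mm * (1 + 0.02 * stats::rnorm(length(mm)))
      tdm <- pmax(tdm, 0)
      peri <- pmin(1, pmax(0, periphery_bias +
                                0.05 * stats::rnorm(length(mm))))
      list(act = act, mm = mm, tdm = tdm, peri = peri)
    })
    id <- sprintf("larva_%s_%02d", g, ((i - 1L) %%
                                         config$n_larvae_per_genotype) + 1L)
    traces[[i]] <- data.frame(larva_id = id, genotype = g, time_s = time_s,
                              activity = sim$act)
    mins <- as.integer(names(sim$mm))
    zones[[i]] <- data.frame(
      larva_id = id, genotype = g,
      minute = rep(mins, 2L),
      zone = rep(c("periphery", "center"), each = length(mins)),
      tdm_mm = c(sim$tdm * sim$peri, sim$tdm * (1 - sim$peri)),
      activity_pct = c(sim$mm * sim$peri, sim$mm * (1 - sim$peri))
    )
  }
  list(traces = do.call(rbind, traces), zones = do.call(rbind, zones),
       protocol = protocol)
}

wrap_angle <- function(a) ((a + pi) %% (2 * pi)) - pi

#' Generate a fish-pair trajectory
#'
#' Fish 1 performs a correlated random walk (Ornstein-Uhlenbeck heading
#' noise, near-constant speed); fish 2's heading additionally relaxes toward
#' fish 1's position with strength `follow_gain` (0 = independent). Positions
#' are contained in the circular arena: a step that would exit is placed on
#' the wall and the heading reversed with jitter.
#'
#' @param config A [sim_config()] (uses `fps`, `arena_radius_cm`,
#'   `follow_gain`, `n_frames`, `seed`).
#' @param speed_cms Mean swim speed (default 3 cm/s).
#' @param heading_noise_sd Per-step heading noise SD in radians at 1 s
#'   timescale (default 1.5).
#' @param genotypes Length-2 genotype labels (default `c("Het", "Del")`,
#'   fish 1 = leader).
#' @param pair_id Identifier carried through to [pair_metrics()].
#' @return Pair object: list with `positions` (two n x 2 matrices), `fps`,
#'   `genotypes`, `arena`, `pair_id`.
#' @export
gen_pair_trajectories <- function(config, speed_cms = 3,
                                  heading_noise_sd = 1.5,
                                  genotypes = c("Het", "Del"),
                                  pair_id = "pair1") {
  stopifnot(inherits(config, "sim_config"))
  R <- config$arena_radius_cm
  dt <- 1 / config$fps
  n <- config$n_frames
  step_sd <- heading_noise_sd * sqrt(dt)

  walk <- function(fish_seed, target = NULL) {
    with_seed(fish_seed, {
      pos <- matrix(NA_real_, n, 2)
      r0 <- R * sqrt(stats::runif(1)) * 0.9
      a0 <- stats::runif(1, -pi, pi)
      p <- c(r0 * cos(a0), r0 * sin(a0))
      theta <- stats::runif(1, -pi, pi)
      noise <- stats::rnorm(n, sd = step_sd)
      for (t in seq_len(n)) {
        if (!is.null(target)) {
          bearing <- atan2(target[t, 2] - p[2], target[t, 1] - p[1])
          theta <- theta +
            wrap_angle(bearing - theta) * min(1, config$follow_gain * dt)
        }
        theta <- theta + noise[t]
        p_new <- p + speed_cms * dt * c(cos(theta), sin(theta))
        if (sqrt(sum(p_new^2)) > R) {
          p_new <- p_new * (R / sqrt(sum(p_new^2)))
          theta <- theta + pi + 0.1 * noise[t] / step_sd * 0.05
        }
        p <- p_new
        pos[t, ] <- p
      }
      pos
    })
  }
  p1 <- walk(child_seed(config$seed, 7001L))
  p2 <- walk(child_seed(config$seed, 7002L), target = p1)
  list(positions = list(p1, p2), fps = config$fps, genotypes = genotypes,
       arena = arena(c(0, 0), R), pair_id = pair_id)
}

#' Generate per-line expression count matrices
#'
#' Negative-binomial WT and Del counts for each deletion line, with a planted
#' gene set shifted by `pathway_shift` (log2 units) in half of the lines
#' (alternating up/down by line), and injectable host-gene and paralog shifts.
#'
#' @param config A [sim_config()] (uses `n_genes`, `n_lines`, `dispersion`,
#'   `pathway_shift`, `seed`).
#' @param n_reps Replicates per genotype per line (default 2).
#' @param planted_set_size Genes in the planted pathway (default
#'   `min(50, n_genes %/% 10)`).
#' @param host_shift Log2 shift of each line's host gene in its own Del
#'   samples (default 0; deletions typically reduce the host, e.g. -1.5).
#' @param paralog_shift Log2 shift of each line's paralog gene (default 0).
#' @param batch_effect Log2 offset applied to all genes of batch `b2`
#'   samples (two batches assigned alternately; default 0).
#' @return List with `counts` (gene x sample), `sample_info` (sample, line,
#'   genotype, batch), `planted_set`, `shifted_lines` (named direction
#'   vector), `hosts`, `paralogs`.
#' @export
gen_expression_counts <- function(config, n_reps = 2L,
                                  planted_set_size = NULL,
                                  host_shift = 0, paralog_shift = 0,
                                  batch_effect = 0) {
  stopifnot(inherits(config, "sim_config"))
  ng <- config$n_genes
  nl <- config$n_lines
  genes <- sprintf("g%05d", seq_len(ng))
  lines <- sprintf("line%02d", seq_len(nl))
  k <- planted_set_size %||% min(50L, max(5L, ng %/% 10L))
  planted <- genes[seq_len(k)]
  n_shift <- ceiling(nl / 2)
  shifted_lines <- stats::setNames(
    rep_len(c(1, -1), n_shift), lines[seq_len(n_shift)])
  hosts <- stats::setNames(genes[ng - seq_len(nl) + 1L], lines)
  paralogs <- stats::setNames(as.list(genes[ng - nl - seq_len(nl) + 1L]),
                              lines)

  sample_info <- do.call(rbind, lapply(lines, function(l) {
    data.frame(sample = paste0(l, "_", rep(c("WT", "Del"), each = n_reps),
                               "_", seq_len(n_reps)),
               line = l,
               genotype = rep(c("WT", "Del"), each = n_reps))
  }))
  sample_info$batch <- rep_len(c("b1", "b2"), nrow(sample_info))

  base_log2 <- with_seed(child_seed(config$seed, 3L),
                         stats::runif(ng, 4, 11))
  # per-sample log2 mean offsets
  lfc <- matrix(0, ng, nrow(sample_info),
                dimnames = list(genes, sample_info$sample))
  for (l in names(shifted_lines)) {
    sel <- sample_info$line == l & sample_info$genotype == "Del"
    lfc[planted, sel] <- lfc[planted, sel] +
      shifted_lines[[l]] * config$pathway_shift
  }
  for (l in lines) {
    sel <- sample_info$line == l & sample_info$genotype == "Del"
    lfc[hosts[[l]], sel] <- lfc[hosts[[l]], sel] + host_shift
    lfc[paralogs[[l]][1], sel] <- lfc[paralogs[[l]][1], sel] + paralog_shift
  }
  lfc[, sample_info$batch == "b2"] <-
    lfc[, sample_info$batch == "b2"] + batch_effect

  counts <- matrix(0L, ng, nrow(sample_info),
                   dimnames = list(genes, sample_info$sample))
  size <- 1 / config$dispersion
  for (gi in seq_len(ng)) {
    counts[gi, ] <- with_seed(child_seed(config$seed, 20000L + gi), {
      mu <- 2^(base_log2[gi] + lfc[gi, ])
      stats::rnbinom(nrow(sample_info), mu = mu, size = size)
    })
  }
  list(counts = counts, sample_info = sample_info, planted_set = planted,
       shifted_lines = shifted_lines, hosts = hosts, paralogs = paralogs)
}
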