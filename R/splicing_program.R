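#' @title Neural exon and microexon program calling from PSI tables
#' @name splicing_program
#' @description
#' Tissue-enriched alternative exons are called from a percent-spliced-in
#' (PSI) matrix with per-cell coverage-quality codes, following the two-
#' threshold scheme used for inclusion-table screens: a target-vs-tissue-means
#' difference and a target-vs-pooled-samples ("global") difference, subject to
#' coverage eligibility across tissue groups.
NULL

QUALITY_LEVELS <- c("N", "VLOW", "LOW", "OK", "SOUND")

quality_rank <- function(q) {
  match(q, QUALITY_LEVELS) - 1L  # N -> 0, SOUND -> 4
}

#' Construct a PSI table
#'
#' @param events data.frame with columns `event_id`, `gene_id`,
#'   `exon_length_nt` (positive integers >= 3).
#' @param psi Numeric matrix (events x samples) of PSI values in \[0, 100\];
#'   `NA` allowed. Rownames must match `events$event_id`.
#' @param quality Character matrix, same dimensions, of coverage codes among
#'   `N`, `VLOW`, `LOW`, `OK`, `SOUND`. A PSI value whose quality is `N` is
#'   treated as missing.
#' @return An object of class `psi_table`.
#' @export
psi_table <- function(events, psi, quality) {
  stopifnot(is.data.frame(events),
            all(c("event_id", "gene_id", "exon_length_nt") %in% names(events)),
            is.matrix(psi), is.matrix(quality),
            all(dim(psi) == dim(quality)),
            nrow(psi) == nrow(events))
  if (any(!is.na(psi) & (psi < 0 | psi > 100))) {
    stop("PSI values must lie in [0, 100]", call. = FALSE)
  }
  if (!all(quality %in% QUALITY_LEVELS)) {
    stop("quality codes must be one of ", paste(QUALITY_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  rownames(psi) <- rownames(quality) <- events$event_id
  # PSI present with quality N is treated as missing
  psi[quality == "N"] <- NA_real_
  structure(list(events = events, psi = psi, quality = quality),
            class = "psi_table")
}

#' @export
print.psi_table <- function(x, ...) {
  cat(sprintf("psi_table: %d events x %d samples\n",
              nrow(x$psi), ncol(x$psi)))
  invisible(x)
}

#' Calling parameters for tissue-enriched exons
#'
#' Defaults mirror the standard inclusion-table screen: target-vs-tissue-mean
#' |dPSI| >= 15, global |dPSI| >= 25, a valid average PSI in at least 5 tissue
#' groups, and at least 1 sufficiently covered sample (VLOW or better) per
#' valid group.
#'
#' @param min_dpsi Minimum |target - mean of other group means| (PSI units).
#' @param min_dpsi_glob Minimum |target - pooled other-sample mean|.
#' @param n_groups Minimum number of valid tissue groups for eligibility.
#' @param min_rep Minimum covered samples per valid group.
#' @param min_quality Minimum coverage code (ordinal; default `VLOW`).
#' @param require_positive Require target enrichment (dpsi_target > 0), not
#'   mere difference; default `TRUE` for neural-enriched calls.
#' @return A list of class `calling_params`.
#' @export
calling_params <- function(min_dpsi = 15, min_dpsi_glob = 25, n_groups = 5L,
                           min_rep = 1L, min_quality = "VLOW",
                           require_positive = TRUE) {
  stopifnot_scalar_number(min_dpsi, "min_dpsi", min = 0)
  stopifnot_scalar_number(min_dpsi_glob, "min_dpsi_glob", min = 0)
  stopifnot_scalar_number(n_groups, "n_groups", min = 2)
  stopifnot_scalar_number(min_rep, "min_rep", min = 1)
  if (!min_quality %in% QUALITY_LEVELS) stop("invalid min_quality", call. = FALSE)
  structure(list(min_dpsi = min_dpsi, min_dpsi_glob = min_dpsi_glob,
                 n_groups = as.integer(n_groups), min_rep = as.integer(min_rep),
                 min_quality = min_quality,
                 require_positive = isTRUE(require_positive)),
            class = "calling_params")
}

#' Classify exon length
#'
#' Microexons are 3-27 nt; mid-size exons 28-51 nt; longer exons > 51 nt.
#' Lengths below 3 nt fall under the defined microexon range and are rejected.
#'
#' @param length_nt Vector of positive integer exon lengths (nt).
#' @return Factor with levels `micro_3_27`, `mid_28_51`, `long_gt51`.
#' @export
classify_exon_length <- function(length_nt) {
  if (!is.numeric(length_nt) || any(is.na(length_nt)) || any(length_nt < 1)) {
    stop("exon lengths must be positive integers", call. = FALSE)
  }
  if (any(length_nt < 3)) {
    stop("exon length below 3 nt: outside the defined microexon range",
         call. = FALSE)
  }
  cls <- ifelse(length_nt <= 27, "micro_3_27",
                ifelse(length_nt <= 51, "mid_28_51", "long_gt51"))
  factor(cls, levels = c("micro_3_27", "mid_28_51", "long_gt51"))
}

#' Call tissue-enriched exons
#'
#' For each event, per-group mean PSI is computed from samples whose coverage
#' code is at least `min_quality`; a group is valid when it has at least
#' `min_rep` such samples. An event is eligible when at least `n_groups`
#' groups are valid. Groups listed in the config's `excluded` column for the
#' target group are dropped from both eligibility counting and comparison
#' means. The event is called when |dpsi_target| >= `min_dpsi` and
#' |dpsi_global| >= `min_dpsi_glob` (and, by default, dpsi_target > 0:
#' enrichment, not depletion).
#'
#' dpsi_target is the target-group mean minus the unweighted mean of the other
#' valid group means (each tissue counts once); dpsi_global is the target mean
#' minus the mean over all pooled other covered samples.
#'
#' @param table A [psi_table()].
#' @param config data.frame with columns `sample`, `group`, and optionally
#'   `excluded` (comma-separated target groups for which this sample's group
#'   is dropped from the comparison).
#' @param params A [calling_params()].
#' @param target_group Target tissue group (e.g. `"Neural"`).
#' @return data.frame with one row per eligible event: `event_id`,
#'   `length_class`, `dpsi_target`, `dpsi_global`, `n_valid_groups`, `called`.
#' @export
call_tissue_enriched <- function(table, config,
                                 params = calling_params(),
                                 target_group) {
  stopifnot(inherits(table, "psi_table"), inherits(params, "calling_params"))
  if (!all(c("sample", "group") %in% names(config))) {
    stop("config needs columns `sample` and `group`", call. = FALSE)
  }
  if (is.null(config$excluded)) config$excluded <- ""
  config$excluded[is.na(config$excluded)] <- ""
  if (!target_group %in% config$group) {
    stop(sprintf("no samples for target group '%s'", target_group),
         call. = FALSE)
  }
  if (nrow(table$psi) == 0L) {
    return(data.frame(event_id = character(), length_class = character(),
                      dpsi_target = numeric(), dpsi_global = numeric(),
                      n_valid_groups = integer(), called = logical()))
  }

  config <- config[match(colnames(table$psi), config$sample), , drop = FALSE]
  if (anyNA(config$sample)) {
    stop("every PSI sample column must appear in the group config",
         call. = FALSE)
  }
  # drop samples whose group is excluded for this target (the target itself
  # is never dropped)
  excl_sets <- strsplit(config$excluded, ",[ ]*")
  dropped <- vapply(excl_sets, function(s) target_group %in% s, logical(1)) &
    config$group != target_group
  keep <- !dropped
  groups <- config$group[keep]
  qual_ok <- quality_rank(table$quality[, keep, drop = FALSE]) >=
    quality_rank(params$min_quality)
  psi <- table$psi[, keep, drop = FALSE]
  valid <- qual_ok & !is.na(psi)

  group_ids <- sort(unique(groups))
  res <- lapply(seq_len(nrow(psi)), function(i) {
    v <- valid[i, ]
    x <- psi[i, ]
    gmeans <- vapply(group_ids, function(g) {
      sel <- v & groups == g
      if (sum(sel) >= params$min_rep) mean(x[sel]) else NA_real_
    }, numeric(1))
    n_valid <- sum(!is.na(gmeans))
    if (n_valid < params$n_groups || is.na(gmeans[target_group])) return(NULL)
    other <- setdiff(group_ids, target_group)
    other_means <- gmeans[other]
    dpsi_target <- gmeans[[target_group]] - mean(other_means, na.rm = TRUE)
    pooled_sel <- v & groups != target_group &
      groups %in% other[!is.na(other_means)]
    dpsi_global <- gmeans[[target_group]] - mean(x[pooled_sel])
    called <- abs(dpsi_target) >= params$min_dpsi &&
      abs(dpsi_global) >= params$min_dpsi_glob &&
      (!params$require_positive || dpsi_target > 0)
    data.frame(event_id = table$events$event_id[i],
               dpsi_target = dpsi_target, dpsi_global = dpsi_global,
               n_valid_groups = n_valid, called = called)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(event_id = character(), length_class = character(),
                      dpsi_target = numeric(), dpsi_global = numeric(),
                      n_valid_groups = integer(), called = logical()))
  }
  out$length_class <- classify_exon_length(
    table$events$exon_length_nt[match(out$event_id, table$events$event_id)])
  out[, c("event_id", "length_class", "dpsi_target", "dpsi_global",
          "n_valid_groups", "called")]
}

#' Classify regulator response of an exon
#'
#' Given dPSI values of the exon across mutant-vs-control comparisons (e.g.
#' srrm3 retina, srrm3/4 larva), the lowest dPSI is selected; the exon is
#' `affected` when that minimum is below -15, `not_affected` otherwise, and
#' `no_coverage` when no comparison had coverage.
#'
#' @param deltas Numeric vector of dPSI values (possibly named by comparison),
#'   `NA` for comparisons without coverage; may be empty.
#' @return List with `min_delta_psi` and `class`.
#' @export
classify_regulator_response <- function(deltas) {
  deltas <- deltas[!is.na(deltas)]
  if (length(deltas) == 0L) {
    return(list(min_delta_psi = NA_real_, class = "no_coverage"))
  }
  m <- min(deltas)
  list(min_delta_psi = m,
       class = if (m < -15) "affected" else "not_affected")
}

#' Classify cross-species regulatory conservation of an exon
#'
#' @param has_ortholog Logical: does the exon have an exon ortholog in the
#'   target species?
#' @param target_dpsi Neural dPSI of the ortholog in the target species, or
#'   `NA` when it lacks read coverage there.
#' @return One of `no_event_ortholog`, `no_coverage_in_target`,
#'   `regulatory_conserved` (ortholog covered with dPSI >= 15), `genomic_only`.
#' @export
classify_conservation <- function(has_ortholog, target_dpsi = NA_real_) {
  if (!isTRUE(has_ortholog)) return("no_event_ortholog")
  if (is.na(target_dpsi)) return("no_coverage_in_target")
  if (target_dpsi >= 15) "regulatory_conserved" else "genomic_only"
}

#' Length-class association test
#'
#' Two-sided Fisher's exact test on a 2x2 contingency table (e.g. regulated vs
#' non-regulated microexons against long exons), with the odds ratio reported
#' as the sample cross-product (a*d)/(b*c), `Inf` when b*c = 0.
#'
#' @param table_2x2 2x2 matrix of non-negative counts; both margins must be
#'   positive.
#' @return List with `odds_ratio` and `p` (two-sided exact).
#' @export
length_class_association <- function(table_2x2) {
  m <- as.matrix(table_2x2)
  if (!all(dim(m) == c(2L, 2L)) || any(m < 0)) {
    stop("need a 2x2 table of non-negative counts", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("both margins must be positive", call. = FALSE)
  }
  or <- if (m[1, 2] * m[2, 1] == 0) Inf else
    (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  list(odds_ratio = or, p = stats::fisher.test(m)$p.value)
}

#' Group-mean imputation of missing PSI (plotting only)
#'
#' Replaces missing PSI cells by their tissue-group mean for that event (grand
#' event mean when the whole group is missing). Intended for heatmap display;
#' the calling path never imputes.
#'
#' @param table A [psi_table()].
#' @param config Sample-to-group config (as in [call_tissue_enriched()]).
#' @return Numeric PSI matrix with imputed values.
#' @export
impute_psi_for_plotting <- function(table, config) {
  psi <- table$psi
  groups <- config$group[match(colnames(psi), config$sample)]
  for (i in seq_len(nrow(psi))) {
    x <- psi[i, ]
    for (g in unique(groups)) {
      sel <- groups == g
      miss <- sel & is.na(x)
      if (any(miss)) {
        fill <- if (any(sel & !is.na(x))) mean(x[sel], na.rm = TRUE)
                else mean(x, na.rm = TRUE)
        x[miss] <- fill
      }
    }
    psi[i, ] <- x
  }
  psi
}
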