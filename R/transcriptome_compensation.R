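#' @title Cross-line transcriptomic compensation analysis
#' @name transcriptome_compensation
#' @description
#' Per-line Del-WT differential expression on a variance-stabilized scale,
#' WT-fitted batch adjustment, host-gene/paralog decile flags, cross-line
#' joint ranking, preranked permutation GSEA and Jaccard clustering of
#' enriched GO terms.
NULL

#' Degradation-correction hook
#'
#' Identity pass-through accepting externally degradation-corrected counts.
#' Transcript-degradation normalization itself is out of scope; supply
#' corrected counts here if you have them.
#'
#' @param counts Gene x sample count matrix (already corrected or raw).
#' @return `counts`, unchanged.
#' @export
degradation_hook <- function(counts) counts

#' Variance-stabilizing normalization of counts
#'
#' Size factors by the median-of-ratios method (per-sample median of
#' count-to-geometric-mean-reference ratios over genes expressed in all
#' samples), then `log2(count / size_factor + pseudocount)`. This is a
#' log-scale approximation of a variance-stabilizing transform; downstream
#' statistics use only differences of these values.
#'
#' @param counts Non-negative integer gene x sample matrix; every sample must
#'   have a positive total.
#' @param pseudocount Added inside the log (default 1).
#' @param reference Optional per-gene reference profile (geometric means) to
#'   take ratios against; by default computed from `counts`. Supplying a
#'   fixed reference makes the transform exactly equivariant to per-sample
#'   count scaling.
#' @return List with `stabilized` (matrix, same dim) and `size_factors`.
#' @export
stabilize <- function(counts, pseudocount = 1, reference = NULL) {
  counts <- as.matrix(counts)
  if (any(colSums(counts) <= 0)) {
    stop("every sample needs a positive total count", call. = FALSE)
  }
  loggeo <- if (is.null(reference)) rowMeans(log(counts)) else log(reference)
  ref_ok <- is.finite(loggeo)
  if (!any(ref_ok)) stop("no gene expressed in all samples", call. = FALSE)
  sf <- apply(counts, 2, function(cnts) {
    exp(stats::median(log(cnts[ref_ok]) - loggeo[ref_ok]))
  })
  stabilized <- log2(sweep(counts, 2, sf, "/") + pseudocount)
  list(stabilized = stabilized, size_factors = sf)
}

#' WT-fitted empirical-Bayes batch adjustment
#'
#' Per-gene batch offsets are estimated from WT samples only (deviation of
#' each batch's WT mean from the WT grand mean), shrunk toward zero by an
#' empirical-Bayes factor estimated from the across-gene distribution of
#' batch offsets (shrinkage grows as offsets become indistinguishable from
#' sampling noise), and subtracted from all samples of the batch — so
#' genotype effects confounded with batch are never removed.
#'
#' @param x Stabilized gene x sample matrix.
#' @param batch Batch label per sample.
#' @param wt_mask Logical per sample, `TRUE` for WT samples. Every batch must
#'   contain at least one WT sample.
#' @return Adjusted matrix, same dimensions.
#' @export
batch_adjust <- function(x, batch, wt_mask) {
  x <- as.matrix(x)
  batch <- as.character(batch)
  stopifnot(length(batch) == ncol(x), length(wt_mask) == ncol(x))
  batches <- unique(batch)
  if (length(batches) < 2L) stop("need >= 2 batches", call. = FALSE)
  if (any(!batches %in% batch[wt_mask])) {
    stop("every batch needs at least one WT sample", call. = FALSE)
  }
  wt <- x[, wt_mask, drop = FALSE]
  wt_batch <- batch[wt_mask]
  grand <- rowMeans(wt)
  out <- x
  for (b in batches) {
    sel <- wt_batch == b
    n_b <- sum(sel)
    dev <- rowMeans(wt[, sel, drop = FALSE]) - grand
    # noise variance of a batch-mean deviation, from within-batch WT spread
    if (n_b > 1L) {
      within <- mean(apply(wt[, sel, drop = FALSE], 1, stats::var))
      noise <- within / n_b
    } else {
      noise <- 0
    }
    # prior on batch offsets is centered at zero, so shrink by the ratio of
    # sampling noise to the across-gene mean square (not the variance, which
    # would be blind to a constant offset)
    total <- mean(dev^2)
    shrink <- if (total > 0) max(0, 1 - noise / total) else 0
    out[, batch == b] <- out[, batch == b, drop = FALSE] - shrink * dev
  }
  out
}

#' Per-line Del - WT expression differences
#'
#' For each deletion line, the per-gene mean of adjusted Del samples minus
#' the mean of adjusted WT samples.
#'
#' @param adjusted Stabilized (and batch-adjusted) gene x sample matrix.
#' @param sample_info data.frame with columns `sample`, `line`, `genotype`
#'   (`WT`/`Del`) covering the matrix columns.
#' @return Gene x line matrix of differences.
#' @export
delta_expression <- function(adjusted, sample_info) {
  stopifnot(all(c("sample", "line", "genotype") %in% names(sample_info)))
  info <- sample_info[match(colnames(adjusted), sample_info$sample), ]
  lines <- unique(info$line)
  delta <- vapply(lines, function(l) {
    del <- info$line == l & info$genotype == "Del"
    wt <- info$line == l & info$genotype == "WT"
    if (!any(del) || !any(wt)) {
      stop(sprintf("line '%s' needs both WT and Del samples", l),
           call. = FALSE)
    }
    rowMeans(adjusted[, del, drop = FALSE]) -
      rowMeans(adjusted[, wt, drop = FALSE])
  }, numeric(nrow(adjusted)))
  rownames(delta) <- rownames(adjusted)
  delta
}

#' Host-gene and paralog decile report
#'
#' For each line, the percentile of the host gene's (and each paralog's)
#' expression difference within that line's full difference distribution;
#' flagged when in the bottom or top decile (<= 10th or >= 90th percentile).
#'
#' @param delta Gene x line difference matrix.
#' @param hosts Named character vector: line -> host gene id.
#' @param paralogs Optional named list: line -> character vector of paralog
#'   gene ids (absent paralogs are skipped).
#' @return data.frame with `line`, `gene`, `role` (`host`/`paralog`),
#'   `delta`, `percentile`, `flagged`.
#' @export
host_paralog_report <- function(delta, hosts, paralogs = NULL) {
  rows <- list()
  for (l in names(hosts)) {
    d <- delta[, l]
    entry <- function(gene, role) {
      if (role == "host" && !gene %in% rownames(delta)) {
        stop(sprintf("host gene '%s' absent from the matrix", gene),
             call. = FALSE)
      }
      if (!gene %in% rownames(delta)) return(NULL)
      pct <- 100 * mean(d <= d[[gene]])
      data.frame(line = l, gene = gene, role = role, delta = d[[gene]],
                 percentile = pct, flagged = pct <= 10 | pct >= 90)
    }
    rows[[length(rows) + 1L]] <- entry(hosts[[l]], "host")
    for (pg in paralogs[[l]] %||% character()) {
      rows[[length(rows) + 1L]] <- entry(pg, "paralog")
    }
  }
  do.call(rbind, rows)
}

#' Joint cross-line ranking score
#'
#' Per gene, the sum of absolute Del-WT differences across lines; genes with
#' coordinated changes in many lines rank first.
#'
#' @param delta Gene x line difference matrix (>= 2 lines).
#' @return Named numeric vector of scores, sorted decreasing.
#' @export
joint_ranking <- function(delta) {
  if (ncol(delta) < 2L) stop("need >= 2 lines", call. = FALSE)
  sort(rowSums(abs(delta)), decreasing = TRUE)
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score on a ranking.
# scores: sorted-decreasing named scores; inset: logical membership aligned
# to scores. Returns ES (extreme deviation, signed), its position, and the
# running sum.
es_running <- function(scores, inset, weight = 1, positive_only = FALSE) {
  N <- length(scores)
  w <- abs(scores)^weight
  w_hit <- ifelse(inset, w, 0)
  denom_hit <- sum(w_hit)
  if (denom_hit == 0) {
    # all in-set weights zero (e.g. weight > 0 with zero scores): fall back
    # to equal hit increments
    w_hit <- ifelse(inset, 1, 0)
    denom_hit <- sum(w_hit)
  }
  n_miss <- N - sum(inset)
  run <- cumsum(w_hit / denom_hit - ifelse(inset, 0, 1 / n_miss))
  if (positive_only) {
    i <- which.max(run)
    es <- run[i]
  } else {
    i_max <- which.max(run); i_min <- which.min(run)
    if (run[i_max] >= -run[i_min]) { i <- i_max; es <- run[i_max] }
    else { i <- i_min; es <- run[i_min] }
  }
  list(es = es, position = i, running = run)
}

#' Preranked gene-set enrichment (permutation GSEA)
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment score on a ranked gene
#' list, with a gene-label permutation null: set membership is reassigned at
#' random `n_perm` times. NES = ES / mean(|null ES| of the matching sign);
#' the p-value is the frequency of same-sign null ES at least as extreme.
#' With `positive_only`, only positive running-sum deviations are scored (a
#' one-sided "positive GSEA" for sets enriched at the top).
#'
#' @param scores Named numeric ranking scores (higher = stronger). Ties are
#'   broken by gene id for reproducibility.
#' @param gene_sets Named list of character vectors (one or more sets).
#' @param weight KS weight exponent on |score| (default 1; 0 = unweighted).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer RNG seed (required).
#' @param positive_only Score only positive deviations (default `FALSE`).
#' @param min_size,max_size Set-size bounds after intersecting with the
#'   ranking universe (defaults 5 and 2000).
#' @return data.frame with `set_name`, `size`, `es`, `nes`, `p`, `padj`
#'   (BH across the tested sets) and `leading_edge` (comma-separated genes).
#' @export
gsea_preranked <- function(scores, gene_sets, weight = 1, n_perm = 1000L,
                           seed, positive_only = FALSE,
                           min_size = 5L, max_size = 2000L) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  if (is.null(names(scores))) stop("scores must be named by gene", call. = FALSE)
  ord <- order(scores, names(scores), decreasing = c(TRUE, FALSE),
               method = "radix")
  scores <- scores[ord]
  universe <- names(scores)
  N <- length(universe)

  sets <- lapply(gene_sets, intersect, y = universe)
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size & sizes < N
  if (!any(keep)) {
    stop("no gene set within size bounds after intersecting with the ranking",
         call. = FALSE)
  }
  sets <- sets[keep]
  sizes <- sizes[keep]

  res <- with_seed(seed, lapply(seq_along(sets), function(si) {
    set <- sets[[si]]
    k <- length(set)
    inset <- universe %in% set
    obs <- es_running(scores, inset, weight, positive_only)
    null_es <- vapply(seq_len(n_perm), function(i) {
      perm <- logical(N)
      perm[sample.int(N, k)] <- TRUE
      es_running(scores, perm, weight, positive_only)$es
    }, numeric(1))
    same_sign <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    if (length(same_sign) == 0L) same_sign <- abs(null_es)
    nes <- obs$es / mean(abs(same_sign))
    p <- (1 + sum(abs(same_sign) >= abs(obs$es))) / (1 + length(same_sign))
    le <- if (obs$es >= 0) {
      universe[seq_len(obs$position)][inset[seq_len(obs$position)]]
    } else {
      universe[obs$position:N][inset[obs$position:N]]
    }
    data.frame(set_name = names(sets)[si], size = k, es = obs$es, nes = nes,
               p = p, leading_edge = paste(le, collapse = ","))
  }))
  out <- do.call(rbind, res)
  out$padj <- bh_adjust(out$p)
  out[, c("set_name", "size", "es", "nes", "p", "padj", "leading_edge")]
}

#' Jaccard clustering of enriched GO terms
#'
#' Enriched terms (adjusted p below `padj_cut`) are clustered by complete-
#' linkage hierarchical clustering of the Jaccard distance between their gene
#' sets (1 - intersection/union), cutting the tree at `cut_height` (0.9 by
#' default: clustered terms share > 10% of genes somewhere in the cluster).
#' Clusters are retained when at least one member has p below `keep_p`, are
#' named after their most significant member, and carry the union of their
#' members' genes (for subsequent per-line enrichment).
#'
#' @param gsea data.frame as from [gsea_preranked()] (needs `set_name`, `p`,
#'   `padj`).
#' @param gene_sets Named list of gene sets covering the enriched terms.
#' @param padj_cut Enrichment cutoff on adjusted p (default 0.01).
#' @param cut_height Tree-cut height on Jaccard distance (default 0.9).
#' @param keep_p Cluster-retention cutoff on nominal p (default 0.001).
#' @return List of clusters, each a list with `representative_term`,
#'   `member_terms`, `union_gene_set`.
#' @export
cluster_go_terms <- function(gsea, gene_sets, padj_cut = 0.01,
                             cut_height = 0.9, keep_p = 0.001) {
  enr <- gsea[gsea$padj < padj_cut, , drop = FALSE]
  if (nrow(enr) == 0L) stop("no enriched term at padj < padj_cut", call. = FALSE)
  terms <- enr$set_name
  sets <- gene_sets[terms]
  if (length(terms) == 1L) {
    memb <- stats::setNames(1L, terms)
  } else {
    n <- length(sets)
    d <- matrix(0, n, n, dimnames = list(terms, terms))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      jac <- length(intersect(sets[[i]], sets[[j]])) /
        length(union(sets[[i]], sets[[j]]))
      d[i, j] <- d[j, i] <- 1 - jac
    }
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    memb <- stats::cutree(hc, h = cut_height)
  }
  out <- lapply(split(names(memb), memb), function(members) {
    ps <- enr$p[match(members, enr$set_name)]
    if (min(ps) >= keep_p) return(NULL)
    list(representative_term = members[which.min(ps)],
         member_terms = members,
         union_gene_set = sort(unique(unlist(sets[members]))))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  unname(out)
}

#' Per-line enrichment of union gene sets
#'
#' Runs two-sided preranked GSEA of each cluster's union gene set against
#' each line's signed expression-difference ranking; cells where the set
#' falls outside the line's universe/size bounds are `NA`. Stars mark
#' adjusted p < 0.01 (adjustment across sets within each line).
#'
#' @param clusters Output of [cluster_go_terms()].
#' @param delta Gene x line difference matrix.
#' @param n_perm,seed,weight Passed to [gsea_preranked()].
#' @param min_size Minimum set size within a line's universe (default 5).
#' @return List with matrices `nes`, `padj` and character matrix `stars`
#'   (cluster representative x line).
#' @export
per_line_union_nes <- function(clusters, delta, n_perm = 1000L, seed,
                               weight = 1, min_size = 5L) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  reps <- vapply(clusters, `[[`, character(1), "representative_term")
  sets <- stats::setNames(lapply(clusters, `[[`, "union_gene_set"), reps)
  lines <- colnames(delta)
  nes <- padj <- matrix(NA_real_, length(reps), length(lines),
                        dimnames = list(reps, lines))
  for (li in seq_along(lines)) {
    scores <- delta[, lines[li]]
    res <- tryCatch(
      gsea_preranked(scores, sets, weight = weight, n_perm = n_perm,
                     seed = child_seed(seed, li), positive_only = FALSE,
                     min_size = min_size),
      error = function(e) NULL)
    if (is.null(res)) next
    idx <- match(res$set_name, reps)
    nes[idx, li] <- res$nes
    padj[idx, li] <- res$padj
  }
  stars <- ifelse(!is.na(padj) & padj < 0.01, "*", "")
  list(nes = nes, padj = padj, stars = stars)
}
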