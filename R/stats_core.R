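#' Two-sided Wilcoxon rank-sum p-value
#'
#' Thin wrapper around [stats::wilcox.test()] used throughout the package for
#' genotype comparisons. The exact null distribution is used for combined
#' sample sizes up to 20 when there are no ties; otherwise the normal
#' approximation with tie and continuity correction applies.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @return Two-sided p-value.
#' @export
wilcoxon_ranksum <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (length(unique(c(a, b))) == 1L) return(1)  # no rank information at all
  n <- length(a) + length(b)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- n <= 20L && !ties
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control via [stats::p.adjust()], with input
#' validation (all p-values must lie in \[0, 1\]).
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("all p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Significance band for a p-value
#'
#' Star scheme used in the package's reports: `***` for p < 0.0001, `**` for
#' 0.0001 <= p < 0.001, `*` for 0.001 <= p < 0.01, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of bands.
#' @export
significance_stars <- function(p) {
  out <- rep("ns", length(p))
  out[p < 0.01] <- "*"
  out[p < 0.001] <- "**"
  out[p < 0.0001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

#' Bootstrap-resampled Wilcoxon median p-value
#'
#' Repeatedly subsamples both groups (with replacement: a bootstrap), runs a
#' two-sided Wilcoxon rank-sum test per iteration, and summarises the p-value
#' distribution by its median. When experiment strata are supplied, the
#' subsample is drawn per stratum (per experiment per genotype).
#'
#' @param a,b Numeric vectors of observations for the two groups.
#' @param n_boot Number of bootstrap iterations (default 10000).
#' @param subsample Observations drawn per group (per stratum if strata are
#'   given) each iteration (default 50).
#' @param seed Integer RNG seed (required, for reproducibility).
#' @param strata_a,strata_b Optional stratum labels, same lengths as `a`/`b`.
#' @param replace Draw with replacement (default `TRUE`). With `replace =
#'   FALSE`, `n_boot = 1` and `subsample` equal to the group sizes, the result
#'   reduces to a single rank-sum test.
#' @return List with `median_p`, the star `band`, and `p_quantiles`
#'   (2.5/25/50/75/97.5 percentiles of the bootstrap p distribution).
#' @export
bootstrap_wilcoxon <- function(a, b, n_boot = 10000L, subsample = 50L, seed,
                               strata_a = NULL, strata_b = NULL,
                               replace = TRUE) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  stopifnot_scalar_number(n_boot, "n_boot", min = 1)
  stopifnot_scalar_number(subsample, "subsample", min = 2)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)

  draw <- function(x, strata) {
    if (is.null(strata)) {
      sample(x, subsample, replace = replace || length(x) < subsample)
    } else {
      unlist(lapply(split(x, strata), function(xs) {
        sample(xs, subsample, replace = replace || length(xs) < subsample)
      }), use.names = FALSE)
    }
  }
  # each group gets its own RNG stream keyed by its (sorted) content, so the
  # median p is invariant to swapping the group arguments
  group_key <- function(x) {
    s <- sort(x)
    as.integer(round(abs(sum(s * seq_along(s))) * 97) %% 1000003L)
  }
  key_a <- group_key(a)
  key_b <- group_key(b)
  ps <- vapply(seq_len(n_boot), function(i) {
    da <- with_seed(child_seed(seed, 7919L * i + key_a), draw(a, strata_a))
    db <- with_seed(child_seed(seed, 7919L * i + key_b), draw(b, strata_b))
    wilcoxon_ranksum(da, db)
  }, numeric(1))

  med <- stats::median(ps)
  list(
    median_p = med,
    band = significance_stars(med),
    p_quantiles = stats::quantile(ps, c(0.025, 0.25, 0.5, 0.75, 0.975),
                                  names = TRUE)
  )
}

#' Rank-based two-way ANOVA for two-founder designs
#'
#' Convenience fixed-effects layout on ranks (genotype + founder) for designs
#' where two founder lines of the same deletion are assayed together. Returns
#' the genotype-term p-value.
#'
#' @param values Numeric response vector.
#' @param genotype Factor-like genotype labels.
#' @param founder Factor-like founder labels.
#' @return p-value for the genotype term.
#' @export
rank_anova_genotype <- function(values, genotype, founder) {
  d <- data.frame(r = rank(values), genotype = factor(genotype),
                  founder = factor(founder))
  fit <- stats::aov(r ~ genotype + founder, data = d)
  summary(fit)[[1]][["Pr(>F)"]][1]
}
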