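make_counts <- function(seed = 1, ng = 200, ns = 8) {
  set.seed(seed)
  m <- matrix(rnbinom(ng * ns, mu = 100, size = 10), ng, ns,
              dimnames = list(sprintf("g%03d", 1:ng), paste0("s", 1:ns)))
  m
}

test_that("stabilization is scale-equivariant given a fixed reference", {
  m <- make_counts(1)
  ref <- exp(rowMeans(log(m)))
  st <- stabilize(m, reference = ref)
  m2 <- m; m2[, 3] <- m2[, 3] * 2L
  st2 <- stabilize(m2, reference = ref)
  expect_equal(st2$size_factors[3], st$size_factors[3] * 2, tolerance = 1e-12)
  expect_equal(st2$stabilized, st$stabilized, tolerance = 1e-12)
})

test_that("stabilization normalizes identical samples identically and is monotone", {
  m <- make_counts(2, ns = 6)
  m[, 2] <- m[, 1]
  st <- stabilize(m)
  expect_equal(st$stabilized[, 1], st$stabilized[, 2])
  o <- order(m[, 4])
  expect_true(all(diff(st$stabilized[o, 4]) >= 0))
  zero_sample <- m; zero_sample[, 1] <- 0L
  expect_error(stabilize(zero_sample), "positive total")
})

test_that("size factors match the reference median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  m <- make_counts(3, ng = 300, ns = 10)
  m[sample(length(m), 200)] <- 0L   # sprinkle zeros to exercise the reference
  sf <- stabilize(m)$size_factors
  sf_ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(sf), unname(sf_ref), tolerance = 1e-8)
})

test_that("batch adjustment recovers a planted offset and fits WT only", {
  set.seed(9)
  ng <- 400
  x <- matrix(rnorm(ng * 12, mean = 8, sd = 0.3), ng, 12,
              dimnames = list(sprintf("g%03d", 1:ng), paste0("s", 1:12)))
  batch <- rep(c("b1", "b2"), each = 6)
  wt <- rep(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), 2)

  # no batch structure: adjustment is near-identity
  adj0 <- batch_adjust(x, batch, wt)
  expect_lt(max(abs(adj0 - x)), 0.15)

  # planted constant +2 on batch b2: the between-batch offset is removed
  x2 <- x; x2[, batch == "b2"] <- x2[, batch == "b2"] + 2
  adj2 <- batch_adjust(x2, batch, wt)
  removed <- mean(x2[, batch == "b2"] - adj2[, batch == "b2"]) -
    mean(x2[, batch == "b1"] - adj2[, batch == "b1"])
  expect_equal(removed, 2, tolerance = 0.1)
  expect_lt(abs(mean(adj2[, batch == "b2"]) - mean(adj2[, batch == "b1"])),
            0.1)

  # a Del-only shift is not removed (fit uses WT only)
  x3 <- x; del_b2 <- batch == "b2" & !wt
  x3[, del_b2] <- x3[, del_b2] + 3
  adj3 <- batch_adjust(x3, batch, wt)
  expect_equal(mean(x3[, del_b2] - adj3[, del_b2]), 0, tolerance = 0.1)

  expect_error(batch_adjust(x, batch, batch == "b1"), "WT sample")
})

test_that("delta expression is the Del-WT mean difference and antisymmetric", {
  x <- matrix(rnorm(50 * 4, 5), 50, 4,
              dimnames = list(sprintf("g%02d", 1:50),
                              c("a_wt1", "a_wt2", "a_del1", "a_del2")))
  info <- data.frame(sample = colnames(x), line = "a",
                     genotype = c("WT", "WT", "Del", "Del"))
  d <- delta_expression(x, info)
  expect_equal(d[, "a"], rowMeans(x[, 3:4]) - rowMeans(x[, 1:2]))

  info_flip <- info; info_flip$genotype <- rev(info$genotype)
  expect_equal(delta_expression(x, info_flip)[, "a"], -d[, "a"])

  x_eq <- x; x_eq[, 3:4] <- x_eq[, 1:2]
  expect_equal(unname(delta_expression(x_eq, info)[, "a"]), rep(0, 50))
})

test_that("host and paralog deltas are flagged in the outer deciles", {
  d <- matrix(seq_len(100), 100, 1,
              dimnames = list(sprintf("g%03d", 1:100), "line01"))
  hosts <- c(line01 = "g100")                 # the maximum
  rep1 <- host_paralog_report(d, hosts)
  expect_equal(rep1$percentile, 100)
  expect_true(rep1$flagged)

  hosts50 <- c(line01 = "g050")               # the median
  rep2 <- host_paralog_report(d, hosts50)
  expect_equal(rep2$percentile, 50)
  expect_false(rep2$flagged)

  hosts91 <- c(line01 = "g091")               # ranked 91st of 100
  expect_true(host_paralog_report(d, hosts91)$flagged)

  expect_error(host_paralog_report(d, c(line01 = "nope")), "absent")
  par <- host_paralog_report(d, hosts50, paralogs = list(line01 = c("g005")))
  expect_true(par$flagged[par$role == "paralog"])
})

test_that("joint ranking sums absolute differences across lines", {
  d <- cbind(l1 = c(a = 1, b = 0, c = -2),
             l2 = c(a = -1, b = 0, c = 2),
             l3 = c(a = 1, b = 0, c = 0))
  jr <- joint_ranking(d)
  expect_equal(jr[["a"]], 3)
  expect_equal(names(jr)[1], "c")
  expect_equal(names(jr)[3], "b")
  expect_equal(jr[["b"]], 0)
  expect_error(joint_ranking(d[, 1, drop = FALSE]), "lines")
})

test_that("running-sum ES matches brute-force prefix recomputation", {
  set.seed(31)
  for (i in 1:6) {
    n <- sample(20:50, 1)
    scores <- setNames(rnorm(n), sprintf("g%02d", 1:n))
    set <- sample(names(scores), sample(4:10, 1))
    for (w in c(0, 1)) {
      got <- gsea_preranked(scores, list(s = set), weight = w, n_perm = 100,
                            seed = 5, min_size = 2)
      expect_equal(got$es, brute_es(scores, set, weight = w),
                   tolerance = 1e-12)
    }
  }
})

test_that("ES agrees with the independent fgsea implementation", {
  skip_if_not_installed("fgsea")
  set.seed(13)
  scores <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  set <- sample(names(scores), 15)
  got <- gsea_preranked(scores, list(s = set), weight = 1, n_perm = 100,
                        seed = 2)
  sorted <- sort(scores, decreasing = TRUE)
  es_ref <- fgsea::calcGseaStat(sorted, which(names(sorted) %in% set),
                                gseaParam = 1)
  expect_equal(got$es, es_ref, tolerance = 1e-10)
})

test_that("a top-k set attains the maximal unweighted enrichment score", {
  scores <- setNames(seq(100, 1), sprintf("g%03d", 1:100))
  res <- gsea_preranked(scores, list(top = names(scores)[1:5]), weight = 0,
                        n_perm = 200, seed = 3, positive_only = TRUE)
  expect_equal(res$es, 1, tolerance = 1e-12)
  expect_equal(res$leading_edge, paste(names(scores)[1:5], collapse = ","))
  # a set spanning the whole universe is rejected
  expect_error(gsea_preranked(scores, list(all = names(scores)), n_perm = 100,
                              seed = 1), "size")
  expect_error(gsea_preranked(scores, list(none = c("x1", "x2")), n_perm = 100,
                              seed = 1), "size")
})

test_that("GSEA p-values are honest under an exchangeable null and BH is monotone", {
  set.seed(17)
  ps <- vapply(1:60, function(i) {
    sc <- setNames(rnorm(150), sprintf("g%03d", 1:150))
    gsea_preranked(sc, list(s = sample(names(sc), 15)), n_perm = 200,
                   seed = 4000 + i)$p
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lte(mean(ps < 0.05), 0.12)

  p <- c(0.01, 0.02, 0.03)
  expect_equal(bh_adjust(p), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  pr <- runif(20)
  expect_true(all(diff(bh_adjust(pr)[order(pr)]) >= -1e-12))
})

test_that("Jaccard clustering merges overlapping terms and keeps significant clusters", {
  sets <- list(A = sprintf("x%02d", 1:20), B = sprintf("x%02d", 1:20),
               C = sprintf("y%02d", 1:20),
               D = c(sprintf("x%02d", 1:2), sprintf("z%02d", 1:11)),
               E = sprintf("w%02d", 1:10))
  gsea <- data.frame(set_name = names(sets),
                     p = c(1e-5, 1e-4, 1e-6, 5e-4, 0.5),
                     padj = c(1e-4, 1e-3, 1e-5, 5e-3, 0.6))
  cl <- cluster_go_terms(gsea, sets)
  members <- lapply(cl, `[[`, "member_terms")
  ab <- members[vapply(members, function(m) "A" %in% m, logical(1))][[1]]
  expect_true(all(c("A", "B") %in% ab))       # identical sets merge
  expect_false("C" %in% ab)                   # disjoint sets split
  # D shares 2/31 with A/B: Jaccard distance 0.935, above the 0.9 cut
  expect_false("D" %in% ab)
  expect_false("E" %in% unlist(members))      # not enriched at padj < 0.01
  reps <- vapply(cl, `[[`, character(1), "representative_term")
  expect_true("C" %in% reps)                  # most significant member names it

  # Jaccard similarity 0.15 (distance 0.85) merges under complete linkage
  sets2 <- list(P = sprintf("p%02d", 1:13),
                Q = c(sprintf("p%02d", 1:3), sprintf("q%02d", 1:7)))
  gsea2 <- data.frame(set_name = c("P", "Q"), p = c(1e-5, 1e-4),
                      padj = c(1e-4, 1e-3))
  cl2 <- cluster_go_terms(gsea2, sets2)
  expect_length(cl2, 1L)
  expect_setequal(cl2[[1]]$member_terms, c("P", "Q"))
  expect_setequal(cl2[[1]]$union_gene_set,
                  union(sets2$P, sets2$Q))

  # clusters without any member below keep_p are dropped
  gsea3 <- data.frame(set_name = "P", p = 0.005, padj = 0.005)
  expect_length(cluster_go_terms(gsea3, sets2), 0L)
})

test_that("per-line union NES flags planted shifts and marks absent sets", {
  ex <- gen_expression_counts(sim_config(seed = 71, n_genes = 400, n_lines = 2,
                                         pathway_shift = 2, dispersion = 0.05),
                              n_reps = 3)
  st <- stabilize(ex$counts)
  d <- delta_expression(st$stabilized, ex$sample_info)
  clusters <- list(
    list(representative_term = "planted", member_terms = "planted",
         union_gene_set = ex$planted_set),
    list(representative_term = "absent", member_terms = "absent",
         union_gene_set = c("zz1", "zz2")))
  res <- per_line_union_nes(clusters, d, n_perm = 300, seed = 6)
  up_line <- names(ex$shifted_lines)[1]
  expect_gt(res$nes["planted", up_line], 0)
  expect_equal(res$stars["planted", up_line], "*")
  expect_true(all(is.na(res$nes["absent", ])))
  expect_true(all(res$stars["absent", ] == ""))
})

test_that("gene sets round-trip through GMT and the degradation hook is identity", {
  gs <- list(one = c("a", "b", "c"), two = c("d", "e"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, path)
  expect_equal(read_gmt(path), gs)
  m <- make_counts(5, ng = 10, ns = 2)
  expect_identical(degradation_hook(m), m)
})
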