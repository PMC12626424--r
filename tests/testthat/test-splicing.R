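test_that("exon length classes follow the 3-27 / 28-51 / >51 nt boundaries", {
  expect_equal(as.character(classify_exon_length(c(3, 27, 28, 51, 52, 300))),
               c("micro_3_27", "micro_3_27", "mid_28_51", "mid_28_51",
                 "long_gt51", "long_gt51"))
  expect_error(classify_exon_length(2), "microexon range")
  expect_error(classify_exon_length(c(10, 0)), "positive")
})

test_that("caller computes dPSI against group means and pooled samples on a toy table", {
  toy <- toy_psi_table(list(
    enriched = c(80, 10, 10, 10, 10, 10),
    weak     = c(24.9, 10, 10, 10, 10, 10),   # dpsi_target 14.9
    flat     = c(10, 10, 10, 10, 10, 10)))
  calls <- call_tissue_enriched(toy$table, toy$config, calling_params(),
                                "Neural")
  enr <- calls[calls$event_id == "enriched", ]
  expect_equal(enr$dpsi_target, 70)
  expect_equal(enr$dpsi_global, 70)
  expect_true(enr$called)
  expect_false(calls$called[calls$event_id == "weak"])
  expect_false(calls$called[calls$event_id == "flat"])
})

test_that("unweighted group means differ from pooled means when group sizes differ", {
  # 3 samples in T1 at 40, 1 sample elsewhere at 10: unweighted mean of group
  # means != pooled sample mean
  groups <- c("Neural", paste0("T", 1:4))
  samples <- c("Neural_1", "T1_1", "T1_2", "T1_3", "T2_1", "T3_1", "T4_1")
  sample_group <- c("Neural", "T1", "T1", "T1", "T2", "T3", "T4")
  psi <- matrix(c(80, 40, 40, 40, 10, 10, 10), 1)
  colnames(psi) <- samples
  qual <- matrix("OK", 1, 7, dimnames = list(NULL, samples))
  tab <- psi_table(data.frame(event_id = "e1", gene_id = "g1",
                              exon_length_nt = 20),
                   psi, qual)
  cfg <- data.frame(sample = samples, group = sample_group, excluded = "")
  call <- call_tissue_enriched(tab, cfg, calling_params(), "Neural")
  expect_equal(call$dpsi_target, 80 - mean(c(40, 10, 10, 10)))
  expect_equal(call$dpsi_global, 80 - mean(c(40, 40, 40, 10, 10, 10)))
})

test_that("coverage eligibility requires n_groups valid groups and min_rep samples", {
  # event covered in only 4 of 6 groups -> ineligible under n_groups = 5
  toy <- toy_psi_table(list(
    sparse = c(80, 10, 10, NA, NA, 10),
    full   = c(80, 10, 10, 10, 10, 10)))
  toy$table$quality[1, 7:10] <- "N"  # T3/T4 samples uncovered
  toy$table$psi[1, 7:10] <- NA
  calls <- call_tissue_enriched(toy$table, toy$config, calling_params(),
                                "Neural")
  expect_false("sparse" %in% calls$event_id)
  expect_true("full" %in% calls$event_id)

  # quality below min_quality is insufficient even with a PSI value
  toy2 <- toy_psi_table(list(e = c(80, 10, 10, 10, 10, 10)))
  toy2$table$quality[1, toy2$config$group == "T5"] <- "N"
  calls2 <- call_tissue_enriched(toy2$table, toy2$config, calling_params(),
                                 "Neural")
  expect_equal(calls2$n_valid_groups, 5L)  # T5 dropped, still eligible
})

test_that("groups excluded for the target are dropped from eligibility and means", {
  toy <- toy_psi_table(list(e = c(80, 70, 10, 10, 10, 10)))
  # T1 (at PSI 70) overlaps the neural program; exclude it for Neural calls
  toy$config$excluded[toy$config$group == "T1"] <- "Neural"
  calls <- call_tissue_enriched(toy$table, toy$config, calling_params(),
                                "Neural")
  expect_equal(calls$dpsi_target, 70)          # mean of T2..T5 only
  expect_equal(calls$n_valid_groups, 5L)       # T1 not counted
  # without the exclusion the event is diluted
  toy$config$excluded <- ""
  calls2 <- call_tissue_enriched(toy$table, toy$config, calling_params(),
                                 "Neural")
  expect_equal(calls2$dpsi_target, 80 - mean(c(70, 10, 10, 10, 10)))
})

test_that("caller errors on absent target group and returns empty on empty table", {
  toy <- toy_psi_table(list(e = c(80, 10, 10, 10, 10, 10)))
  expect_error(call_tissue_enriched(toy$table, toy$config, calling_params(),
                                    "Gonad"), "no samples")
  empty <- psi_table(data.frame(event_id = character(),
                                gene_id = character(),
                                exon_length_nt = integer()),
                     matrix(numeric(), 0, 12,
                            dimnames = list(NULL, toy$config$sample)),
                     matrix(character(), 0, 12,
                            dimnames = list(NULL, toy$config$sample)))
  expect_equal(nrow(call_tissue_enriched(empty, toy$config, calling_params(),
                                         "Neural")), 0L)
})

test_that("caller is invariant to row and column order and monotone in min_dpsi", {
  cfg <- sim_config(seed = 11, n_events = 30, dpsi_effect = 30,
                    coverage_dropout = 0.1)
  g <- gen_psi_table(cfg)
  ref <- call_tissue_enriched(g$table, g$config_table, calling_params(),
                              "Neural")
  perm_r <- sample(nrow(g$table$psi))
  perm_c <- sample(ncol(g$table$psi))
  shuf <- psi_table(g$table$events[perm_r, ],
                    g$table$psi[perm_r, perm_c],
                    g$table$quality[perm_r, perm_c])
  got <- call_tissue_enriched(shuf, g$config_table, calling_params(),
                              "Neural")
  got <- got[match(ref$event_id, got$event_id), ]
  expect_equal(got$dpsi_target, ref$dpsi_target)
  expect_equal(got$called, ref$called)

  for (thr in c(20, 30, 40)) {
    stricter <- call_tissue_enriched(g$table, g$config_table,
                                     calling_params(min_dpsi = thr),
                                     "Neural")
    expect_true(all(stricter$event_id[stricter$called] %in%
                      ref$event_id[ref$called]))
  }
})

test_that("caller agrees with a brute-force reimplementation on random tables", {
  params <- calling_params()
  for (s in 1:5) {
    g <- gen_psi_table(sim_config(seed = 100 + s, n_events = 15,
                                  dpsi_effect = 25,
                                  coverage_dropout = 0.2))
    oracle <- brute_call(g$table, g$config_table, params, "Neural")
    got <- call_tissue_enriched(g$table, g$config_table, params, "Neural")
    expect_setequal(got$event_id, names(oracle))
    expect_equal(
      got$called[match(names(oracle), got$event_id)],
      unname(unlist(oracle)))
  }
})

test_that("planted neural events are recovered exactly at strong effect, none at zero", {
  g <- gen_psi_table(sim_config(seed = 21, n_events = 40, dpsi_effect = 40,
                                coverage_dropout = 0))
  calls <- call_tissue_enriched(g$table, g$config_table, calling_params(),
                                "Neural")
  expect_setequal(calls$event_id[calls$called],
                  g$truth$event_id[g$truth$label == "neural"])

  g0 <- gen_psi_table(sim_config(seed = 21, n_events = 40, dpsi_effect = 0,
                                 coverage_dropout = 0))
  calls0 <- call_tissue_enriched(g0$table, g0$config_table, calling_params(),
                                 "Neural")
  expect_equal(sum(calls0$called), 0L)
})

test_that("regulator response takes the lowest dPSI and applies the -15 cut", {
  r <- classify_regulator_response(c(retina_srrm3 = -30, larva = -5))
  expect_equal(r$min_delta_psi, -30)
  expect_equal(r$class, "affected")
  expect_equal(classify_regulator_response(c(-10, -14))$class, "not_affected")
  expect_equal(classify_regulator_response(c(-15, 0))$class, "not_affected")
  expect_equal(classify_regulator_response(numeric())$class, "no_coverage")
  expect_equal(classify_regulator_response(c(NA_real_, NA_real_))$class,
               "no_coverage")
})

test_that("conservation classes follow ortholog presence, coverage and the +15 cut", {
  expect_equal(classify_conservation(TRUE, 20), "regulatory_conserved")
  expect_equal(classify_conservation(TRUE, 15), "regulatory_conserved")
  expect_equal(classify_conservation(TRUE, 14.9), "genomic_only")
  expect_equal(classify_conservation(TRUE, NA), "no_coverage_in_target")
  expect_equal(classify_conservation(FALSE), "no_event_ortholog")
})

test_that("Fisher test matches exhaustive hypergeometric enumeration", {
  expect_equal(length_class_association(matrix(c(5, 5, 5, 5), 2))$p, 1)
  r <- length_class_association(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(r$odds_ratio, Inf)
  set.seed(5)
  for (i in 1:8) {
    m <- matrix(rpois(4, 6) + 1, 2)
    r <- length_class_association(m)
    expect_equal(r$p, enum_fisher_p(m), tolerance = 1e-10)
    expect_equal(r$odds_ratio, m[1, 1] * m[2, 2] / (m[1, 2] * m[2, 1]))
  }
  expect_error(length_class_association(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("PSI table round-trips through the inclusion-table TSV dialect", {
  g <- gen_psi_table(sim_config(seed = 31, n_events = 8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psi_table(g$table, path)
  back <- read_psi_table(path)
  expect_equal(back$events$event_id, g$table$events$event_id)
  expect_equal(back$quality, g$table$quality)
  expect_equal(back$psi, g$table$psi, tolerance = 1e-9)
})

test_that("group-mean imputation fills only missing cells, for plotting", {
  toy <- toy_psi_table(list(e = c(80, NA, 10, 10, 10, 10)))
  imp <- impute_psi_for_plotting(toy$table, toy$config)
  expect_false(anyNA(imp))
  filled <- toy$config$group == "T1"
  expect_true(all(imp[1, filled] == mean(imp[1, ])))
  expect_equal(imp[1, !filled], toy$table$psi[1, !filled])
})
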