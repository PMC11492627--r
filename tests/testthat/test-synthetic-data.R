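test_that("LD matrix follows the block AR(1) contract", {
  expect_equal(simulate_ld_matrix(4, 1, 0.9), diag(4))
  expect_equal(simulate_ld_matrix(2, 2, 0.5),
               matrix(c(1, 0.5, 0.5, 1), 2))
  R <- simulate_ld_matrix(50, 5, 0.8)
  expect_equal(R, t(R))
  expect_equal(diag(R), rep(1, 50))
  # cross-block entries vanish, within-block decay is rho^lag
  expect_equal(R[5, 6], 0)
  expect_equal(R[1, 3], 0.8^2)
  # positive semi-definiteness by direct eigendecomposition
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-10))
  expect_error(simulate_ld_matrix(4, 1, 1), "rho")
  expect_error(simulate_ld_matrix(4, 1, -0.1), "rho")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_variants = 0), "positive integer")
  expect_error(sim_config(ld_rho = 1), "\\[0, 1\\)")
  expect_error(sim_config(pleiotropy_mean = 0.1, pleiotropy_mode = "balanced"),
               "directional")
  expect_silent(sim_config(pleiotropy_mean = 0.1,
                           pleiotropy_mode = "directional"))
})

test_that("dataset simulation is seed-deterministic with contracted scaling", {
  cfg <- sim_config(n_variants = 40, causal_effect = 0.2, seed = 11)
  d1 <- simulate_mr_dataset(cfg)
  d2 <- simulate_mr_dataset(cfg)
  expect_identical(d1, d2)
  d3 <- simulate_mr_dataset(sim_config(n_variants = 40, causal_effect = 0.2,
                                       seed = 12))
  expect_false(identical(d1$exposure$beta, d3$exposure$beta))

  expect_equal(unique(d1$exposure$se), 1 / sqrt(cfg$n_exposure))
  expect_equal(unique(d1$outcome$se), 1 / sqrt(cfg$n_outcome))
  expect_identical(rownames(d1$ld), d1$exposure$variant_id)
  expect_length(d1$truth$exposure_betas_true, 40)
  expect_length(d1$truth$per_variant_pleiotropy, 40)

  # flipped outcome records have swapped alleles and complemented frequency
  i <- match(d1$truth$flipped_variants, d1$exposure$variant_id)
  expect_length(i, round(0.1 * 40))
  expect_equal(d1$outcome$effect_allele[i], d1$exposure$other_allele[i])
  expect_equal(d1$outcome$other_allele[i], d1$exposure$effect_allele[i])
  expect_equal(d1$outcome$eaf[i], 1 - d1$exposure$eaf[i])
  j <- setdiff(seq_len(40), i)
  expect_equal(d1$outcome$effect_allele[j], d1$exposure$effect_allele[j])
})

test_that("null simulation yields centred outcome z-scores", {
  d <- simulate_mr_dataset(sim_config(n_variants = 200, causal_effect = 0,
                                      seed = 3))
  expect_lt(abs(mean(d$outcome$beta / d$outcome$se)), 0.2)
})

test_that("IVW recovers the causal slope when outcome noise is negligible", {
  # 50 repetitions at slope 0.3 with a very large outcome sample
  slopes <- vapply(1:50, function(s) {
    d <- simulate_mr_dataset(sim_config(n_variants = 60, causal_effect = 0.3,
                                        n_outcome = 1e6, seed = 300 + s))
    run_mr(d$exposure, d$outcome, d$ld, outcome_type = "binary")$ivw$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.3), 0.02)
})

test_that("annotation fixtures honour shape, ranges and determinism", {
  a <- simulate_annotation_fixtures(10, 3, 61, seed = 1)
  expect_equal(nrow(a$expression), 10)
  tissue_cols <- setdiff(names(a$expression), "protein_id")
  expect_length(tissue_cols, 61)
  expect_true("heart_muscle" %in% tissue_cols)
  expect_true(all(as.matrix(a$expression[tissue_cols]) >= 0))
  expect_true(all(a$druggability$status %in% c("drugged", "druggable", "none")))
  expect_true(all(a$druggability$n_drugs[a$druggability$status == "none"] == 0))
  expect_true(all(a$genes$start <= a$genes$end))
  expect_true(all(a$pathways$protein_id %in% a$expression$protein_id))
  expect_identical(a, simulate_annotation_fixtures(10, 3, 61, seed = 1))
  b <- simulate_annotation_fixtures(100, 5, 61, seed = 2)
  expect_identical(b, simulate_annotation_fixtures(100, 5, 61, seed = 2))
  expect_false(identical(a$expression[1, 2], b$expression[1, 2]))
})

test_that("summary-statistic and LD round-trips through TSV are faithful", {
  d <- simulate_mr_dataset(sim_config(n_variants = 15, seed = 5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gwas_table(d$exposure, f)
  back <- read_gwas_table(f)
  expect_equal(back$beta, d$exposure$beta)
  expect_equal(back$variant_id, d$exposure$variant_id)
  expect_identical(back$chromosome, d$exposure$chromosome)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(d$ld, f2)
  ld2 <- read_ld_matrix(f2)
  expect_equal(rownames(ld2), rownames(d$ld))
  expect_equal(unname(ld2), unname(d$ld), tolerance = 1e-5)
})
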