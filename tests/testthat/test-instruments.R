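test_that("F statistic is the squared z, sign-invariant", {
  expect_equal(f_statistic(0.5, 0.1), 25)
  expect_equal(f_statistic(0, 1), 0)
  expect_equal(f_statistic(-0.489898, 0.1), 24.0, tolerance = 1e-4)
  expect_error(f_statistic(0.1, 0), "se")
})

test_that("instrument filter applies inclusive F and folded-MAF cutoffs", {
  v <- make_gwas(c("a", "b", "c", "d"),
                 beta = c(0.5, 0.5, -0.489898, 0.05),
                 se = c(0.1, 0.1, 0.1, 0.1),
                 eaf = c(0.995, 0.01, 0.3, 0.3))
  out <- filter_instruments(v)
  expect_equal(out$variant_id, c("b", "c"))  # a fails MAF, d fails F; boundaries kept
  expect_equal(nrow(filter_instruments(v, f_min = 0, maf_min = 0)), 4)
  expect_equal(nrow(filter_instruments(v[0, ])), 0)
})

test_that("raising the F cutoff never adds variants (monotonicity)", {
  set.seed(42)
  v <- make_gwas(sprintf("v%02d", 1:100), beta = rnorm(100, 0, 0.5),
                 se = runif(100, 0.05, 0.2), eaf = runif(100, 0.01, 0.99))
  prev <- filter_instruments(v, f_min = 0)$variant_id
  for (f in c(1, 5, 24, 50, 200)) {
    cur <- filter_instruments(v, f_min = f)$variant_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("cis window is a closed interval on the gene's chromosome", {
  gene <- list(chromosome = "2", start = 1000000, end = 1010000)
  v <- make_gwas(c("in_l", "out_l", "in_r", "out_r", "wrong_chr"),
                 beta = 0.5, se = 0.1,
                 chromosome = c("2", "2", "2", "2", "3"),
                 position = c(810000, 799999, 1210000, 1210001, 1000000))
  out <- select_cis_window(gene, v)
  expect_setequal(out$variant_id, c("in_l", "in_r"))
})

test_that("greedy clumping keeps the smallest-p representative", {
  v <- make_gwas(c("v1", "v2", "v3"), beta = c(0.9, 0.8, 0.7), se = 0.1,
                 position = c(1000, 2000, 3000))
  v$p_value <- c(1e-8, 1e-6, 1e-4)
  r <- sqrt(c(0.5, 0.1, 0.1))
  ld <- matrix(c(1, r[1], r[2],
                 r[1], 1, r[3],
                 r[2], r[3], 1), 3, byrow = TRUE,
               dimnames = list(v$variant_id, v$variant_id))
  expect_equal(clump(v, ld)$variant_id, c("v1", "v3"))
  # identity LD keeps everything; total correlation keeps the best only
  expect_equal(nrow(clump(v, diag(3))), 3)
  ones <- matrix(1, 3, 3)
  expect_equal(clump(v, ones)$variant_id, "v1")
  expect_error(clump(v, diag(2)), "aligned")
})

test_that("clumping is idempotent and certifies every drop", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:12, 1)
    A <- matrix(rnorm(n * n), n)
    R <- cov2cor(crossprod(A) + diag(n))
    v <- make_gwas(sprintf("s%02d", sample(n)), beta = rnorm(n, 0, 0.3),
                   se = 0.05, position = sample(1e6, n))
    dimnames(R) <- list(v$variant_id, v$variant_id)
    kept <- clump(v, R, 0.3)
    # idempotence
    kept2 <- clump(kept, R[kept$variant_id, kept$variant_id], 0.3)
    expect_equal(kept2$variant_id, kept$variant_id)
    # no retained pair exceeds the threshold
    if (nrow(kept) > 1) {
      sub <- R[kept$variant_id, kept$variant_id]^2
      diag(sub) <- 0
      expect_true(all(sub <= 0.3))
    }
    # every dropped variant correlates with a retained better-or-equal one
    for (id in setdiff(v$variant_id, kept$variant_id)) {
      better <- kept$variant_id[kept$p_value <= v$p_value[v$variant_id == id]]
      expect_true(any(R[id, better]^2 > 0.3))
    }
  }
})

test_that("harmonisation aligns, flips and drops per the allele rules", {
  exp <- make_gwas(c("r1", "r2", "r3", "r4"), beta = c(0.1, 0.2, 0.3, 0.4),
                   se = 0.01,
                   effect_allele = c("A", "A", "A", "C"),
                   other_allele = c("G", "G", "T", "A"))
  out <- exp
  out$beta <- c(0.15, -0.2, 0.05, 0.4)
  out$se <- 0.02
  # r2 swapped coding; r3 palindromic with eaf 0.5; r4 allele mismatch
  out$effect_allele <- c("A", "G", "A", "C")
  out$other_allele <- c("G", "A", "T", "T")
  out$eaf[2] <- 1 - out$eaf[2]
  exp$eaf[3] <- 0.5
  out$eaf[3] <- 0.5
  h <- harmonize(exp, out)
  expect_equal(h$variants$variant_id, c("r1", "r2"))
  expect_equal(h$variants$beta_outcome, c(0.15, 0.2))  # r2 sign restored
  # identical coding throughout is a pass-through
  h2 <- harmonize(exp[c(1, 2), ], exp[c(1, 2), ])
  expect_equal(h2$variants$beta_outcome, exp$beta[1:2])
  expect_error(harmonize(exp, make_gwas("zz", 0.1, 0.1)), "overlapping")
})

test_that("re-coding every outcome allele leaves the harmonised set invariant", {
  d <- simulate_mr_dataset(sim_config(n_variants = 30, seed = 9))
  h1 <- harmonize(d$exposure, d$outcome, d$ld)
  flipped <- d$outcome
  tmp <- flipped$effect_allele
  flipped$effect_allele <- flipped$other_allele
  flipped$other_allele <- tmp
  flipped$beta <- -flipped$beta
  flipped$eaf <- 1 - flipped$eaf
  h2 <- harmonize(d$exposure, flipped, d$ld)
  expect_equal(h1$variants, h2$variants)
  expect_equal(h1$ld, h2$ld)
})

test_that("outcome-coded LD gets its signs flipped for swapped variants", {
  exp <- make_gwas(c("x1", "x2"), beta = c(0.2, 0.3), se = 0.01,
                   effect_allele = c("A", "A"), other_allele = c("G", "G"))
  out <- exp
  out$effect_allele[2] <- "G"
  out$other_allele[2] <- "A"
  out$beta[2] <- -out$beta[2]
  out$eaf[2] <- 1 - out$eaf[2]
  ld <- matrix(c(1, 0.6, 0.6, 1), 2, dimnames = list(c("x1", "x2"), c("x1", "x2")))
  expect_equal(harmonize(exp, out, ld)$ld[1, 2], 0.6)
  expect_equal(harmonize(exp, out, ld, ld_coding = "outcome")$ld[1, 2], -0.6)
})
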