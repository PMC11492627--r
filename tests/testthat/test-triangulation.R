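test_that("Bonferroni thresholds reproduce the one-significant-figure values", {
  expect_equal(bonferroni_threshold(0.05, 174, 4)$threshold_reported, 7e-5)
  expect_equal(bonferroni_threshold(0.05, 1567, 36)$threshold_reported, 9e-7)
  expect_equal(bonferroni_threshold(0.05, 686, 4)$threshold_reported, 2e-5)
  expect_equal(bonferroni_threshold(0.05, 174, 4)$threshold, 0.05 / 696)
  expect_error(bonferroni_threshold(0.05, 0, 4), "positive")
})

test_that("the threshold decreases strictly in each count", {
  base <- bonferroni_threshold(0.05, 100, 10)$threshold
  for (k in c(101, 150, 500))
    expect_lt(bonferroni_threshold(0.05, k, 10)$threshold, base)
  for (k in c(11, 20, 100))
    expect_lt(bonferroni_threshold(0.05, 100, k)$threshold, base)
})

test_that("the largest study is primary, ties broken lexicographically", {
  studies <- data.frame(study_id = c("deCODE", "INTERVAL"),
                        sample_size = c(35559, 3301))
  expect_equal(select_primary_study(studies), "deCODE")
  expect_equal(select_primary_study(studies[2, ]), "INTERVAL")
  tie <- data.frame(study_id = c("B_study", "A_study"),
                    sample_size = c(100, 100))
  expect_equal(select_primary_study(tie), "A_study")
  expect_error(select_primary_study(studies[0, ]), "no studies")
})

test_that("concordance is the sign-product rule", {
  expect_true(concordant(+1, -1, -1))   # raising a risk-lowering metabolite
  expect_false(concordant(+1, +1, -1))
  expect_true(concordant(-1, +1, +1) == FALSE)
  # negating every sign preserves concordance
  expect_equal(concordant(-1, +1, -1), concordant(+1, -1, -1))
  expect_error(concordant(0, 1, 1), "zero sign")
})

test_that("triangles require three significant, direction-consistent edges", {
  thr <- list(metabolite_outcome = 1e-3, protein_metabolite = 1e-3,
              protein_outcome = 1e-3)
  mo <- data.frame(exposure = "M", outcome = "D", slope = 0.4, p_value = 1e-6)
  pm <- data.frame(exposure = "P", outcome = "M", slope = 0.5, p_value = 1e-9)
  po <- data.frame(exposure = "P", outcome = "D", slope = 0.2, p_value = 1e-6)
  tri <- build_triangles(mo, pm, po, thr)
  expect_equal(nrow(tri), 1)
  expect_true(tri$concordant)
  expect_equal(tri$protein_id, "P")

  po_bad <- transform(po, slope = -slope)
  expect_equal(nrow(build_triangles(mo, pm, po_bad, thr)), 0)
  po_ns <- transform(po, p_value = 0.5)
  expect_equal(nrow(build_triangles(mo, pm, po_ns, thr)), 0)
  expect_error(build_triangles(NULL, pm, po, thr), "missing edge table")
})

test_that("triangle assembly matches a brute-force triple scan", {
  proteins <- sprintf("P%02d", 1:50)
  mets <- sprintf("M%02d", 1:8)
  outs <- c("O1", "O2", "O3")
  mo <- random_edge_table(mets, outs, seed = 1)
  pm <- random_edge_table(proteins, mets, seed = 2)
  po <- random_edge_table(proteins, outs, seed = 3)
  thr <- list(metabolite_outcome = 0.05, protein_metabolite = 0.02,
              protein_outcome = 0.05)
  tri <- build_triangles(mo, pm, po, thr)
  expect_gt(nrow(tri), 0)
  got <- tri[, c("protein_id", "metabolite_id", "outcome_id")]
  rownames(got) <- NULL
  expect_equal(got, oracle_triangles(mo, pm, po, thr))
  # invariance to input row order
  tri2 <- build_triangles(mo[sample(nrow(mo)), ], pm[sample(nrow(pm)), ],
                          po[sample(nrow(po)), ], thr)
  expect_equal(tri, tri2)
  # emitted triangles satisfy the concordance identity, re-checked directly
  expect_true(all(sign(tri$beta_protein_metabolite) *
                  sign(tri$beta_metabolite_outcome) ==
                  sign(tri$beta_protein_outcome)))
})

test_that("pleiotropic proteins are those reaching two or more outcomes", {
  tri <- data.frame(protein_id = c("A", "A", "A", "B"),
                    metabolite_id = c("m1", "m2", "m3", "m1"),
                    outcome_id = c("AF", "AF", "HF", "AF"))
  s <- pleiotropic_summary(tri)
  expect_equal(s$n_outcomes[s$protein_id == "A"], 2)
  expect_true(s$pleiotropic[s$protein_id == "A"])
  expect_false(s$pleiotropic[s$protein_id == "B"])
  expect_equal(nrow(pleiotropic_summary(tri[0, ])), 0)
})

test_that("the network export types nodes and signs edges", {
  thr <- list(metabolite_outcome = 1, protein_metabolite = 1,
              protein_outcome = 1)
  mo <- data.frame(exposure = "M", outcome = "D", slope = -0.4, p_value = 1e-6)
  pm <- data.frame(exposure = "P", outcome = "M", slope = 0.5, p_value = 1e-9)
  po <- data.frame(exposure = "P", outcome = "D", slope = -0.2, p_value = 1e-6)
  net <- triangle_network(build_triangles(mo, pm, po, thr))
  expect_setequal(net$nodes$type, c("protein", "metabolite", "outcome"))
  expect_equal(nrow(net$edges), 3)
  expect_equal(sort(net$edges$sign), c(-1, -1, 1))
})
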