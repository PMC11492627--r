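# Independent oracles and small fixture builders used across the suite.

# Brute-force GLS solve via explicit matrix inversion of the normal equations.
oracle_gls <- function(bx, by, se_out, R, intercept = FALSE) {
  Omega <- R * outer(se_out, se_out)
  W <- solve(Omega)
  X <- if (intercept) cbind(1, bx) else cbind(bx)
  A <- solve(t(X) %*% W %*% X)
  theta <- A %*% t(X) %*% W %*% by
  r <- by - X %*% theta
  slope_idx <- if (intercept) 2 else 1
  ses <- unname(sqrt(diag(A)))
  list(slope = unname(theta[slope_idx, 1]),
       intercept = if (intercept) unname(theta[1, 1]) else 0,
       slope_se = ses[slope_idx],
       intercept_se = if (intercept) ses[1] else NA_real_,
       q = drop(t(r) %*% W %*% r))
}

# Textbook fixed-effect IVW (independent instruments, weights 1/se^2).
oracle_ivw_textbook <- function(bx, by, se_out) {
  w <- 1 / se_out^2
  slope <- sum(w * bx * by) / sum(w * bx^2)
  list(slope = slope, slope_se = sqrt(1 / sum(w * bx^2)))
}

# Straightforward re-implementation of the greedy clumping rule.
oracle_clump <- function(variants, ld, r2_max) {
  kept <- character()
  pool <- variants
  pool_ld <- ld
  while (nrow(pool) > 0) {
    best <- which(pool$p_value == min(pool$p_value))
    if (length(best) > 1)
      best <- best[which.min(as.character(pool$variant_id[best]))]
    id <- pool$variant_id[best]
    kept <- c(kept, id)
    drop <- pool_ld[best, ]^2 > r2_max
    drop[best] <- TRUE
    pool <- pool[!drop, , drop = FALSE]
    pool_ld <- pool_ld[!drop, !drop, drop = FALSE]
  }
  out <- variants[variants$variant_id %in% kept, , drop = FALSE]
  out[order(out$chromosome, out$position), , drop = FALSE]
}

# Exhaustive triple scan over three edge tables.
oracle_triangles <- function(mo, pm, po, thr) {
  hits <- list()
  for (i in seq_len(nrow(pm))) for (j in seq_len(nrow(mo))) for (k in seq_len(nrow(po))) {
    if (pm$outcome[i] != mo$exposure[j]) next
    if (pm$exposure[i] != po$exposure[k]) next
    if (mo$outcome[j] != po$outcome[k]) next
    if (!(pm$p_value[i] < thr$protein_metabolite)) next
    if (!(mo$p_value[j] < thr$metabolite_outcome)) next
    if (!(po$p_value[k] < thr$protein_outcome)) next
    s <- sign(pm$slope[i]) * sign(mo$slope[j])
    if (s == 0 || sign(po$slope[k]) == 0 || s != sign(po$slope[k])) next
    hits[[length(hits) + 1L]] <- data.frame(
      protein_id = pm$exposure[i], metabolite_id = pm$outcome[i],
      outcome_id = mo$outcome[j], stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(protein_id = character(), metabolite_id = character(),
                      outcome_id = character(), stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, hits))
  out <- out[order(out$protein_id, out$metabolite_id, out$outcome_id), ]
  rownames(out) <- NULL
  out
}

# Instrument set straight from effect vectors (identity LD by default).
make_instr <- function(bx, by, sy, R = NULL, sx = rep(0.01, length(bx)),
                       outcome_type = "continuous") {
  n <- length(bx)
  if (is.null(R)) R <- diag(n)
  ids <- sprintf("v%03d", seq_len(n))
  v <- data.frame(variant_id = ids, chromosome = "1",
                  position = seq_len(n) * 1000L, eaf = 0.3,
                  beta_exposure = bx, se_exposure = sx,
                  p_exposure = 2 * pnorm(-abs(bx / sx)),
                  beta_outcome = by, se_outcome = sy,
                  stringsAsFactors = FALSE)
  instrument_set(v, R, outcome_type = outcome_type)
}

# Random MR-result-style edge table.
random_edge_table <- function(exposures, outcomes, seed) {
  set.seed(seed)
  g <- expand.grid(exposure = exposures, outcome = outcomes,
                   stringsAsFactors = FALSE)
  g$slope <- round(rnorm(nrow(g)), 3)
  g$p_value <- runif(nrow(g))^3
  g$status <- "ok"
  g
}

# Minimal summary-statistic table with the full column contract.
make_gwas <- function(ids, beta, se, eaf = 0.3, chromosome = "1",
                      position = seq_along(ids) * 1000L,
                      effect_allele = "A", other_allele = "G", n = 10000L) {
  data.frame(variant_id = ids, chromosome = chromosome,
             position = as.integer(position),
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se,
             p_value = 2 * pnorm(-abs(beta / se)), n = n,
             stringsAsFactors = FALSE)
}
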