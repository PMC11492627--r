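#' Simulation configuration for two-sample GWAS summary statistics
#'
#' Defines the generative model used throughout the test-bench: per-variant
#' exposure effects drawn uniformly from `exposure_effect_range`, an outcome
#' effect for variant j with mean `causal_effect * b_j + alpha_j` (where
#' `alpha_j` is a horizontal-pleiotropy term), and estimation noise whose
#' covariance is proportional to the LD correlation matrix. Standard errors
#' scale as `1/sqrt(n)` for each sample, mirroring a standardised trait.
#'
#' Defaults emulate the scale of a large metabolite GWAS as exposure
#' (n = 86,507) against a modest binary cardiac outcome (effective sample
#' size 6,639, the scale of a dilated-cardiomyopathy GWAS with 2,719 cases
#' and 4,261 controls).
#'
#' @param n_variants Number of variants to simulate (>= 1).
#' @param causal_effect True slope of exposure on outcome (log-odds per unit
#'   for a binary outcome).
#' @param exposure_effect_range Length-2 interval for per-variant true
#'   exposure effects.
#' @param n_exposure,n_outcome Sample-size proxies controlling exposure and
#'   outcome standard errors (`se = 1/sqrt(n)`).
#' @param pleiotropy_mode One of `"none"`, `"balanced"`, `"directional"`.
#' @param pleiotropy_sd Standard deviation of per-variant pleiotropic effects.
#' @param pleiotropy_mean Mean pleiotropic effect; must be 0 unless
#'   `pleiotropy_mode = "directional"`.
#' @param ld_block_size Size of AR(1) LD blocks.
#' @param ld_rho Within-block lag-1 correlation, in `[0, 1)`.
#' @param seed Integer seed; identical configurations give identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_variants = 50L,
                       causal_effect = 0,
                       exposure_effect_range = c(0.1, 0.3),
                       n_exposure = 86507,
                       n_outcome = 6639,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_sd = 0,
                       pleiotropy_mean = 0,
                       ld_block_size = 5L,
                       ld_rho = 0.5,
                       seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (!is_count(n_variants)) stop_domain("n_variants must be a positive integer")
  if (length(exposure_effect_range) != 2L || diff(exposure_effect_range) < 0)
    stop_domain("exposure_effect_range must be an ordered length-2 interval")
  if (n_exposure <= 0 || n_outcome <= 0)
    stop_domain("sample-size proxies must be positive")
  if (pleiotropy_sd < 0) stop_domain("pleiotropy_sd must be >= 0")
  if (pleiotropy_mode != "directional" && pleiotropy_mean != 0)
    stop_domain("pleiotropy_mean must be 0 unless pleiotropy_mode is 'directional'")
  if (!is_count(ld_block_size)) stop_domain("ld_block_size must be a positive integer")
  if (ld_rho < 0 || ld_rho >= 1) stop_domain("ld_rho must lie in [0, 1)")
  structure(list(
    n_variants = as.integer(n_variants),
    causal_effect = causal_effect,
    exposure_effect_range = exposure_effect_range,
    n_exposure = n_exposure,
    n_outcome = n_outcome,
    pleiotropy_mode = pleiotropy_mode,
    pleiotropy_sd = pleiotropy_sd,
    pleiotropy_mean = pleiotropy_mean,
    ld_block_size = as.integer(ld_block_size),
    ld_rho = ld_rho,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Block AR(1) LD correlation matrix
#'
#' Variants are grouped into consecutive blocks of `block_size`; within a
#' block the signed correlation decays as `rho^|i - j|` and across blocks it
#' is 0. The result is symmetric with unit diagonal and positive
#' semi-definite (a stand-in for an external LD reference panel).
#'
#' @param n_variants Number of variants.
#' @param block_size Block size (>= 1); block size 1 gives the identity.
#' @param rho Lag-1 correlation in `[0, 1)`.
#' @param seed Unused (the matrix is deterministic); accepted for interface
#'   symmetry with the other simulators.
#' @return An `n_variants` x `n_variants` correlation matrix.
#' @export
simulate_ld_matrix <- function(n_variants, block_size, rho, seed = NULL) {
  if (!is_count(n_variants)) stop_domain("n_variants must be a positive integer")
  if (!is_count(block_size)) stop_domain("block_size must be a positive integer")
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1)
    stop_domain("rho must lie in [0, 1)")
  idx <- seq_len(n_variants)
  block <- (idx - 1L) %/% block_size
  same_block <- outer(block, block, "==")
  lag <- abs(outer(idx, idx, "-"))
  R <- ifelse(same_block, rho^lag, 0)
  diag(R) <- 1
  R
}

# AR(1) blocks are positive definite for rho in [0,1); chol therefore exists.
mvn_correlated <- function(R, sd) {
  drop(crossprod(chol(R), stats::rnorm(nrow(R)))) * sd
}

variant_table <- function(variant_id, chromosome, position, effect_allele,
                          other_allele, eaf, beta, se, n) {
  data.frame(
    variant_id = variant_id,
    chromosome = as.character(chromosome),
    position = as.integer(position),
    effect_allele = effect_allele,
    other_allele = other_allele,
    eaf = eaf,
    beta = beta,
    se = se,
    p_value = z_pvalue(beta / se),
    n = n,
    stringsAsFactors = FALSE
  )
}

# Swap the allele coding of the given rows of a summary-statistic table.
flip_coding <- function(tab, idx) {
  ea <- tab$effect_allele[idx]
  tab$effect_allele[idx] <- tab$other_allele[idx]
  tab$other_allele[idx] <- ea
  tab$beta[idx] <- -tab$beta[idx]
  tab$eaf[idx] <- 1 - tab$eaf[idx]
  tab
}

#' Simulate a two-sample MR dataset with known ground truth
#'
#' Generates exposure and outcome summary-statistic tables over a shared set
#' of variants. Exposure estimates are the true per-variant effects plus
#' independent noise (two-sample independence); outcome estimates have mean
#' `causal_effect * b_j + alpha_j` and correlated noise with covariance
#' `se_outcome^2 * R`, the model the GLS estimator downstream assumes. Ten
#' percent of variants (rounded) have their allele coding flipped in the
#' outcome table to exercise harmonisation; the LD matrix is reported in the
#' exposure coding.
#'
#' @param config A [sim_config()].
#' @return A list with elements `exposure`, `outcome` (summary-statistic
#'   data frames), `ld` (correlation matrix with variant-id dimnames), and
#'   `truth` (list with `causal_effect`, `per_variant_pleiotropy`,
#'   `exposure_betas_true`, `flipped_variants`).
#' @export
simulate_mr_dataset <- function(config) {
  if (!inherits(config, "sim_config")) stop_domain("config must be a sim_config")
  with_seed(config$seed, {
    n <- config$n_variants
    ld <- simulate_ld_matrix(n, config$ld_block_size, config$ld_rho)
    bx_true <- stats::runif(n, config$exposure_effect_range[1],
                            config$exposure_effect_range[2])
    alpha <- switch(config$pleiotropy_mode,
      none = rep(0, n),
      balanced = stats::rnorm(n, 0, config$pleiotropy_sd),
      directional = stats::rnorm(n, config$pleiotropy_mean, config$pleiotropy_sd)
    )
    se_x <- 1 / sqrt(config$n_exposure)
    se_y <- 1 / sqrt(config$n_outcome)
    bx_hat <- bx_true + stats::rnorm(n, 0, se_x)
    by_hat <- config$causal_effect * bx_true + alpha + mvn_correlated(ld, se_y)

    ids <- sprintf("rs%05d", seq_len(n))
    dimnames(ld) <- list(ids, ids)
    pos <- seq(100000L, by = 50000L, length.out = n)
    alleles <- t(vapply(seq_len(n), function(i) sample(c("A", "C", "G", "T"), 2L),
                        character(2L)))
    eaf <- stats::runif(n, 0.05, 0.95)

    exposure <- variant_table(ids, "1", pos, alleles[, 1], alleles[, 2],
                              eaf, bx_hat, se_x, config$n_exposure)
    outcome <- variant_table(ids, "1", pos, alleles[, 1], alleles[, 2],
                             eaf, by_hat, se_y, config$n_outcome)
    flip_idx <- sample(n, size = round(0.1 * n))
    outcome <- flip_coding(outcome, flip_idx)

    list(
      exposure = exposure,
      outcome = outcome,
      ld = ld,
      truth = list(
        causal_effect = config$causal_effect,
        per_variant_pleiotropy = alpha,
        exposure_betas_true = bx_true,
        flipped_variants = ids[sort(flip_idx)]
      )
    )
  })
}

#' Simulate annotation fixture tables
#'
#' Produces the local stand-ins for the external annotation resources used
#' for prioritisation: a tissue-expression table (one row per protein with
#' `n_tissues` non-negative abundances, the first labelled `heart_muscle`),
#' a druggability table, a pathway-membership table, and a gene annotation
#' table locating each protein-encoding gene.
#'
#' @param n_proteins,n_pathways Numbers of proteins and pathways (>= 1).
#' @param n_tissues Number of tissues (default 61, one cardiac plus 60 other).
#' @param seed Integer seed.
#' @return A list with data frames `expression`, `druggability`, `pathways`,
#'   `genes`.
#' @export
simulate_annotation_fixtures <- function(n_proteins, n_pathways,
                                         n_tissues = 61L, seed = 1L) {
  if (!is_count(n_proteins) || !is_count(n_pathways) || !is_count(n_tissues))
    stop_domain("counts must be positive integers")
  with_seed(seed, {
    proteins <- sprintf("P%03d", seq_len(n_proteins))
    tissues <- c("heart_muscle", sprintf("tissue_%02d", seq_len(n_tissues - 1L)))
    abund <- matrix(stats::rlnorm(n_proteins * n_tissues, meanlog = 1, sdlog = 1),
                    nrow = n_proteins, dimnames = list(NULL, tissues))
    expression <- cbind(data.frame(protein_id = proteins, stringsAsFactors = FALSE),
                        as.data.frame(abund))

    status <- sample(c("drugged", "druggable", "none"), n_proteins,
                     replace = TRUE, prob = c(0.2, 0.2, 0.6))
    n_drugs <- ifelse(status == "none", 0L, sample.int(20L, n_proteins, replace = TRUE))
    druggability <- data.frame(
      protein_id = proteins,
      status = status,
      n_drugs = n_drugs,
      drugs = vapply(n_drugs, function(k) {
        if (k == 0L) "" else paste(sprintf("drug%02d", sample.int(99L, k)), collapse = ";")
      }, character(1L)),
      cardiac_indication = status != "none" & stats::runif(n_proteins) < 0.3,
      cardiac_side_effect = status != "none" & stats::runif(n_proteins) < 0.3,
      stringsAsFactors = FALSE
    )

    member <- matrix(stats::runif(n_proteins * n_pathways) < 0.15,
                     nrow = n_proteins)
    pathways <- do.call(rbind, lapply(seq_len(n_pathways), function(w) {
      hit <- proteins[member[, w]]
      if (!length(hit)) return(NULL)
      data.frame(pathway_id = sprintf("PW%02d", w), protein_id = hit,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(pathways))
      pathways <- data.frame(pathway_id = character(), protein_id = character(),
                             stringsAsFactors = FALSE)

    start <- sample(1e6:2e8, n_proteins, replace = TRUE)
    genes <- data.frame(
      gene_id = sprintf("GENE%03d", seq_len(n_proteins)),
      chromosome = as.character(sample(1:22, n_proteins, replace = TRUE)),
      start = start,
      end = start + sample(5e3:2e5, n_proteins, replace = TRUE),
      encoded_protein = proteins,
      stringsAsFactors = FALSE
    )

    list(expression = expression, druggability = druggability,
         pathways = pathways, genes = genes)
  })
}
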