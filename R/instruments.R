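#' Per-variant instrument-strength F statistic
#'
#' The squared z statistic `(beta/se)^2` of the variant-exposure association,
#' the usual single-variant instrument-strength measure in two-sample MR.
#'
#' @param beta Per-allele effect estimate(s).
#' @param se Standard error(s), strictly positive.
#' @return Numeric vector of F statistics.
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) stop_domain("se must be > 0")
  (beta / se)^2
}

#' Filter candidate instruments on strength and frequency
#'
#' Retains variants with `f_statistic >= f_min` and a minor allele frequency
#' (the folded frequency `min(eaf, 1 - eaf)`) of at least `maf_min`. Both
#' boundaries are inclusive and input order is preserved.
#'
#' @param variants Summary-statistic data frame with columns `beta`, `se`,
#'   `eaf`.
#' @param f_min Minimum exposure F statistic (default 24).
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @return The retained rows of `variants`.
#' @export
filter_instruments <- function(variants, f_min = 24, maf_min = 0.01) {
  if (nrow(variants) == 0L) return(variants)
  keep <- f_statistic(variants$beta, variants$se) >= f_min &
    pmin(variants$eaf, 1 - variants$eaf) >= maf_min
  variants[keep, , drop = FALSE]
}

#' Restrict variants to the cis window of a gene
#'
#' Keeps variants on the gene's chromosome whose position lies in the closed
#' interval `[start - flank, end + flank]` (1-based coordinates). The default
#' flank of 200 kb on each side of the gene body is the usual cis-pQTL
#' window in drug-target MR.
#'
#' @param gene A list or one-row data frame with `chromosome`, `start`, `end`.
#' @param variants Summary-statistic data frame with `chromosome`, `position`.
#' @param flank Flank size in base pairs (default 200,000).
#' @return The retained rows of `variants`.
#' @export
select_cis_window <- function(gene, variants, flank = 200000) {
  if (gene$start > gene$end) stop_domain("gene start must be <= end")
  keep <- variants$chromosome == as.character(gene$chromosome) &
    variants$position >= gene$start - flank &
    variants$position <= gene$end + flank
  variants[keep, , drop = FALSE]
}

#' Greedy LD clumping
#'
#' Repeatedly retains the remaining variant with the smallest p-value (ties
#' broken by lexicographically smallest `variant_id`) and drops every
#' remaining variant whose squared correlation with it exceeds `r2_max`.
#' The output is sorted by genomic position and no retained pair has
#' `r^2 > r2_max`.
#'
#' @param variants Data frame with `variant_id`, `p_value`, `chromosome`,
#'   `position`, aligned row-wise with `ld`.
#' @param ld Signed correlation matrix aligned to `variants`.
#' @param r2_max Maximum allowed pairwise r-squared (default 0.3).
#' @return The retained rows of `variants`, position-sorted.
#' @export
clump <- function(variants, ld, r2_max = 0.3) {
  n <- nrow(variants)
  if (!is.matrix(ld) || nrow(ld) != n || ncol(ld) != n)
    stop_domain("LD matrix is not aligned to the variant table")
  if (!is.null(rownames(ld)) &&
      !identical(unname(rownames(ld)), as.character(variants$variant_id)))
    stop_domain("LD matrix row names do not match variant ids")
  remaining <- seq_len(n)
  kept <- integer()
  while (length(remaining)) {
    o <- order(variants$p_value[remaining],
               as.character(variants$variant_id[remaining]))
    i <- remaining[o[1L]]
    kept <- c(kept, i)
    r2 <- ld[i, remaining]^2
    remaining <- setdiff(remaining[r2 <= r2_max], i)
  }
  out <- variants[kept, , drop = FALSE]
  out[order(out$chromosome, out$position), , drop = FALSE]
}

is_palindromic <- function(a1, a2) {
  p <- paste0(a1, a2)
  p %in% c("AT", "TA", "CG", "GC")
}

#' Construct an instrument set
#'
#' Container for harmonised exposure/outcome effect pairs over an ordered
#' variant list, together with the signed LD correlation submatrix aligned
#' to that order.
#'
#' @param variants Data frame with at least `variant_id`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`.
#' @param ld Signed correlation matrix aligned to `variants`.
#' @param exposure_id,outcome_id Identifiers.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @return An object of class `instrument_set`.
#' @export
instrument_set <- function(variants, ld, exposure_id = "exposure",
                           outcome_id = "outcome",
                           outcome_type = c("continuous", "binary")) {
  outcome_type <- match.arg(outcome_type)
  n <- nrow(variants)
  if (!is.matrix(ld) || nrow(ld) != n || ncol(ld) != n)
    stop_domain("LD matrix dimensions do not match the variant count")
  if (n > 0) {
    if (max(abs(ld - t(ld))) > 1e-8) stop_domain("LD matrix must be symmetric")
    if (max(abs(diag(ld) - 1)) > 1e-8) stop_domain("LD matrix must have unit diagonal")
  }
  dimnames(ld) <- list(variants$variant_id, variants$variant_id)
  structure(list(variants = variants, ld = ld, exposure_id = exposure_id,
                 outcome_id = outcome_id, outcome_type = outcome_type),
            class = "instrument_set")
}

subset_instruments <- function(instr, keep) {
  instrument_set(instr$variants[keep, , drop = FALSE],
                 instr$ld[keep, keep, drop = FALSE],
                 instr$exposure_id, instr$outcome_id, instr$outcome_type)
}

#' Harmonise exposure and outcome summary statistics
#'
#' Intersects the two tables on `variant_id` (exposure order preserved) and
#' aligns the outcome records to the exposure allele coding: where the
#' outcome's effect allele equals the exposure's other allele (and vice
#' versa) the outcome beta sign is flipped and its frequency replaced by
#' `1 - eaf`. Palindromic variants (A/T or C/G) whose folded frequency
#' exceeds `palindrome_eaf_max` in either sample are dropped as strand-
#' unresolvable, as are variants whose allele sets do not match.
#'
#' The LD matrix is subset to the surviving variants. By default it is taken
#' to be aligned to the exposure coding (exposure data pre-aligned to the LD
#' reference) and its signs are untouched; with `ld_coding = "outcome"` the
#' sign of r is flipped for every allele-flipped variant.
#'
#' @param exposure,outcome Summary-statistic data frames (columns
#'   `variant_id`, `chromosome`, `position`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `p_value`).
#' @param ld Optional signed LD matrix with variant-id dimnames covering the
#'   intersection.
#' @param palindrome_eaf_max Folded-frequency cutoff above which palindromic
#'   variants are dropped (default 0.42).
#' @param ld_coding Allele coding the LD matrix is aligned to.
#' @param exposure_id,outcome_id,outcome_type Passed to [instrument_set()].
#' @return An [instrument_set()].
#' @export
harmonize <- function(exposure, outcome, ld = NULL,
                      palindrome_eaf_max = 0.42,
                      ld_coding = c("exposure", "outcome"),
                      exposure_id = "exposure", outcome_id = "outcome",
                      outcome_type = c("continuous", "binary")) {
  ld_coding <- match.arg(ld_coding)
  outcome_type <- match.arg(outcome_type)
  common <- exposure$variant_id[exposure$variant_id %in% outcome$variant_id]
  if (!length(common)) stop_domain("no overlapping instruments")
  e <- exposure[match(common, exposure$variant_id), , drop = FALSE]
  o <- outcome[match(common, outcome$variant_id), , drop = FALSE]

  same <- e$effect_allele == o$effect_allele & e$other_allele == o$other_allele
  swap <- e$effect_allele == o$other_allele & e$other_allele == o$effect_allele
  pal <- is_palindromic(e$effect_allele, e$other_allele)
  folded_e <- pmin(e$eaf, 1 - e$eaf)
  folded_o <- pmin(o$eaf, 1 - o$eaf)
  drop_pal <- pal & (folded_e > palindrome_eaf_max | folded_o > palindrome_eaf_max)
  keep <- (same | swap) & !drop_pal
  if (!any(keep)) stop_domain("no overlapping instruments after harmonisation")

  flip <- swap[keep]
  ek <- e[keep, , drop = FALSE]
  ok <- o[keep, , drop = FALSE]
  variants <- data.frame(
    variant_id = ek$variant_id,
    chromosome = ek$chromosome,
    position = ek$position,
    eaf = ek$eaf,
    beta_exposure = ek$beta,
    se_exposure = ek$se,
    p_exposure = ek$p_value,
    beta_outcome = ifelse(flip, -ok$beta, ok$beta),
    se_outcome = ok$se,
    stringsAsFactors = FALSE
  )

  if (is.null(ld)) {
    ldk <- diag(nrow(variants))
  } else {
    if (is.null(rownames(ld))) stop_domain("LD matrix needs variant-id dimnames")
    if (!all(variants$variant_id %in% rownames(ld)))
      stop_domain("LD matrix does not cover all harmonised variants")
    ldk <- ld[variants$variant_id, variants$variant_id, drop = FALSE]
    if (ld_coding == "outcome") {
      s <- ifelse(flip, -1, 1)
      ldk <- ldk * tcrossprod(s)
    }
  }
  instrument_set(variants, ldk, exposure_id, outcome_id, outcome_type)
}

# Clump an instrument set on the exposure p-values, keeping LD aligned.
clump_instruments <- function(instr, r2_max = 0.3) {
  v <- instr$variants
  v$p_value <- v$p_exposure
  kept <- clump(v, instr$ld, r2_max)$variant_id
  subset_instruments(instr, match(kept, instr$variants$variant_id))
}
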