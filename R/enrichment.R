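#' Cardiac expression fraction
#'
#' Each tissue's share of a gene's total abundance; zero when the total is
#' zero. Across all tissues the fractions sum to 1 (for a positive total).
#'
#' @param abundances Named non-negative abundance vector.
#' @return Vector of fractions aligned with `abundances`.
#' @export
expression_fractions <- function(abundances) {
  total <- sum(abundances)
  if (total <= 0) return(abundances * 0)
  abundances / total
}

#' Cardiac expression and overexpression flags
#'
#' A gene is "expressed" in cardiac tissue when its cardiac abundance
#' exceeds `expressed_min` (default 0). It is "overexpressed" when the
#' cardiac abundance exceeds the mean of the other 60 tissues by a one-sided
#' z test using the across-tissue standard deviation of those other tissues,
#' significant at `overexpression_alpha`. This test is a provisional
#' screening statistic, not a calibrated differential-expression model.
#'
#' @param abundances Named abundance vector over all tissues.
#' @param cardiac Name of the cardiac tissue (default `"heart_muscle"`).
#' @param n_tissues Expected tissue count (default 61); a mismatch is a
#'   structural error.
#' @param overexpression_alpha One-sided test level (default 0.05).
#' @param expressed_min Abundance strictly above which the gene counts as
#'   expressed (default 0).
#' @return List with `expressed`, `overexpressed`, `z`, `cardiac_fraction`.
#' @export
cardiac_expression_flags <- function(abundances, cardiac = "heart_muscle",
                                     n_tissues = 61L,
                                     overexpression_alpha = 0.05,
                                     expressed_min = 0) {
  if (length(abundances) != n_tissues)
    stop_domain("expected ", n_tissues, " tissues, got ", length(abundances))
  if (!cardiac %in% names(abundances))
    stop_domain("no tissue named '", cardiac, "'")
  heart <- abundances[[cardiac]]
  others <- abundances[names(abundances) != cardiac]
  expressed <- heart > expressed_min
  s <- stats::sd(others)
  z <- if (s > 0) (heart - mean(others)) / s else if (heart > mean(others)) Inf else -Inf
  overexpressed <- expressed && z > stats::qnorm(1 - overexpression_alpha)
  list(expressed = expressed, overexpressed = overexpressed, z = z,
       cardiac_fraction = expression_fractions(abundances)[[cardiac]])
}

#' Wald test for enrichment of a group among prioritised proteins
#'
#' Compares the proportion of prioritised proteins in a group with the
#' background proportion over all tested proteins:
#' `z = (p1 - p0) / sqrt(p0 (1 - p0) / n1)` with `p1` the prioritised and
#' `p0` the background proportion, referred to a standard normal. The
#' background-proportion standard error is the default; a pooled two-sample
#' form is available via `se_method = "pooled"`. A degenerate background
#' proportion (0 or 1) yields p = 1 with `degenerate = TRUE`.
#'
#' @param prioritised Character vector of prioritised protein ids (subset of
#'   `background`; must be non-empty).
#' @param background Character vector of all tested protein ids.
#' @param group Character vector of group members (non-empty).
#' @param group_label Label echoed into the result.
#' @param se_method `"null"` (background proportion) or `"pooled"`.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return One-row data frame with the four counts, `z`, `p_value`,
#'   `degenerate`.
#' @export
wald_proportion_enrichment <- function(prioritised, background, group,
                                       group_label = "group",
                                       se_method = c("null", "pooled"),
                                       alternative = c("two.sided", "greater")) {
  se_method <- match.arg(se_method)
  alternative <- match.arg(alternative)
  prioritised <- unique(prioritised)
  background <- unique(background)
  group <- unique(group)
  if (!length(prioritised)) stop_domain("prioritised set is empty")
  if (!length(group)) stop_domain("group is empty")
  if (!all(prioritised %in% background))
    stop_domain("prioritised proteins must be a subset of the background")
  n1 <- length(prioritised)
  n0 <- length(background)
  k1 <- sum(prioritised %in% group)
  k0 <- sum(background %in% group)
  p1 <- k1 / n1
  p0 <- k0 / n0
  degenerate <- p0 <= 0 || p0 >= 1
  if (degenerate) {
    z <- 0
    p <- 1
  } else {
    se <- switch(se_method,
      null = sqrt(p0 * (1 - p0) / n1),
      pooled = sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
    )
    z <- (p1 - p0) / se
    p <- if (alternative == "two.sided") z_pvalue(z) else stats::pnorm(z, lower.tail = FALSE)
  }
  data.frame(group_label = group_label,
             k_prioritised_in_group = k1, n_prioritised = n1,
             k_background_in_group = k0, n_background = n0,
             z = z, p_value = p, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Annotate proteins with druggability status
#'
#' Left-joins the prioritised proteins against a druggability table
#' (protein, status in {drugged, druggable, none}, drug list and cardiac
#' indication/side-effect flags); proteins missing from the table are
#' labelled `none` with zero drugs.
#'
#' @param proteins Character vector of protein ids.
#' @param druggability Data frame with `protein_id`, `status`, `n_drugs`,
#'   and optionally `drugs`, `cardiac_indication`, `cardiac_side_effect`.
#' @return Data frame with one row per input protein, order preserved.
#' @export
annotate_druggability <- function(proteins, druggability) {
  out <- data.frame(protein_id = proteins, stringsAsFactors = FALSE)
  if (!nrow(out)) {
    out$status <- character(0)
    out$n_drugs <- integer(0)
    return(out)
  }
  m <- match(proteins, druggability$protein_id)
  out$status <- ifelse(is.na(m), "none", druggability$status[m])
  out$n_drugs <- ifelse(is.na(m), 0L, druggability$n_drugs[m])
  for (col in c("drugs", "cardiac_indication", "cardiac_side_effect")) {
    if (col %in% names(druggability)) {
      fill <- if (col == "drugs") "" else FALSE
      out[[col]] <- ifelse(is.na(m), fill, druggability[[col]][m])
    }
  }
  out
}

#' Assess replication of discovery associations
#'
#' A discovery association replicates nominally when at least one
#' replication study shows the same effect direction with p < 0.05, and
#' conservatively when the replication p-value additionally passes the
#' multiplicity-corrected cut `0.05 / n_tested`. Summary percentages are
#' reported relative to `n_tested` and rounded to one decimal.
#'
#' @param discovery Data frame with `protein_id`, `outcome_id`, `slope`
#'   (discovery effect on the log-odds / mean-difference scale).
#' @param replication Data frame with `protein_id`, `outcome_id`,
#'   `study_id`, `slope`, `p_value`.
#' @param n_tested Number of proteins sought for replication (>= 1).
#' @param alpha Nominal replication level (default 0.05).
#' @return List with `verdicts` (per discovery row: `nominal`,
#'   `conservative`, `n_studies`) and `summary` (counts and percentages at
#'   the protein level, plus the conservative threshold).
#' @export
assess_replication <- function(discovery, replication, n_tested,
                               alpha = 0.05) {
  if (!is_count(n_tested)) stop_domain("n_tested must be a positive integer")
  conservative_cut <- alpha / n_tested
  verdicts <- discovery[, c("protein_id", "outcome_id")]
  verdicts$discovery_sign <- sign(discovery$slope)
  verdicts$n_studies <- 0L
  verdicts$nominal <- FALSE
  verdicts$conservative <- FALSE
  for (i in seq_len(nrow(verdicts))) {
    rep_i <- replication[replication$protein_id == verdicts$protein_id[i] &
                         replication$outcome_id == verdicts$outcome_id[i], ,
                         drop = FALSE]
    verdicts$n_studies[i] <- nrow(rep_i)
    if (!nrow(rep_i)) next
    same <- sign(rep_i$slope) == verdicts$discovery_sign[i]
    verdicts$nominal[i] <- any(same & rep_i$p_value < alpha)
    verdicts$conservative[i] <- any(same & rep_i$p_value < conservative_cut)
  }
  by_protein <- function(flag) {
    length(unique(verdicts$protein_id[flag]))
  }
  n_nominal <- by_protein(verdicts$nominal)
  n_conservative <- by_protein(verdicts$conservative)
  list(
    verdicts = verdicts,
    summary = list(
      n_tested = n_tested,
      conservative_threshold = conservative_cut,
      n_nominal = n_nominal,
      pct_nominal = round(100 * n_nominal / n_tested, 1),
      n_conservative = n_conservative,
      pct_conservative = round(100 * n_conservative / n_tested, 1)
    )
  )
}
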