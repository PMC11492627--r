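#' MR analysis configuration
#'
#' Collects the numeric knobs of the MR pipeline. Defaults follow standard
#' drug-target MR practice: instruments need an exposure F statistic of at
#' least 24 and MAF >= 0.01, are clumped to r-squared 0.3, protein
#' instruments come from a 200-kb window around the encoding gene, analyses
#' with fewer than 6 variants are discarded, variants with leverage above
#' three times the mean or a squared standardised residual above 10.83 (the
#' 0.999 quantile of chi-square with 1 df) are excluded, and the
#' IVW-vs-Egger choice tests the Q difference at alpha 0.05.
#'
#' @param f_min,maf_min Instrument-strength and frequency cutoffs.
#' @param r2_max Clumping r-squared threshold.
#' @param flank Cis-window flank in base pairs.
#' @param min_variants Minimum variants below which an analysis is discarded.
#' @param leverage_factor Multiple of the mean leverage above which a variant
#'   is excluded.
#' @param outlier_cut Squared standardised residual above which a variant is
#'   excluded.
#' @param selection_alpha Alpha for the heterogeneity-difference model
#'   selection.
#' @param max_prune_rounds Cap on prune/refit iterations.
#' @param ridge Ridge added to the LD diagonal before inversion.
#' @param palindrome_eaf Folded-frequency cutoff for palindromic variants.
#' @param conf_z Normal quantile used for 95 percent confidence intervals
#'   (1.96 verbatim, so printed intervals round-trip).
#' @return A list of class `mr_config`.
#' @export
mr_config <- function(f_min = 24, maf_min = 0.01, r2_max = 0.3,
                      flank = 200000, min_variants = 6, leverage_factor = 3,
                      outlier_cut = 10.83, selection_alpha = 0.05,
                      max_prune_rounds = 10, ridge = 1e-8,
                      palindrome_eaf = 0.42, conf_z = 1.96) {
  structure(as.list(environment()), class = "mr_config")
}

#' Generalised least squares IVW / Egger fit
#'
#' Regresses outcome betas on exposure betas with weight matrix
#' `solve(Omega)`, `Omega = D R D` with `D = diag(se_outcome)` and `R` the
#' signed LD correlation matrix — the GLS implementation of the
#' inverse-variance-weighted estimator for correlated instruments. With
#' `with_intercept = TRUE` an unpenalised intercept column is added (the
#' Egger correction; the intercept absorbs directional pleiotropy).
#'
#' Returns, besides the coefficient estimates and their standard errors from
#' `solve(t(X) Omega^-1 X)`, the heterogeneity statistic
#' `Q = r' Omega^-1 r`, the diagonal of the GLS hat matrix (leverage, which
#' sums to the number of fitted parameters), and per-variant squared
#' whitened residuals (each variant's additive contribution to Q).
#'
#' @param instr An [instrument_set()].
#' @param with_intercept Fit the Egger model (free intercept)?
#' @param ridge Ridge added to the diagonal of `R` before factorisation;
#'   a matrix that remains non-factorisable fails with an
#'   "ill-conditioned LD" error.
#' @return An object of class `mr_fit`.
#' @export
fit_gls <- function(instr, with_intercept = FALSE, ridge = 1e-8) {
  v <- instr$variants
  n <- nrow(v)
  p <- if (with_intercept) 2L else 1L
  if (n < p + 1L)
    stop_domain("need at least ", p + 1L, " variants for this fit")
  R <- instr$ld
  R <- R + diag(ridge, n)
  Omega <- R * tcrossprod(v$se_outcome)
  U <- tryCatch(chol(Omega),
                error = function(e) stop_domain("ill-conditioned LD correlation matrix"))
  X <- if (with_intercept) {
    cbind(intercept = rep(1, n), slope = v$beta_exposure)
  } else {
    cbind(slope = v$beta_exposure)
  }
  Xw <- backsolve(U, X, transpose = TRUE)
  yw <- backsolve(U, v$beta_outcome, transpose = TRUE)
  XtXi <- solve(crossprod(Xw))
  theta <- drop(XtXi %*% crossprod(Xw, yw))
  names(theta) <- colnames(X)
  rw <- drop(yw - Xw %*% theta)
  se <- stats::setNames(sqrt(diag(XtXi)), colnames(X))
  leverage <- rowSums((Xw %*% XtXi) * Xw)
  structure(list(
    estimator = if (with_intercept) "Egger" else "IVW",
    slope = theta[["slope"]],
    slope_se = se[["slope"]],
    intercept = if (with_intercept) theta[["intercept"]] else 0,
    intercept_se = if (with_intercept) se[["intercept"]] else NA_real_,
    q_statistic = sum(rw^2),
    df = n - p,
    n_variants_used = n,
    leverage = stats::setNames(leverage, v$variant_id),
    outlier_stats = stats::setNames(rw^2, v$variant_id)
  ), class = "mr_fit")
}

#' Exclude high-leverage and outlier variants
#'
#' Removes the union of variants whose leverage exceeds `leverage_factor`
#' times the mean leverage and variants whose squared standardised residual
#' exceeds `outlier_cut` (10.83 by default, the chi-square(1) 0.999
#' quantile), returning the reduced instrument set with its LD submatrix.
#' The excluded ids are attached as attributes `excluded_leverage` and
#' `excluded_outlier`.
#'
#' @param instr The [instrument_set()] the fit was computed on.
#' @param fit An [fit_gls()] result on `instr`.
#' @param leverage_factor,outlier_cut Exclusion thresholds.
#' @return The pruned [instrument_set()].
#' @export
prune_variants <- function(instr, fit, leverage_factor = 3, outlier_cut = 10.83) {
  if (!identical(names(fit$leverage), as.character(instr$variants$variant_id)))
    stop_domain("fit was not computed on this instrument set")
  lev_out <- fit$leverage > leverage_factor * mean(fit$leverage)
  chi_out <- fit$outlier_stats > outlier_cut
  keep <- !(lev_out | chi_out)
  out <- subset_instruments(instr, which(keep))
  attr(out, "excluded_leverage") <- names(fit$leverage)[lev_out]
  attr(out, "excluded_outlier") <- names(fit$outlier_stats)[chi_out]
  out
}

#' Heterogeneity-difference model selection
#'
#' Chooses between the IVW and Egger fits by the drop in heterogeneity: the
#' Egger model is selected iff `Q_IVW - Q_Egger` exceeds the upper-alpha
#' quantile of the chi-square distribution with 1 df (3.841 at alpha 0.05).
#' Because the models are nested, a Q difference materially below zero
#' signals an internal inconsistency and errors.
#'
#' @param ivw_fit,egger_fit [fit_gls()] results on the same instrument set.
#' @param alpha Test level (default 0.05).
#' @return `"IVW"` or `"Egger"`.
#' @export
rucker_select <- function(ivw_fit, egger_fit, alpha = 0.05) {
  qdiff <- ivw_fit$q_statistic - egger_fit$q_statistic
  if (qdiff < -1e-6 * (1 + abs(ivw_fit$q_statistic)))
    stop_domain("internal inconsistency: Q_IVW < Q_Egger on nested fits")
  if (qdiff > stats::qchisq(1 - alpha, df = 1)) "Egger" else "IVW"
}

#' Convert a slope to the reporting scale
#'
#' For binary outcomes the slope (log odds ratio) and its Wald limits
#' `slope +/- 1.96 * se` are exponentiated to an odds ratio with 95 percent
#' confidence interval; continuous outcomes are reported as mean differences
#' on the identity scale.
#'
#' @param slope,slope_se Estimate and standard error (`slope_se > 0`).
#' @param outcome_type `"binary"` or `"continuous"`.
#' @param conf_z Normal quantile for the interval (default 1.96).
#' @return List with `estimate`, `ci_lower`, `ci_upper`, `effect_scale`.
#' @export
to_reported_effect <- function(slope, slope_se,
                               outcome_type = c("binary", "continuous"),
                               conf_z = 1.96) {
  outcome_type <- match.arg(outcome_type)
  if (!is.finite(slope_se) || slope_se <= 0) stop_domain("slope_se must be > 0")
  lo <- slope - conf_z * slope_se
  hi <- slope + conf_z * slope_se
  if (outcome_type == "binary") {
    list(estimate = exp(slope), ci_lower = exp(lo), ci_upper = exp(hi),
         effect_scale = "odds ratio")
  } else {
    list(estimate = slope, ci_lower = lo, ci_upper = hi,
         effect_scale = "mean difference")
  }
}

discarded_result <- function(exposure_id, outcome_id, outcome_type, n_input,
                             stage, n_at_stage) {
  data.frame(
    exposure = exposure_id, outcome = outcome_id, status = "discarded",
    estimator = "discarded", outcome_type = outcome_type,
    effect_scale = NA_character_, n_input = n_input,
    n_variants = n_at_stage, slope = NA_real_, se = NA_real_,
    intercept = NA_real_, intercept_se = NA_real_, p_value = NA_real_,
    estimate = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
    q_ivw = NA_real_, q_egger = NA_real_,
    excluded_leverage = "", excluded_outlier = "",
    discard_stage = stage, stringsAsFactors = FALSE
  )
}

#' Run a complete two-sample MR analysis
#'
#' Pipeline: strength/frequency filter, optional cis-window restriction,
#' allele harmonisation, LD clumping, GLS-IVW and Egger fits with iterative
#' leverage/outlier pruning (statistics recomputed from the IVW fit each
#' round, union removed, refit; capped rounds), heterogeneity-difference
#' model selection, and reporting on the odds-ratio or mean-difference
#' scale. If fewer than `min_variants` variants remain at any stage the
#' analysis is discarded and no estimate is reported. The p-value is a
#' two-sided normal test of `slope / slope_se` of the selected estimator.
#'
#' @param exposure,outcome Summary-statistic data frames.
#' @param ld Signed LD matrix with variant-id dimnames (exposure coding);
#'   `NULL` for independent instruments.
#' @param gene Optional gene annotation (`chromosome`, `start`, `end`) for a
#'   cis analysis.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param exposure_id,outcome_id Identifiers echoed into the result.
#' @param config An [mr_config()].
#' @return An object of class `mr_analysis`: list with `result` (one-row
#'   data frame), `ivw`, `egger` (final [fit_gls()] objects or `NULL`),
#'   `instruments` (final set), `excluded` (ids by reason), `stage_counts`.
#' @export
run_mr <- function(exposure, outcome, ld = NULL, gene = NULL,
                   outcome_type = c("continuous", "binary"),
                   exposure_id = "exposure", outcome_id = "outcome",
                   config = mr_config()) {
  outcome_type <- match.arg(outcome_type)
  counts <- c(input = nrow(exposure))
  discard <- function(stage, n) {
    list(result = discarded_result(exposure_id, outcome_id, outcome_type,
                                   counts[["input"]], stage, n),
         ivw = NULL, egger = NULL, instruments = NULL,
         excluded = list(leverage = character(), outlier = character()),
         stage_counts = counts)
  }

  x <- filter_instruments(exposure, config$f_min, config$maf_min)
  counts["filtered"] <- nrow(x)
  if (nrow(x) < config$min_variants) return(discard("filter", nrow(x)))
  if (!is.null(gene)) {
    x <- select_cis_window(gene, x, config$flank)
    counts["cis"] <- nrow(x)
    if (nrow(x) < config$min_variants) return(discard("cis_window", nrow(x)))
  }
  instr <- harmonize(x, outcome, ld, config$palindrome_eaf,
                     exposure_id = exposure_id, outcome_id = outcome_id,
                     outcome_type = outcome_type)
  counts["harmonised"] <- nrow(instr$variants)
  if (nrow(instr$variants) < config$min_variants)
    return(discard("harmonise", nrow(instr$variants)))
  instr <- clump_instruments(instr, config$r2_max)
  counts["clumped"] <- nrow(instr$variants)
  if (nrow(instr$variants) < config$min_variants)
    return(discard("clump", nrow(instr$variants)))

  excl_lev <- character()
  excl_out <- character()
  ivw <- fit_gls(instr, with_intercept = FALSE, ridge = config$ridge)
  for (round in seq_len(config$max_prune_rounds)) {
    pruned <- prune_variants(instr, ivw, config$leverage_factor, config$outlier_cut)
    if (nrow(pruned$variants) == nrow(instr$variants)) break
    excl_lev <- c(excl_lev, attr(pruned, "excluded_leverage"))
    excl_out <- c(excl_out, attr(pruned, "excluded_outlier"))
    instr <- pruned
    if (nrow(instr$variants) < config$min_variants) {
      out <- discard("prune", nrow(instr$variants))
      out$excluded <- list(leverage = excl_lev, outlier = excl_out)
      return(out)
    }
    ivw <- fit_gls(instr, with_intercept = FALSE, ridge = config$ridge)
  }
  counts["pruned"] <- nrow(instr$variants)

  egger <- fit_gls(instr, with_intercept = TRUE, ridge = config$ridge)
  chosen <- rucker_select(ivw, egger, config$selection_alpha)
  fit <- if (chosen == "Egger") egger else ivw
  rep_eff <- to_reported_effect(fit$slope, fit$slope_se, outcome_type,
                                config$conf_z)
  result <- data.frame(
    exposure = exposure_id, outcome = outcome_id, status = "ok",
    estimator = chosen, outcome_type = outcome_type,
    effect_scale = rep_eff$effect_scale, n_input = counts[["input"]],
    n_variants = fit$n_variants_used, slope = fit$slope, se = fit$slope_se,
    intercept = fit$intercept, intercept_se = fit$intercept_se,
    p_value = z_pvalue(fit$slope / fit$slope_se),
    estimate = rep_eff$estimate, ci_lower = rep_eff$ci_lower,
    ci_upper = rep_eff$ci_upper,
    q_ivw = ivw$q_statistic, q_egger = egger$q_statistic,
    excluded_leverage = paste(excl_lev, collapse = ";"),
    excluded_outlier = paste(excl_out, collapse = ";"),
    discard_stage = NA_character_, stringsAsFactors = FALSE
  )
  structure(list(result = result, ivw = ivw, egger = egger,
                 instruments = instr,
                 excluded = list(leverage = excl_lev, outlier = excl_out),
                 stage_counts = counts),
            class = "mr_analysis")
}
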