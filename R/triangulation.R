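#' Bonferroni multiplicity threshold
#'
#' `alpha / (n_exposures * n_outcomes)`, kept exact for filtering, together
#' with its one-significant-figure value for reporting. With alpha 0.05 the
#' pairings (174, 4), (1567, 36) and (686, 4) give reported thresholds
#' 7e-5, 9e-7 and 2e-5.
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_exposures,n_outcomes Numbers of tested exposures and outcomes.
#' @return List with `alpha`, `n_exposures`, `n_outcomes`, `threshold`
#'   (exact) and `threshold_reported` (one significant figure).
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_exposures, n_outcomes) {
  if (!is_count(n_exposures) || !is_count(n_outcomes))
    stop_domain("counts must be positive integers")
  thr <- alpha / (n_exposures * n_outcomes)
  list(alpha = alpha, n_exposures = n_exposures, n_outcomes = n_outcomes,
       threshold = thr, threshold_reported = signif(thr, 1))
}

#' Select the primary study for a protein
#'
#' When a protein is measured in several proteomic GWAS, the largest sample
#' size study is used for the primary analysis; ties are broken by
#' lexicographically smallest study id for determinism.
#'
#' @param studies Data frame with columns `study_id`, `sample_size`.
#' @return The selected `study_id`.
#' @export
select_primary_study <- function(studies) {
  if (is.null(studies) || nrow(studies) == 0L) stop_domain("no studies supplied")
  o <- order(-studies$sample_size, as.character(studies$study_id))
  studies$study_id[o[1L]]
}

#' Directional concordance of a triangle
#'
#' A (protein, metabolite, outcome) triple is concordant when the sign of
#' the protein-outcome effect equals the product of the protein-metabolite
#' and metabolite-outcome signs: for example, if an increase in a metabolite
#' lowers disease risk, a protein that raises that metabolite must lower
#' disease risk to be deemed concordant.
#'
#' @param sign_pm,sign_mo,sign_po Signs in {-1, +1} (vectorised).
#' @return Logical vector.
#' @export
concordant <- function(sign_pm, sign_mo, sign_po) {
  if (any(sign_pm == 0 | sign_mo == 0 | sign_po == 0))
    stop_domain("undefined direction: zero sign")
  sign_pm * sign_mo == sign_po
}

#' Assemble directionally concordant triangles
#'
#' Keeps every (protein, metabolite, outcome) triple whose three edges each
#' pass their multiplicity threshold (`p < threshold`, tested on the exact
#' Bonferroni value) and whose effect directions are concordant. Signs are
#' taken from the slope on the log-odds / mean-difference scale. A protein
#' may appear in many triangles.
#'
#' @param metabolite_outcome,protein_metabolite,protein_outcome Tidy MR
#'   result tables as produced by [run_mr()] (columns `exposure`, `outcome`,
#'   `slope`, `p_value`; rows with `status != "ok"` are ignored).
#' @param thresholds List with exact thresholds `metabolite_outcome`,
#'   `protein_metabolite`, `protein_outcome` (numbers or
#'   [bonferroni_threshold()] results).
#' @return Data frame with one row per concordant triangle: ids, the three
#'   slopes and p-values, and the `concordant` flag.
#' @export
build_triangles <- function(metabolite_outcome, protein_metabolite,
                            protein_outcome, thresholds) {
  for (nm in c("metabolite_outcome", "protein_metabolite", "protein_outcome"))
    if (is.null(get(nm))) stop_domain("missing edge table: ", nm)
  thr <- lapply(thresholds, function(t) if (is.list(t)) t$threshold else t)

  pass <- function(tab, cut) {
    if (!is.null(tab$status)) tab <- tab[tab$status == "ok", , drop = FALSE]
    tab[!is.na(tab$p_value) & tab$p_value < cut & tab$slope != 0, , drop = FALSE]
  }
  mo <- pass(metabolite_outcome, thr$metabolite_outcome)
  pm <- pass(protein_metabolite, thr$protein_metabolite)
  po <- pass(protein_outcome, thr$protein_outcome)

  empty <- data.frame(protein_id = character(), metabolite_id = character(),
                      outcome_id = character(),
                      beta_protein_metabolite = numeric(),
                      beta_metabolite_outcome = numeric(),
                      beta_protein_outcome = numeric(),
                      p_protein_metabolite = numeric(),
                      p_metabolite_outcome = numeric(),
                      p_protein_outcome = numeric(),
                      concordant = logical(), stringsAsFactors = FALSE)
  if (!nrow(mo) || !nrow(pm) || !nrow(po)) return(empty)

  pm2 <- data.frame(protein_id = pm$exposure, metabolite_id = pm$outcome,
                    beta_protein_metabolite = pm$slope,
                    p_protein_metabolite = pm$p_value, stringsAsFactors = FALSE)
  mo2 <- data.frame(metabolite_id = mo$exposure, outcome_id = mo$outcome,
                    beta_metabolite_outcome = mo$slope,
                    p_metabolite_outcome = mo$p_value, stringsAsFactors = FALSE)
  po2 <- data.frame(protein_id = po$exposure, outcome_id = po$outcome,
                    beta_protein_outcome = po$slope,
                    p_protein_outcome = po$p_value, stringsAsFactors = FALSE)

  tri <- merge(pm2, mo2, by = "metabolite_id")
  tri <- merge(tri, po2, by = c("protein_id", "outcome_id"))
  if (!nrow(tri)) return(empty)
  tri$concordant <- concordant(sign(tri$beta_protein_metabolite),
                               sign(tri$beta_metabolite_outcome),
                               sign(tri$beta_protein_outcome))
  tri <- tri[tri$concordant, , drop = FALSE]
  tri <- tri[order(tri$protein_id, tri$metabolite_id, tri$outcome_id), ,
             drop = FALSE]
  rownames(tri) <- NULL
  tri[, names(empty)]
}

#' Per-protein outcome pleiotropy summary
#'
#' Counts the distinct outcomes each protein's triangles reach and flags
#' proteins affecting two or more (pleiotropic proteins).
#'
#' @param triangles A [build_triangles()] result.
#' @return Data frame with `protein_id`, `n_outcomes`, `pleiotropic`.
#' @export
pleiotropic_summary <- function(triangles) {
  if (is.null(triangles) || !nrow(triangles))
    return(data.frame(protein_id = character(), n_outcomes = integer(),
                      pleiotropic = logical(), stringsAsFactors = FALSE))
  counts <- tapply(triangles$outcome_id, triangles$protein_id,
                   function(x) length(unique(x)))
  out <- data.frame(protein_id = names(counts),
                    n_outcomes = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$pleiotropic <- out$n_outcomes >= 2L
  out[order(out$protein_id), , drop = FALSE]
}

#' Export triangles as a typed node/edge list
#'
#' Mirrors the annotated network view of the triangulation without
#' rendering: nodes typed protein/metabolite/outcome, edges signed.
#'
#' @param triangles A [build_triangles()] result.
#' @return List with data frames `nodes` (`id`, `type`) and `edges`
#'   (`from`, `to`, `edge_type`, `sign`, `beta`, `p_value`).
#' @export
triangle_network <- function(triangles) {
  nodes <- rbind(
    data.frame(id = unique(triangles$protein_id), type = "protein"),
    data.frame(id = unique(triangles$metabolite_id), type = "metabolite"),
    data.frame(id = unique(triangles$outcome_id), type = "outcome")
  )
  edge <- function(from, to, type, beta, p) {
    data.frame(from = from, to = to, edge_type = type,
               sign = sign(beta), beta = beta, p_value = p,
               stringsAsFactors = FALSE)
  }
  edges <- rbind(
    edge(triangles$protein_id, triangles$metabolite_id, "protein_metabolite",
         triangles$beta_protein_metabolite, triangles$p_protein_metabolite),
    edge(triangles$metabolite_id, triangles$outcome_id, "metabolite_outcome",
         triangles$beta_metabolite_outcome, triangles$p_metabolite_outcome),
    edge(triangles$protein_id, triangles$outcome_id, "protein_outcome",
         triangles$beta_protein_outcome, triangles$p_protein_outcome)
  )
  edges <- unique(edges)
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}
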