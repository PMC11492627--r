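#' Load a study bundle from its manifest
#'
#' Reads the `study.yaml` manifest written by [simulate_study()] (or an
#' equivalently structured bundle of real summary statistics) and loads all
#' referenced tables; paths in the manifest are resolved relative to its
#' location.
#'
#' @param study Path to a study manifest, or an already-loaded study list.
#' @return A list with `metabolites`, `outcomes`, `protein_studies`, `ld`,
#'   `genes`, `expression`, `druggability`, `pathways`,
#'   `metabolite_classes`.
#' @export
read_study <- function(study) {
  if (is.list(study) && !is.null(study$metabolites) &&
      is.data.frame(study$metabolites[[1]]))
    return(study)
  if (is.character(study)) {
    dir <- dirname(study)
    y <- yaml::read_yaml(study)
  } else {
    stop_domain("study must be a manifest path or a loaded study list")
  }
  rel <- function(p) file.path(dir, p)
  must <- function(p) {
    if (!file.exists(rel(p))) stop_domain("study file not found: ", p)
    rel(p)
  }
  list(
    ld = read_ld_matrix(must(y$ld_file)),
    genes = read_tsv(must(y$gene_file), colClasses = c(chromosome = "character")),
    expression = read_tsv(must(y$expression_file)),
    druggability = read_tsv(must(y$druggability_file)),
    pathways = read_tsv(must(y$pathway_file)),
    metabolite_classes = if (!is.null(y$metabolite_class_file))
      read_tsv(must(y$metabolite_class_file)) else NULL,
    metabolites = lapply(y$metabolites, function(p) read_gwas_table(must(p))),
    outcomes = lapply(y$outcomes, function(o)
      list(table = read_gwas_table(must(o$file)), type = o$type)),
    protein_studies = lapply(y$protein_studies, function(s)
      list(study_id = s$study_id, sample_size = s$sample_size,
           proteins = lapply(s$proteins, function(p) read_gwas_table(must(p)))))
  )
}

#' Pipeline configuration
#'
#' @param study Path to a study manifest (see [read_study()]).
#' @param out_dir Output directory for the tidy result tables and manifest.
#' @param seed Integer seed echoed into the run manifest (the pipeline
#'   itself is deterministic).
#' @param alpha Family-wise error rate for the stage thresholds.
#' @param overexpression_alpha,expressed_min Cardiac-expression knobs (see
#'   [cardiac_expression_flags()]).
#' @param ... Overrides for [mr_config()] knobs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(study, out_dir, seed = 1L, alpha = 0.05,
                            overexpression_alpha = 0.05, expressed_min = 0,
                            ...) {
  if (is.character(study) && !file.exists(study))
    stop_domain("study manifest not found: ", study)
  structure(list(study = study, out_dir = out_dir, seed = seed,
                 alpha = alpha, overexpression_alpha = overexpression_alpha,
                 expressed_min = expressed_min, mr = mr_config(...)),
            class = "pipeline_config")
}

run_pair <- function(stage, exposure, outcome, ld, gene, outcome_type,
                     exposure_id, outcome_id, config) {
  tryCatch(
    run_mr(exposure, outcome, ld, gene, outcome_type,
           exposure_id, outcome_id, config),
    error = function(e) stop(sprintf("[%s] %s -> %s: %s", stage, exposure_id,
                                     outcome_id, conditionMessage(e)),
                             call. = FALSE)
  )
}

gene_for <- function(genes, protein) {
  g <- genes[genes$encoded_protein == protein, , drop = FALSE]
  if (!nrow(g)) stop_domain("no gene annotation for protein ", protein)
  as.list(g[1, ])
}

#' Run the full triangulation pipeline
#'
#' Executes the three MR screening stages — (1) genome-wide metabolite to
#' outcome MR, (2) cis protein to metabolite MR restricted to the
#' metabolites passing stage 1, (3) cis protein to outcome MR for the
#' proteins passing stage 2 — each filtered at its exact Bonferroni
#' threshold, then assembles directionally concordant triangles, annotates
#' the prioritised proteins with cardiac expression and druggability, runs
#' Wald proportion enrichment for pathways (and metabolite classes per
#' outcome), and assesses replication of the prioritised protein-outcome
#' associations in the non-primary proteomic studies. All tidy outputs plus
#' a run manifest are written to `out_dir`; identical configuration and
#' inputs give byte-identical outputs.
#'
#' @param config A [pipeline_config()] (or a study manifest path, in which
#'   case `out_dir` must be given).
#' @param out_dir Output directory when `config` is a path.
#' @return Invisibly, the result bundle: the three stage tables,
#'   `thresholds`, `triangles`, `network`, `annotation`, `enrichment`,
#'   `replication`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config"))
    config <- pipeline_config(config, out_dir)
  study <- read_study(config$study)
  mrc <- config$mr
  met_ids <- names(study$metabolites)
  out_ids <- names(study$outcomes)

  # stage 1: genome-wide metabolite -> outcome MR
  step1 <- do.call(rbind, lapply(met_ids, function(m) {
    do.call(rbind, lapply(out_ids, function(o) {
      run_pair("step1", study$metabolites[[m]], study$outcomes[[o]]$table,
               study$ld, NULL, study$outcomes[[o]]$type, m, o, mrc)$result
    }))
  }))
  thr1 <- bonferroni_threshold(config$alpha, length(met_ids), length(out_ids))
  sig1 <- step1[step1$status == "ok" & step1$p_value < thr1$threshold, ,
                drop = FALSE]
  sig_metabolites <- sort(unique(sig1$exposure))

  # primary proteomic study per protein (largest sample size)
  all_proteins <- sort(unique(unlist(lapply(study$protein_studies,
                                            function(s) names(s$proteins)))))
  study_index <- do.call(rbind, lapply(study$protein_studies, function(s)
    data.frame(study_id = s$study_id, sample_size = s$sample_size,
               protein_id = names(s$proteins), stringsAsFactors = FALSE)))
  primary <- vapply(all_proteins, function(p)
    select_primary_study(study_index[study_index$protein_id == p, , drop = FALSE]),
    character(1))
  get_table <- function(study_id, protein) {
    s <- Filter(function(x) x$study_id == study_id, study$protein_studies)[[1]]
    s$proteins[[protein]]
  }

  # stage 2: cis protein -> metabolite MR for stage-1 metabolites
  step2 <- if (length(sig_metabolites)) do.call(rbind, lapply(all_proteins, function(p) {
    gene <- gene_for(study$genes, p)
    do.call(rbind, lapply(sig_metabolites, function(m) {
      run_pair("step2", get_table(primary[[p]], p), study$metabolites[[m]],
               study$ld, gene, "continuous", p, m, mrc)$result
    }))
  })) else NULL
  thr2 <- bonferroni_threshold(config$alpha, length(all_proteins),
                               max(1L, length(sig_metabolites)))
  sig2 <- if (is.null(step2)) NULL else
    step2[step2$status == "ok" & step2$p_value < thr2$threshold, , drop = FALSE]
  step2_proteins <- if (is.null(sig2)) character() else sort(unique(sig2$exposure))

  # stage 3: cis protein -> outcome MR for stage-2 proteins
  step3 <- if (length(step2_proteins)) do.call(rbind, lapply(step2_proteins, function(p) {
    gene <- gene_for(study$genes, p)
    do.call(rbind, lapply(out_ids, function(o) {
      run_pair("step3", get_table(primary[[p]], p), study$outcomes[[o]]$table,
               study$ld, gene, study$outcomes[[o]]$type, p, o, mrc)$result
    }))
  })) else NULL
  thr3 <- bonferroni_threshold(config$alpha, max(1L, length(step2_proteins)),
                               length(out_ids))
  sig3 <- if (is.null(step3)) step3 else
    step3[step3$status == "ok" & step3$p_value < thr3$threshold, , drop = FALSE]

  thresholds <- list(metabolite_outcome = thr1, protein_metabolite = thr2,
                     protein_outcome = thr3)
  triangles <- build_triangles(
    step1, step2 %||% discarded_result("x", "y", "continuous", 0, "none", 0)[0, ],
    step3 %||% discarded_result("x", "y", "continuous", 0, "none", 0)[0, ],
    list(metabolite_outcome = thr1$threshold,
         protein_metabolite = thr2$threshold,
         protein_outcome = thr3$threshold))
  prioritised <- sort(unique(triangles$protein_id))
  network <- triangle_network(triangles)
  pleio <- pleiotropic_summary(triangles)

  # annotation: cardiac expression + druggability of prioritised proteins
  tissue_cols <- setdiff(names(study$expression), "protein_id")
  annotation <- annotate_druggability(prioritised, study$druggability)
  if (length(prioritised)) {
    flags <- lapply(prioritised, function(p) {
      row <- study$expression[study$expression$protein_id == p, tissue_cols]
      ab <- stats::setNames(as.numeric(row[1, ]), tissue_cols)
      cardiac_expression_flags(ab, n_tissues = length(tissue_cols),
                               overexpression_alpha = config$overexpression_alpha,
                               expressed_min = config$expressed_min)
    })
    annotation$cardiac_expressed <- vapply(flags, `[[`, logical(1), "expressed")
    annotation$cardiac_overexpressed <- vapply(flags, `[[`, logical(1), "overexpressed")
    annotation$cardiac_fraction <- vapply(flags, `[[`, numeric(1), "cardiac_fraction")
  } else {
    annotation$cardiac_expressed <- logical(0)
    annotation$cardiac_overexpressed <- logical(0)
    annotation$cardiac_fraction <- numeric(0)
  }

  # enrichment: pathways over all tested proteins; metabolite classes per outcome
  pathway_enrichment <- if (length(prioritised)) do.call(rbind, lapply(
    sort(unique(study$pathways$pathway_id)), function(w) {
      members <- study$pathways$protein_id[study$pathways$pathway_id == w]
      wald_proportion_enrichment(prioritised, all_proteins, members, w)
    })) else NULL
  class_enrichment <- if (!is.null(study$metabolite_classes)) do.call(rbind, lapply(
    out_ids, function(o) {
      sig_m <- unique(sig1$exposure[sig1$outcome == o])
      if (!length(sig_m)) return(NULL)
      do.call(rbind, lapply(sort(unique(study$metabolite_classes$class)), function(cl) {
        members <- study$metabolite_classes$metabolite_id[
          study$metabolite_classes$class == cl]
        res <- wald_proportion_enrichment(sig_m, met_ids, members, cl)
        cbind(data.frame(outcome = o, stringsAsFactors = FALSE), res)
      }))
    })) else NULL

  # replication of prioritised protein-outcome associations
  rep_proteins <- prioritised[vapply(prioritised, function(p)
    sum(study_index$protein_id == p) > 1L, logical(1))]
  replication <- NULL
  if (length(rep_proteins) && !is.null(sig3) && nrow(sig3)) {
    discovery <- sig3[sig3$exposure %in% rep_proteins, , drop = FALSE]
    discovery <- data.frame(protein_id = discovery$exposure,
                            outcome_id = discovery$outcome,
                            slope = discovery$slope, stringsAsFactors = FALSE)
    rep_rows <- do.call(rbind, lapply(seq_len(nrow(discovery)), function(i) {
      p <- discovery$protein_id[i]
      o <- discovery$outcome_id[i]
      studies <- study_index$study_id[study_index$protein_id == p]
      do.call(rbind, lapply(setdiff(studies, primary[[p]]), function(s) {
        res <- run_pair("replication", get_table(s, p),
                        study$outcomes[[o]]$table, study$ld,
                        gene_for(study$genes, p), study$outcomes[[o]]$type,
                        p, o, mrc)$result
        if (res$status != "ok") return(NULL)
        data.frame(protein_id = p, outcome_id = o, study_id = s,
                   slope = res$slope, p_value = res$p_value,
                   stringsAsFactors = FALSE)
      }))
    }))
    if (nrow(discovery))
      replication <- assess_replication(discovery, rep_rows %||%
        data.frame(protein_id = character(), outcome_id = character(),
                   study_id = character(), slope = numeric(),
                   p_value = numeric(), stringsAsFactors = FALSE),
        n_tested = length(rep_proteins), alpha = config$alpha)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mrtriangle")),
    seed = config$seed,
    alpha = config$alpha,
    mr_config = unclass(mrc),
    thresholds = list(
      metabolite_outcome = thr1[c("threshold", "threshold_reported")],
      protein_metabolite = thr2[c("threshold", "threshold_reported")],
      protein_outcome = thr3[c("threshold", "threshold_reported")]),
    counts = list(
      metabolites = length(met_ids),
      outcomes = length(out_ids),
      proteins = length(all_proteins),
      step1_tests = nrow(step1),
      step1_significant_metabolites = length(sig_metabolites),
      step2_tests = if (is.null(step2)) 0L else nrow(step2),
      step2_discarded = if (is.null(step2)) 0L else sum(step2$status == "discarded"),
      step2_significant_proteins = length(step2_proteins),
      step3_tests = if (is.null(step3)) 0L else nrow(step3),
      step3_significant_pairs = if (is.null(sig3)) 0L else nrow(sig3),
      triangles = nrow(triangles),
      prioritised_proteins = length(prioritised),
      pleiotropic_proteins = sum(pleio$pleiotropic),
      cardiac_expressed = sum(annotation$cardiac_expressed),
      cardiac_overexpressed = sum(annotation$cardiac_overexpressed)),
    step1_significant_metabolites = sig_metabolites,
    step2_exposure_metabolites = sig_metabolites,
    discarded_analyses = {
      disc <- rbind(step1[step1$status == "discarded", c("exposure", "outcome", "discard_stage")],
                    if (!is.null(step2)) step2[step2$status == "discarded", c("exposure", "outcome", "discard_stage")],
                    if (!is.null(step3)) step3[step3$status == "discarded", c("exposure", "outcome", "discard_stage")])
      if (nrow(disc)) disc else NULL
    },
    prioritised_proteins = prioritised,
    replication = if (!is.null(replication)) replication$summary else NULL
  )

  # write the bundle
  od <- config$out_dir
  dir.create(od, showWarnings = FALSE, recursive = TRUE)
  write_tsv(step1, file.path(od, "step1_metabolite_outcome.tsv"))
  if (!is.null(step2)) write_tsv(step2, file.path(od, "step2_protein_metabolite.tsv"))
  if (!is.null(step3)) write_tsv(step3, file.path(od, "step3_protein_outcome.tsv"))
  write_tsv(triangles, file.path(od, "triangles.tsv"))
  write_tsv(network$nodes, file.path(od, "network_nodes.tsv"))
  write_tsv(network$edges, file.path(od, "network_edges.tsv"))
  write_tsv(annotation, file.path(od, "protein_annotation.tsv"))
  write_tsv(pleio, file.path(od, "pleiotropic_proteins.tsv"))
  if (!is.null(pathway_enrichment))
    write_tsv(pathway_enrichment, file.path(od, "pathway_enrichment.tsv"))
  if (!is.null(class_enrichment))
    write_tsv(class_enrichment, file.path(od, "metabolite_class_enrichment.tsv"))
  if (!is.null(replication))
    write_tsv(replication$verdicts, file.path(od, "replication_verdicts.tsv"))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)

  invisible(list(step1 = step1, step2 = step2, step3 = step3,
                 thresholds = thresholds, triangles = triangles,
                 network = network, pleiotropic = pleio,
                 annotation = annotation,
                 pathway_enrichment = pathway_enrichment,
                 class_enrichment = class_enrichment,
                 replication = replication, manifest = manifest))
}
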