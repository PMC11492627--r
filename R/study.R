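#' Simulate a complete toy omics-triangulation study
#'
#' Writes a self-contained study bundle — metabolite, protein (discovery and
#' replication proteomic studies) and binary-outcome GWAS summary
#' statistics, a global LD matrix, gene annotation, and annotation fixture
#' tables — with a fully known causal structure, so the end-to-end pipeline
#' can be exercised and checked offline.
#'
#' The planted design has 6 metabolites, 8 proteins and 2 binary outcomes.
#' Protein effects on metabolites (`gamma`), metabolite effects on outcomes
#' (`beta_mo`) and total protein effects on outcomes (`delta`, mediated
#' `gamma %*% beta_mo` except where overridden) are fixed:
#' * `P07` has only 5 cis variants, so its cis analyses are discarded under
#'   the minimum-variant rule;
#' * `P08` carries a direct protein-outcome effect opposing its mediated
#'   path, making its triple directionally discordant;
#' * `P06` only affects the null metabolite `M06`, which fails the
#'   metabolite-outcome screen.
#' The remaining proteins form seven concordant triangles (enumerable from
#' the planted matrices; returned in `truth`). Sample-size proxies follow
#' the source-data scale: metabolites n = 86,507, discovery proteomics
#' n = 35,559, replication proteomics n = 3,301, outcomes effective
#' n = 20,000. Exposure datasets are written in the LD-reference allele
#' coding; 10 percent of outcome-table records are allele-flipped.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, a list with `dir`, `study` (path to the study
#'   manifest `study.yaml`) and `truth` (planted matrices, the expected
#'   concordant triangles, discarded and prioritised proteins).
#' @export
simulate_study <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("metabolites", "outcomes", "proteins/discovery_large",
              "proteins/replication_small"))
    dir.create(file.path(dir, d), showWarnings = FALSE, recursive = TRUE)

  metabolites <- sprintf("M%02d", 1:6)
  outcomes <- c("O1", "O2")
  proteins <- sprintf("P%02d", 1:8)
  n_cis <- stats::setNames(c(12L, 12L, 12L, 12L, 12L, 12L, 5L, 12L), proteins)

  gamma <- matrix(0, 8, 6, dimnames = list(proteins, metabolites))
  gamma["P01", "M01"] <- 0.5
  gamma["P02", "M01"] <- -0.5
  gamma["P03", "M02"] <- 0.5
  gamma["P04", "M05"] <- 0.5
  gamma["P05", "M03"] <- 0.5
  gamma["P05", "M04"] <- -0.5
  gamma["P06", "M06"] <- 0.5
  gamma["P07", "M01"] <- 0.5
  gamma["P08", "M01"] <- 0.5

  beta_mo <- matrix(0, 6, 2, dimnames = list(metabolites, outcomes))
  beta_mo["M01", "O1"] <- 0.3
  beta_mo["M02", "O1"] <- -0.3
  beta_mo["M03", "O2"] <- 0.3
  beta_mo["M04", "O2"] <- -0.3
  beta_mo["M05", ] <- c(0.3, 0.3)

  delta <- gamma %*% beta_mo
  delta["P08", "O1"] <- -0.15  # direct effect opposing the mediated path

  # expected concordant triangles from the planted matrices
  expected <- do.call(rbind, lapply(proteins, function(p) {
    do.call(rbind, lapply(metabolites, function(m) {
      do.call(rbind, lapply(outcomes, function(o) {
        ok <- gamma[p, m] != 0 && beta_mo[m, o] != 0 && delta[p, o] != 0 &&
          sign(gamma[p, m]) * sign(beta_mo[m, o]) == sign(delta[p, o]) &&
          n_cis[[p]] >= 6L
        if (ok) data.frame(protein_id = p, metabolite_id = m, outcome_id = o,
                           stringsAsFactors = FALSE) else NULL
      }))
    }))
  }))

  n_metab <- 86507
  n_prot_primary <- 35559
  n_prot_repl <- 3301
  n_outcome <- 20000
  se_m <- 1 / sqrt(n_metab)
  se_pp <- 1 / sqrt(n_prot_primary)
  se_pr <- 1 / sqrt(n_prot_repl)
  se_o <- 1 / sqrt(n_outcome)

  truth_file <- file.path(dir, "truth.json")
  study_file <- file.path(dir, "study.yaml")

  with_seed(seed, {
    # -- variant map -------------------------------------------------------
    cis <- do.call(rbind, lapply(proteins, function(p) {
      k <- n_cis[[p]]
      data.frame(
        variant_id = sprintf("cis_%s_%02d", p, seq_len(k)),
        chromosome = as.character(match(p, proteins)),
        position = as.integer(1e6 - 80000 + (seq_len(k) - 1L) * 15000),
        locus = p, stringsAsFactors = FALSE
      )
    }))
    met_own <- do.call(rbind, lapply(metabolites, function(m) {
      data.frame(
        variant_id = sprintf("met_%s_%02d", m, 1:30),
        chromosome = as.character(20L + match(m, metabolites)),
        position = as.integer(seq(1e6, by = 1e6, length.out = 30)),
        locus = m, stringsAsFactors = FALSE
      )
    }))
    vmap <- rbind(cis, met_own)
    nv <- nrow(vmap)
    vmap$bx <- stats::runif(nv, 0.1, 0.3)
    vmap$eaf <- stats::runif(nv, 0.05, 0.95)
    al <- t(vapply(seq_len(nv), function(i) sample(c("A", "C", "G", "T"), 2L),
                   character(2L)))
    vmap$effect_allele <- al[, 1]
    vmap$other_allele <- al[, 2]

    # -- LD: AR(1) rho 0.4 within each cis locus, independent elsewhere ----
    ld <- matrix(0, nv, nv, dimnames = list(vmap$variant_id, vmap$variant_id))
    diag(ld) <- 1
    for (p in proteins) {
      idx <- which(vmap$locus == p)
      ld[idx, idx] <- simulate_ld_matrix(length(idx), length(idx), 0.4)
    }
    ld_chol <- chol(ld)
    noise <- function(sd) drop(crossprod(ld_chol, stats::rnorm(nv))) * sd

    base_table <- function(beta_mean, se, n) {
      variant_table(vmap$variant_id, vmap$chromosome, vmap$position,
                    vmap$effect_allele, vmap$other_allele, vmap$eaf,
                    beta_mean, se, n)
    }

    # -- protein GWAS (exposures; LD-reference coding) ---------------------
    protein_tables <- function(se, n, subset_proteins) {
      out <- list()
      for (p in subset_proteins) {
        rows <- vmap$locus == p
        tab <- base_table(vmap$bx + noise(se), se, n)[rows, , drop = FALSE]
        out[[p]] <- tab
      }
      out
    }
    prot_primary <- protein_tables(se_pp, n_prot_primary, proteins)
    repl_proteins <- c("P01", "P02", "P03", "P04", "P08")
    prot_repl <- protein_tables(se_pr, n_prot_repl, repl_proteins)

    # -- metabolite GWAS: own instruments plus every cis locus -------------
    met_tables <- list()
    for (m in metabolites) {
      mean_beta <- ifelse(vmap$locus == m, vmap$bx, 0)
      for (p in proteins) {
        rows <- vmap$locus == p
        mean_beta[rows] <- gamma[p, m] * vmap$bx[rows]
      }
      keep <- vmap$locus == m | vmap$locus %in% proteins
      met_tables[[m]] <- base_table(mean_beta + noise(se_m), se_m, n_metab)[keep, , drop = FALSE]
    }

    # -- outcome GWAS over all variants, 10% allele-flipped ----------------
    out_tables <- list()
    for (o in outcomes) {
      mean_beta <- numeric(nv)
      for (m in metabolites) {
        rows <- vmap$locus == m
        mean_beta[rows] <- beta_mo[m, o] * vmap$bx[rows]
      }
      for (p in proteins) {
        rows <- vmap$locus == p
        mean_beta[rows] <- delta[p, o] * vmap$bx[rows]
      }
      tab <- base_table(mean_beta + noise(se_o), se_o, n_outcome)
      tab <- flip_coding(tab, sample(nv, size = round(0.1 * nv)))
      out_tables[[o]] <- tab
    }

    # -- annotation fixtures ----------------------------------------------
    ann <- simulate_annotation_fixtures(8L, 3L, 61L, seed = seed + 1L)
    ann$expression$protein_id <- proteins
    ann$druggability$protein_id <- proteins
    tissue_cols <- setdiff(names(ann$expression), "protein_id")
    others <- as.numeric(ann$expression[1, setdiff(tissue_cols, "heart_muscle")])
    ann$expression[1, "heart_muscle"] <- 0  # P01: not expressed in cardiac tissue
    others2 <- as.numeric(ann$expression[2, setdiff(tissue_cols, "heart_muscle")])
    ann$expression[2, "heart_muscle"] <- mean(others2) + 10 * stats::sd(others2)
    ann$druggability$status[1] <- "drugged"
    ann$druggability$n_drugs[1] <- 6L
    ann$druggability$drugs[1] <- paste(sprintf("drug%02d", 1:6), collapse = ";")
    ann$druggability$cardiac_indication[1] <- TRUE
    ann$pathways <- data.frame(
      pathway_id = rep(c("PW01", "PW02", "PW03"), each = 3L),
      protein_id = c("P01", "P02", "P03", "P02", "P04", "P06",
                     "P06", "P07", "P08"),
      stringsAsFactors = FALSE
    )
    genes <- data.frame(
      gene_id = sprintf("GENE_%s", proteins),
      chromosome = as.character(seq_along(proteins)),
      start = 1000000L, end = 1050000L,
      encoded_protein = proteins, stringsAsFactors = FALSE
    )
    met_classes <- data.frame(
      metabolite_id = metabolites,
      class = c("acylcarnitine", "acylcarnitine", "phosphatidylcholine",
                "phosphatidylcholine", "amino_acid", "sphingomyelin"),
      stringsAsFactors = FALSE
    )

    # -- write the bundle --------------------------------------------------
    write_ld_matrix(ld, file.path(dir, "ld_matrix.tsv"))
    write_tsv(genes, file.path(dir, "genes.tsv"))
    write_tsv(ann$expression, file.path(dir, "expression.tsv"))
    write_tsv(ann$druggability, file.path(dir, "druggability.tsv"))
    write_tsv(ann$pathways, file.path(dir, "pathways.tsv"))
    write_tsv(met_classes, file.path(dir, "metabolite_classes.tsv"))
    for (m in metabolites)
      write_gwas_table(met_tables[[m]], file.path(dir, "metabolites", paste0(m, ".tsv")))
    for (o in outcomes)
      write_gwas_table(out_tables[[o]], file.path(dir, "outcomes", paste0(o, ".tsv")))
    for (p in proteins)
      write_gwas_table(prot_primary[[p]],
                       file.path(dir, "proteins/discovery_large", paste0(p, ".tsv")))
    for (p in repl_proteins)
      write_gwas_table(prot_repl[[p]],
                       file.path(dir, "proteins/replication_small", paste0(p, ".tsv")))

    truth <- list(
      gamma = gamma, beta_mo = beta_mo, delta = delta,
      n_cis = as.list(n_cis),
      expected_triangles = expected,
      n_expected_triangles = nrow(expected),
      discarded_proteins = "P07",
      prioritised_proteins = sort(unique(expected$protein_id))
    )
    jsonlite::write_json(truth, truth_file, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")

    study <- list(
      seed = seed,
      ld_file = "ld_matrix.tsv",
      gene_file = "genes.tsv",
      expression_file = "expression.tsv",
      druggability_file = "druggability.tsv",
      pathway_file = "pathways.tsv",
      metabolite_class_file = "metabolite_classes.tsv",
      metabolites = stats::setNames(
        as.list(file.path("metabolites", paste0(metabolites, ".tsv"))), metabolites),
      outcomes = stats::setNames(lapply(outcomes, function(o)
        list(file = file.path("outcomes", paste0(o, ".tsv")), type = "binary")),
        outcomes),
      protein_studies = list(
        list(study_id = "discovery_large", sample_size = n_prot_primary,
             proteins = stats::setNames(as.list(
               file.path("proteins/discovery_large", paste0(proteins, ".tsv"))),
               proteins)),
        list(study_id = "replication_small", sample_size = n_prot_repl,
             proteins = stats::setNames(as.list(
               file.path("proteins/replication_small", paste0(repl_proteins, ".tsv"))),
               repl_proteins))
      )
    )
    yaml::write_yaml(study, study_file)
    invisible(list(dir = dir, study = study_file, truth = truth))
  })
}
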