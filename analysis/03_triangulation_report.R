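#!/usr/bin/env Rscript
# Summarise the triangulation results: the concordant triangles, the
# annotation of prioritised proteins (cardiac expression, druggability),
# the enrichment tables, and replication in the smaller proteomic study.

library(mrtriangle)

tri <- read.table("results/pipeline/triangles.tsv", header = TRUE, sep = "\t")
ann <- read.table("results/pipeline/protein_annotation.tsv", header = TRUE,
                  sep = "\t")
cat("Concordant triangles:\n")
print(tri[, c("protein_id", "metabolite_id", "outcome_id",
              "beta_protein_metabolite", "beta_metabolite_outcome",
              "beta_protein_outcome")], row.names = FALSE)

cat("\nPrioritised-protein annotation:\n")
print(ann[, c("protein_id", "status", "n_drugs", "cardiac_expressed",
              "cardiac_overexpressed")], row.names = FALSE)

enr <- read.table("results/pipeline/pathway_enrichment.tsv", header = TRUE,
                  sep = "\t")
cat("\nPathway enrichment (Wald proportion test):\n")
print(enr[, c("group_label", "k_prioritised_in_group", "n_prioritised",
              "k_background_in_group", "n_background", "z", "p_value")],
      row.names = FALSE)

if (file.exists("results/pipeline/replication_verdicts.tsv")) {
  rv <- read.table("results/pipeline/replication_verdicts.tsv", header = TRUE,
                   sep = "\t")
  m <- jsonlite::read_json("results/pipeline/manifest.json")
  cat("\nReplication in the smaller proteomic study:\n")
  print(rv, row.names = FALSE)
  cat(sprintf("Nominal replication: %s%% | conservative (0.05/%d): %s%%\n",
              m$replication$pct_nominal, m$replication$n_tested,
              m$replication$pct_conservative))
}
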