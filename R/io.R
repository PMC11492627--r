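# Readers/writers for the tab-separated interchange formats: GWAS summary
# statistics in a GWAS-SSF-style dialect, a whitespace-delimited LD matrix
# with a variant-id header, and plain annotation TSVs.

ssf_names <- c(variant_id = "variant_id", chromosome = "chromosome",
               position = "base_pair_location", effect_allele = "effect_allele",
               other_allele = "other_allele", eaf = "effect_allele_frequency",
               beta = "beta", se = "standard_error", p_value = "p_value",
               n = "n")

#' Write / read GWAS summary statistics
#'
#' Tab-separated text with columns `variant_id`, `chromosome`,
#' `base_pair_location`, `effect_allele`, `other_allele`,
#' `effect_allele_frequency`, `beta`, `standard_error`, `p_value`, `n`.
#'
#' @param tab Internal summary-statistic data frame.
#' @param path File path.
#' @return `read_gwas_table` returns the data frame in internal column
#'   naming; `write_gwas_table` returns `path` invisibly.
#' @export
write_gwas_table <- function(tab, path) {
  out <- tab[, names(ssf_names)]
  names(out) <- unname(ssf_names)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gwas_table
#' @export
read_gwas_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c(chromosome = "character"),
                           stringsAsFactors = FALSE)
  m <- match(names(tab), unname(ssf_names))
  names(tab)[!is.na(m)] <- names(ssf_names)[m[!is.na(m)]]
  tab
}

#' Write / read an LD correlation matrix
#'
#' Square whitespace-delimited matrix with a header row of variant ids.
#'
#' @param ld Matrix with variant-id dimnames.
#' @param path File path.
#' @param digits Decimal places written (default 6).
#' @return `read_ld_matrix` returns the matrix with variant-id dimnames.
#' @export
write_ld_matrix <- function(ld, path, digits = 6) {
  utils::write.table(round(ld, digits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_ld_matrix
#' @export
read_ld_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(tab)
  dimnames(m) <- list(colnames(tab), colnames(tab))
  m
}

write_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE, ...)
}
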