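## Plain-text interchange formats: library manifests (TSV + FASTA),
## PSI/count matrices (TSV).

#' Write / read a minigene library manifest
#'
#' The manifest is a TSV with columns `id`, `barcode`, `exon_start`,
#' `exon_end` (0-based half-open within the variable region),
#' `provenance` and `variable_region`. `write_library` optionally also
#' writes the variable regions as FASTA.
#'
#' @param elements List of minigene elements.
#' @param path Output TSV path.
#' @param fasta Optional FASTA path for the variable regions.
#' @return Invisibly, `path`.
#' @export
write_library <- function(elements, path, fasta = NULL) {
  df <- data.frame(
    id = vapply(elements, `[[`, "", "id"),
    barcode = vapply(elements, `[[`, "", "barcode"),
    exon_start = as.integer(vapply(elements,
                                   function(e) e$exon_interval[[1]], 0)),
    exon_end = as.integer(vapply(elements,
                                 function(e) e$exon_interval[[2]], 0)),
    provenance = vapply(elements, `[[`, "", "provenance"),
    variable_region = vapply(elements, `[[`, "", "variable_region"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fasta)) {
    ss <- Biostrings::DNAStringSet(df$variable_region)
    names(ss) <- df$id
    Biostrings::writeXStringSet(ss, fasta)
  }
  invisible(path)
}

#' @rdname write_library
#' @return `read_library`: a list of minigene elements.
#' @export
read_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    el <- list(id = df$id[i], variable_region = df$variable_region[i],
               exon_interval = c(start = df$exon_start[i],
                                 end = df$exon_end[i]),
               barcode = df$barcode[i],
               provenance = df$provenance[i], over_budget = FALSE)
    class(el) <- "minigene_element"
    el
  })
}

#' Write / read a PSI matrix as TSV
#'
#' Elements x cell types, with an `element` id column.
#'
#' @param psi A `psi_matrix` object or bare matrix.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_psi_matrix <- function(psi, path) {
  m <- if (inherits(psi, "psi_matrix")) psi$psi else psi
  df <- data.frame(element = rownames(m), as.data.frame(m, optional = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psi_matrix
#' @return `read_psi_matrix`: numeric matrix with element rownames.
#' @export
read_psi_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
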