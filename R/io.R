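## Readers/writers for the pipeline's on-disk formats: MatrixMarket + TSV
## sidecars for sparse matrices, Newick for trees, TSV for tables, and a
## JSON run report. TSV dialect: tab-separated, UTF-8, header row, no
## quoting.

#' Write a sparse cells-by-variants matrix as MatrixMarket plus sidecars
#'
#' Writes `<prefix>.mtx`, `<prefix>.cells.tsv` and `<prefix>.variants.tsv`.
#' @param C sparse matrix with dimnames, or `mtl_vcmatrix`.
#' @param prefix file path prefix.
#' @return the prefix, invisibly.
#' @export
write_matrix <- function(C, prefix) {
  if (inherits(C, "mtl_vcmatrix")) C <- C$C
  Matrix::writeMM(methods::as(C, "CsparseMatrix"), paste0(prefix, ".mtx"))
  writeLines(rownames(C) %||% as.character(seq_len(nrow(C))),
             paste0(prefix, ".cells.tsv"))
  writeLines(colnames(C) %||% as.character(seq_len(ncol(C))),
             paste0(prefix, ".variants.tsv"))
  invisible(prefix)
}

#' Read a sparse matrix written by [write_matrix()]
#' @param prefix file path prefix.
#' @return sparse `dgCMatrix` with cell/variant dimnames.
#' @export
read_matrix <- function(prefix) {
  C <- methods::as(Matrix::readMM(paste0(prefix, ".mtx")), "CsparseMatrix")
  cells <- readLines(paste0(prefix, ".cells.tsv"))
  vars <- readLines(paste0(prefix, ".variants.tsv"))
  if (length(cells) != nrow(C) || length(vars) != ncol(C))
    stop("sidecar/matrix dimension mismatch")
  dimnames(C) <- list(cells, vars)
  C
}

#' Write a tree as Newick
#' @param tree `ape::phylo`.
#' @param path output file.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Newick file.
#' @return `ape::phylo`; duplicate leaf labels are fatal.
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("malformed Newick in ", path)
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in ", path)
  tr
}

#' Write / read a TSV table (tab-separated, header, no quoting)
#' @param x data.frame.
#' @param path file path.
#' @rdname tsv
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             fileEncoding = "UTF-8")
}

#' Write a JSON run report
#'
#' Records the resolved configuration, package version and stage counts for
#' provenance.
#' @param report named list.
#' @param path output file.
#' @export
write_run_report <- function(report, path) {
  report$package_version <- as.character(utils::packageVersion("mitolin"))
  report$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read simulated reads or metadata tables
#'
#' Thin wrappers around the TSV dialect with column checks.
#' @param path TSV file.
#' @return data.frame.
#' @export
read_read_table <- function(path) {
  x <- read_tsv(path)
  need <- c("cell", "start", "end", "mate", "mismatches")
  if (!all(need %in% names(x)))
    stop("read table must have columns: ", paste(need, collapse = ", "))
  x$mismatches[is.na(x$mismatches)] <- ""
  x
}
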