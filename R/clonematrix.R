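## Variant-by-cell matrix algebra: binarization, heteroplasmy, mutation-rate
## priors, prior-weighted Jaccard distance, TF-IDF/SVD (LSI) embedding and
## connectedness QC.

as_count_matrix <- function(C) {
  if (inherits(C, "mtl_vcmatrix")) C <- C$C
  C <- methods::as(methods::as(Matrix::Matrix(C, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (any(C@x < 0)) stop("negative counts are not allowed")
  C
}

#' Binarize a count matrix
#'
#' @param C cells x variants count matrix (sparse ok) or `mtl_vcmatrix`.
#' @param min_support count needed for presence (default 1).
#' @return sparse binary matrix of the same dimensions.
#' @export
binarize <- function(C, min_support = 1L) {
  C <- as_count_matrix(C)
  stopifnot_pos_int(min_support, "min_support")
  B <- C
  B@x <- as.numeric(B@x >= min_support)
  Matrix::drop0(B)
}

#' Heteroplasmy matrix
#'
#' Divides supporting-molecule counts by per-cell, per-position mtDNA copy
#' numbers; values are capped at 1 (capped entries are flagged in the
#' `"capped"` attribute) and zero-coverage entries are 0.
#'
#' @param C count matrix or `mtl_vcmatrix` (which carries its own copies).
#' @param copies matrix of copy numbers, same dimensions as `C`.
#' @return dense or sparse heteroplasmy matrix in \[0, 1\].
#' @export
heteroplasmy <- function(C, copies = NULL) {
  if (inherits(C, "mtl_vcmatrix") && is.null(copies)) { copies <- C$copies; C <- C$C }
  C <- as_count_matrix(C)
  if (is.null(copies)) stop("copies matrix required")
  if (!all(dim(C) == dim(copies))) stop("shape mismatch between counts and copies")
  H <- C
  cp <- copies[Matrix::which(C != 0)]
  val <- C@x / cp
  capped <- val > 1 | cp == 0
  val[cp == 0] <- 0
  H@x <- pmin(val, 1)
  H <- Matrix::drop0(H)
  attr(H, "capped") <- sum(capped)
  H
}

#' Variant priors from cross-donor mutation rates
#'
#' `prior = 1 - average mutation rate across donors`, down-weighting
#' recurrent (homoplasy-prone) positions. Defaults to 1 for every variant
#' when no cross-donor table is supplied.
#'
#' @param variants character vector of variant ids.
#' @param avg_rate optional named vector of cross-donor average mutation
#'   rates in \[0, 1\].
#' @return named prior vector in \[0, 1\].
#' @export
variant_priors <- function(variants, avg_rate = NULL) {
  p <- setNames(rep(1, length(variants)), variants)
  if (!is.null(avg_rate)) {
    hit <- intersect(names(avg_rate), variants)
    p[hit] <- 1 - avg_rate[hit]
  }
  if (any(p < 0 | p > 1)) stop("priors must lie in [0, 1]")
  p
}

#' Prior-weighted Jaccard distance between cells
#'
#' For cells x, y with binary profiles, `D = 1 - sum(prior over shared
#' variants) / sum(prior over the union of variants carried by x or y)`.
#' With all priors 1 this is the classical Jaccard distance. Cells with an
#' empty profile are at distance 1 from every non-empty cell and at 0 from
#' each other; they are flagged in the `"empty_cells"` attribute.
#'
#' @param C_bin binary cells x variants matrix.
#' @param priors named prior vector (see [variant_priors()]); variants
#'   missing from it default to prior 1 with a warning.
#' @return dense symmetric distance matrix with zero diagonal.
#' @export
weighted_jaccard <- function(C_bin, priors = NULL) {
  B <- as_count_matrix(C_bin)
  B@x[] <- 1
  v <- colnames(B) %||% as.character(seq_len(ncol(B)))
  if (is.null(priors)) priors <- variant_priors(v)
  if (!all(v %in% names(priors))) {
    warning("variant(s) missing from priors default to prior 1")
    priors <- c(priors, setNames(rep(1, sum(!(v %in% names(priors)))),
                                 v[!(v %in% names(priors))]))
  }
  w <- unname(priors[v])
  S <- as.matrix(B %*% (w * Matrix::t(B)))       # shared prior mass
  r <- as.numeric(B %*% w)                       # per-cell prior mass
  U <- outer(r, r, "+") - S                      # union prior mass
  D <- 1 - S / U
  D[U == 0] <- 0                                 # empty vs empty: identical
  empty <- r == 0
  if (any(empty)) {
    D[empty, !empty] <- 1
    D[!empty, empty] <- 1
  }
  diag(D) <- 0
  dimnames(D) <- list(rownames(B), rownames(B))
  attr(D, "empty_cells") <- rownames(B)[empty] %||% which(empty)
  D
}

#' TF-IDF / SVD (LSI) embedding
#'
#' Term frequency is the row-normalized binary profile; inverse document
#' frequency is `log(1 + n_cells / df)`. The embedding is the top
#' `n_components` left singular vectors scaled by their singular values; all
#' components are retained and signs are fixed so each component's largest-
#' magnitude loading is positive.
#'
#' @param C_bin binary cells x variants matrix.
#' @param n_components number of components (default 30).
#' @param seed seed for the truncated SVD initialisation.
#' @return object of class `mtl_lsi`: list with `embedding` (cells x
#'   n_components), `d` (singular values), `idf`, and `dropped` (all-zero
#'   cells excluded with a warning).
#' @export
lsi_embed <- function(C_bin, n_components = 30L, seed = 1L) {
  B <- as_count_matrix(C_bin)
  B@x[] <- 1
  rs <- Matrix::rowSums(B)
  dropped <- rownames(B)[rs == 0] %||% which(rs == 0)
  if (any(rs == 0)) {
    warning(sprintf("%d all-zero cell(s) excluded from LSI", sum(rs == 0)))
    B <- B[rs > 0, , drop = FALSE]
    rs <- rs[rs > 0]
  }
  df <- Matrix::colSums(B)
  keep <- df > 0
  B <- B[, keep, drop = FALSE]
  idf <- log(1 + nrow(B) / df[keep])
  X <- Matrix::Diagonal(x = 1 / rs) %*% B %*% Matrix::Diagonal(x = idf)
  n_components <- as.integer(n_components)
  if (n_components > min(dim(X)))
    stop("n_components exceeds matrix rank bound")
  sv <- if (n_components >= min(dim(X)) - 1L) {
    s <- svd(as.matrix(X), nu = n_components, nv = n_components)
    list(u = s$u, d = s$d[seq_len(n_components)], v = s$v)
  } else {
    with_seed(seed, irlba::irlba(X, nv = n_components))
  }
  ## sign convention: largest |loading| of each right singular vector positive
  sgn <- vapply(seq_len(n_components), function(j) {
    v <- sv$v[, j]; sign(v[which.max(abs(v))])
  }, 0)
  emb <- sv$u %*% diag(sv$d[seq_len(n_components)] * sgn, n_components)
  rownames(emb) <- rownames(B)
  colnames(emb) <- paste0("LSI", seq_len(n_components))
  structure(list(embedding = emb, d = sv$d[seq_len(n_components)], idf = idf,
                 dropped = dropped), class = "mtl_lsi")
}

#' @export
print.mtl_lsi <- function(x, ...) {
  cat(sprintf("LSI embedding: %d cells x %d components\n",
              nrow(x$embedding), ncol(x$embedding)))
  invisible(x)
}

#' Cell connectedness
#'
#' Number of other cells sharing at least one variant with each cell.
#'
#' @param C_bin binary cells x variants matrix.
#' @return named integer vector per cell.
#' @export
connectedness <- function(C_bin) {
  B <- as_count_matrix(C_bin)
  B@x[] <- 1
  A <- Matrix::tcrossprod(B)
  n <- Matrix::rowSums(A > 0) - as.integer(Matrix::diag(A) > 0)
  setNames(as.integer(n), rownames(B))
}
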