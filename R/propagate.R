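## Mutual-KNN graph construction and random-walk-with-restart propagation
## assigning every cell a probability over stem-cell clonal groups.

#' Propagation configuration
#'
#' @param restart restart probability (the damping factor: per-step mass
#'   returned to the seeds; default 0.05).
#' @param tol L1 convergence tolerance (default 1e-6).
#' @param max_iter iteration cap (default 1000).
#' @param prob_cutoff maximum-probability cutoff below which a cell is left
#'   unassigned (default 0.7).
#' @param k mutual-KNN neighbourhood size (default 30).
#' @return object of class `mtl_prop_config`.
#' @export
propagation_config <- function(restart = 0.05, tol = 1e-6, max_iter = 1000L,
                               prob_cutoff = 0.7, k = 30L) {
  stopifnot_prob(restart, "restart")
  if (restart == 0) stop("restart must be in (0, 1]")
  if (tol <= 0) stop("tol must be positive")
  stopifnot_pos_int(max_iter, "max_iter")
  stopifnot_prob(prob_cutoff, "prob_cutoff")
  stopifnot_pos_int(k, "k")
  structure(list(restart = restart, tol = tol, max_iter = as.integer(max_iter),
                 prob_cutoff = prob_cutoff, k = as.integer(k)),
            class = "mtl_prop_config")
}

#' Mutual k-nearest-neighbour graph
#'
#' Connects two cells iff each is among the other's `k` nearest neighbours
#' (Euclidean distance in the supplied embedding). Isolated cells are
#' permitted and reported.
#'
#' @param embedding cells x dims matrix (e.g. `lsi_embed()$embedding`).
#' @param k neighbourhood size (default 30).
#' @return object of class `mtl_mknn`: list with sparse symmetric `adjacency`
#'   (no self-loops), `k`, `isolated` (cell names).
#' @export
build_mknn <- function(embedding, k = 30L) {
  if (inherits(embedding, "mtl_lsi")) embedding <- embedding$embedding
  n <- nrow(embedding)
  stopifnot_pos_int(k, "k")
  if (k >= n) stop("k must be smaller than the number of cells")
  nn <- RANN::nn2(embedding, k = k + 1L)$nn.idx[, -1, drop = FALSE]
  i <- rep.int(seq_len(n), ncol(nn))
  j <- as.vector(nn)
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  A <- Matrix::drop0(A * Matrix::t(A))     # mutual edges only
  Matrix::diag(A) <- 0
  A <- Matrix::drop0(A)
  dimnames(A) <- list(rownames(embedding), rownames(embedding))
  iso <- rownames(A)[Matrix::rowSums(A) == 0] %||% which(Matrix::rowSums(A) == 0)
  structure(list(adjacency = A, k = as.integer(k), isolated = iso),
            class = "mtl_mknn")
}

#' @export
print.mtl_mknn <- function(x, ...) {
  cat(sprintf("mutual-KNN graph: %d cells, %d edges, %d isolated (k = %d)\n",
              nrow(x$adjacency), Matrix::nnzero(x$adjacency) / 2,
              length(x$isolated), x$k))
  invisible(x)
}

## Column-stochastic transition matrix; degree-0 nodes absorb (self-loop).
transition_matrix <- function(A) {
  deg <- Matrix::colSums(A)
  zero <- deg == 0
  if (any(zero)) {
    A <- A + Matrix::Diagonal(n = nrow(A), x = as.numeric(zero))
    deg[zero] <- 1
  }
  A %*% Matrix::Diagonal(x = 1 / deg)
}

#' Random walk with restart
#'
#' Iterates `p <- (1 - restart) W p + restart p0` with `W` the column-
#' stochastic transition matrix of the graph and `p0` uniform over the seed
#' cells, until the L1 change falls below `tol`. Because `W` is column-
#' stochastic the total score mass is conserved at 1.
#'
#' @param graph `mtl_mknn` or a symmetric adjacency matrix.
#' @param seeds cell names (or indices) of the seed set, non-empty.
#' @param config `mtl_prop_config`.
#' @return named stationary score vector summing to 1; attribute
#'   `"iterations"` records the iteration count.
#' @export
rwr_propagate <- function(graph, seeds, config = propagation_config()) {
  A <- if (inherits(graph, "mtl_mknn")) graph$adjacency else graph
  nodes <- rownames(A) %||% as.character(seq_len(nrow(A)))
  si <- if (is.character(seeds)) match(seeds, nodes) else as.integer(seeds)
  if (length(si) == 0 || anyNA(si)) stop("seeds must be a non-empty subset of graph nodes")
  W <- transition_matrix(A)
  p0 <- numeric(nrow(A)); p0[si] <- 1 / length(si)
  p <- p0
  it <- 0L
  repeat {
    it <- it + 1L
    pn <- as.numeric((1 - config$restart) * (W %*% p) + config$restart * p0)
    delta <- sum(abs(pn - p))
    p <- pn
    if (delta < config$tol) break
    if (it >= config$max_iter)
      stop(sprintf("propagation failed to converge in %d iterations (L1 change %.3g)",
                   it, delta))
  }
  structure(setNames(p, nodes), iterations = it)
}

#' Assign cells to clonal groups by iterative network propagation
#'
#' Runs one random walk with restart per clonal group (seeded uniformly on
#' the clone's cells), normalizes each cell's scores across clones to sum 1,
#' and assigns the argmax clone; cells whose maximum normalized probability
#' does not exceed `prob_cutoff` (or that no walk reaches) are unassigned.
#' All clones are propagated simultaneously as columns of one iteration.
#'
#' @param graph `mtl_mknn` or adjacency matrix.
#' @param clones `mtl_clones`, or a named list clone -> cell vector.
#' @param config `mtl_prop_config`.
#' @return object of class `mtl_assignment`: list with `prob` (cells x
#'   clones normalized probability matrix), `raw` (stationary scores),
#'   `table` (cell, clone, max_prob, assigned).
#' @export
assign_clones <- function(graph, clones, config = propagation_config()) {
  A <- if (inherits(graph, "mtl_mknn")) graph$adjacency else graph
  nodes <- rownames(A) %||% as.character(seq_len(nrow(A)))
  cl <- if (inherits(clones, "mtl_clones")) clones$clones else clones
  seeds <- lapply(cl, function(cells) {
    si <- match(intersect(cells, nodes), nodes)
    si[!is.na(si)]
  })
  empty <- lengths(seeds) == 0
  if (any(empty)) {
    warning(sprintf("%d clone(s) with no graph-resident cells skipped",
                    sum(empty)))
    seeds <- seeds[!empty]
  }
  if (!length(seeds)) stop("no clones with graph-resident cells")
  W <- transition_matrix(A)
  P0 <- Matrix::sparseMatrix(
    i = unlist(seeds, use.names = FALSE),
    j = rep.int(seq_along(seeds), lengths(seeds)),
    x = unlist(lapply(seeds, function(s) rep(1 / length(s), length(s))),
               use.names = FALSE),
    dims = c(nrow(A), length(seeds)))
  P <- as.matrix(P0)
  it <- 0L
  repeat {
    it <- it + 1L
    Pn <- as.matrix((1 - config$restart) * (W %*% P) + config$restart * P0)
    delta <- max(colSums(abs(Pn - P)))
    P <- Pn
    if (delta < config$tol) break
    if (it >= config$max_iter)
      stop(sprintf("propagation failed to converge in %d iterations", it))
  }
  dimnames(P) <- list(nodes, names(seeds))
  rs <- rowSums(P)
  Pn <- P / ifelse(rs > 0, rs, 1)
  maxp <- apply(Pn, 1, max)
  best <- colnames(Pn)[max.col(Pn, ties.method = "first")]
  assigned <- rs > 0 & maxp > config$prob_cutoff
  tab <- data.frame(cell = nodes, clone = ifelse(assigned, best, NA_character_),
                    max_prob = maxp, assigned = assigned,
                    stringsAsFactors = FALSE)
  structure(list(prob = Pn, raw = P, table = tab, config = config,
                 iterations = it), class = "mtl_assignment")
}

#' @export
print.mtl_assignment <- function(x, ...) {
  cat(sprintf("clonal assignment: %d / %d cells assigned at max-prob > %.2f (%d clones)\n",
              sum(x$table$assigned), nrow(x$table), x$config$prob_cutoff,
              ncol(x$prob)))
  invisible(x)
}

#' Benchmark self-assignment against truth clone labels
#'
#' For cells with known clonal-group membership (e.g. the stem cells that
#' seeded the propagation), tabulates assignment accuracy by
#' maximum-probability bin and the overall accuracy above each cutoff.
#'
#' @param result `mtl_assignment`.
#' @param truth named vector cell -> true clone id.
#' @param breaks bin boundaries for max probability.
#' @return list with `by_bin` (bin, n, accuracy) and `above_cutoff`
#'   (cutoff, n, accuracy), and `overall` accuracy among assigned cells.
#' @export
benchmark_self_assignment <- function(result, truth,
                                      breaks = seq(0, 1, 0.1)) {
  stopifnot(inherits(result, "mtl_assignment"))
  tab <- result$table
  tab <- tab[tab$cell %in% names(truth), , drop = FALSE]
  if (!nrow(tab)) stop("no overlap between assignments and truth labels")
  hit <- !is.na(tab$clone) & tab$clone == truth[tab$cell]
  ## cells not meeting the cutoff still have an argmax; score it for binning
  best <- colnames(result$prob)[max.col(result$prob[tab$cell, , drop = FALSE],
                                        ties.method = "first")]
  hit_any <- best == truth[tab$cell]
  bin <- cut(tab$max_prob, breaks, include.lowest = TRUE)
  by_bin <- data.frame(bin = levels(bin),
                       n = as.integer(table(bin)),
                       accuracy = as.numeric(tapply(hit_any, bin, mean)))
  cuts <- head(breaks, -1)
  above <- data.frame(cutoff = cuts,
                      n = vapply(cuts, function(ct) sum(tab$max_prob > ct), 0L),
                      accuracy = vapply(cuts, function(ct) {
                        s <- tab$max_prob > ct
                        if (!any(s)) NA_real_ else mean(hit_any[s])
                      }, 0))
  list(by_bin = by_bin, above_cutoff = above,
       overall = if (any(tab$assigned)) mean(hit[tab$assigned]) else NA_real_)
}
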