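#' @importFrom stats rbinom rpois rhyper rnorm runif rgamma pbinom phyper
#'   pchisq binom.test setNames predict lm hclust dist cor as.dist smooth.spline
#'   aggregate quantile median sd
#' @importFrom utils head read.delim write.table
#' @importFrom methods as
NULL

DNA_BASES <- c("A", "C", "G", "T")

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

revcomp <- function(s) {
  vapply(strsplit(s, ""), function(x) paste(rev(unname(comp_base(x))), collapse = ""), "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
}

stopifnot_pos_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 || x != round(x))
    stop(sprintf("'%s' must be a positive integer", name), call. = FALSE)
}

## Run code under a local RNG state: seeds the generator, restores the
## caller's .Random.seed on exit so library calls do not perturb user RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

## ---- rooted-tree helpers (ape 'phylo') -------------------------------------

#' Children lists and postorder for a rooted phylo tree
#'
#' @param tree rooted `ape::phylo`.
#' @return list with `children` (list indexed by node id), `parent` (integer
#'   vector), `postorder` (node ids, children before parents), `root`,
#'   `n_tip`, `n_node`.
#' @keywords internal
tree_index <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  parent <- integer(n_all)
  children <- vector("list", n_all)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; c <- tree$edge[i, 2]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  ## postorder over nodes: reorder edges postorder, children appear before parents
  po_edges <- ape::reorder.phylo(tree, "postorder")$edge
  postorder <- c(po_edges[, 2][!duplicated(po_edges[, 2])], root)
  ## ensure tips come in order too (they do: every tip is a child exactly once)
  list(children = children, parent = parent, postorder = postorder,
       root = root, n_tip = n_tip, n_node = n_all)
}

#' Per-node descendant-leaf counts
#' @keywords internal
clade_sizes <- function(tree, idx = tree_index(tree)) {
  sz <- integer(idx$n_node)
  sz[seq_len(idx$n_tip)] <- 1L
  for (v in idx$postorder) {
    if (v > idx$n_tip) sz[v] <- sum(sz[idx$children[[v]]])
  }
  sz
}

#' Sparse node-by-leaf descendant incidence matrix
#'
#' Row `v` has 1 at leaf `j` iff leaf `j` descends from node `v` (a node
#' descends from itself, so leaf rows are unit vectors; the root row is all 1).
#' @keywords internal
clade_leaf_matrix <- function(tree, idx = tree_index(tree)) {
  leaves_under <- vector("list", idx$n_node)
  for (v in seq_len(idx$n_tip)) leaves_under[[v]] <- v
  for (v in idx$postorder) {
    if (v > idx$n_tip)
      leaves_under[[v]] <- unlist(leaves_under[idx$children[[v]]], use.names = FALSE)
  }
  i <- rep.int(seq_len(idx$n_node), lengths(leaves_under))
  j <- unlist(leaves_under, use.names = FALSE)
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(idx$n_node, idx$n_tip),
                       dimnames = list(NULL, tree$tip.label))
}

## ---- Storey q-values -------------------------------------------------------

#' Storey q-values
#'
#' False-discovery-rate q-values with the Storey pi0 estimate. pi0 is taken
#' from the lambda-grid estimator smoothed with a natural cubic spline and
#' evaluated at the largest lambda; for small families (< 100 tests) the
#' conservative pi0 = 1 (Benjamini-Hochberg) is used instead, since the
#' smoother is unstable there.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param pi0 optional fixed pi0 override in (0, 1\].
#' @return numeric vector of q-values, same length/order as `p`.
#' @export
storey_qvalue <- function(p, pi0 = NULL) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 100) {
      pi0 <- 1
    } else {
      lambda <- seq(0.05, 0.95, 0.05)
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
      sp <- try(smooth.spline(lambda, pi0_l, df = 3), silent = TRUE)
      pi0 <- if (inherits(sp, "try-error")) min(pi0_l) else predict(sp, x = 0.95)$y
      pi0 <- min(max(pi0, 1 / m), 1)
    }
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m * p[o] / seq(m, 1)
  q <- cummin(q)[ro]
  pmin(q, 1)
}
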