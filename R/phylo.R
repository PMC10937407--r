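## Neighbour-joining tree construction, maximum-likelihood variant-to-branch
## assignment, tree cutting into clonal groups, and clade-level cell-type
## enrichment.

#' Neighbour-joining tree rooted by an artificial empty-profile outgroup
#'
#' Runs neighbour joining on a cell-to-cell distance matrix after appending
#' an artificial outgroup cell with an empty mutation profile (distance 1 to
#' every cell under weighted Jaccard, or `outgroup_dist` otherwise), roots
#' the tree on it, then removes it. Negative NJ branch lengths are clamped
#' to 0.
#'
#' @param D symmetric distance matrix with zero diagonal, >= 3 cells.
#' @param outgroup_dist distance from the artificial outgroup to each cell.
#' @return rooted `ape::phylo` whose tip set equals the cells of `D`.
#' @export
build_nj_tree <- function(D, outgroup_dist = 1) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("at least 3 cells required for neighbour joining")
  if (any(!is.finite(D))) stop("non-finite distances")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("cell", seq_len(nrow(D)))
  og <- "__outgroup__"
  D2 <- rbind(cbind(D, rep(outgroup_dist, nrow(D))), c(rep(outgroup_dist, nrow(D)), 0))
  rownames(D2) <- colnames(D2) <- c(rownames(D), og)
  tr <- ape::nj(as.dist(D2))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- ape::root(tr, outgroup = og, resolve.root = TRUE)
  tr <- ape::drop.tip(tr, og)
  tr
}

#' Branch-assignment likelihood configuration
#'
#' @param s detection sensitivity (P(carrier observed), default 0.9).
#' @param f false-positive rate (P(non-member observed), default 0.001).
#' @param confident_prob assignment probability needed to call a variant
#'   confidently placed (default 0.6).
#' @return object of class `mtl_branch_config`.
#' @export
branch_assign_config <- function(s = 0.9, f = 0.001, confident_prob = 0.6) {
  stopifnot_prob(s, "s"); stopifnot_prob(f, "f"); stopifnot_prob(confident_prob, "confident_prob")
  if (s <= f) stop("s must exceed f")
  structure(list(s = s, f = f, confident_prob = confident_prob),
            class = "mtl_branch_config")
}

#' Maximum-likelihood assignment of variants to tree branches
#'
#' Each edge `e` (identified by its child node; the root node stands for the
#' root edge, whose clade is all leaves) defines a clade C_e. For a variant
#' with carrier set O, `log L(e) = |O∩C_e| log s + |C_e\\O| log(1-s) +
#' |O\\C_e| log f + |rest| log(1-f)`; per-variant assignment probabilities
#' are the softmax of log L over candidate edges. This is a generic
#' sensitivity/false-positive placement model, not a reimplementation of any
#' specific published branch-assignment code.
#'
#' @param tree rooted `ape::phylo` whose tips are cells.
#' @param C_bin binary cells x variants matrix (rows must cover the tips).
#' @param config `mtl_branch_config`.
#' @return object of class `mtl_branch_assign`: data.frame `assignment`
#'   (variant, node = best edge's child node id, prob, n_carriers,
#'   confident), plus `prob_matrix` attribute-free list entries `nodes`
#'   (candidate node ids) and `skipped` (carrier-free variants).
#' @export
assign_variants_to_branches <- function(tree, C_bin, config = branch_assign_config()) {
  B <- as_count_matrix(C_bin)
  B@x[] <- 1
  if (!all(tree$tip.label %in% rownames(B)))
    stop("tree tips missing from matrix rows")
  B <- B[tree$tip.label, , drop = FALSE]
  idx <- tree_index(tree)
  P <- clade_leaf_matrix(tree, idx)        # nodes x leaves
  csz <- Matrix::rowSums(P)
  nO <- Matrix::colSums(B)
  skipped <- colnames(B)[nO == 0]
  if (length(skipped))
    warning(sprintf("%d variant(s) with no carriers skipped", length(skipped)))
  keep <- nO > 0
  B <- B[, keep, drop = FALSE]
  nO <- nO[keep]
  n <- idx$n_tip
  inter <- as.matrix(P %*% B)              # |O ∩ C_e| ; nodes x variants
  s <- config$s; f <- config$f
  log1 <- function(x) ifelse(x > 0, log(x), -Inf)
  ## term-by-term in log space; 0 * -Inf handled as 0
  mult <- function(k, lg) ifelse(k == 0, 0, k * lg)
  ll <- mult(inter, log1(s)) +
    mult(csz - inter, log1(1 - s)) +
    mult(matrix(nO, nrow(inter), ncol(inter), byrow = TRUE) - inter, log1(f)) +
    mult(n - csz - matrix(nO, nrow(inter), ncol(inter), byrow = TRUE) + inter, log1(1 - f))
  ## softmax per variant (columns)
  mx <- apply(ll, 2, max)
  pr <- exp(sweep(ll, 2, mx))
  pr <- sweep(pr, 2, colSums(pr), "/")
  best <- apply(pr, 2, which.max)
  bestp <- pr[cbind(best, seq_along(best))]
  assignment <- data.frame(variant = colnames(B), node = as.integer(best),
                           prob = as.numeric(bestp),
                           n_carriers = as.integer(nO),
                           confident = as.numeric(bestp) >= config$confident_prob,
                           stringsAsFactors = FALSE)
  structure(list(assignment = assignment, prob_matrix = pr,
                 nodes = seq_len(idx$n_node), tree = tree, config = config,
                 skipped = skipped), class = "mtl_branch_assign")
}

#' @export
print.mtl_branch_assign <- function(x, ...) {
  cat(sprintf("branch assignment: %d variants, %d confident (P >= %.2f)\n",
              nrow(x$assignment), sum(x$assignment$confident),
              x$config$confident_prob))
  invisible(x)
}

#' Tree-cut configuration
#'
#' @param m minimum cells per clone (default 50).
#' @param n minimum confidently assigned variants on the based edge (default 1).
#' @param P minimum assignment probability for a confident variant (default 0.6).
#' @param D dump threshold: selected clones with fewer than `D` cells are
#'   discarded (default 0, keep all).
#' @return object of class `mtl_treecut_config`.
#' @export
tree_cut_config <- function(m = 50L, n = 1L, P = 0.6, D = 0L) {
  stopifnot_pos_int(m, "m"); stopifnot_pos_int(n, "n"); stopifnot_prob(P, "P")
  structure(list(m = as.integer(m), n = as.integer(n), P = P, D = as.integer(D)),
            class = "mtl_treecut_config")
}

#' Cut a tree into clonal groups
#'
#' Bottom-up traversal selecting minimal (deepest) disjoint clades with at
#' least `m` leaves whose based edge carries at least `n` variants assigned
#' with probability >= `P`. Selected clades with fewer than `D` cells are
#' then discarded; remaining cells are unassigned.
#'
#' @param tree rooted `ape::phylo`.
#' @param assignment `mtl_branch_assign` computed on this tree.
#' @param config `mtl_treecut_config`.
#' @return object of class `mtl_clones`: list with `clones` (named list clone
#'   id -> cell vector), `defining_variants` (named list per clone),
#'   `unassigned` (cells), `nodes` (clade node per clone).
#' @export
cut_tree <- function(tree, assignment, config = tree_cut_config()) {
  stopifnot(inherits(assignment, "mtl_branch_assign"))
  idx <- tree_index(tree)
  sz <- clade_sizes(tree, idx)
  a <- assignment$assignment
  conf <- a[a$prob >= config$P, , drop = FALSE]
  nconf <- tabulate(conf$node, nbins = idx$n_node)
  qualifies <- sz >= config$m & nconf >= config$n
  selected <- logical(idx$n_node)
  has_sel_below <- logical(idx$n_node)
  for (v in idx$postorder) {
    below <- if (v > idx$n_tip) any(has_sel_below[idx$children[[v]]] |
                                    selected[idx$children[[v]]]) else FALSE
    if (qualifies[v] && !below) selected[v] <- TRUE
    has_sel_below[v] <- below || selected[v]
  }
  P <- clade_leaf_matrix(tree, idx)
  nodes <- which(selected)
  clones <- lapply(nodes, function(v) tree$tip.label[P[v, ] > 0])
  keep <- lengths(clones) >= config$D
  nodes <- nodes[keep]; clones <- clones[keep]
  ord <- order(-lengths(clones))
  nodes <- nodes[ord]; clones <- clones[ord]
  ids <- sprintf("clone%03d", seq_along(clones))
  names(clones) <- ids
  defining <- lapply(nodes, function(v) conf$variant[conf$node == v])
  names(defining) <- ids
  unassigned <- setdiff(tree$tip.label, unlist(clones, use.names = FALSE))
  structure(list(clones = clones, defining_variants = defining,
                 unassigned = unassigned, nodes = setNames(nodes, ids),
                 config = config), class = "mtl_clones")
}

#' @export
print.mtl_clones <- function(x, ...) {
  cat(sprintf("clonal groups: %d clones covering %d cells (%d unassigned)\n",
              length(x$clones), sum(lengths(x$clones)), length(x$unassigned)))
  invisible(x)
}

#' Clone labels as a named vector
#' @param clones `mtl_clones`.
#' @return named character vector cell -> clone id (assigned cells only).
#' @export
clone_labels <- function(clones) {
  stopifnot(inherits(clones, "mtl_clones"))
  setNames(rep(names(clones$clones), lengths(clones$clones)),
           unlist(clones$clones, use.names = FALSE))
}

#' Clade-level cell-type enrichment
#'
#' For every internal clade of at least `min_clade_size` leaves and every
#' cell type: fold change of the in-clade type frequency over the global
#' frequency, a one-sided binomial p-value, and Storey q-values over all
#' tests. Flagged iff `q < fdr` and fold change > `fc`.
#'
#' @param tree rooted `ape::phylo`.
#' @param cell_types named vector tip -> cell type; untyped tips are
#'   excluded with a warning.
#' @param min_clade_size smallest clade tested (default 10).
#' @param fdr,fc flagging thresholds (defaults 0.2 and 2).
#' @return data.frame: clade (node id), clade_size, cell_type, n, k, fc, p,
#'   q, flagged.
#' @export
clade_celltype_enrichment <- function(tree, cell_types, min_clade_size = 10L,
                                      fdr = 0.2, fc = 2) {
  untyped <- setdiff(tree$tip.label, names(cell_types))
  if (length(untyped)) {
    warning(sprintf("%d untyped leaf(s) excluded", length(untyped)))
    tree <- ape::drop.tip(tree, untyped)
  }
  idx <- tree_index(tree)
  P <- clade_leaf_matrix(tree, idx)
  sz <- clade_sizes(tree, idx)
  types <- factor(cell_types[tree$tip.label])
  Tm <- Matrix::sparseMatrix(i = seq_along(types), j = as.integer(types), x = 1,
                             dims = c(length(types), nlevels(types)))
  counts <- as.matrix(P %*% Tm)            # nodes x types
  colnames(counts) <- levels(types)
  glob <- table(types) / length(types)
  cl <- which(sz >= min_clade_size & seq_len(idx$n_node) > idx$n_tip)
  rows <- expand.grid(clade = cl, cell_type = levels(types),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  k <- counts[cbind(rows$clade, match(rows$cell_type, levels(types)))]
  nn <- sz[rows$clade]
  p0 <- as.numeric(glob[rows$cell_type])
  out <- data.frame(clade = rows$clade, clade_size = nn,
                    cell_type = rows$cell_type, n = nn, k = k,
                    fc = (k / nn) / p0,
                    p = pbinom(k - 1, nn, p0, lower.tail = FALSE))
  out$q <- storey_qvalue(out$p)
  out$flagged <- out$q < fdr & out$fc > fc
  out[order(out$p), , drop = FALSE]
}
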