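## Clonal-diversity and expansion analyses: Shannon index, coalescent
## clade-expansion test, a tree-shape fitness proxy, and loss-of-chromosome-Y
## detection with clade enrichment.

#' Shannon diversity of a clonal composition
#'
#' `S = -sum (size_i / n) * ln(size_i / n)` with `n = sum(size_i)`; 0 for a
#' single clone and at most `ln(#clones)`.
#'
#' @param sizes positive clone sizes.
#' @return Shannon index (natural log).
#' @export
shannon_diversity <- function(sizes) {
  if (!length(sizes)) stop("empty clone-size vector")
  if (any(sizes <= 0)) stop("clone sizes must be positive")
  p <- sizes / sum(sizes)
  -sum(p * log(p))
}

#' Neutral-coalescent clade-size probability
#'
#' Under a neutral coalescent, the probability that a given child of an
#' internal node with `n` descendant leaves and `m` children has exactly `b`
#' leaves is `choose(n-b-1, m-2) / choose(n-1, m-1)`. The expansion p-value
#' is the upper tail `P(B >= b)`.
#'
#' @param n leaves under the parent node.
#' @param m children of the parent node (>= 2).
#' @param b leaves under the focal child (`1 <= b <= n - m + 1`).
#' @param tail if TRUE (default) return the upper-tail p-value, else the
#'   point probability.
#' @return probability.
#' @export
coalescent_clade_probability <- function(n, m, b, tail = TRUE) {
  if (m < 2 || b < 1 || b > n - m + 1 || n < m)
    stop("require m >= 2 and 1 <= b <= n - m + 1")
  pt <- function(bb) exp(lchoose(n - bb - 1, m - 2) - lchoose(n - 1, m - 1))
  if (!tail) return(pt(b))
  sum(vapply(b:(n - m + 1), pt, 0))
}

#' Clade-expansion test on a tree
#'
#' Computes the coalescent clade-size p-value for every non-root internal
#' node (against its direct sisters under the parent) and flags expanded
#' clades: `p < alpha` and at least `min_frac` of all cells. Maximal flagged
#' clades (no flagged ancestor) define the expanded clades; the fraction of
#' cells they contain is reported. An absolute-size rule is available via
#' `min_cells`.
#'
#' @param tree rooted `ape::phylo`.
#' @param min_frac minimum cell fraction for annotation (default 0.05).
#' @param alpha p-value threshold (default 0.01).
#' @param min_cells optional absolute clade-size floor used instead of
#'   `min_frac` when supplied.
#' @return object of class `mtl_expansion`: list with `table` (node, n, m,
#'   b, p, flagged), `expanded_nodes` (maximal flagged clades meeting the
#'   size rule), `expanded_fraction`, `leaves` (list per expanded node).
#' @export
expansion_test <- function(tree, min_frac = 0.05, alpha = 0.01,
                           min_cells = NULL) {
  if (!ape::is.rooted(tree)) stop("rooted tree required")
  idx <- tree_index(tree)
  sz <- clade_sizes(tree, idx)
  ntot <- idx$n_tip
  nodes <- setdiff(seq_len(idx$n_node), c(seq_len(idx$n_tip), idx$root))
  res <- data.frame(node = nodes,
                    n = sz[idx$parent[nodes]],
                    m = lengths(idx$children[idx$parent[nodes]]),
                    b = sz[nodes])
  res$p <- vapply(seq_len(nrow(res)), function(i)
    coalescent_clade_probability(res$n[i], res$m[i], res$b[i]), 0)
  size_ok <- if (is.null(min_cells)) res$b / ntot >= min_frac
    else res$b >= min_cells
  res$flagged <- res$p < alpha & size_ok
  flagged_nodes <- res$node[res$flagged]
  ## maximal flagged clades: no flagged proper ancestor
  anc_flagged <- function(v) {
    p <- idx$parent[v]
    while (p != 0 && p != idx$root) {
      if (p %in% flagged_nodes) return(TRUE)
      p <- idx$parent[p]
    }
    FALSE
  }
  expanded <- flagged_nodes[!vapply(flagged_nodes, anc_flagged, TRUE)]
  P <- clade_leaf_matrix(tree, idx)
  leaves <- lapply(expanded, function(v) tree$tip.label[P[v, ] > 0])
  names(leaves) <- as.character(expanded)
  frac <- if (length(expanded)) sum(sz[expanded]) / ntot else 0
  structure(list(table = res, expanded_nodes = expanded,
                 expanded_fraction = frac, leaves = leaves,
                 alpha = alpha, min_frac = min_frac),
            class = "mtl_expansion")
}

#' @export
print.mtl_expansion <- function(x, ...) {
  cat(sprintf("expansion test: %d expanded clade(s), %.1f%% of cells (p < %g)\n",
              length(x$expanded_nodes), 100 * x$expanded_fraction, x$alpha))
  invisible(x)
}

#' Local-branching-index fitness proxy
#'
#' Scores every leaf by the exponentially discounted tree length in its
#' neighbourhood (timescale `tau`), via up/down message passing. Leaves
#' inside large, recently expanded clades score high; isolated long
#' branches score low. This is a tree-shape proxy for relative fitness, not
#' a probabilistic fitness estimate.
#'
#' @param tree rooted `ape::phylo`; missing branch lengths default to 1
#'   (cladogram).
#' @param tau discount timescale in branch-length units; default 0.3 times
#'   the mean root-to-leaf depth.
#' @return named score vector per leaf, non-negative.
#' @export
fitness_scores <- function(tree, tau = NULL) {
  idx <- tree_index(tree)
  bl <- numeric(idx$n_node)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  bl[tree$edge[, 2]] <- tree$edge.length
  if (is.null(tau)) {
    depth <- numeric(idx$n_node)
    for (v in rev(idx$postorder)) for (c in idx$children[[v]] %||% integer(0))
      depth[c] <- depth[v] + bl[c]
    tau <- 0.3 * mean(depth[seq_len(idx$n_tip)])
  }
  if (tau <= 0) stop("tau must be positive")
  up <- numeric(idx$n_node)
  for (v in idx$postorder) {
    kids <- idx$children[[v]]
    if (!is.null(kids))
      up[v] <- sum(tau * (1 - exp(-bl[kids] / tau)) + exp(-bl[kids] / tau) * up[kids])
  }
  down <- numeric(idx$n_node)
  for (v in rev(idx$postorder)) {
    kids <- idx$children[[v]]
    if (is.null(kids)) next
    msg <- tau * (1 - exp(-bl[kids] / tau)) + exp(-bl[kids] / tau) * up[kids]
    tot <- sum(msg)
    for (c in kids) {
      inflow <- down[v] + (tot - msg[match(c, kids)])
      down[c] <- tau * (1 - exp(-bl[c] / tau)) + exp(-bl[c] / tau) * inflow
    }
  }
  lbi <- up + down
  setNames(lbi[seq_len(idx$n_tip)], tree$tip.label)
}

#' LOY detector configuration
#'
#' @param p_expected expected chrY fragment fraction; `NULL` (default)
#'   estimates it as total chrY fragments / total fragments; `"median"`
#'   uses the median per-cell fraction instead.
#' @param fold_threshold observed count must fall below expected /
#'   `fold_threshold` (default 10).
#' @param alpha binomial p-value threshold (default 0.001).
#' @return object of class `mtl_loy_config`.
#' @export
loy_config <- function(p_expected = NULL, fold_threshold = 10, alpha = 0.001) {
  if (fold_threshold <= 1) stop("fold_threshold must exceed 1")
  stopifnot_prob(alpha, "alpha")
  structure(list(p_expected = p_expected, fold_threshold = fold_threshold,
                 alpha = alpha), class = "mtl_loy_config")
}

#' Detect loss of chromosome Y from per-cell fragment counts
#'
#' A cell is called LOY when its chrY fragment count is more than
#' `fold_threshold`-fold below expectation and the binomial lower-tail
#' `P(X <= obs | n_cell, p_expected)` is below `alpha`. With `p_expected`
#' = 0 (e.g. a female donor) the detector is disabled with a message.
#'
#' @param counts data.frame with columns cell, chrom, n_fragments; chrY rows
#'   are those with `chrom == "chrY"` (or `"Y"`).
#' @param config `mtl_loy_config`.
#' @return data.frame per cell: cell, n_total, n_y, expected, p, loy; the
#'   `"p_expected"` attribute records the rate used. `NULL` (invisibly)
#'   when disabled.
#' @export
detect_loy <- function(counts, config = loy_config()) {
  stopifnot(all(c("cell", "chrom", "n_fragments") %in% names(counts)))
  isy <- counts$chrom %in% c("chrY", "Y")
  tot <- tapply(counts$n_fragments, counts$cell, sum)
  ycnt <- tapply(counts$n_fragments[isy], counts$cell[isy], sum)
  cells <- names(tot)
  y <- as.numeric(ycnt[cells]); y[is.na(y)] <- 0
  n <- as.numeric(tot)
  keep <- n > 0
  if (any(!keep)) {
    warning(sprintf("%d cell(s) with zero total fragments skipped", sum(!keep)))
    cells <- cells[keep]; y <- y[keep]; n <- n[keep]
  }
  pexp <- config$p_expected
  if (is.null(pexp)) pexp <- sum(y) / sum(n)
  else if (identical(pexp, "median")) pexp <- median(y / n)
  if (pexp <= 0) {
    message("aggregate chrY fraction is 0; LOY detector disabled")
    return(invisible(NULL))
  }
  expd <- n * pexp
  p <- pbinom(y, n, pexp)
  loy <- y < expd / config$fold_threshold & p < config$alpha
  out <- data.frame(cell = cells, n_total = n, n_y = y, expected = expd,
                    p = p, loy = loy, stringsAsFactors = FALSE)
  attr(out, "p_expected") <- pexp
  out
}

#' LOY enrichment per clade or clone
#'
#' Per clade: LOY density, its z-score against the total density under a
#' binomial variance, a one-tailed binomial p-value and Storey q-values.
#' Returns an empty table when no LOY cells exist.
#'
#' @param clades named list clade/clone id -> cell vector (e.g.
#'   `mtl_clones$clones` or `mtl_expansion$leaves`).
#' @param loy data.frame from [detect_loy()].
#' @param min_size clades smaller than this are skipped (default 10).
#' @return data.frame: clade, size, n_loy, density, z, p, q.
#' @export
loy_clade_enrichment <- function(clades, loy, min_size = 10L) {
  if (is.null(loy) || !any(loy$loy))
    return(data.frame(clade = character(0), size = integer(0),
                      n_loy = integer(0), density = numeric(0),
                      z = numeric(0), p = numeric(0), q = numeric(0)))
  loy_cells <- loy$cell[loy$loy]
  total_density <- mean(loy$loy)
  clades <- clades[lengths(clades) >= min_size]
  rows <- lapply(names(clades), function(id) {
    cs <- intersect(clades[[id]], loy$cell)
    sz <- length(cs)
    if (sz < min_size) return(NULL)
    k <- sum(cs %in% loy_cells)
    dens <- k / sz
    z <- (dens - total_density) /
      sqrt(total_density * (1 - total_density) / sz)
    p <- pbinom(k - 1, sz, total_density, lower.tail = FALSE)
    data.frame(clade = id, size = sz, n_loy = k, density = dens, z = z, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(clade = character(0), size = integer(0),
                                      n_loy = integer(0), density = numeric(0),
                                      z = numeric(0), p = numeric(0),
                                      q = numeric(0)))
  out$q <- storey_qvalue(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Expanded-clade cell-type composition and cumulative clone-size curve
#'
#' Per expanded clade: observed cell-type proportions next to the global
#' (expected) proportions. Also returns the ranked cumulative clone-size
#' curve used to compare clonal structure between donors; for equal clone
#' sizes the curve is the straight line k/K.
#'
#' @param clades named list clade id -> cells.
#' @param cell_types named vector cell -> type.
#' @return list with `composition` (clade, cell_type, n, prop, expected)
#'   and `cumulative` (rank, size, cumulative fraction).
#' @export
expanded_clade_composition <- function(clades, cell_types) {
  glob <- table(cell_types) / length(cell_types)
  comp <- do.call(rbind, lapply(names(clades), function(id) {
    ct <- cell_types[intersect(clades[[id]], names(cell_types))]
    tab <- table(factor(ct, names(glob)))
    data.frame(clade = id, cell_type = names(tab), n = as.integer(tab),
               prop = as.numeric(tab) / max(1, sum(tab)),
               expected = as.numeric(glob), stringsAsFactors = FALSE)
  }))
  sizes <- sort(lengths(clades), decreasing = TRUE)
  cum <- data.frame(rank = seq_along(sizes), clone = names(sizes),
                    size = as.integer(sizes),
                    cumulative = if (length(sizes)) cumsum(sizes) / sum(sizes)
                      else numeric(0))
  list(composition = comp, cumulative = cum)
}
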