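# Shared fixture builders; everything is generated in code.

# A minimal read table: one eUMI group per row-spec entry.
# groups: list of list(cell, start, end, n, alt = c(pos = "A"), n_alt)
# n_alt reads carry the alt mismatches, the rest are reference.
make_reads <- function(groups) {
  rows <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    n_alt <- g$n_alt %||% g$n
    mm <- if (is.null(g$alt)) "" else
      paste0(names(g$alt), ":", unname(g$alt), collapse = ";")
    data.frame(cell = g$cell, start = g$start, end = g$end,
               mate = rep(c("plus", "minus"), length.out = g$n),
               mismatches = c(rep(mm, n_alt), rep("", g$n - n_alt)),
               molecule_id = paste0("m", i), sample = "s1",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Binary matrix from a named list cell -> variant ids.
make_cbin <- function(profiles, variants = sort(unique(unlist(profiles)))) {
  M <- Matrix::sparseMatrix(
    i = rep(seq_along(profiles), lengths(profiles)),
    j = match(unlist(profiles, use.names = FALSE), variants),
    x = 1, dims = c(length(profiles), length(variants)),
    dimnames = list(names(profiles), variants))
  M
}

# Balanced binary tree over n = 2^k tips labelled t1..tn.
balanced_tree <- function(n) {
  tr <- ape::stree(n, type = "balanced")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

# Small standard simulation shared by several tests.
small_truth <- function(seed = 42, n_clones = 6, cells_per_clone = 15, ...) {
  simulate_lineage(sim_config(n_clones = n_clones,
                              cells_per_clone = cells_per_clone,
                              seed = seed, ...))
}

# Independent closed-form RWR solve: p = r (I - (1-r) W)^-1 p0.
rwr_closed_form <- function(A, seeds, restart) {
  A <- as.matrix(A)
  deg <- colSums(A)
  zero <- deg == 0
  diag(A)[zero] <- 1
  deg[zero] <- 1
  W <- A %*% diag(1 / deg)
  p0 <- numeric(nrow(A)); p0[seeds] <- 1 / length(seeds)
  as.numeric(restart * solve(diag(nrow(A)) - (1 - restart) * W, p0))
}
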