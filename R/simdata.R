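## Generative model of a clonally structured cell population accruing
## heteroplasmic mtDNA mutations, with molecule capture, eUMI read groups,
## sequencing error and clone-biased cell-state labels. Every downstream
## module can be benchmarked against the ground truth this emits.

#' Simulation configuration
#'
#' Parameters of the population simulator. The mutation process is per genome
#' replication: every division each mtDNA molecule replicates once and each
#' replication acquires `Poisson(mu)` substitutions at uniform positions; the
#' `2 * n` molecules are then partitioned binomially between daughters
#' (neutral copy-number drift). Clone founders descend from a single root cell
#' through `founder_depth` divisions of the same process, so founders carry
#' clone-enriched heteroplasmic variants; sampled cells sit
#' `divisions_per_cell` divisions below their founder.
#'
#' Defaults are calibrated so that the default population shows a median of
#' about 9 detected variants per cell at the default capture rate, the regime
#' reported for deep mtDNA mutation profiling of human haematopoietic cells
#' (~300 mtDNA copies per cell, ~51 captured, ~4.8 reads per eUMI group).
#'
#' @param n_clones number of clone founders.
#' @param cells_per_clone sampled cells per clone (scalar or per-clone vector).
#' @param divisions_per_cell divisions from clone founder to each sampled cell.
#' @param founder_depth divisions from the population root to the founders.
#' @param mt_copies mtDNA genomes per cell at the root (drifts thereafter).
#' @param mu expected new substitutions per genome replication (Poisson).
#' @param genome_length mtDNA genome length (1-based, circular).
#' @param capture_rate fraction of a cell's molecules captured by sequencing.
#' @param reads_per_eumi_mean mean reads per eUMI group (shifted Poisson, min 1).
#' @param seq_error_rate per-base substitution error per read.
#' @param fragment_len_mean,fragment_len_sd fragment length distribution (bp).
#' @param bias_alpha Dirichlet concentration for per-clone lineage proportions
#'   (scalar symmetric, or one value per lineage).
#' @param frac_hsc fraction of sampled cells flagged as stem cells.
#' @param n_timepoints number of sampling timepoints.
#' @param sample_id sample label attached to simulated reads.
#' @param seed integer seed; all stages derive their streams from it.
#' @return object of class `mtl_sim_config` (a validated list).
#' @export
sim_config <- function(n_clones = 78L, cells_per_clone = 64L,
                       divisions_per_cell = 20L, founder_depth = 50L,
                       mt_copies = 300L, mu = 0.011, genome_length = 16569L,
                       capture_rate = 0.17, reads_per_eumi_mean = 4.8,
                       seq_error_rate = 1e-3, fragment_len_mean = 250,
                       fragment_len_sd = 60, bias_alpha = 1.5,
                       frac_hsc = 0.25, n_timepoints = 2L,
                       sample_id = "s1", seed = 1L) {
  stopifnot_pos_int(n_clones, "n_clones")
  stopifnot_pos_int(divisions_per_cell, "divisions_per_cell")
  stopifnot_pos_int(mt_copies, "mt_copies")
  stopifnot_pos_int(genome_length, "genome_length")
  if (length(cells_per_clone) == 1L) cells_per_clone <- rep(cells_per_clone, n_clones)
  if (length(cells_per_clone) != n_clones)
    stop("cells_per_clone must be scalar or length n_clones")
  for (k in cells_per_clone) stopifnot_pos_int(k, "cells_per_clone")
  if (!is.numeric(mu) || !is.finite(mu) || mu < 0) stop("mu must be finite and >= 0")
  stopifnot_prob(capture_rate, "capture_rate")
  stopifnot_prob(seq_error_rate, "seq_error_rate")
  stopifnot_prob(frac_hsc, "frac_hsc")
  if (founder_depth < 0) stop("founder_depth must be >= 0")
  if (reads_per_eumi_mean < 1) stop("reads_per_eumi_mean must be >= 1")
  if (fragment_len_mean <= 0 || fragment_len_sd <= 0) stop("fragment lengths must be positive")
  if (any(bias_alpha <= 0)) stop("bias_alpha must be positive")
  structure(list(
    n_clones = as.integer(n_clones), cells_per_clone = as.integer(cells_per_clone),
    divisions_per_cell = as.integer(divisions_per_cell),
    founder_depth = as.integer(founder_depth), mt_copies = as.integer(mt_copies),
    mu = mu, genome_length = as.integer(genome_length),
    capture_rate = capture_rate, reads_per_eumi_mean = reads_per_eumi_mean,
    seq_error_rate = seq_error_rate, fragment_len_mean = fragment_len_mean,
    fragment_len_sd = fragment_len_sd, bias_alpha = bias_alpha,
    frac_hsc = frac_hsc, n_timepoints = as.integer(n_timepoints),
    sample_id = sample_id, seed = as.integer(seed)), class = "mtl_sim_config")
}

## One cell division applied to a molecule-population state
## state: list(n = molecule count, pos, alt, cnt = per-variant carrier counts)
## Replication doubles every molecule (counts double exactly) and adds
## Poisson(mu * n) single-copy mutations; partition sends n1 ~ Binomial(2n, .5)
## molecules to the followed daughter, per-variant counts hypergeometric.
divide_state <- function(state, mu, L, split = FALSE) {
  n2 <- 2L * state$n
  cnt <- 2L * state$cnt
  pos <- state$pos; alt <- state$alt
  k_new <- rpois(1L, mu * state$n)
  if (k_new > 0) {
    npos <- sample.int(L, k_new, replace = TRUE)
    nalt <- sample.int(3L, k_new, replace = TRUE)  # resolved vs reference later
    pos <- c(pos, npos); alt <- c(alt, nalt); cnt <- c(cnt, rep(1L, k_new))
    key <- paste0(pos, "_", alt)
    if (anyDuplicated(key)) {
      cnt <- as.integer(rowsum(cnt, key, reorder = FALSE))
      keep <- !duplicated(key)
      pos <- pos[keep]; alt <- alt[keep]
    }
  }
  n1 <- rbinom(1L, n2, 0.5)
  n1 <- max(1L, min(n2 - if (split) 1L else 0L, n1))
  nv <- length(pos)
  c1 <- if (nv) as.integer(rhyper(nv, cnt, n2 - cnt, n1)) else integer(0)
  d1 <- list(n = n1, pos = pos[c1 > 0], alt = alt[c1 > 0], cnt = c1[c1 > 0])
  if (!split) return(list(d1))
  c2 <- cnt - c1
  d2 <- list(n = n2 - n1, pos = pos[c2 > 0], alt = alt[c2 > 0], cnt = c2[c2 > 0])
  list(d1, d2)
}

## Random division-tree topology: subtree with k sampled leaves and exactly D
## divisions on every root-to-leaf path. Each internal node records g solo
## divisions before its split; the split itself is one division.
grow_topology <- function(k, D) {
  if (k == 1L) return(list(g = D, children = NULL))
  clog2 <- function(x) ceiling(log2(x))
  repeat {
    k1 <- sample.int(k - 1L, 1L)
    k2 <- k - k1
    need <- max(clog2(k1), clog2(k2))
    if (D - 1L >= need) break
  }
  g <- if (D - 1L - need > 0) sample.int(D - need, 1L) - 1L else 0L
  Dc <- D - g - 1L
  list(g = g, children = list(grow_topology(k1, Dc), grow_topology(k2, Dc)))
}

## Evolve a state down a topology; collect leaf states and a newick fragment.
sim_subtree <- function(state, node, mu, L, labeller) {
  for (i in seq_len(node$g)) state <- divide_state(state, mu, L)[[1]]
  if (is.null(node$children)) {
    lab <- labeller()
    return(list(states = setNames(list(state), lab),
                newick = paste0(lab, ":", node$g)))
  }
  ds <- divide_state(state, mu, L, split = TRUE)
  r1 <- sim_subtree(ds[[1]], node$children[[1]], mu, L, labeller)
  r2 <- sim_subtree(ds[[2]], node$children[[2]], mu, L, labeller)
  list(states = c(r1$states, r2$states),
       newick = paste0("(", r1$newick, ",", r2$newick, "):", node$g + 1L))
}

#' Simulate a clonally structured lineage with mtDNA mutation accrual
#'
#' Runs the division process from a single unmutated root: `founder_depth`
#' divisions to the clone founders (random division-tree topology), then
#' `divisions_per_cell` divisions from each founder to its sampled cells.
#' Mutations arise per genome replication and drift neutrally through binomial
#' partition of molecules at each division.
#'
#' @param config `mtl_sim_config`.
#' @return object of class `mtl_truth`: list with `tree` (rooted `ape::phylo`
#'   over sampled cells, branch lengths in divisions), `clone` (named vector
#'   cell -> clone id), `variants` (data.frame: cell, variant, pos, ref, alt,
#'   count, n_mol, het), `n_mol` (named molecule counts per cell), `reference`
#'   (simulated mtDNA sequence), `config`.
#' @export
simulate_lineage <- function(config) {
  stopifnot(inherits(config, "mtl_sim_config"))
  with_seed(config$seed, {
    L <- config$genome_length
    reference <- sample(DNA_BASES, L, replace = TRUE)
    root <- list(n = config$mt_copies, pos = integer(0), alt = integer(0), cnt = integer(0))

    ftopo <- if (config$n_clones > 1L)
      grow_topology(config$n_clones, max(config$founder_depth,
                                         ceiling(log2(config$n_clones)) + 1L))
      else list(g = config$founder_depth, children = NULL)
    fi <- 0L
    fres <- sim_subtree(root, ftopo, config$mu, L,
                        function() { fi <<- fi + 1L; sprintf("F%03d", fi) })
    founders <- fres$states

    ci <- 0L
    clone_states <- vector("list", config$n_clones)
    clone_newick <- character(config$n_clones)
    for (f in seq_len(config$n_clones)) {
      ctopo <- if (config$cells_per_clone[f] > 1L)
        grow_topology(config$cells_per_clone[f],
                      max(config$divisions_per_cell,
                          ceiling(log2(config$cells_per_clone[f])) + 1L))
        else list(g = config$divisions_per_cell, children = NULL)
      cres <- sim_subtree(founders[[f]], ctopo, config$mu, L,
                          function() { ci <<- ci + 1L; sprintf("C%05d", ci) })
      clone_states[[f]] <- cres$states
      clone_newick[f] <- cres$newick
    }

    ## splice clone subtrees into the founder newick at the founder tips
    newick <- fres$newick
    for (f in seq_len(config$n_clones)) {
      flab <- sprintf("F%03d", f)
      frag <- sub(paste0("^", flab, ":"), "", regmatches(
        newick, regexpr(paste0(flab, ":[0-9]+"), newick)))
      croot <- sub("^.*:", "", clone_newick[f])
      newlen <- as.integer(frag) + as.integer(croot)
      newick <- sub(paste0(flab, ":[0-9]+"),
                    sub(":[0-9]+$", paste0(":", newlen), clone_newick[f]),
                    newick)
    }
    tree <- if (sum(config$cells_per_clone) >= 2) {
      ape::read.tree(text = paste0(newick, ";"))
    } else {
      structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = "C00001",
                     Nnode = 1L,
                     edge.length = config$founder_depth + config$divisions_per_cell),
                class = "phylo")
    }

    states <- do.call(c, clone_states)
    cells <- names(states)
    clone <- setNames(rep(sprintf("clone%03d", seq_len(config$n_clones)),
                          config$cells_per_clone), cells)
    n_mol <- setNames(vapply(states, `[[`, 0L, "n"), cells)

    vr <- lapply(cells, function(cl) {
      s <- states[[cl]]
      if (!length(s$pos)) return(NULL)
      ref <- reference[s$pos]
      ## alt index 1..3 maps to the non-reference bases at that position
      alt <- vapply(seq_along(s$pos),
                    function(i) setdiff(DNA_BASES, ref[i])[s$alt[i]], "")
      data.frame(cell = cl, variant = paste0(s$pos, "_", ref, "_", alt),
                 pos = s$pos, ref = ref, alt = alt, count = s$cnt,
                 n_mol = s$n, het = s$cnt / s$n, stringsAsFactors = FALSE)
    })
    variants <- do.call(rbind, vr)
    if (is.null(variants))
      variants <- data.frame(cell = character(0), variant = character(0),
                             pos = integer(0), ref = character(0),
                             alt = character(0), count = integer(0),
                             n_mol = integer(0), het = numeric(0))
    structure(list(tree = tree, clone = clone, variants = variants,
                   n_mol = n_mol, reference = reference, config = config),
              class = "mtl_truth")
  })
}

#' @export
print.mtl_truth <- function(x, ...) {
  cat("Simulated lineage truth set\n")
  cat(sprintf("  %d cells in %d clones; %d variant observations (%d distinct)\n",
              length(x$clone), length(unique(x$clone)),
              nrow(x$variants), length(unique(x$variants$variant))))
  med <- median(tabulate(factor(x$variants$cell, levels = names(x$clone))))
  cat(sprintf("  median true variants per cell: %.0f\n", med))
  invisible(x)
}

#' True variant-by-cell count matrix, optionally capture-thinned
#'
#' Converts the truth set into a sparse cells-by-variants matrix of molecule
#' counts. With `capture_rate < 1`, per-cell captured molecule totals are
#' binomial and per-variant captured counts hypergeometric, emulating perfect
#' detection on the captured fraction of each cell's molecules.
#'
#' @param truth `mtl_truth`.
#' @param capture_rate capture fraction; defaults to the truth's config value.
#'   Use 1 for the noiseless truth matrix.
#' @param seed seed for the capture thinning.
#' @return sparse `dgCMatrix`, cells x variants.
#' @export
truth_variant_matrix <- function(truth, capture_rate = truth$config$capture_rate,
                                 seed = truth$config$seed + 17L) {
  stopifnot(inherits(truth, "mtl_truth"))
  stopifnot_prob(capture_rate, "capture_rate")
  v <- truth$variants
  cells <- names(truth$clone)
  if (!nrow(v))
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(length(cells), 0),
                                dimnames = list(cells, character(0))))
  cnt <- v$count
  if (capture_rate < 1) {
    with_seed(seed, {
      m_cap <- setNames(rbinom(length(cells), truth$n_mol[cells], capture_rate), cells)
      cnt <- as.integer(rhyper(nrow(v), v$count, v$n_mol - v$count, m_cap[v$cell]))
    })
  }
  keep <- cnt > 0
  vid <- sort(unique(v$variant[keep]))
  Matrix::sparseMatrix(i = match(v$cell[keep], cells),
                       j = match(v$variant[keep], vid), x = cnt[keep],
                       dims = c(length(cells), length(vid)),
                       dimnames = list(cells, vid))
}

#' Simulate eUMI-structured reads from a truth set
#'
#' Each cell's molecules are captured at `capture_rate`; a captured molecule
#' receives a fragment (start, end), a shifted-Poisson number of reads
#' (minimum 1, mean `reads_per_eumi_mean`) alternating plus/minus mates, the
#' molecule's variants inside the fragment as mismatches, and independent
#' per-base sequencing errors at `seq_error_rate`. Fragments never cross the
#' circular origin (starts are drawn from 1..L-len+1).
#'
#' @param truth `mtl_truth`.
#' @param config `mtl_sim_config`; defaults to the truth's config.
#' @return data.frame read table: cell, start, end, mate, mismatches
#'   (semicolon-joined "pos:alt"), molecule_id, sample. The
#'   `"molecule_truth"` attribute records, per captured molecule, the true
#'   variants lying inside its fragment (molecule_id, cell, size, pos, alt).
#' @export
simulate_reads <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "mtl_truth"))
  stopifnot_prob(config$capture_rate, "capture_rate")
  L <- config$genome_length
  vs <- split(truth$variants, truth$variants$cell)
  with_seed(config$seed + 1L, {
    out <- vector("list", length(truth$n_mol))
    mtruth <- vector("list", length(truth$n_mol))
    for (ci in seq_along(truth$n_mol)) {
      cell <- names(truth$n_mol)[ci]
      n <- truth$n_mol[[ci]]
      M <- rbinom(1L, n, config$capture_rate)
      if (M == 0L) next
      len <- pmax(50L, pmin(L, as.integer(round(
        rnorm(M, config$fragment_len_mean, config$fragment_len_sd)))))
      start <- as.integer(floor(runif(M) * (L - len + 1))) + 1L
      end <- start + len - 1L
      ## which captured molecules carry which of the cell's variants
      mol_vars <- vector("list", M)
      v <- vs[[cell]]
      if (!is.null(v) && nrow(v)) {
        kcap <- as.integer(rhyper(nrow(v), v$count, n - v$count, M))
        for (j in which(kcap > 0)) {
          idx <- sample.int(M, kcap[j])
          hit <- idx[v$pos[j] >= start[idx] & v$pos[j] <= end[idx]]
          for (m in hit) mol_vars[[m]] <- c(mol_vars[[m]],
                                            setNames(v$alt[j], v$pos[j]))
        }
      }
      sizes <- 1L + rpois(M, config$reads_per_eumi_mean - 1)
      nv_mol <- lengths(mol_vars)
      if (any(nv_mol > 0)) {
        mi <- rep.int(which(nv_mol > 0), nv_mol[nv_mol > 0])
        vv <- unlist(mol_vars[nv_mol > 0], use.names = TRUE)
        mtruth[[ci]] <- data.frame(
          molecule_id = paste0(cell, ".m", mi), cell = cell,
          size = sizes[mi], pos = as.integer(names(vv)), alt = unname(vv),
          stringsAsFactors = FALSE)
      }
      mol_of_read <- rep.int(seq_len(M), sizes)
      within <- sequence(sizes)
      nr <- length(mol_of_read)
      mm <- character(nr)
      nerr <- rbinom(nr, len[mol_of_read], config$seq_error_rate)
      active <- which(nerr > 0L | lengths(mol_vars)[mol_of_read] > 0L)
      for (r in active) {
        m <- mol_of_read[r]
        vars <- mol_vars[[m]]
        if (nerr[r] > 0L) {
          epos <- start[m] + sample.int(len[m], nerr[r]) - 1L
          ebase <- vapply(epos, function(p) {
            cur <- if (!is.null(vars) && as.character(p) %in% names(vars))
              vars[[as.character(p)]] else truth$reference[p]
            sample(setdiff(DNA_BASES, cur), 1L)
          }, "")
          keepv <- if (is.null(vars)) NULL else vars[!(names(vars) %in% as.character(epos))]
          keep_err <- ebase != truth$reference[epos]  # errors back to ref vanish
          vars <- c(keepv, setNames(ebase[keep_err], epos[keep_err]))
        }
        if (!is.null(vars) && length(vars)) {
          o <- order(as.integer(names(vars)))
          mm[r] <- paste0(names(vars)[o], ":", vars[o], collapse = ";")
        }
      }
      out[[ci]] <- data.frame(
        cell = cell, start = start[mol_of_read], end = end[mol_of_read],
        mate = c("plus", "minus")[(within %% 2L) + 1L], mismatches = mm,
        molecule_id = paste0(cell, ".m", mol_of_read),
        sample = config$sample_id, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    if (is.null(res))
      res <- data.frame(cell = character(0), start = integer(0), end = integer(0),
                        mate = character(0), mismatches = character(0),
                        molecule_id = character(0), sample = character(0))
    rownames(res) <- NULL
    mt <- do.call(rbind, mtruth)
    if (is.null(mt))
      mt <- data.frame(molecule_id = character(0), cell = character(0),
                       size = integer(0), pos = integer(0), alt = character(0))
    rownames(mt) <- NULL
    attr(res, "molecule_truth") <- mt
    res
  })
}

#' Default cell-type -> lineage map for haematopoietic progeny
#'
#' myeloid = Mono, GMP, MDP, cDC; erythroid = MEP, EryP; MK = MKP;
#' lymphoid = CD4, CD8, NK, B, ProB, CLP.
#' @return named character vector, cell type -> lineage.
#' @export
default_lineage_map <- function() {
  c(Mono = "myeloid", GMP = "myeloid", MDP = "myeloid", cDC = "myeloid",
    MEP = "erythroid", EryP = "erythroid", MKP = "MK",
    CD4 = "lymphoid", CD8 = "lymphoid", NK = "lymphoid", B = "lymphoid",
    ProB = "lymphoid", CLP = "lymphoid")
}

#' Default cell-type -> differentiation-trajectory map
#'
#' The grouping used when selecting lineage-informative variants:
#' myeloid = GMP, MDP, Mono; lymphoid = CLP, ProB, CD4, CD8, B, NK;
#' MK = MKP; erythroid = MEP, EryP.
#' @return named character vector, cell type -> trajectory.
#' @export
default_trajectory_map <- function() {
  c(GMP = "myeloid", MDP = "myeloid", Mono = "myeloid",
    CLP = "lymphoid", ProB = "lymphoid", CD4 = "lymphoid", CD8 = "lymphoid",
    B = "lymphoid", NK = "lymphoid", MKP = "MK",
    MEP = "erythroid", EryP = "erythroid")
}

#' Simulate clone-biased cell states over timepoints
#'
#' Per clone, lineage proportions are drawn once from
#' `Dirichlet(bias_alpha)` and reused at every timepoint; each progeny cell
#' draws its lineage from its clone's proportions and a uniform cell type
#' within the lineage. A fraction `frac_hsc` of cells is flagged as stem cells
#' (type "HSC", no lineage). Timepoints are assigned uniformly.
#'
#' @param truth `mtl_truth`.
#' @param config `mtl_sim_config`; defaults to the truth's config.
#' @return data.frame: cell, clone, cell_type, lineage, is_hsc, timepoint;
#'   attribute `clone_props` holds the per-clone lineage proportions.
#' @export
simulate_states <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "mtl_truth"))
  if (any(config$bias_alpha <= 0)) stop("bias_alpha must be positive")
  lmap <- default_lineage_map()
  lineages <- unique(unname(lmap))
  alpha <- if (length(config$bias_alpha) == 1L)
    rep(config$bias_alpha, length(lineages)) else config$bias_alpha
  if (length(alpha) != length(lineages)) stop("bias_alpha must be scalar or one per lineage")
  cells <- names(truth$clone)
  clones <- sort(unique(truth$clone))
  with_seed(config$seed + 2L, {
    props <- t(vapply(clones, function(cl) {
      g <- rgamma(length(lineages), alpha); g / sum(g)
    }, numeric(length(lineages))))
    colnames(props) <- lineages
    is_hsc <- runif(length(cells)) < config$frac_hsc
    lin <- character(length(cells)); typ <- character(length(cells))
    for (i in seq_along(cells)) {
      if (is_hsc[i]) { typ[i] <- "HSC"; lin[i] <- NA_character_; next }
      lin[i] <- sample(lineages, 1L, prob = props[truth$clone[cells[i]], ])
      typ[i] <- sample(names(lmap)[lmap == lin[i]], 1L)
    }
    tp <- sample.int(config$n_timepoints, length(cells), replace = TRUE)
    out <- data.frame(cell = cells, clone = unname(truth$clone[cells]),
                      cell_type = typ, lineage = lin, is_hsc = is_hsc,
                      timepoint = tp, stringsAsFactors = FALSE)
    attr(out, "clone_props") <- props
    out
  })
}
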