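## Clone-level behavioural statistics: output activity, lineage bias,
## clone-to-state enrichment, lineage-informative variant selection and
## cell-type-origin KNN analysis.

#' Fisher combination of independent p-values
#'
#' `-2 sum(log p)` against a chi-squared with `2 * length(p)` degrees of
#' freedom (4 for two timepoints).
#' @param p vector of p-values.
#' @return combined p-value.
#' @export
fisher_combine <- function(p) {
  p <- pmax(p, .Machine$double.xmin)
  pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Clonal output activity
#'
#' Progeny assigned to each clonal group per timepoint, normalized by the
#' clone's stem-cell count. Summaries: top-vs-bottom decile fold change of
#' normalized output, the ranked cumulative-contribution curve, and the
#' Pearson correlation of normalized output between the first two
#' timepoints (clones observed at both).
#'
#' @param assignments `mtl_assignment` or its `table` (cell, clone, assigned).
#' @param states data.frame with cell, is_hsc, timepoint.
#' @param clone_sizes named vector clone -> number of stem cells; by default
#'   counted from the seeds present in `states` (`is_hsc` cells per clone).
#' @return object of class `mtl_output`: list with `activity` (clone,
#'   timepoint, progeny, clone_size, output), `decile_fc`, `cumulative`
#'   (per timepoint ranked curves), `pearson_r`.
#' @export
clonal_output <- function(assignments, states, clone_sizes = NULL) {
  tab <- if (inherits(assignments, "mtl_assignment")) assignments$table else assignments
  tab <- tab[tab$assigned %||% TRUE, , drop = FALSE]
  tab <- tab[!is.na(tab$clone), , drop = FALSE]
  st <- states[match(tab$cell, states$cell), ]
  prog <- !st$is_hsc
  if (is.null(clone_sizes)) {
    hs <- states[states$is_hsc & states$cell %in% tab$cell, , drop = FALSE]
    hcl <- tab$clone[match(hs$cell, tab$cell)]
    clone_sizes <- table(hcl)
  }
  df <- data.frame(clone = tab$clone[prog], timepoint = st$timepoint[prog])
  if (nrow(df) == 0)
    return(structure(list(activity = data.frame(clone = character(0),
                                                timepoint = integer(0),
                                                progeny = integer(0),
                                                clone_size = numeric(0),
                                                output = numeric(0)),
                          decile_fc = NA_real_, cumulative = list(),
                          pearson_r = NA_real_), class = "mtl_output"))
  cnt <- as.data.frame(table(clone = df$clone, timepoint = df$timepoint),
                       stringsAsFactors = FALSE)
  names(cnt)[3] <- "progeny"
  cnt$clone_size <- as.numeric(clone_sizes[cnt$clone])
  cnt <- cnt[!is.na(cnt$clone_size) & cnt$clone_size > 0, , drop = FALSE]
  if (nrow(cnt) == 0)
    return(structure(list(activity = cnt, decile_fc = NA_real_,
                          cumulative = list(), pearson_r = NA_real_),
                     class = "mtl_output"))
  cnt$output <- cnt$progeny / cnt$clone_size
  dec <- quantile(cnt$output, c(0.1, 0.9))
  top <- mean(cnt$output[cnt$output >= dec[2]])
  bot <- mean(cnt$output[cnt$output <= dec[1]])
  decile_fc <- if (bot > 0) top / bot else Inf
  if (stats::var(cnt$output) == 0) decile_fc <- 1
  cum <- lapply(split(cnt, cnt$timepoint), function(d) {
    d <- d[order(-d$progeny), ]
    tot <- sum(d$progeny)
    data.frame(clone = c(NA_character_, d$clone), rank = 0:nrow(d),
               cumulative = c(0, if (tot > 0) cumsum(d$progeny) / tot else
                 rep(0, nrow(d))))
  })
  tps <- sort(unique(cnt$timepoint))
  r <- NA_real_
  if (length(tps) >= 2) {
    a <- cnt[cnt$timepoint == tps[1], ]; b <- cnt[cnt$timepoint == tps[2], ]
    common <- intersect(a$clone, b$clone)
    if (length(common) >= 3)
      r <- cor(a$output[match(common, a$clone)], b$output[match(common, b$clone)])
  }
  structure(list(activity = cnt, decile_fc = decile_fc, cumulative = cum,
                 pearson_r = r), class = "mtl_output")
}

## per-clone x lineage x timepoint counts with totals
.lineage_counts <- function(assignments, states, lineage_map) {
  tab <- if (inherits(assignments, "mtl_assignment")) assignments$table else assignments
  tab <- tab[!is.na(tab$clone) & (tab$assigned %||% TRUE), , drop = FALSE]
  st <- states[match(tab$cell, states$cell), ]
  prog <- !st$is_hsc & st$cell_type %in% names(lineage_map)
  data.frame(clone = tab$clone[prog],
             lineage = unname(lineage_map[st$cell_type[prog]]),
             timepoint = st$timepoint[prog], stringsAsFactors = FALSE)
}

#' Clone lineage-bias table
#'
#' Per clone and lineage: exact two-sided binomial test of the clone's
#' progeny lineage count against the background lineage proportion, per
#' timepoint; Fisher-combined p over the two timepoints; Storey q-values;
#' FDR classes `*` (0.05-0.20), `**` (0.01-0.05), `***` (< 0.01). A
#' clone-lineage pair is `biased` only when the fold-change direction agrees
#' at both timepoints and the FDR class is at least `*`. (A p-value sided
#' toward the observed direction would be anti-conservative under the null
#' and destroy FDR calibration; the direction requirement carries the
#' sidedness instead.)
#'
#' @param assignments `mtl_assignment` or assignment table.
#' @param states data.frame with cell, cell_type, is_hsc, timepoint.
#' @param lineage_map named vector cell type -> lineage
#'   (default [default_lineage_map()]).
#' @param background named lineage proportions; defaults to the pooled
#'   proportions over all progeny at both timepoints.
#' @param min_progeny minimum progeny per clone-timepoint to test (default 1).
#' @return data.frame: clone, lineage, fc_tp1, fc_tp2, p_tp1, p_tp2,
#'   p_combined, q, class, biased.
#' @export
lineage_bias <- function(assignments, states,
                         lineage_map = default_lineage_map(),
                         background = NULL, min_progeny = 1L) {
  lc <- .lineage_counts(assignments, states, lineage_map)
  if (!nrow(lc)) stop("no typed progeny to test")
  tps <- sort(unique(lc$timepoint))[1:2]
  if (anyNA(tps)) stop("two timepoints required")
  lineages <- sort(unique(unname(lineage_map)))
  if (is.null(background)) {
    bt <- table(factor(lc$lineage, lineages))
    background <- as.numeric(bt) / sum(bt)
    names(background) <- lineages
  }
  clones <- sort(unique(lc$clone))
  res <- list()
  for (cl in clones) {
    for (lin in lineages) {
      p0 <- background[[lin]]
      if (is.na(p0) || p0 == 0 || p0 == 1) next
      fcv <- pv <- rep(NA_real_, 2)
      for (ti in 1:2) {
        sub <- lc[lc$clone == cl & lc$timepoint == tps[ti], , drop = FALSE]
        ntot <- nrow(sub)
        if (ntot < min_progeny) next
        x <- sum(sub$lineage == lin)
        fcv[ti] <- (x / ntot) / p0
        pv[ti] <- binom.test(x, ntot, p0)$p.value
      }
      if (anyNA(pv)) next
      res[[length(res) + 1L]] <- data.frame(
        clone = cl, lineage = lin, fc_tp1 = fcv[1], fc_tp2 = fcv[2],
        p_tp1 = pv[1], p_tp2 = pv[2], p_combined = fisher_combine(pv),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) stop("no testable clone-lineage pairs")
  out <- do.call(rbind, res)
  out$q <- storey_qvalue(out$p_combined)
  out$class <- cut(out$q, c(-Inf, 0.01, 0.05, 0.2, Inf),
                   labels = c("***", "**", "*", "none"))
  consistent <- (out$fc_tp1 - 1) * (out$fc_tp2 - 1) > 0
  out$biased <- consistent & out$class != "none"
  out[order(out$p_combined), , drop = FALSE]
}

#' Clone-to-state enrichment
#'
#' Per clone and cell-state subpopulation and timepoint: hypergeometric
#' enrichment p-value and log2 fold change; Fisher-combined p over the two
#' timepoints and Storey q-values. Flagged iff combined p < `p_cut`, FDR <
#' `fdr_cut`, and log2 fold change > `lfc_cut` at both timepoints.
#'
#' @param clone named vector cell -> clone id.
#' @param subpop named vector cell -> subpopulation label.
#' @param timepoint named vector cell -> timepoint.
#' @param p_cut,fdr_cut,lfc_cut flag thresholds (defaults 0.01, 0.05, 0.25).
#' @return data.frame: clone, subpop, k_tp1, k_tp2, log2fc_tp1, log2fc_tp2,
#'   p_tp1, p_tp2, p_combined, q, flagged.
#' @export
clone_state_enrichment <- function(clone, subpop, timepoint,
                                   p_cut = 0.01, fdr_cut = 0.05,
                                   lfc_cut = 0.25) {
  cells <- intersect(intersect(names(clone), names(subpop)), names(timepoint))
  if (!length(cells)) stop("no cells carry all three labels")
  d <- data.frame(clone = clone[cells], subpop = subpop[cells],
                  timepoint = timepoint[cells], stringsAsFactors = FALSE)
  tps <- sort(unique(d$timepoint))[1:2]
  res <- list()
  for (cl in sort(unique(d$clone))) {
    for (sp in sort(unique(d$subpop))) {
      pv <- lfc <- kk <- rep(NA_real_, 2)
      ok <- TRUE
      for (ti in 1:2) {
        dt <- d[d$timepoint == tps[ti], , drop = FALSE]
        N <- nrow(dt)
        m <- sum(dt$subpop == sp)
        ksz <- sum(dt$clone == cl)
        q <- sum(dt$subpop == sp & dt$clone == cl)
        if (m == 0 || ksz == 0) { ok <- FALSE; break }
        pv[ti] <- phyper(q - 1, m, N - m, ksz, lower.tail = FALSE)
        lfc[ti] <- log2((q / ksz) / (m / N))
        kk[ti] <- q
      }
      if (!ok) next
      res[[length(res) + 1L]] <- data.frame(
        clone = cl, subpop = sp, k_tp1 = kk[1], k_tp2 = kk[2],
        log2fc_tp1 = lfc[1], log2fc_tp2 = lfc[2],
        p_tp1 = pv[1], p_tp2 = pv[2], p_combined = fisher_combine(pv),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) stop("no testable clone-subpopulation pairs")
  out <- do.call(rbind, res)
  out$q <- storey_qvalue(out$p_combined)
  out$flagged <- out$p_combined < p_cut & out$q < fdr_cut &
    out$log2fc_tp1 > lfc_cut & out$log2fc_tp2 > lfc_cut
  out[order(out$p_combined), , drop = FALSE]
}

#' Select lineage-informative variants
#'
#' Tests each variant's carrier frequency between every pair of
#' differentiation trajectories with an exact binomial test (carriers in
#' trajectory A among carriers in A+B, against the null proportion
#' `nA / (nA + nB)`). A variant whose pairwise p-values are all > `alpha`
#' is "randomly distributed" and removed; the rest are returned.
#'
#' @param C_bin binary cells x variants matrix.
#' @param trajectory named vector cell -> trajectory (e.g. types mapped
#'   through [default_trajectory_map()]). Trajectories with < 2 cells are
#'   excluded.
#' @param alpha per-test threshold (default 0.05).
#' @return character vector of retained (informative) variant ids.
#' @export
select_lineage_informative <- function(C_bin, trajectory, alpha = 0.05) {
  B <- as_count_matrix(C_bin)
  B@x[] <- 1
  if (ncol(B) == 0) return(character(0))
  cells <- intersect(rownames(B), names(trajectory))
  B <- B[cells, , drop = FALSE]
  traj <- trajectory[cells]
  sizes <- table(traj)
  use <- names(sizes)[sizes >= 2]
  if (length(use) < 2) stop("need at least two trajectories with >= 2 cells")
  carriers <- vapply(use, function(tr)
    Matrix::colSums(B[traj == tr, , drop = FALSE]), numeric(ncol(B)))
  n <- as.numeric(sizes[use])
  pairs <- utils::combn(seq_along(use), 2)
  informative <- rep(FALSE, ncol(B))
  for (pi in seq_len(ncol(pairs))) {
    a <- pairs[1, pi]; b <- pairs[2, pi]
    xa <- carriers[, a]; xb <- carriers[, b]
    tot <- xa + xb
    p0 <- n[a] / (n[a] + n[b])
    idx <- which(tot > 0 & !informative)
    for (j in idx) {
      p <- binom.test(xa[j], tot[j], p = p0)$p.value
      if (p <= alpha) informative[j] <- TRUE
    }
  }
  colnames(B)[informative]
}

#' Cell-type origins from mtDNA-mutation KNN neighbourhoods
#'
#' Builds the weighted-Jaccard KNN neighbourhood of every cell (over
#' lineage-informative variants) and computes, per query cell type, the mean
#' proportion of each target cell type among its cells' neighbours. Rows are
#' optionally z-scaled, and query types are ordered by hierarchical
#' clustering of their target profiles.
#'
#' @param C_bin binary cells x variants matrix (informative variants).
#' @param cell_types named vector cell -> type.
#' @param k neighbourhood size (default 30; reduced with a message when
#'   fewer than `k + 1` cells are available).
#' @param priors variant priors for the distance (default all 1).
#' @param scale_rows z-scale each query row (default TRUE).
#' @return list with `proportions` (query x target, unscaled; rows sum to 1),
#'   `scaled`, `order` (hclust order of query types), `k`.
#' @export
celltype_origin_knn <- function(C_bin, cell_types, k = 30L, priors = NULL,
                                scale_rows = TRUE) {
  B <- as_count_matrix(C_bin)
  cells <- intersect(rownames(B), names(cell_types))
  B <- B[cells, , drop = FALSE]
  n <- nrow(B)
  if (k >= n) {
    message(sprintf("k reduced from %d to %d (only %d cells)", k, n - 1L, n))
    k <- n - 1L
  }
  D <- weighted_jaccard(B, priors)
  types <- factor(cell_types[cells])
  prop <- matrix(0, nlevels(types), nlevels(types),
                 dimnames = list(levels(types), levels(types)))
  nn_types <- matrix(NA_integer_, n, k)
  for (i in seq_len(n)) {
    o <- order(D[i, ])[-1][seq_len(k)]    # nearest excluding self
    nn_types[i, ] <- as.integer(types[o])
  }
  for (q in seq_len(nlevels(types))) {
    rows <- which(as.integer(types) == q)
    tab <- tabulate(nn_types[rows, , drop = FALSE], nbins = nlevels(types))
    prop[q, ] <- tab / sum(tab)
  }
  scaled <- if (scale_rows && nlevels(types) > 1) t(scale(t(prop))) else prop
  ord <- if (nlevels(types) > 2)
    hclust(dist(prop))$order else seq_len(nlevels(types))
  list(proportions = prop, scaled = scaled, order = ord, k = k)
}

#' Correlation of clonal output with lineage bias
#'
#' Per lineage, regresses z-scaled clonal output (mean over timepoints) on
#' z-scaled lineage fold change (mean over timepoints) across clones,
#' reporting Pearson r, the regression slope, its Wald p-value, and 95%
#' prediction-band endpoints at the observed bias values.
#'
#' @param output `mtl_output` from [clonal_output()].
#' @param bias bias table from [lineage_bias()].
#' @return data.frame per lineage: lineage, n, r, slope, p_wald, flagged
#'   (TRUE when variance is zero and the fit is undefined); attribute
#'   `"bands"` holds per-lineage prediction bands.
#' @export
output_bias_correlation <- function(output, bias) {
  act <- output$activity
  out_mean <- tapply(act$output, act$clone, mean)
  res <- list(); bands <- list()
  for (lin in sort(unique(bias$lineage))) {
    b <- bias[bias$lineage == lin, , drop = FALSE]
    common <- intersect(b$clone, names(out_mean))
    if (length(common) < 3) next
    x <- rowMeans(cbind(b$fc_tp1, b$fc_tp2))[match(common, b$clone)]
    y <- as.numeric(out_mean[common])
    if (sd(x) == 0 || sd(y) == 0) {
      res[[lin]] <- data.frame(lineage = lin, n = length(common), r = NA_real_,
                               slope = NA_real_, p_wald = NA_real_, flagged = TRUE)
      next
    }
    xs <- as.numeric(scale(x)); ys <- as.numeric(scale(y))
    fit <- lm(ys ~ xs)
    sm <- suppressWarnings(summary(fit))
    ## prediction interval evaluated at the fitted bias values
    band <- suppressWarnings(predict(fit, interval = "prediction", level = 0.95))
    res[[lin]] <- data.frame(lineage = lin, n = length(common),
                             r = cor(xs, ys), slope = coef(fit)[2],
                             p_wald = sm$coefficients[2, 4], flagged = FALSE)
    bands[[lin]] <- data.frame(clone = common, x = xs, fit = band[, "fit"],
                               lwr = band[, "lwr"], upr = band[, "upr"])
  }
  if (!length(res)) stop("fewer than 3 clones shared between output and bias tables")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "bands") <- bands
  out
}

#' Match clonal groups across timepoints by defining variants
#'
#' Two clones match when the Jaccard similarity of their defining-variant
#' sets is at least `min_jaccard`; matches are greedy on decreasing
#' similarity, each clone used once (a symmetric, idempotent rule).
#'
#' @param clones_a,clones_b `mtl_clones` objects (or named lists of
#'   defining-variant sets).
#' @param min_jaccard similarity threshold (default 0.5).
#' @return data.frame: clone_a, clone_b, jaccard.
#' @export
match_clones <- function(clones_a, clones_b, min_jaccard = 0.5) {
  va <- if (inherits(clones_a, "mtl_clones")) clones_a$defining_variants else clones_a
  vb <- if (inherits(clones_b, "mtl_clones")) clones_b$defining_variants else clones_b
  if (!length(va) || !length(vb))
    return(data.frame(clone_a = character(0), clone_b = character(0),
                      jaccard = numeric(0)))
  sim <- outer(seq_along(va), seq_along(vb), Vectorize(function(i, j) {
    u <- union(va[[i]], vb[[j]])
    if (!length(u)) return(0)
    length(intersect(va[[i]], vb[[j]])) / length(u)
  }))
  pairs <- which(sim >= min_jaccard, arr.ind = TRUE)
  if (!nrow(pairs))
    return(data.frame(clone_a = character(0), clone_b = character(0),
                      jaccard = numeric(0)))
  ord <- order(-sim[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  used_a <- used_b <- logical(0)
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    if (!(a %in% used_a) && !(b %in% used_b)) {
      keep[i] <- TRUE; used_a <- c(used_a, a); used_b <- c(used_b, b)
    }
  }
  pairs <- pairs[keep, , drop = FALSE]
  data.frame(clone_a = names(va)[pairs[, 1]], clone_b = names(vb)[pairs[, 2]],
             jaccard = sim[pairs], stringsAsFactors = FALSE)
}
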