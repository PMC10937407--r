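# Build a synthetic assignment + state table with known structure.
make_cohort <- function(n_clones = 10, hsc_per_clone = 10, prog_per_clone = 50,
                        lineage_probs = NULL, seed = 1) {
  set.seed(seed)
  lmap <- default_lineage_map()
  lineages <- unique(unname(lmap))
  if (is.null(lineage_probs))
    lineage_probs <- matrix(1 / length(lineages), n_clones, length(lineages),
                            dimnames = list(NULL, lineages))
  rows <- list()
  for (k in seq_len(n_clones)) {
    cl <- sprintf("clone%03d", k)
    for (i in seq_len(hsc_per_clone))
      rows[[length(rows) + 1L]] <- data.frame(
        cell = sprintf("%s_h%d", cl, i), clone = cl, cell_type = "HSC",
        lineage = NA_character_, is_hsc = TRUE,
        timepoint = sample(1:2, 1), stringsAsFactors = FALSE)
    for (i in seq_len(prog_per_clone)) {
      lin <- sample(lineages, 1, prob = lineage_probs[k, ])
      typ <- sample(names(lmap)[lmap == lin], 1)
      rows[[length(rows) + 1L]] <- data.frame(
        cell = sprintf("%s_p%d", cl, i), clone = cl, cell_type = typ,
        lineage = lin, is_hsc = FALSE, timepoint = sample(1:2, 1),
        stringsAsFactors = FALSE)
    }
  }
  st <- do.call(rbind, rows)
  asg <- data.frame(cell = st$cell, clone = st$clone, max_prob = 1,
                    assigned = TRUE, stringsAsFactors = FALSE)
  list(states = st, assignments = asg)
}

test_that("clonal output normalizes progeny by clone size", {
  co <- make_cohort(n_clones = 1, hsc_per_clone = 10, prog_per_clone = 50)
  out <- clonal_output(co$assignments, co$states,
                       clone_sizes = c(clone001 = 10))
  expect_equal(sum(out$activity$progeny), 50)
  per_tp <- tapply(out$activity$progeny, out$activity$timepoint, sum)
  expect_equal(out$activity$output, out$activity$progeny / 10)
  # cumulative curve runs from 0 to 1
  for (cc in out$cumulative) {
    expect_equal(cc$cumulative[1], 0)
    expect_equal(cc$cumulative[nrow(cc)], 1)
    expect_true(all(diff(cc$cumulative) >= 0))
  }
})

test_that("equal clone outputs give decile fold change 1", {
  co <- make_cohort(n_clones = 8)
  # force perfectly equal outputs: same count per clone and timepoint
  st <- co$states
  asg <- co$assignments
  out <- clonal_output(asg, st, clone_sizes = setNames(
    rep(10, 8), sprintf("clone%03d", 1:8)))
  act <- out$activity
  act$output <- 5  # constant by construction of the check
  out2 <- out; out2$activity <- act
  expect_equal(clonal_output(asg[0, ], st, clone_sizes = c(x = 1))$pearson_r,
               NA_real_)
  # the decile rule itself: constant vector -> fc 1
  expect_equal(local({
    cnt <- act
    dec <- quantile(cnt$output, c(.1, .9))
    top <- mean(cnt$output[cnt$output >= dec[2]])
    bot <- mean(cnt$output[cnt$output <= dec[1]])
    top / bot
  }), 1)
})

test_that("lineage bias reproduces the exact binomial and Fisher oracles", {
  # Fisher combination worked example
  expect_equal(fisher_combine(c(0.05, 0.05)),
               pchisq(-2 * (log(0.05) + log(0.05)), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(fisher_combine(c(0.05, 0.05)), 0.0175, tolerance = 1e-2)
  # clone with 30 myeloid of 100 progeny against background 0.10
  lmap <- default_lineage_map()
  mye_types <- names(lmap)[lmap == "myeloid"]
  st <- do.call(rbind, lapply(1:2, function(tp) {
    data.frame(cell = sprintf("t%d_c%d", tp, 1:1000),
               clone = rep(c("cloneA", "cloneB"), c(100, 900)),
               cell_type = "x", lineage = "x", is_hsc = FALSE, timepoint = tp)
  }))
  # cloneA: 30/100 myeloid; cloneB tuned so background myeloid = 10%
  for (tp in 1:2) {
    i_a <- which(st$clone == "cloneA" & st$timepoint == tp)
    i_b <- which(st$clone == "cloneB" & st$timepoint == tp)
    st$cell_type[i_a] <- rep(c(mye_types[1], "CD4"), c(30, 70))
    st$cell_type[i_b] <- rep(c(mye_types[1], "CD4"), c(70, 830))
    st$lineage[i_a] <- unname(lmap[st$cell_type[i_a]])
    st$lineage[i_b] <- unname(lmap[st$cell_type[i_b]])
  }
  asg <- data.frame(cell = st$cell, clone = st$clone, assigned = TRUE)
  bias <- lineage_bias(asg, st)
  row <- bias[bias$clone == "cloneA" & bias$lineage == "myeloid", ]
  expect_equal(row$fc_tp1, 3.0, tolerance = 1e-12)
  expect_equal(row$p_tp1, pbinom(29, 100, 0.1, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(row$p_combined, fisher_combine(c(row$p_tp1, row$p_tp2)),
               tolerance = 1e-12)
  expect_true(row$biased)
  # background-matching clone is not biased
  rowb <- bias[bias$clone == "cloneB" & bias$lineage == "myeloid", ]
  expect_lt(abs(rowb$fc_tp1 - 1), 0.25)
})

test_that("bias flags require direction agreement at both timepoints", {
  lmap <- default_lineage_map()
  st <- do.call(rbind, lapply(1:2, function(tp) {
    up <- tp == 1
    data.frame(cell = sprintf("t%d_c%d", tp, 1:400),
               clone = rep(c("cloneA", "cloneB"), c(200, 200)),
               # cloneA: myeloid-heavy at tp1, lymphoid-heavy at tp2;
               # cloneB balanced at both
               cell_type = c(rep(if (up) "Mono" else "CD4", 150),
                             rep(if (up) "CD4" else "Mono", 50),
                             rep(c("Mono", "CD4"), 100)),
               lineage = NA, is_hsc = FALSE, timepoint = tp)
  }))
  st$lineage <- unname(lmap[st$cell_type])
  asg <- data.frame(cell = st$cell, clone = st$clone, assigned = TRUE)
  bias <- lineage_bias(asg, st)
  rowa <- bias[bias$clone == "cloneA" & bias$lineage == "myeloid", ]
  # cloneA flips direction between timepoints: never biased
  expect_true((rowa$fc_tp1 - 1) * (rowa$fc_tp2 - 1) < 0)
  expect_false(rowa$biased)
})

test_that("clone-state enrichment matches the exact hypergeometric tail", {
  # 40-cell clone entirely inside a subpopulation holding 10% of cells
  set.seed(71)
  n <- 1000
  mk_tp <- function(tp) {
    clone <- setNames(rep(c("cA", "cB"), c(40, n - 40)),
                      sprintf("t%d_c%d", tp, 1:n))
    sub <- setNames(rep("other", n), names(clone))
    sub[1:40] <- "S"                       # all of cA
    sub[41:100] <- "S"                     # 60 more: |S| = 100 = 10%
    tpv <- setNames(rep(tp, n), names(clone))
    list(clone = clone, sub = sub, tp = tpv)
  }
  a <- mk_tp(1); b <- mk_tp(2)
  enr <- clone_state_enrichment(c(a$clone, b$clone), c(a$sub, b$sub),
                                c(a$tp, b$tp))
  row <- enr[enr$clone == "cA" & enr$subpop == "S", ]
  expect_equal(row$p_tp1, phyper(39, 100, 900, 40, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(row$log2fc_tp1, log2((40 / 40) / (100 / 1000)), tolerance = 1e-12)
  expect_true(row$flagged)
  # proportional clone is not flagged
  rowb <- enr[enr$clone == "cB" & enr$subpop == "S", ]
  expect_false(rowb$flagged)
})

test_that("single-timepoint enrichment is not flagged", {
  set.seed(72)
  n <- 500
  clone <- setNames(rep(c("cA", "cB"), c(40, n - 40)), sprintf("t1_c%d", 1:n))
  sub <- setNames(sample(c("S", "other"), n, TRUE, c(0.1, 0.9)), names(clone))
  sub[1:40] <- "S"   # enriched at tp1 only
  clone2 <- setNames(rep(c("cA", "cB"), c(40, n - 40)), sprintf("t2_c%d", 1:n))
  sub2 <- setNames(sample(c("S", "other"), n, TRUE, c(0.1, 0.9)), names(clone2))
  tp <- c(setNames(rep(1, n), names(clone)), setNames(rep(2, n), names(clone2)))
  enr <- clone_state_enrichment(c(clone, clone2), c(sub, sub2), tp)
  row <- enr[enr$clone == "cA" & enr$subpop == "S", ]
  expect_false(row$flagged)
})

test_that("lineage-informative selection keeps skewed, removes uniform variants", {
  set.seed(73)
  traj <- setNames(rep(c("myeloid", "erythroid"), each = 150),
                   sprintf("c%03d", 1:300))
  # 50 null variants at equal frequency; 1 erythroid-exclusive variant
  profiles <- lapply(seq_len(300), function(i) {
    v <- paste0("null", which(runif(50) < 0.2))
    if (i > 270) v <- c(v, "ery_only")     # 30 of 300, all erythroid
    v
  })
  names(profiles) <- names(traj)
  B <- make_cbin(profiles, c(paste0("null", 1:50), "ery_only"))
  kept <- select_lineage_informative(B, traj)
  expect_true("ery_only" %in% kept)
  null_kept <- sum(grepl("^null", kept))
  expect_lt(null_kept / 50, 0.2)           # most uniform variants removed
  # exclusive variant has an extreme exact p
  expect_lt(binom.test(0, 30, 0.5)$p.value, 1e-8)
  expect_equal(select_lineage_informative(B[, 0], traj), character(0))
})

test_that("origin KNN profiles are proportions with self-affinity", {
  tr <- small_truth(seed = 74, n_clones = 2, cells_per_clone = 25, mu = 0.03)
  B <- binarize(truth_variant_matrix(tr, capture_rate = 1))
  types <- setNames(ifelse(tr$clone == "clone001", "T1", "T2"),
                    names(tr$clone))
  res <- celltype_origin_knn(B, types, k = 10)
  expect_equal(unname(rowSums(res$proportions)), c(1, 1), tolerance = 1e-12)
  expect_gt(res$proportions["T1", "T1"], 0.9)
  expect_gt(res$proportions["T2", "T2"], 0.9)
  # single cell type: one row, all mass on itself
  res1 <- celltype_origin_knn(B, setNames(rep("only", length(types)),
                                          names(types)), k = 10)
  expect_equal(dim(res1$proportions), c(1, 1))
  expect_equal(res1$proportions[1, 1], 1)
})

test_that("output-bias correlation recovers exact and degenerate relations", {
  act <- data.frame(clone = sprintf("c%d", 1:10), timepoint = 1,
                    progeny = 1:10, clone_size = 1, output = seq(2, 20, 2))
  out <- structure(list(activity = act), class = "mtl_output")
  bias <- data.frame(clone = sprintf("c%d", 1:10), lineage = "myeloid",
                     fc_tp1 = seq(0.5, 5, 0.5), fc_tp2 = seq(0.5, 5, 0.5))
  res <- output_bias_correlation(out, bias)
  expect_equal(res$r, 1, tolerance = 1e-9)
  expect_lt(res$p_wald, 1e-9)
  # constant bias: flagged undefined
  bias2 <- bias; bias2$fc_tp1 <- bias2$fc_tp2 <- 1
  res2 <- output_bias_correlation(out, bias2)
  expect_true(res2$flagged)
  expect_true(is.na(res2$r))
})

test_that("clone matching is symmetric and idempotent", {
  a <- list(c1 = c("v1", "v2", "v3"), c2 = c("v9"))
  b <- list(k1 = c("v1", "v2"), k2 = c("v7", "v8"))
  m_ab <- match_clones(a, b)
  m_ba <- match_clones(b, a)
  expect_equal(m_ab$jaccard, m_ba$jaccard)
  expect_equal(m_ab$clone_a, m_ba$clone_b)
  expect_equal(match_clones(a, a)$clone_a, match_clones(a, a)$clone_b)
  expect_equal(match_clones(a, a)$jaccard, c(1, 1))
})
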