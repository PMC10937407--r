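ref_string <- function(L = 2000, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

test_that("reads partition by the exact eUMI key", {
  rd <- make_reads(list(
    list(cell = "CB1", start = 1001, end = 1180, n = 2),
    list(cell = "CB1", start = 1001, end = 1181, n = 1),
    list(cell = "CB2", start = 1001, end = 1180, n = 3)))
  g <- group_eumis(rd)
  expect_equal(nrow(g$groups), 3)
  expect_setequal(g$groups$size, c(2, 1, 3))
  # reads differing only in frag_end are separate groups
  expect_equal(sum(g$groups$cell == "CB1"), 2)
})

test_that("malformed coordinates are flagged per record, not fatal", {
  rd <- make_reads(list(list(cell = "CB1", start = 100, end = 300, n = 2)))
  rd2 <- rbind(rd, data.frame(cell = "CB9", start = 500, end = 400,
                              mate = "plus", mismatches = "", molecule_id = "mx",
                              sample = "s1"))
  expect_warning(g <- group_eumis(rd2), "malformed")
  expect_equal(g$n_malformed, 1)
  expect_equal(nrow(g$groups), 1)
})

test_that("consensus scores and rejections follow the group-size rules", {
  # 4 reads all carrying the alt: score 1.0
  g1 <- make_reads(list(list(cell = "C", start = 3000, end = 3400, n = 4,
                             alt = c("3243" = "G"))))
  m1 <- call_consensus(g1)
  expect_equal(m1$calls$score, 1.0)
  expect_equal(m1$calls$pos, 3243)
  # 3 of 4 reads carry the alt: score 0.75 retained at threshold 0.75
  g2 <- make_reads(list(list(cell = "C", start = 3000, end = 3400, n = 4,
                             alt = c("3243" = "G"), n_alt = 3)))
  m2 <- call_consensus(g2, filter_config(require_strand_agreement = FALSE))
  expect_equal(m2$calls$score, 0.75)
  # above the threshold the 0.75-majority molecule is ambiguous -> rejected
  m2b <- call_consensus(g2, filter_config(consensus_threshold = 0.8,
                                          require_strand_agreement = FALSE))
  expect_null(m2b)
  # size-1 group rejected at min_group_size 2
  g3 <- make_reads(list(list(cell = "C", start = 10, end = 200, n = 1)))
  expect_null(call_consensus(g3))
})

test_that("strand agreement requires support on both mates", {
  # 4 reads (2 plus, 2 minus); alt on the two plus reads only
  rd <- data.frame(cell = "C", start = 100, end = 300,
                   mate = c("plus", "minus", "plus", "minus"),
                   mismatches = c("150:T", "", "150:T", ""),
                   molecule_id = "m1", sample = "s1")
  cm <- consensus_molecules(group_eumis(rd),
                            filter_config(consensus_threshold = 0.5))
  expect_equal(nrow(cm$calls), 0)
  cm2 <- consensus_molecules(group_eumis(rd),
                             filter_config(consensus_threshold = 0.5,
                                           require_strand_agreement = FALSE))
  expect_equal(nrow(cm2$calls), 0)  # score 0.5 fails the majority rule
  rd$mismatches <- c("150:T", "150:T", "150:T", "")
  cm3 <- consensus_molecules(group_eumis(rd), filter_config())
  expect_equal(cm3$calls$score, 0.75)
})

test_that("variant filters: blacklist, germline, min cells", {
  ref <- ref_string()
  refv <- strsplit(ref, "")[[1]]
  alt_at <- function(p) setdiff(c("A", "C", "G", "T"), refv[p])[1]
  mk <- function(cell, p, id) list(cell = cell, start = p - 50, end = p + 50,
                                   n = 3, alt = setNames(alt_at(p), p))
  # variant at blacklisted position 310; shared variant at 1500 in 3 cells;
  # germline-like variant at 1600 in all cells at het 1
  gr <- c(lapply(c("c1", "c2"), function(cc) mk(cc, 310)),
          lapply(c("c1", "c2", "c3"), function(cc) mk(cc, 1500)),
          lapply(c("c1", "c2", "c3"), function(cc) mk(cc, 1600)),
          # reference molecules covering 1500 so it is subclonal, not germline
          lapply(c("c4", "c5"), function(cc)
            list(cell = cc, start = 1450, end = 1550, n = 3)))
  cm <- consensus_molecules(group_eumis(make_reads(gr)), filter_config())
  vc <- call_variants(cm, ref, filter_config())
  expect_false(any(vc$variants$pos == 310))   # blacklist
  expect_false(any(vc$variants$pos == 1600))  # germline: all cells, het 1
  expect_true(any(vc$variants$pos == 1500))
  # min_cells_per_variant: raise to 4 and the 3-cell variant disappears
  vc2 <- call_variants(cm, ref, filter_config(min_cells_per_variant = 4))
  expect_false(any(vc2$variants$pos == 1500))
})

test_that("zero-error full-capture calls equal the molecule-level truth", {
  cfg <- sim_config(n_clones = 3, cells_per_clone = 6, mu = 0.05,
                    capture_rate = 1, seq_error_rate = 0, seed = 21)
  tr <- simulate_lineage(cfg)
  rd <- simulate_reads(tr)
  mt <- attr(rd, "molecule_truth")
  g <- group_eumis(rd)
  # germline removal effectively off at frac = het = 1 for subclonal truth
  fc <- filter_config(min_cells_per_variant = 1, germline_cell_frac = 1,
                      germline_het = 1, blacklist = integer(0))
  cm <- consensus_molecules(g, fc)
  vc <- call_variants(cm, paste(tr$reference, collapse = ""), fc)
  # truth restricted to molecules in retained (size >= 2) groups
  mt_kept <- mt[mt$size >= 2, ]
  truth_pairs <- unique(paste(mt_kept$cell, mt_kept$pos, mt_kept$alt))
  called <- Matrix::which(vc$C > 0, arr.ind = TRUE)
  called_pairs <- paste(rownames(vc$C)[called[, 1]],
                        vc$variants$pos[called[, 2]],
                        vc$variants$alt[called[, 2]])
  expect_true(all(called_pairs %in% truth_pairs))   # zero false positives
  expect_setequal(called_pairs, truth_pairs)        # full recall
})

test_that("stricter consensus settings never add variants", {
  cfg <- sim_config(n_clones = 3, cells_per_clone = 8, mu = 0.05,
                    capture_rate = 0.6, seq_error_rate = 2e-3, seed = 22)
  tr <- simulate_lineage(cfg)
  g <- group_eumis(simulate_reads(tr))
  ref <- paste(tr$reference, collapse = "")
  nvar <- function(fc) nrow(call_variants(consensus_molecules(g, fc), ref, fc)$variants)
  base <- filter_config(min_cells_per_variant = 1)
  expect_gte(nvar(base),
             nvar(filter_config(min_cells_per_variant = 1, min_group_size = 3)))
  expect_gte(nvar(base),
             nvar(filter_config(min_cells_per_variant = 1, consensus_threshold = 1.0)))
  expect_gte(nvar(base), nvar(filter_config(min_cells_per_variant = 1,
                                            preset = "specific")))
})

test_that("coverage is total fragment length over genome length", {
  L <- 1000
  rd <- make_reads(list(list(cell = "c1", start = 1, end = 1000, n = 2),
                        list(cell = "c2", start = 1, end = 500, n = 2),
                        list(cell = "c2", start = 501, end = 1000, n = 2)))
  cm <- consensus_molecules(group_eumis(rd))
  cov <- compute_coverage(cm, L)
  expect_equal(cov$coverage[cov$cell == "c1"], 1.0)
  expect_equal(cov$coverage[cov$cell == "c2"], 1.0)
  cov2 <- compute_coverage(cm, L, cells = c("c1", "c2", "c3"))
  expect_equal(cov2$coverage[cov2$cell == "c3"], 0)
  expect_true(cov2$flagged[cov2$cell == "c3"])
})

test_that("burden follows the normalization formula", {
  b <- compute_burden(c(cellA = 5), c(s1 = 1), c(cellA = 1))
  expect_equal(b$burden, 5)
  b2 <- compute_burden(c(cellA = 9), c(s1 = 0.6), c(cellA = 30))
  expect_equal(b2$burden, 0.5, tolerance = 1e-12)
  b3 <- compute_burden(c(cellA = 0), c(s1 = 0.8), c(cellA = 10))
  expect_equal(b3$burden, 0)
  expect_error(compute_burden(c(cellA = 1), c(s1 = 0), c(cellA = 1)), "rate")
  expect_warning(compute_burden(c(cellA = 1, cellB = 2), c(s1 = 1),
                                c(cellA = 1, cellB = 0)), "zero coverage")
})

test_that("burden is invariant to duplicating every molecule", {
  rd <- make_reads(list(
    list(cell = "c1", start = 100, end = 400, n = 3, alt = c("200" = "A")),
    list(cell = "c1", start = 500, end = 800, n = 3),
    list(cell = "c2", start = 100, end = 400, n = 3, alt = c("200" = "A"))))
  # same molecules re-observed at shifted keys (same fragment lengths)
  dup <- rd; dup$start <- dup$start + 1; dup$end <- dup$end + 1
  rd2 <- rbind(rd, dup)
  fc <- filter_config(min_cells_per_variant = 1, blacklist = integer(0))
  ref <- ref_string()
  refv <- strsplit(ref, "")[[1]]
  if (refv[200] == "A") { substr(ref, 200, 200) <- "C"; refv[200] <- "C" }
  run <- function(r) {
    cm <- consensus_molecules(group_eumis(r), fc)
    vc <- call_variants(cm, ref, fc)
    cov <- compute_coverage(cm, 2000)
    nm <- setNames(as.numeric(Matrix::rowSums(vc$C > 0)), rownames(vc$C))
    compute_burden(nm, cm$eumi_filter_rate, cov)
  }
  b1 <- run(rd); b2 <- run(rd2)
  expect_equal(b2$coverage, 2 * b1$coverage)
  expect_equal(b2$burden, b1$burden / 2 * 1)  # same mutations, doubled coverage
  expect_equal(b1$n_mutations, b2$n_mutations)
})

test_that("signature classes conserve counts and follow the strand convention", {
  ref <- "ACGTACGTAC"
  v <- data.frame(variant = c("2_C_T", "3_G_A"), pos = c(2L, 3L),
                  ref = c("C", "G"), alt = c("T", "A"))
  sig <- mutation_signature(v, ref)
  expect_equal(sum(sig$count), 2)
  # C>T with pyrimidine ref on the reference (light) strand
  expect_true(any(sig$strand == "L" & sig$substitution == "C>T" &
                  sig$context == "A[C>T]G"))
  # G>A is reported as C>T on the heavy strand, context reverse-complemented
  expect_true(any(sig$strand == "H" & sig$substitution == "C>T" &
                  sig$context == "A[C>T]G"))
  expect_error(mutation_signature(data.frame(variant = "2_G_A", pos = 2L,
                                             ref = "G", alt = "A"), ref),
               "mismatch")
})

test_that("uniform substitutions give context-proportional class frequencies", {
  set.seed(31)
  L <- 6000
  refv <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  pos <- sample(L, 3000, replace = TRUE)
  alt <- vapply(pos, function(p) sample(setdiff(c("A", "C", "G", "T"), refv[p]), 1), "")
  v <- data.frame(variant = paste0(pos, "_", refv[pos], "_", alt),
                  pos = pos, ref = refv[pos], alt = alt)
  sig <- mutation_signature(v, paste(refv, collapse = ""))
  expect_equal(sum(sig$count), nrow(v))
  # mononucleotide classes: pyrimidine-strand substitution frequencies are
  # uniform over the 6 substitution types within each strand (by symmetry)
  mono <- tapply(sig$count, sig$substitution, sum)
  expect_equal(as.numeric(mono) / sum(mono), rep(1 / 6, 6), tolerance = 0.15)
})
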