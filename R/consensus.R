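## Endogenous-UMI grouping, single-molecule consensus error correction, and
## multistep variant/cell filtering. The eUMI of a molecule is the exact
## (cell barcode, fragment start, fragment end) triple; reads sharing it are
## treated as redundant observations of one mtDNA molecule.

#' Variant filtering configuration
#'
#' Numeric defaults reflect the intent of stringent multistep filtering and
#' known mtDNA artefact regions; they are exposed here precisely because they
#' are tunable. The `specific` preset raises `min_group_size` to 3 and
#' requires unanimous read support.
#'
#' @param min_group_size minimum reads per eUMI group (default 2).
#' @param consensus_threshold minimum fraction of reads supporting a non-
#'   reference consensus base (default 0.75).
#' @param require_strand_agreement require support on both mates when a group
#'   contains both orientations (default TRUE).
#' @param blacklist positions excluded from calling (defaults to the
#'   homopolymeric artefact tracts 300-316 and 3106-3110).
#' @param germline_cell_frac,germline_het a variant carried at mean
#'   heteroplasmy >= `germline_het` by >= `germline_cell_frac` of covered
#'   cells is removed as germline/haplogroup.
#' @param min_cells_per_variant minimum carrier cells (default 2).
#' @param min_molecules_per_cellvariant minimum supporting consensus
#'   molecules per cell-variant entry (default 1).
#' @param preset `"sensitive"` (the defaults) or `"specific"`.
#' @return object of class `mtl_filter_config`.
#' @export
filter_config <- function(min_group_size = 2L, consensus_threshold = 0.75,
                          require_strand_agreement = TRUE,
                          blacklist = c(300:316, 3106:3110),
                          germline_cell_frac = 0.9, germline_het = 0.9,
                          min_cells_per_variant = 2L,
                          min_molecules_per_cellvariant = 1L,
                          preset = c("sensitive", "specific")) {
  preset <- match.arg(preset)
  if (preset == "specific") {
    min_group_size <- max(min_group_size, 3L)
    consensus_threshold <- 1.0
  }
  stopifnot_pos_int(min_group_size, "min_group_size")
  stopifnot_prob(consensus_threshold, "consensus_threshold")
  stopifnot_prob(germline_cell_frac, "germline_cell_frac")
  stopifnot_prob(germline_het, "germline_het")
  stopifnot_pos_int(min_cells_per_variant, "min_cells_per_variant")
  stopifnot_pos_int(min_molecules_per_cellvariant, "min_molecules_per_cellvariant")
  structure(list(min_group_size = as.integer(min_group_size),
                 consensus_threshold = consensus_threshold,
                 require_strand_agreement = isTRUE(require_strand_agreement),
                 blacklist = as.integer(blacklist),
                 germline_cell_frac = germline_cell_frac,
                 germline_het = germline_het,
                 min_cells_per_variant = as.integer(min_cells_per_variant),
                 min_molecules_per_cellvariant = as.integer(min_molecules_per_cellvariant),
                 preset = preset), class = "mtl_filter_config")
}

#' Group reads by endogenous UMI
#'
#' Partitions a read table by the exact (cell, fragment start, fragment end)
#' key. Records with malformed coordinates (non-finite, start > end, start
#' < 1) are flagged and excluded with a warning, not fatal.
#'
#' @param reads data.frame with columns cell, start, end, mate, mismatches
#'   and optionally molecule_id, sample.
#' @return object of class `mtl_eumi_groups`: list with `groups` (group_id,
#'   cell, start, end, sample, size) and `reads` (input rows annotated with
#'   group_id), plus `n_malformed`.
#' @export
group_eumis <- function(reads) {
  stopifnot(all(c("cell", "start", "end") %in% names(reads)))
  bad <- !is.finite(reads$start) | !is.finite(reads$end) |
    reads$start > reads$end | reads$start < 1
  if (any(bad)) {
    warning(sprintf("%d read(s) with malformed coordinates excluded", sum(bad)))
    reads <- reads[!bad, , drop = FALSE]
  }
  if (is.null(reads$sample)) reads$sample <- "s1"
  key <- paste(reads$cell, reads$start, reads$end, sep = "\r")
  gid <- match(key, unique(key))
  reads$group_id <- gid
  first <- !duplicated(gid)
  groups <- data.frame(group_id = gid[first], cell = reads$cell[first],
                       start = reads$start[first], end = reads$end[first],
                       sample = reads$sample[first],
                       size = as.integer(tabulate(gid)[gid[first]]),
                       stringsAsFactors = FALSE)
  structure(list(groups = groups[order(groups$group_id), , drop = FALSE],
                 reads = reads, n_malformed = sum(bad)),
            class = "mtl_eumi_groups")
}

#' @export
print.mtl_eumi_groups <- function(x, ...) {
  cat(sprintf("eUMI groups: %d groups from %d reads (mean size %.2f)\n",
              nrow(x$groups), nrow(x$reads), mean(x$groups$size)))
  invisible(x)
}

#' eUMI collision rate from truth molecule ids
#'
#' Fraction of groups whose reads come from more than one distinct true
#' molecule. Requires a `molecule_id` column (simulated data).
#' @param groups `mtl_eumi_groups`.
#' @return collision rate in \[0, 1\].
#' @export
eumi_collision_rate <- function(groups) {
  stopifnot(inherits(groups, "mtl_eumi_groups"))
  if (is.null(groups$reads$molecule_id))
    stop("molecule_id column required to estimate collisions")
  nd <- tapply(groups$reads$molecule_id, groups$reads$group_id,
               function(m) length(unique(m)))
  mean(nd > 1)
}

#' Consensus-call all eUMI groups
#'
#' Vectorized single-molecule consensus over every group. Returns the
#' retained consensus molecules (one per surviving group) and their
#' non-reference consensus calls. A group is rejected by the size filter
#' (`size < min_group_size`) or by the consensus filter (some base has
#' majority support but falls below the consensus threshold: an ambiguous
#' molecule). Strand agreement is enforced only for groups containing both
#' read orientations.
#'
#' @param groups `mtl_eumi_groups` from [group_eumis()].
#' @param config `mtl_filter_config`.
#' @return object of class `mtl_molecules`: list with `molecules` (retained
#'   groups), `calls` (group_id, pos, alt, score), per-sample
#'   `eumi_filter_rate` (passing groups / all groups), and rejection counts.
#' @export
consensus_molecules <- function(groups, config = filter_config()) {
  stopifnot(inherits(groups, "mtl_eumi_groups"),
            inherits(config, "mtl_filter_config"))
  g <- groups$groups
  reads <- groups$reads
  keep_size <- g$size >= config$min_group_size
  kept_ids <- g$group_id[keep_size]
  r <- reads[reads$group_id %in% kept_ids, , drop = FALSE]

  mm <- r$mismatches
  nmm <- ifelse(is.na(mm) | mm == "", 0L,
                lengths(regmatches(mm, gregexpr(";", mm))) + 1L)
  has <- nmm > 0L
  calls <- NULL
  rejected_consensus <- integer(0)
  if (any(has)) {
    parts <- strsplit(mm[has], ";", fixed = TRUE)
    ri <- rep.int(which(has), lengths(parts))
    tok <- unlist(parts, use.names = FALSE)
    pos <- as.integer(sub(":.*", "", tok))
    alt <- sub(".*:", "", tok)
    df <- data.frame(group_id = r$group_id[ri], pos = pos, alt = alt,
                     mate = r$mate[ri], stringsAsFactors = FALSE)
    key <- paste(df$group_id, df$pos, df$alt, sep = "\r")
    sup <- as.integer(rowsum(rep(1L, nrow(df)), key, reorder = FALSE))
    first <- !duplicated(key)
    agg <- df[first, c("group_id", "pos", "alt")]
    agg$support <- sup[match(key[first], key[first])]
    agg$size <- g$size[match(agg$group_id, g$group_id)]
    agg$score <- agg$support / agg$size
    ## strand agreement
    if (config$require_strand_agreement && !is.null(r$mate)) {
      both_grp <- tapply(r$mate, r$group_id, function(m) length(unique(m)) > 1)
      pl <- rowsum((df$mate == "plus") + 0, key, reorder = FALSE)[match(key[first], key[first])]
      mi <- agg$support - pl
      need <- both_grp[as.character(agg$group_id)]
      agg$strand_ok <- !need | (pl > 0 & mi > 0)
    } else agg$strand_ok <- TRUE
    maj <- agg$score > 0.5
    pass <- maj & agg$score >= config$consensus_threshold & agg$strand_ok
    ambiguous <- maj & agg$score < config$consensus_threshold
    rejected_consensus <- unique(agg$group_id[ambiguous])
    calls <- agg[pass & !(agg$group_id %in% rejected_consensus),
                 c("group_id", "pos", "alt", "score")]
  }
  if (is.null(calls))
    calls <- data.frame(group_id = integer(0), pos = integer(0),
                        alt = character(0), score = numeric(0))
  mol <- g[keep_size & !(g$group_id %in% rejected_consensus), , drop = FALSE]
  n_all <- tapply(rep(1L, nrow(g)), g$sample, sum)
  n_pass <- tapply(mol$group_id, mol$sample, length)
  rate <- setNames(as.numeric(n_pass[names(n_all)]) / as.numeric(n_all),
                   names(n_all))
  rate[is.na(rate)] <- 0
  structure(list(molecules = mol, calls = calls, eumi_filter_rate = rate,
                 n_groups = nrow(g),
                 n_rejected_size = sum(!keep_size),
                 n_rejected_consensus = length(rejected_consensus),
                 config = config), class = "mtl_molecules")
}

#' @export
print.mtl_molecules <- function(x, ...) {
  cat(sprintf("consensus molecules: %d retained of %d eUMI groups (%d size-rejected, %d ambiguous); %d non-reference calls\n",
              nrow(x$molecules), x$n_groups, x$n_rejected_size,
              x$n_rejected_consensus, nrow(x$calls)))
  invisible(x)
}

#' Consensus-call a single eUMI group
#'
#' Single-group surface over the vectorized consensus caller: returns the
#' consensus molecule with its retained non-reference calls, or `NULL` when
#' the group is rejected (too few reads, or an ambiguous majority base).
#'
#' @param group data.frame of reads sharing one eUMI key.
#' @param config `mtl_filter_config`.
#' @return list(key, size, calls) or `NULL` if rejected.
#' @export
call_consensus <- function(group, config = filter_config()) {
  if (nrow(group) == 0) stop("empty group")
  cm <- consensus_molecules(group_eumis(group), config)
  if (nrow(cm$molecules) == 0) return(NULL)
  m <- cm$molecules[1, ]
  list(key = list(cell = m$cell, start = m$start, end = m$end),
       size = m$size, calls = cm$calls[, c("pos", "alt", "score")])
}

#' Call variants across cells from consensus molecules
#'
#' Applies the multistep variant filters: supporting-molecule minimum per
#' cell-variant, position blacklist, germline/haplogroup removal (carried at
#' high heteroplasmy by nearly all covered cells), and minimum carrier-cell
#' count. Variant ids are `"{pos}_{ref}_{alt}"`, 1-based.
#'
#' @param molecules `mtl_molecules` from [consensus_molecules()].
#' @param reference character vector of reference bases (length =
#'   genome length) or a single string.
#' @param config `mtl_filter_config`.
#' @return object of class `mtl_vcmatrix`: list with sparse count matrix `C`
#'   (cells x variants, supporting consensus molecules), `copies` (molecule
#'   coverage of each cell at each variant position, same dims), `variants`
#'   (variant table), `cells`, and `stage_counts`.
#' @export
call_variants <- function(molecules, reference, config = filter_config()) {
  stopifnot(inherits(molecules, "mtl_molecules"))
  if (length(reference) == 1L) reference <- strsplit(reference, "")[[1]]
  mol <- molecules$molecules
  calls <- molecules$calls
  if (any(calls$pos > length(reference)))
    stop("reference length mismatch: call position beyond reference end")
  cells <- sort(unique(mol$cell))
  stage <- list(raw_calls = nrow(calls))
  empty_result <- function() {
    dn <- list(cells, character(0))
    Z <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(length(cells), 0), dimnames = dn)
    structure(list(C = Z, copies = Z, cells = cells,
                   variants = data.frame(variant = character(0), pos = integer(0),
                                         ref = character(0), alt = character(0),
                                         n_cells = integer(0),
                                         total_molecules = numeric(0),
                                         mean_het = numeric(0)),
                   stage_counts = stage,
                   eumi_filter_rate = molecules$eumi_filter_rate),
              class = "mtl_vcmatrix")
  }
  if (nrow(calls) == 0) return(empty_result())

  cl <- calls
  cl$cell <- mol$cell[match(cl$group_id, mol$group_id)]
  cl$ref <- reference[cl$pos]
  cl <- cl[cl$ref != cl$alt, , drop = FALSE]
  cl$variant <- paste0(cl$pos, "_", cl$ref, "_", cl$alt)

  ## supporting molecules per (cell, variant)
  key <- paste(cl$cell, cl$variant, sep = "\r")
  cnt <- as.integer(rowsum(rep(1L, nrow(cl)), key, reorder = FALSE))
  first <- !duplicated(key)
  cv <- cl[first, c("cell", "variant", "pos", "ref", "alt")]
  cv$count <- cnt[match(key[first], key[first])]
  cv <- cv[cv$count >= config$min_molecules_per_cellvariant, , drop = FALSE]
  stage$after_min_molecules <- length(unique(cv$variant))

  cv <- cv[!(cv$pos %in% config$blacklist), , drop = FALSE]
  stage$after_blacklist <- length(unique(cv$variant))

  ## per-cell molecule coverage at each remaining variant position
  upos <- sort(unique(cv$pos))
  cov_list <- lapply(upos, function(p) {
    sp <- mol[mol$start <= p & mol$end >= p, , drop = FALSE]
    tab <- table(sp$cell)
    data.frame(pos = p, cell = names(tab), copies = as.integer(tab),
               stringsAsFactors = FALSE)
  })
  cov <- if (length(cov_list)) do.call(rbind, cov_list)
    else data.frame(pos = integer(0), cell = character(0), copies = integer(0))
  cv$copies <- cov$copies[match(paste(cv$pos, cv$cell), paste(cov$pos, cov$cell))]
  cv$copies[is.na(cv$copies)] <- cv$count[is.na(cv$copies)]  # defensive
  cv$het <- pmin(1, cv$count / cv$copies)

  ## germline/haplogroup removal
  covered_cells <- tapply(cov$cell, cov$pos, function(x) length(unique(x)))
  per_var <- split(seq_len(nrow(cv)), cv$variant)
  germ <- vapply(per_var, function(ix) {
    p <- cv$pos[ix[1]]
    frac <- length(ix) / covered_cells[[as.character(p)]]
    frac >= config$germline_cell_frac && mean(cv$het[ix]) >= config$germline_het
  }, logical(1))
  cv <- cv[!(cv$variant %in% names(germ)[germ]), , drop = FALSE]
  stage$after_germline <- length(unique(cv$variant))

  ## minimum carrier cells
  ncells_v <- table(cv$variant)
  keep_v <- names(ncells_v)[ncells_v >= config$min_cells_per_variant]
  cv <- cv[cv$variant %in% keep_v, , drop = FALSE]
  stage$after_min_cells <- length(unique(cv$variant))
  if (nrow(cv) == 0) return(empty_result())

  vid <- sort(unique(cv$variant))
  C <- Matrix::sparseMatrix(i = match(cv$cell, cells), j = match(cv$variant, vid),
                            x = cv$count, dims = c(length(cells), length(vid)),
                            dimnames = list(cells, vid))
  CN <- Matrix::sparseMatrix(i = match(cv$cell, cells), j = match(cv$variant, vid),
                             x = cv$copies, dims = c(length(cells), length(vid)),
                             dimnames = list(cells, vid))
  vfirst <- cv[!duplicated(cv$variant), c("variant", "pos", "ref", "alt")]
  vfirst <- vfirst[match(vid, vfirst$variant), , drop = FALSE]
  vtab <- data.frame(vfirst,
                     n_cells = as.integer(ncells_v[vid]),
                     total_molecules = as.numeric(tapply(cv$count, cv$variant, sum)[vid]),
                     mean_het = as.numeric(tapply(cv$het, cv$variant, mean)[vid]),
                     row.names = NULL, stringsAsFactors = FALSE)
  structure(list(C = C, copies = CN, variants = vtab, cells = cells,
                 stage_counts = stage, eumi_filter_rate = molecules$eumi_filter_rate),
            class = "mtl_vcmatrix")
}

#' @export
print.mtl_vcmatrix <- function(x, ...) {
  cat(sprintf("variant-by-cell matrix: %d cells x %d variants (%.3f%% non-zero)\n",
              nrow(x$C), ncol(x$C),
              if (length(x$C)) 100 * Matrix::nnzero(x$C) / length(x$C) else 0))
  invisible(x)
}

#' Per-cell mtDNA coverage
#'
#' Mean mtDNA copies per position: the sum of retained consensus-molecule
#' fragment lengths divided by the genome length. Cells present in `cells`
#' but with no retained molecules get coverage 0 and are flagged.
#'
#' @param molecules `mtl_molecules`.
#' @param genome_length genome length in bp.
#' @param cells optional cell universe (default: cells seen in molecules).
#' @return data.frame: cell, coverage, flagged.
#' @export
compute_coverage <- function(molecules, genome_length, cells = NULL) {
  stopifnot(inherits(molecules, "mtl_molecules"))
  mol <- molecules$molecules
  lens <- tapply(mol$end - mol$start + 1, mol$cell, sum)
  if (is.null(cells)) cells <- sort(unique(mol$cell))
  cov <- as.numeric(lens[cells]) / genome_length
  cov[is.na(cov)] <- 0
  data.frame(cell = cells, coverage = cov, flagged = cov == 0,
             stringsAsFactors = FALSE)
}

#' Per-cell mtDNA mutation burden
#'
#' Burden for cell i in sample j = n_mutations(i) /
#' (eUMI filtering rate(j) x coverage(i)): the detected mutation count
#' normalized for technical detectability.
#'
#' @param n_mutations named vector of detected mutation counts per cell.
#' @param eumi_filter_rate named per-sample filter pass rates.
#' @param coverage data.frame from [compute_coverage()] or a named vector.
#' @param sample_of_cell named vector cell -> sample (default: single sample).
#' @return data.frame: cell, sample, n_mutations, eumi_filter_rate, coverage,
#'   burden. Cells with zero coverage are excluded with a warning.
#' @export
compute_burden <- function(n_mutations, eumi_filter_rate, coverage,
                           sample_of_cell = NULL) {
  if (is.data.frame(coverage))
    coverage <- setNames(coverage$coverage, coverage$cell)
  cells <- names(n_mutations)
  if (is.null(sample_of_cell))
    sample_of_cell <- setNames(rep(names(eumi_filter_rate)[1], length(cells)), cells)
  rate <- eumi_filter_rate[sample_of_cell[cells]]
  if (any(rate == 0)) stop("eumi_filter_rate of 0 for sample(s): ",
                           paste(unique(sample_of_cell[cells][rate == 0]), collapse = ", "))
  cov <- coverage[cells]
  drop <- is.na(cov) | cov == 0
  if (any(drop)) {
    warning(sprintf("%d cell(s) with zero coverage excluded from burden", sum(drop)))
  }
  k <- cells[!drop]
  data.frame(cell = k, sample = unname(sample_of_cell[k]),
             n_mutations = as.numeric(n_mutations[k]),
             eumi_filter_rate = as.numeric(rate[!drop]),
             coverage = as.numeric(cov[!drop]),
             burden = as.numeric(n_mutations[k]) /
               (as.numeric(rate[!drop]) * as.numeric(cov[!drop])),
             stringsAsFactors = FALSE)
}

#' Mutational-signature classification
#'
#' Assigns each variant a (strand, substitution, trinucleotide context)
#' class. Convention: the reference sense strand is taken as the light (L)
#' strand; substitutions are reported with a pyrimidine reference base, so a
#' purine-reference variant is complemented and attributed to the heavy (H)
#' strand, with its context reverse-complemented. Context is circular at the
#' genome ends.
#'
#' @param variants variant table (columns pos, ref, alt), e.g.
#'   `x$variants` from [call_variants()].
#' @param reference reference bases (vector or single string).
#' @return data.frame: strand, substitution, context, count; the counts sum
#'   to `nrow(variants)`.
#' @export
mutation_signature <- function(variants, reference) {
  if (length(reference) == 1L) reference <- strsplit(reference, "")[[1]]
  L <- length(reference)
  if (nrow(variants) == 0)
    return(data.frame(strand = character(0), substitution = character(0),
                      context = character(0), count = integer(0)))
  if (any(variants$ref != reference[variants$pos]))
    stop("reference base mismatch for variant(s): ",
         paste(head(variants$variant[variants$ref != reference[variants$pos]]),
               collapse = ", "))
  up <- reference[((variants$pos - 2) %% L) + 1]
  dn <- reference[(variants$pos %% L) + 1]
  pyr <- variants$ref %in% c("C", "T")
  strand <- ifelse(pyr, "L", "H")
  sub5 <- ifelse(pyr, paste0(variants$ref, ">", variants$alt),
                 paste0(comp_base(variants$ref), ">", comp_base(variants$alt)))
  ctx <- ifelse(pyr,
                paste0(up, "[", sub5, "]", dn),
                paste0(comp_base(dn), "[", sub5, "]", comp_base(up)))
  out <- aggregate(list(count = rep(1L, length(ctx))),
                   by = list(strand = strand, substitution = sub5, context = ctx),
                   FUN = sum)
  out[order(out$strand, out$substitution, out$context), , drop = FALSE]
}
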