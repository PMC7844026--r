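#' Eigenvector matrix across samples
#'
#' Regions (grid bins) by samples matrix of EV coefficients with a
#' sample-to-group assignment; the input of the case-control and subtype
#' analyses.
#'
#' @param values numeric matrix, one column per sample (NA = non-assigned
#'   bin in that sample); row names are region identifiers (defaulting to
#'   the row index).
#' @param sample_groups named character vector sample -> group label, names
#'   matching `colnames(values)`.
#' @return object of class `ev_matrix`.
#' @export
ev_matrix <- function(values, sample_groups) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- names(sample_groups)
  if (is.null(rownames(values)))
    rownames(values) <- as.character(seq_len(nrow(values)))
  if (!setequal(colnames(values), names(sample_groups)))
    stop("sample_groups names must match the sample columns")
  structure(list(values = values,
                 sample_groups = sample_groups[colnames(values)]),
            class = "ev_matrix")
}

#' Differential compartment regions between two groups
#'
#' Per-region Welch two-sample t test of case versus control EV
#' coefficients, Benjamini-Hochberg adjustment across tested regions, and
#' the two-threshold significance rule: adjusted p below `alpha` and
#' absolute mean EV difference above `delta_min`.  Regions with a missing
#' value in any compared sample are removed before testing.
#'
#' @param evm an [ev_matrix()].
#' @param case_group,control_group group labels in `evm$sample_groups`.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param delta_min minimum absolute EV difference (default 0.4).
#' @param var_equal use the pooled-variance Student t test instead of
#'   Welch (default FALSE).
#' @return data.frame of class `differential_result`: per region
#'   `mean_case`, `mean_control`, `delta`, `t_statistic`, `p_value`,
#'   `p_adjusted`, `significant`, `direction` ("activation" when the case
#'   gains EV).  Attribute `n_removed` counts regions dropped for missing
#'   values.
#' @export
differential_compartments <- function(evm, case_group, control_group,
                                      alpha = 0.05, delta_min = 0.4,
                                      var_equal = FALSE) {
  gr <- evm$sample_groups
  ci <- which(gr == case_group)
  ki <- which(gr == control_group)
  if (length(ci) < 2 || length(ki) < 2)
    stop("each group needs at least 2 samples")
  sub <- evm$values[, c(ci, ki), drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0
  n_removed <- sum(!complete)
  X <- evm$values[complete, ci, drop = FALSE]
  Y <- evm$values[complete, ki, drop = FALSE]
  n1 <- ncol(X); n2 <- ncol(Y)
  m1 <- rowMeans(X); m2 <- rowMeans(Y)
  v1 <- apply(X, 1, stats::var); v2 <- apply(Y, 1, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  }
  delta <- m1 - m2
  tstat <- delta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- se == 0
  p[degen & delta == 0] <- 1
  p[degen & delta != 0] <- 0
  tstat[degen] <- ifelse(delta[degen] == 0, 0, sign(delta[degen]) * Inf)
  padj <- stats::p.adjust(p, method = "BH")
  res <- data.frame(
    region = rownames(evm$values)[complete],
    mean_case = m1, mean_control = m2, delta = delta,
    t_statistic = tstat, p_value = p, p_adjusted = padj,
    significant = padj < alpha & abs(delta) > delta_min,
    direction = ifelse(delta > 0, "activation", "inactivation"),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, class = c("differential_result", "data.frame"),
            n_removed = n_removed, alpha = alpha, delta_min = delta_min)
}

#' Bins with a conserved compartment label across samples
#'
#' Returns the bin indices whose label is identical (and non-NA) in every
#' supplied call set — the control universe of the case-control designs,
#' where "control" means regions conserved across all reference samples.
#' The complement (assigned everywhere but not conserved) is returned as an
#' attribute `non_conserved`.
#'
#' @param calls_list list of [call_compartments()] results on a shared grid.
#' @return integer vector of conserved bin indices, with attributes
#'   `labels` (the shared label per conserved bin) and `non_conserved`.
#' @export
conserved_compartment_regions <- function(calls_list) {
  if (length(calls_list) < 2) stop("need >= 2 call sets")
  labs <- vapply(calls_list, function(x) x$labels,
                 character(length(calls_list[[1]]$labels)))
  assigned <- rowSums(is.na(labs)) == 0
  same <- assigned & apply(labs, 1, function(r) length(unique(r)) == 1)
  out <- which(same)
  attr(out, "labels") <- labs[same, 1]
  attr(out, "non_conserved") <- which(assigned & !same)
  out
}

#' Partition two significant-region sets into shared and specific parts
#'
#' The set-difference bookkeeping used to separate entity-specific from
#' shared compartment changes: common = A intersect B, A-specific = A minus
#' B, B-specific = B minus A.
#'
#' @param set_a,set_b vectors of region identifiers on the same grid.
#' @return list with `common`, `a_specific`, `b_specific` and `counts`
#'   (named vector: a, b, common, a_specific, b_specific, union).
#' @export
specificity_partition <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  common <- intersect(set_a, set_b)
  a_spec <- setdiff(set_a, set_b)
  b_spec <- setdiff(set_b, set_a)
  list(common = common, a_specific = a_spec, b_specific = b_spec,
       counts = c(a = length(set_a), b = length(set_b),
                  common = length(common), a_specific = length(a_spec),
                  b_specific = length(b_spec),
                  union = length(union(set_a, set_b))))
}

#' Subtype-specific compartment regions within one disease
#'
#' Two-step rule.  Homogenization: within each subtype, keep regions whose
#' EV range (max - min across that subtype's samples) is strictly below
#' `homog_max`, removing regions with any missing value first.
#' Significance: among retained regions, the absolute difference of the two
#' subtype mean EVs must reach `min_delta`; a positive difference of at
#' least `min_delta` is a gain of activation in that subtype.
#'
#' @param evm an [ev_matrix()] restricted to one disease.
#' @param subtype1,subtype2 group labels in `evm$sample_groups`.
#' @param homog_max within-subtype EV range cutoff (default 0.4, strict).
#' @param min_delta between-subtype mean difference (default 0.4, >=).
#' @return data.frame per retained region: subtype means, `delta`
#'   (subtype1 - subtype2), `significant`, `gain` (which subtype gains
#'   activity among significant regions).  Attributes: `retention`
#'   (fraction of complete regions surviving homogenization),
#'   `n_complete`, `n_removed_na`.
#' @export
subtype_regions <- function(evm, subtype1, subtype2, homog_max = 0.4,
                            min_delta = 0.4) {
  gr <- evm$sample_groups
  i1 <- which(gr == subtype1)
  i2 <- which(gr == subtype2)
  if (length(i1) == 0 || length(i2) == 0) stop("empty subtype")
  sub <- evm$values[, c(i1, i2), drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0
  X <- evm$values[complete, i1, drop = FALSE]
  Y <- evm$values[complete, i2, drop = FALSE]
  rng <- function(m) apply(m, 1, max) - apply(m, 1, min)
  homog <- rng(X) < homog_max & rng(Y) < homog_max
  m1 <- rowMeans(X[homog, , drop = FALSE])
  m2 <- rowMeans(Y[homog, , drop = FALSE])
  delta <- m1 - m2
  sig <- abs(delta) >= min_delta
  res <- data.frame(
    region = rownames(evm$values)[complete][homog],
    mean_subtype1 = m1, mean_subtype2 = m2, delta = delta,
    significant = sig,
    gain = ifelse(!sig, NA_character_,
                  ifelse(delta > 0, subtype1, subtype2)),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, retention = mean(homog), n_complete = sum(complete),
            n_removed_na = sum(!complete))
}

#' Monte-Carlo chromosome enrichment of a region set
#'
#' Compares the observed per-chromosome count of a region set against the
#' distribution obtained by drawing equally many bins uniformly without
#' replacement from the assignable genome, `n_perm` times.  The one-tailed
#' empirical p value is (1 + number of draws with count >= observed) /
#' (n_perm + 1), so the smallest attainable p is 1/(n_perm + 1).
#'
#' @param regions integer vector of global bin indices (the region set).
#' @param grid the [bin_grid()].
#' @param n_perm Monte-Carlo repetitions (default 10000).
#' @param seed RNG seed; results are bit-for-bit reproducible given it.
#' @param assignable optional integer vector of bin indices the draws come
#'   from (defaults to all grid bins); should match the universe the
#'   regions were tested on.
#' @return data.frame per chromosome: `observed`, `expected_mean`,
#'   `expected_sd`, `p_value`.
#' @export
chromosome_enrichment_mc <- function(regions, grid, n_perm = 10000L,
                                     seed = 1L, assignable = NULL) {
  regions <- unique(as.integer(regions))
  if (length(regions) < 1) stop("empty region set")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(assignable)) assignable <- seq_len(n_bins(grid))
  if (length(regions) > length(assignable))
    stop("more regions than assignable bins")
  chroms <- names(grid$chrom_sizes)
  chrom_id <- match(grid$bins$chrom, chroms)
  obs <- tabulate(chrom_id[regions], length(chroms))
  rng <- .local_rng(seed)
  on.exit(rng$restore())
  m <- length(regions)
  counts <- matrix(0L, n_perm, length(chroms))
  pool <- chrom_id[assignable]
  for (r in seq_len(n_perm))
    counts[r, ] <- tabulate(pool[sample.int(length(pool), m)],
                            length(chroms))
  ge <- colSums(counts >= matrix(obs, n_perm, length(chroms), byrow = TRUE))
  data.frame(chrom = chroms, observed = obs,
             expected_mean = colMeans(counts),
             expected_sd = apply(counts, 2, stats::sd),
             p_value = (1 + ge) / (n_perm + 1),
             stringsAsFactors = FALSE)
}

#' Monte-Carlo enrichment of flagged genes in a region set
#'
#' Tests whether flagged genes (e.g. differentially expressed) overlap a
#' region set more often than random region sets of the same size.  Genes
#' are annotated to regions by coordinate overlap
#' (GenomicRanges::findOverlaps); each permutation redraws the region set
#' uniformly without replacement from the assignable bins and recounts
#' overlapping flagged genes.  One-tailed p as in
#' [chromosome_enrichment_mc()].
#'
#' @param regions integer vector of global bin indices.
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param flagged_genes character vector of flagged gene ids.
#' @param grid the [bin_grid()].
#' @inheritParams chromosome_enrichment_mc
#' @return list with `observed`, `p_value`, `n_perm`, `null_mean`.
#' @export
region_gene_enrichment_mc <- function(regions, genes, flagged_genes, grid,
                                      n_perm = 10000L, seed = 1L,
                                      assignable = NULL) {
  if (nrow(genes) == 0) stop("empty gene table")
  if (n_perm < 1) stop("n_perm must be >= 1")
  regions <- unique(as.integer(regions))
  if (is.null(assignable)) assignable <- seq_len(n_bins(grid))
  if (length(regions) > length(assignable))
    stop("more regions than assignable bins")
  bins_gr <- GenomicRanges::GRanges(
    grid$bins$chrom,
    IRanges::IRanges(start = grid$bins$start + 1L, end = grid$bins$end))
  genes_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$start + 1L, end = genes$end))
  hits <- GenomicRanges::findOverlaps(genes_gr, bins_gr)
  flagged <- which(genes$gene_id %in% flagged_genes)
  # bins overlapped by each flagged gene
  gene_bins <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  gene_bins <- gene_bins[as.character(flagged)]
  gene_bins <- gene_bins[!vapply(gene_bins, is.null, TRUE)]
  count_overlap <- function(region_set) {
    member <- logical(n_bins(grid))
    member[region_set] <- TRUE
    sum(vapply(gene_bins, function(b) any(member[b]), TRUE))
  }
  observed <- count_overlap(regions)
  rng <- .local_rng(seed)
  on.exit(rng$restore())
  m <- length(regions)
  null_counts <- integer(n_perm)
  for (r in seq_len(n_perm))
    null_counts[r] <- count_overlap(assignable[sample.int(length(assignable), m)])
  list(observed = observed,
       p_value = (1 + sum(null_counts >= observed)) / (n_perm + 1),
       n_perm = n_perm, null_mean = mean(null_counts))
}
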