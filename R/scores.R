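#' Compartment interaction score (C-score)
#'
#' Ratio of intra-compartment contacts over all chromosomal contacts
#' involving the compartment.  In per-label mode (default), for label L the
#' numerator sums contacts over bin pairs both labeled L and the
#' denominator adds pairs with exactly one endpoint labeled L.  In
#' per-segment mode, runs of adjacent same-label bins are merged into
#' segments and scored against all same-label bins.  Every unordered pair
#' is counted once and the diagonal once; NA bins are excluded.
#'
#' @param cm a [contact_matrix()].
#' @param calls a [call_compartments()] result on the same grid.
#' @param mode `"label"` or `"segment"`.
#' @return data.frame with `chrom`, `label` (and `segment` in segment
#'   mode), `intra_contacts`, `total_contacts`, `cscore`.
#' @export
compartment_score <- function(cm, calls, mode = c("label", "segment")) {
  mode <- match.arg(mode)
  if (n_bins(cm$grid) != length(calls$labels))
    stop("matrix and calls must share the grid")
  chrom <- cm$grid$bins$chrom[1]
  lab <- calls$labels
  lab[!cm$mask] <- NA
  W <- cm$values
  assigned <- which(!is.na(lab))
  if (length(assigned) == 0)
    return(data.frame(chrom = character(), label = character(),
                      intra_contacts = numeric(), total_contacts = numeric(),
                      cscore = numeric()))
  if (mode == "label") {
    labels <- intersect(c("A", "IA", "IB", "I", "B"), unique(lab[assigned]))
    rows <- lapply(labels, function(L) {
      idx <- which(!is.na(lab) & lab == L)
      other <- setdiff(assigned, idx)
      intra <- (sum(W[idx, idx]) + sum(W[cbind(idx, idx)])) / 2
      cross <- if (length(other)) sum(W[idx, other]) else 0
      total <- intra + cross
      data.frame(chrom = chrom, label = L, intra_contacts = intra,
                 total_contacts = total, cscore = intra / total)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }
  # segment mode
  r <- rle(ifelse(is.na(lab), "<NA>", lab))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg_rows <- list()
  seg_id <- 0L
  for (s in seq_along(r$values)) {
    if (r$values[s] == "<NA>") next
    seg_id <- seg_id + 1L
    idx <- starts[s]:ends[s]
    L <- r$values[s]
    same <- which(!is.na(lab) & lab == L)
    # sum(W[idx, set]) counts within-idx off-diagonal pairs twice; subtract
    # half of them so every unordered pair (and the diagonal) counts once
    dup <- (sum(W[idx, idx, drop = FALSE]) - sum(W[cbind(idx, idx)])) / 2
    intra <- sum(W[idx, same, drop = FALSE]) - dup
    total <- sum(W[idx, assigned, drop = FALSE]) - dup
    seg_rows[[seg_id]] <- data.frame(
      chrom = chrom, label = L, segment = seg_id,
      start_bin = starts[s], end_bin = ends[s],
      intra_contacts = intra, total_contacts = total,
      cscore = intra / total)
  }
  out <- do.call(rbind, seg_rows)
  rownames(out) <- NULL
  out
}

#' Chromatin-state enrichment by compartment group
#'
#' For each replicate segmentation and each bin group, the frequency of
#' every chromatin state within the group's bins is divided by its
#' genome-wide frequency.  The enrichment score is the median of these
#' corrected frequencies across replicates, z-scaled by columns and then by
#' rows.
#'
#' @param segmentations list of [state_segmentation()] replicates.
#' @param groups character vector, one group name per grid bin (NA bins are
#'   excluded from groups but still count toward genome-wide frequencies).
#' @param grid the [bin_grid()].
#' @return matrix groups x states of enrichment scores, with attribute
#'   `corrected` holding the per-replicate corrected-frequency arrays.
#' @export
state_enrichment <- function(segmentations, groups, grid) {
  if (length(segmentations) == 0) stop("at least one replicate required")
  if (length(groups) != n_bins(grid)) stop("one group per bin required")
  glev <- if (is.factor(groups)) levels(groups)
          else unique(groups[!is.na(groups)])
  groups <- as.character(groups)
  empty <- glev[vapply(glev, function(g) sum(groups == g, na.rm = TRUE), 0) == 0]
  if (length(empty)) stop(sprintf("group '%s' has zero bins", empty[1]))
  alphabet <- chromatin_state_alphabet()
  reps <- lapply(segmentations, function(seg) {
    bp <- .state_bp_by_bin(seg, grid)
    genome_bp <- colSums(bp)
    genome_tot <- sum(genome_bp)
    freq <- t(vapply(glev, function(g) {
      rows <- which(!is.na(groups) & groups == g)
      gbp <- colSums(bp[rows, , drop = FALSE])
      gtot <- sum(gbp)
      if (gtot == 0) return(rep(NA_real_, length(alphabet)))
      (gbp / gtot) / (genome_bp / genome_tot)
    }, numeric(length(alphabet))))
    rownames(freq) <- glev
    freq
  })
  med <- apply(simplify2array(reps), c(1, 2), stats::median)
  scaled <- .zscale(.zscale(med, by = "col"), by = "row")
  attr(scaled, "corrected") <- reps
  scaled
}

.zscale <- function(m, by = c("col", "row")) {
  by <- match.arg(by)
  if (by == "row") return(t(.zscale(t(m), "col")))
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    mu <- mean(v, na.rm = TRUE)
    s <- stats::sd(v, na.rm = TRUE)
    m[, j] <- if (!is.finite(s) || s == 0) ifelse(is.na(v), NA, 0)
              else (v - mu) / s
  }
  m
}

#' Comparison-map configuration
#' @param log_base logarithm base for the contact ratio (default 2).
#' @param pseudocount added to both matrices before the ratio (default 1).
#' @param sigma Gaussian smoothing sd in bins (default 1.0; 0 = none).
#' @param map_resolution bp resolution of the maps (informational; default
#'   50000).
#' @return object of class `compare_config`.
#' @export
compare_config <- function(log_base = 2, pseudocount = 1, sigma = 1.0,
                           map_resolution = 50000L) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(log_base = log_base, pseudocount = pseudocount,
                 sigma = sigma, map_resolution = map_resolution),
            class = "compare_config")
}

#' Smoothed log-ratio of two contact maps
#'
#' Computes log((A + eps) / (B + eps)) in `cfg$log_base` and convolves the
#' result with a one-dimensional Gaussian filter of standard deviation
#' `cfg$sigma` bins along both axes (separably, reflecting at the edges).
#' Bins masked in either matrix are filled from the nearest unmasked bin
#' before the ratio.
#'
#' @param cm_a,cm_b [contact_matrix()] objects on the same grid.
#' @param cfg a [compare_config()].
#' @return numeric matrix of smoothed log ratios.
#' @export
log_ratio_map <- function(cm_a, cm_b, cfg = compare_config()) {
  if (n_bins(cm_a$grid) != n_bins(cm_b$grid) ||
      cm_a$grid$resolution != cm_b$grid$resolution ||
      cm_a$grid$bins$chrom[1] != cm_b$grid$bins$chrom[1])
    stop("contact matrices are on different grids")
  A <- .nn_fill(cm_a$values, cm_a$mask)
  B <- .nn_fill(cm_b$values, cm_b$mask)
  eps <- cfg$pseudocount
  R <- log((A + eps) / (B + eps)) / log(cfg$log_base)
  gaussian_smooth(R, cfg$sigma)
}

#' Separable Gaussian smoothing of a matrix
#' @param m numeric matrix.
#' @param sigma kernel sd in bins (0 returns `m` unchanged); the kernel is
#'   truncated at 4 sigma and normalized; edges are handled by reflection.
#' @return smoothed matrix.
#' @export
gaussian_smooth <- function(m, sigma = 1.0) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(4 * sigma))
  kern <- stats::dnorm(-r:r, sd = sigma)
  kern <- kern / sum(kern)
  m <- apply(m, 2, .conv_reflect, kern = kern)
  t(apply(m, 1, .conv_reflect, kern = kern))
}

.conv_reflect <- function(v, kern) {
  r <- (length(kern) - 1L) / 2L
  n <- length(v)
  # reflect-about-edge padding (scipy "reflect": abcd -> dcba|abcd|dcba)
  idx <- c(rev(seq_len(min(r, n))), seq_len(n),
           n + 1L - seq_len(min(r, n)))
  if (r > n) stop("kernel wider than the matrix; reduce sigma")
  padded <- v[idx]
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- sum(padded[i:(i + 2 * r)] * kern)
  out
}

# Replace masked rows/columns by the nearest unmasked row/column.
.nn_fill <- function(values, mask) {
  if (all(mask)) return(values)
  if (!any(mask)) return(values)
  idx <- which(mask)
  nearest <- vapply(seq_along(mask), function(i) idx[which.min(abs(idx - i))],
                    integer(1))
  v <- values[nearest, nearest, drop = FALSE]
  v
}
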