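#' Pearson correlation matrix of a contact matrix
#'
#' Restricts the contact matrix to unmasked bins and computes the pairwise
#' Pearson correlation between bin contact profiles (matrix columns).  A
#' zero-variance column among the unmasked bins is masked and excluded with
#' a warning.
#'
#' @param cm a [contact_matrix()].
#' @return object of class `compartment_cor`: list with `corr` (correlation
#'   matrix over the retained bins, unit diagonal), `bin_index` (row indices
#'   of retained bins in the grid) and `n_bins` (grid size).
#' @export
correlation_matrix <- function(cm) {
  keep <- which(cm$mask)
  if (length(keep) < 3) stop("need at least 3 unmasked bins")
  sub <- cm$values[keep, keep, drop = FALSE]
  v <- apply(sub, 2, stats::var)
  if (any(v == 0)) {
    warning(sprintf("%d zero-variance bin(s) masked for correlation",
                    sum(v == 0)))
    keep <- keep[v > 0]
    if (length(keep) < 3) stop("need at least 3 unmasked bins")
    sub <- cm$values[keep, keep, drop = FALSE]
  }
  corr <- stats::cor(sub)
  diag(corr) <- 1
  structure(list(corr = corr, bin_index = keep, n_bins = n_bins(cm$grid)),
            class = "compartment_cor")
}

#' Eigenvector of a correlation matrix at a given eigenvalue rank
#'
#' Ranks eigenvectors by descending eigenvalue.  The sign of the returned
#' vector is arbitrary; orientation happens in [orient_and_scale()].  When
#' given a `compartment_cor`, the vector is re-expanded to the full grid
#' with NA at masked bins.
#'
#' @param corr a `compartment_cor` from [correlation_matrix()] or a plain
#'   symmetric matrix.
#' @param rank 1-based eigenvalue rank (default 1, the compartment axis).
#' @param tol symmetry tolerance for plain-matrix input.
#' @return numeric vector (full grid length for `compartment_cor` input).
#' @export
leading_eigenvector <- function(corr, rank = 1L, tol = 1e-8) {
  expand <- inherits(corr, "compartment_cor")
  m <- if (expand) corr$corr else as.matrix(corr)
  if (max(abs(m - t(m))) > tol * max(abs(m), 1))
    stop("matrix is not symmetric within tolerance")
  if (rank < 1 || rank > nrow(m)) stop("invalid eigenvalue rank")
  es <- eigen((m + t(m)) / 2, symmetric = TRUE)
  v <- es$vectors[, rank]
  if (!expand) return(v)
  out <- rep(NA_real_, corr$n_bins)
  out[corr$bin_index] <- v
  out
}

#' Orient an eigenvector by active-chromatin signal and scale to [-1, 1]
#'
#' The sign of a Hi-C eigenvector is arbitrary; the vector is flipped when
#' its Pearson correlation with an activity track (H3K4me1 or ATAC signal)
#' is negative, so positive values mean active chromatin.  With two tracks
#' the mean of the two per-track correlations decides.  The oriented vector
#' is divided by its maximum absolute value so coefficients span [-1, +1].
#'
#' @param ev numeric vector of eigenvector coefficients (NA = masked bins),
#'   or a plain vector from [leading_eigenvector()].
#' @param activity a [bin_track()] (or numeric vector) of active-chromatin
#'   signal on the same grid.
#' @param activity2 optional second activity track.
#' @param grid the [bin_grid()] of the track (required when `activity` is a
#'   plain vector and `ev` carries no grid).
#' @param sample_id label stored in the result.
#' @param eigen_index eigenvalue rank recorded in the result.
#' @return object of class `eigen_track`: list(grid, values, sample_id,
#'   eigen_index).
#' @export
orient_and_scale <- function(ev, activity, activity2 = NULL, grid = NULL,
                             sample_id = "sample", eigen_index = 1L) {
  if (inherits(activity, "bin_track")) {
    grid <- activity$grid
    act <- activity$values
  } else act <- as.numeric(activity)
  if (length(act) != length(ev))
    stop("eigenvector and activity track must share the grid")
  if (all(is.na(act))) stop("activity track is entirely missing")
  rs <- .act_cor(ev, act)
  if (!is.null(activity2)) {
    act2 <- if (inherits(activity2, "bin_track")) activity2$values
            else as.numeric(activity2)
    rs <- mean(c(rs, .act_cor(ev, act2)))
  }
  if (is.na(rs)) stop("orientation correlation undefined")
  if (rs == 0) warning("zero orientation correlation; keeping sign as-is")
  if (rs < 0) ev <- -ev
  mx <- max(abs(ev), na.rm = TRUE)
  if (mx > 0) ev <- ev / mx
  structure(list(grid = grid, values = ev, sample_id = sample_id,
                 eigen_index = as.integer(eigen_index)),
            class = "eigen_track")
}

.act_cor <- function(ev, act) {
  ok <- !is.na(ev) & !is.na(act)
  if (sum(ok) < 2) stop("need >= 2 bins with both eigenvector and activity")
  if (stats::sd(ev[ok]) == 0 || stats::sd(act[ok]) == 0) return(0)
  stats::cor(ev[ok], act[ok])
}

#' @export
print.eigen_track <- function(x, ...) {
  cat(sprintf("eigen_track '%s' (rank %d): %d bins, %d missing, range [%.3f, %.3f]\n",
              x$sample_id, x$eigen_index, length(x$values),
              sum(is.na(x$values)), min(x$values, na.rm = TRUE),
              max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Compartment eigenvector of one chromosome
#'
#' The full per-chromosome pipeline: Pearson correlation of the contact
#' matrix, eigenvector extraction, activity-based orientation and [-1, 1]
#' scaling.  Chromosomes with fewer than `min_unmasked_frac` usable bins are
#' returned all-missing (compartments cannot be assigned unequivocally on
#' very sparse chromosomes).
#'
#' @inheritParams orient_and_scale
#' @param cm a [contact_matrix()].
#' @param rank eigenvalue rank, or `"auto"` to pick, among ranks 1-3, the
#'   one with the largest absolute activity correlation.
#' @param oe divide contacts by the mean at each genomic distance before
#'   correlating (off by default; the standard procedure correlates the
#'   normalized matrix directly).
#' @param min_unmasked_frac minimum usable-bin fraction (default 0.5).
#' @return an `eigen_track` on the matrix grid.
#' @export
compartment_eigenvector <- function(cm, activity, activity2 = NULL,
                                    rank = 1L, oe = FALSE,
                                    min_unmasked_frac = 0.5,
                                    sample_id = "sample") {
  grid <- cm$grid
  if (mean(cm$mask) < min_unmasked_frac) {
    warning(sprintf("only %.0f%% of bins usable; emitting all-missing track",
                    100 * mean(cm$mask)))
    return(structure(list(grid = grid, values = rep(NA_real_, n_bins(grid)),
                          sample_id = sample_id, eigen_index = NA_integer_),
                     class = "eigen_track"))
  }
  if (oe) cm <- .oe_normalize(cm)
  corr <- correlation_matrix(cm)
  ranks <- if (identical(rank, "auto")) 1:3 else as.integer(rank)
  act <- if (inherits(activity, "bin_track")) activity$values
         else as.numeric(activity)
  best <- NULL; best_r <- -Inf; best_rank <- ranks[1]
  for (rk in ranks) {
    if (rk > nrow(corr$corr)) next
    v <- leading_eigenvector(corr, rk)
    r <- abs(.act_cor(v, act))
    if (r > best_r) { best <- v; best_r <- r; best_rank <- rk }
  }
  orient_and_scale(best, activity, activity2, grid = grid,
                   sample_id = sample_id, eigen_index = best_rank)
}

# Observed/expected by distance: divide each diagonal by its mean over
# unmasked pairs.
.oe_normalize <- function(cm) {
  v <- cm$values
  n <- nrow(v)
  keep <- cm$mask
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d)
    j <- i + d
    ok <- keep[i] & keep[j]
    if (!any(ok)) next
    m <- mean(v[cbind(i[ok], j[ok])])
    if (m > 0) {
      v[cbind(i, j)] <- v[cbind(i, j)] / m
      if (d > 0) v[cbind(j, i)] <- v[cbind(j, i)] / m
    }
  }
  out <- cm
  out$values <- v
  out
}
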