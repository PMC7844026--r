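#' Contact matrix container
#'
#' A symmetric matrix of normalized Hi-C contacts for one chromosome on a
#' fixed bin grid, with a per-bin usability mask.  Bins whose whole row is
#' zero (unmappable / filtered regions) are masked and stay masked through
#' every downstream stage.
#'
#' @param grid single-chromosome [bin_grid()].
#' @param values symmetric non-negative numeric matrix, one row per bin.
#' @param symmetrize_tol relative tolerance above which asymmetry triggers a
#'   warning before averaging with the transpose.
#' @return object of class `contact_matrix`: list(grid, values, mask) where
#'   `mask` is TRUE for usable bins.
#' @export
contact_matrix <- function(grid, values, symmetrize_tol = 1e-8) {
  if (length(unique(grid$bins$chrom)) != 1L)
    stop("'grid' must cover exactly one chromosome")
  values <- as.matrix(values)
  nb <- n_bins(grid)
  if (nrow(values) != ncol(values))
    stop("contact matrix must be square")
  if (nrow(values) != nb)
    stop(sprintf("dimension mismatch: grid has %d bins, matrix has %d rows",
                 nb, nrow(values)))
  if (any(values < 0)) stop("contact matrix has negative entries")
  asym <- max(abs(values - t(values)))
  scale <- max(abs(values), 1)
  if (asym > symmetrize_tol * scale)
    warning(sprintf("asymmetry %.3g beyond tolerance; symmetrizing by (M + t(M))/2",
                    asym))
  values <- (values + t(values)) / 2
  mask <- rowSums(values) > 0
  values[!mask, ] <- 0
  values[, !mask] <- 0
  dimnames(values) <- NULL
  structure(list(grid = grid, values = values, mask = mask),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s, %d bins (%d masked), total contacts %.4g\n",
              x$grid$bins$chrom[1], n_bins(x$grid), sum(!x$mask),
              sum(x$values[upper.tri(x$values, diag = TRUE)])))
  invisible(x)
}

#' Load a dense contact matrix from a TSV file
#'
#' Reads a whitespace/tab-separated square matrix of normalized contacts for
#' one chromosome and places it on the grid.  Zero rows are masked;
#' asymmetries beyond tolerance are averaged with a warning.
#'
#' @param path dense matrix file.
#' @param chromosome chromosome name in `grid`.
#' @param grid a [bin_grid()] (multi-chromosome grids are restricted to
#'   `chromosome`).
#' @return a [contact_matrix()].
#' @export
load_contact_matrix <- function(path, chromosome, grid) {
  g <- restrict_grid(grid, chromosome)
  values <- as.matrix(utils::read.table(path, header = FALSE))
  nb <- n_bins(g)
  if (nrow(values) != nb || ncol(values) != nb)
    stop(sprintf(
      "dimension mismatch for %s: expected %d bins, found %d x %d",
      chromosome, nb, nrow(values), ncol(values)))
  contact_matrix(g, values)
}

#' Write a contact matrix as dense TSV
#' @param cm a [contact_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(cm, path) {
  utils::write.table(format(cm$values, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-bin signal track
#' @param grid a [bin_grid()].
#' @param values numeric vector, one value per bin, NA = missing.
#' @param name track label (e.g. "H3K4me1", "ATAC").
#' @return object of class `bin_track`.
#' @export
bin_track <- function(grid, values, name = "signal") {
  if (length(values) != n_bins(grid))
    stop("one value per bin required")
  if (any(!is.finite(values) & !is.na(values)))
    stop("track values must be finite or NA")
  structure(list(grid = grid, values = as.numeric(values), name = name),
            class = "bin_track")
}

#' Average scored intervals onto a bin grid
#'
#' Assigns to each bin the unweighted mean of the scores of all peaks that
#' overlap it (bedmap --mean semantics): a peak spanning two bins contributes
#' its full score to both.  Bins with no overlapping peak are missing.
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end`, `score`
#'   (0-based half-open), or a path readable by [read_scored_bed()].
#' @param grid a [bin_grid()].
#' @param name track label.
#' @return a [bin_track()].
#' @export
bin_scored_intervals <- function(peaks, grid, name = "signal") {
  if (is.character(peaks)) peaks <- read_scored_bed(peaks)
  vals <- rep(NA_real_, n_bins(grid))
  if (nrow(peaks) > 0) {
    if (any(!is.finite(peaks$score))) stop("peak scores must be finite")
    bad <- !(peaks$chrom %in% names(grid$chrom_sizes))
    if (any(bad))
      stop(sprintf("unknown chromosome '%s'", peaks$chrom[which(bad)[1]]))
    over <- peaks$end > grid$chrom_sizes[peaks$chrom] | peaks$start < 0
    if (any(over))
      stop(sprintf("interval %s:%d-%d beyond chromosome end",
                   peaks$chrom[which(over)[1]], peaks$start[which(over)[1]],
                   peaks$end[which(over)[1]]))
    if (any(peaks$start >= peaks$end)) stop("intervals must have start < end")
    off <- .chrom_offsets(grid)
    res <- grid$resolution
    b0 <- .bin_of(peaks$start, res)
    b1 <- .bin_of(peaks$end - 1L, res)
    nb <- b1 - b0 + 1L
    bin_idx <- off[peaks$chrom][rep(seq_len(nrow(peaks)), nb)] +
      (sequence(nb) - 1L) + rep(b0, nb)
    sc <- rep(peaks$score, nb)
    sums <- rowsum(sc, bin_idx)
    cnts <- rowsum(rep(1, length(sc)), bin_idx)
    idx <- as.integer(rownames(sums))
    vals[idx] <- sums[, 1] / cnts[, 1]
  }
  bin_track(grid, vals, name)
}

#' Read a scored BED (score in column 5) or bedGraph (column 4) file
#' @param path input file; 4 columns are read as bedGraph, 5+ as BED5.
#' @return data.frame with `chrom`, `start`, `end`, `score`.
#' @export
read_scored_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), score = numeric()))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 4)
  if (length(bad))
    stop(sprintf("malformed line %d: fewer than 4 fields", bad[1]))
  score_col <- if (all(nf >= 5)) 5L else 4L
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L))),
    end = suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L))),
    score = suppressWarnings(as.numeric(vapply(fields, `[[`, "", score_col))),
    stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$score))
  if (length(bad))
    stop(sprintf("malformed line %d: non-numeric coordinates or score", bad[1]))
  df
}

#' Write a bin track as bedGraph
#' @param track a [bin_track()]; missing bins are omitted.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  keep <- !is.na(track$values)
  df <- cbind(track$grid$bins[keep, , drop = FALSE],
              score = format(track$values[keep], digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
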