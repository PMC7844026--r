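#' Fixed-width genomic bin grid
#'
#' Tiles each chromosome left to right with bins of `resolution` base pairs
#' (the last bin of a chromosome may be shorter).  All coordinates are
#' 0-based, half-open (BED convention).  The grid is the coordinate system
#' shared by contact matrices, signal tracks and compartment calls.
#'
#' @param chrom_sizes named numeric vector, chromosome name -> length in bp.
#' @param resolution bin width in bp (default 100000, the compartment-calling
#'   resolution; 50000 is typical for comparison maps).
#' @return An object of class `bin_grid`: a list with `chrom_sizes`,
#'   `resolution`, and `bins`, a data.frame with columns `chrom`, `start`,
#'   `end` ordered by chromosome then position.
#' @examples
#' g <- bin_grid(c(chrI = 450000, chrII = 250000), resolution = 100000)
#' n_bins(g)
#' @export
bin_grid <- function(chrom_sizes, resolution = 100000L) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("'chrom_sizes' must be a named vector (chromosome -> length)")
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be positive")
  resolution <- as.integer(resolution)
  if (resolution <= 0) stop("'resolution' must be positive")
  bins <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    len <- as.integer(chrom_sizes[[ch]])
    starts <- seq.int(0L, len - 1L, by = resolution)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + resolution, len),
               stringsAsFactors = FALSE)
  }))
  rownames(bins) <- NULL
  structure(list(chrom_sizes = chrom_sizes, resolution = resolution,
                 bins = bins),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("bin_grid: %d chromosome(s), resolution %d bp, %d bins\n",
              length(x$chrom_sizes), x$resolution, n_bins(x)))
  invisible(x)
}

#' Number of bins in a grid
#' @param grid a [bin_grid()].
#' @return integer bin count.
#' @export
n_bins <- function(grid) nrow(grid$bins)

#' Restrict a grid to one chromosome
#' @param grid a [bin_grid()].
#' @param chromosome chromosome name present in the grid.
#' @return a single-chromosome `bin_grid`.
#' @export
restrict_grid <- function(grid, chromosome) {
  if (!chromosome %in% names(grid$chrom_sizes))
    stop(sprintf("chromosome '%s' not in grid", chromosome))
  bin_grid(grid$chrom_sizes[chromosome], grid$resolution)
}

#' Read a two-column chromosome-sizes file
#' @param path TSV with chromosome name and length.
#' @return named numeric vector suitable for [bin_grid()].
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab[[2]]), tab[[1]])
}

# Map 0-based positions to 1-based bin row indices within one chromosome.
.bin_of <- function(pos, resolution) as.integer(pos %/% resolution) + 1L

# Global bin index offsets per chromosome, in grid order.
.chrom_offsets <- function(grid) {
  counts <- table(factor(grid$bins$chrom, levels = names(grid$chrom_sizes)))
  stats::setNames(cumsum(c(0L, as.integer(counts)))[seq_along(counts)],
                  names(grid$chrom_sizes))
}

# Number of bins of one chromosome.
.chrom_nbins <- function(grid, chromosome) {
  sum(grid$bins$chrom == chromosome)
}
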