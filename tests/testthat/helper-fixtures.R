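# Small in-code fixtures shared across test files.

toy_grid <- function(n = 4, resolution = 100000L, chrom = "chrT") {
  sizes <- stats::setNames(n * resolution, chrom)
  bin_grid(sizes, resolution)
}

# symmetric random contact matrix with positive row sums
random_symmetric <- function(n, seed = 1, lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(n * n, lambda), n, n)
  (m + t(m)) / 2
}

# the 4-bin two-label toy used for hand-computed C-scores:
# labels A,A,B,B; within-pair contact 8, all cross contacts 1, diagonal 10
toy_cscore_matrix <- function() {
  w <- matrix(1, 4, 4)
  w[1, 2] <- w[2, 1] <- 8
  w[3, 4] <- w[4, 3] <- 8
  diag(w) <- 10
  w
}

toy_calls <- function(labels, grid = NULL) {
  if (is.null(grid)) grid <- toy_grid(length(labels))
  structure(list(grid = grid, labels = labels,
                 thresholds = NULL, sample_id = "toy"),
            class = "compartment_call")
}

# two-block contact matrix: strong within blocks, weak between
two_block_matrix <- function(n_half = 5, within = 10, between = 1) {
  n <- 2 * n_half
  w <- matrix(between, n, n)
  w[1:n_half, 1:n_half] <- within
  w[(n_half + 1):n, (n_half + 1):n] <- within
  w
}
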