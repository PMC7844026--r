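#' Chromatin-state vocabulary
#'
#' The 12 input states of the 200-bp hidden-Markov segmentation and the
#' 11-state alphabet obtained by merging the active-promoter and
#' strong-enhancer-1 states.  States are grouped by the compartment they
#' characterize: active states are A-related, poised-promoter and
#' polycomb-repressed are I-related, and the two heterochromatin states are
#' B-related.
#'
#' @return `chromatin_state_alphabet()` returns the 11 merged state names;
#'   `chromatin_state_groups()` a named character vector state ->
#'   `"A-related"|"I-related"|"B-related"`.
#' @export
chromatin_state_alphabet <- function() {
  c("ActProm_StrEnh1", "WeakProm", "StrEnh2", "WeakEnh", "TxnTrans",
    "TxnElong", "WeakTxn", "PoisProm", "PolycombRepr", "HetRepr",
    "HetLowSign")
}

#' @rdname chromatin_state_alphabet
#' @export
chromatin_state_groups <- function() {
  c(ActProm_StrEnh1 = "A-related", WeakProm = "A-related",
    StrEnh2 = "A-related", WeakEnh = "A-related", TxnTrans = "A-related",
    TxnElong = "A-related", WeakTxn = "A-related",
    PoisProm = "I-related", PolycombRepr = "I-related",
    HetRepr = "B-related", HetLowSign = "B-related")
}

# 12-state input vocabulary before the ActProm + StrEnh1 merge.
.input_states <- function() {
  c("ActProm", "StrEnh1", chromatin_state_alphabet()[-1])
}

#' Chromatin-state segmentation
#'
#' 200-bp-granularity functional annotation intervals over the genome,
#' restricted to the 11-state alphabet of [chromatin_state_alphabet()].
#'
#' @param intervals data.frame with `chrom`, `start`, `end`, `state`
#'   (0-based half-open); states must belong to the 11-state alphabet.
#' @return object of class `state_segmentation` (the interval data.frame
#'   with attributes `alphabet` and `group_map`).
#' @export
state_segmentation <- function(intervals) {
  alphabet <- chromatin_state_alphabet()
  if (nrow(intervals) > 0) {
    unknown <- setdiff(unique(intervals$state), alphabet)
    if (length(unknown))
      stop(sprintf("unknown state(s) %s; alphabet: %s",
                   paste(unknown, collapse = ", "),
                   paste(alphabet, collapse = ", ")))
    if (any(intervals$start >= intervals$end))
      stop("intervals must have start < end")
  }
  structure(intervals, class = c("state_segmentation", "data.frame"),
            alphabet = alphabet, group_map = chromatin_state_groups())
}

#' Load a 200-bp chromatin-state segmentation from BED
#'
#' Reads a BED4 file whose fourth column holds one of the 12 input state
#' names, merges the active-promoter and strong-enhancer-1 records into the
#' single `ActProm_StrEnh1` state, and returns the 11-state segmentation.
#'
#' @param path BED4 file.
#' @param grid optional [bin_grid()]; when given, intervals beyond
#'   chromosome ends raise an error.
#' @return a [state_segmentation()].
#' @export
load_state_segmentation <- function(path, grid = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(state_segmentation(data.frame(
      chrom = character(), start = integer(), end = integer(),
      state = character(), stringsAsFactors = FALSE)))
  fields <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(fields) < 4)
  if (length(bad)) stop(sprintf("malformed line %d: fewer than 4 fields", bad[1]))
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.integer(vapply(fields, `[[`, "", 2L)),
    end = as.integer(vapply(fields, `[[`, "", 3L)),
    state = vapply(fields, `[[`, "", 4L),
    stringsAsFactors = FALSE)
  unknown <- setdiff(unique(df$state), .input_states())
  if (length(unknown))
    stop(sprintf("unknown state(s) %s; expected one of: %s",
                 paste(unknown, collapse = ", "),
                 paste(.input_states(), collapse = ", ")))
  df$state[df$state %in% c("ActProm", "StrEnh1")] <- "ActProm_StrEnh1"
  if (!is.null(grid)) {
    bad <- !(df$chrom %in% names(grid$chrom_sizes)) |
      df$end > grid$chrom_sizes[df$chrom]
    if (any(bad))
      stop(sprintf("interval %s:%d-%d beyond chromosome end",
                   df$chrom[which(bad)[1]], df$start[which(bad)[1]],
                   df$end[which(bad)[1]]))
  }
  state_segmentation(df)
}

#' Write a state segmentation as BED4
#' @param seg a [state_segmentation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_state_segmentation <- function(seg, path) {
  utils::write.table(as.data.frame(seg)[, c("chrom", "start", "end", "state")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Base pairs of each state falling in each grid bin.
# Returns matrix n_bins x length(alphabet).
.state_bp_by_bin <- function(seg, grid) {
  alphabet <- attr(seg, "alphabet")
  out <- matrix(0, n_bins(grid), length(alphabet),
                dimnames = list(NULL, alphabet))
  if (nrow(seg) == 0) return(out)
  off <- .chrom_offsets(grid)
  res <- grid$resolution
  df <- as.data.frame(seg)
  # split intervals at bin boundaries, then accumulate bp per (bin, state)
  b0 <- .bin_of(df$start, res)
  b1 <- .bin_of(df$end - 1L, res)
  nbk <- b1 - b0 + 1L
  rep_i <- rep(seq_len(nrow(df)), nbk)
  bin_local <- (sequence(nbk) - 1L) + rep(b0, nbk)
  bin_global <- off[df$chrom][rep_i] + bin_local
  piece_start <- pmax(df$start[rep_i], (bin_local - 1L) * res)
  piece_end <- pmin(df$end[rep_i], bin_local * res)
  bp <- piece_end - piece_start
  st <- factor(df$state[rep_i], levels = alphabet)
  acc <- rowsum(bp, interaction(bin_global, st, drop = TRUE))
  key <- strsplit(rownames(acc), ".", fixed = TRUE)
  for (i in seq_along(key))
    out[as.integer(key[[i]][1]), key[[i]][2]] <-
      out[as.integer(key[[i]][1]), key[[i]][2]] + acc[i, 1]
  out
}
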