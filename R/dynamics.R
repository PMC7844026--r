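#' Classify a compartment transition
#'
#' Compartment activity is ordered A > I > B.  A step up the order
#' (B to I, B to A, I to A) is an activation event, a step down an
#' inactivation event, and an unchanged label is stable.  Vectorized.
#'
#' @param from_label,to_label labels in {"A","I","B"} (no NA; callers filter
#'   path-incomplete bins first).
#' @return character vector in {"activation","inactivation","stable"}.
#' @export
classify_transition <- function(from_label, to_label) {
  ord <- c(B = 1L, I = 2L, A = 3L)
  if (any(is.na(from_label)) || any(is.na(to_label)))
    stop("NA labels: filter path-incomplete bins before classifying")
  if (!all(from_label %in% names(ord)) || !all(to_label %in% names(ord)))
    stop("labels must be A, I or B")
  d <- ord[to_label] - ord[from_label]
  unname(ifelse(d > 0, "activation", ifelse(d < 0, "inactivation", "stable")))
}

#' Compartment dynamics along a differentiation path
#'
#' Classifies every path-complete bin (no NA at any state) at each step of
#' an ordered sequence of compartment calls and summarizes per-step
#' percentages and the overall dynamic fraction.
#'
#' @param calls_per_state ordered list (>= 2) of [call_compartments()]
#'   results on a shared grid; list names are used as state names.
#' @return object of class `transition_table`: list with `table`
#'   (data.frame: bin, one label column per state, one class column per
#'   step, `pattern`), `summary` (data.frame per step: percent activation /
#'   inactivation / stable over path-complete bins), `dynamic_fraction`
#'   (bins with >= 1 non-stable step / path-complete bins),
#'   `n_path_complete`, `n_excluded`.
#' @export
path_dynamics <- function(calls_per_state) {
  if (length(calls_per_state) < 2) stop("need >= 2 states along the path")
  labs <- vapply(calls_per_state, function(x) x$labels,
                 character(length(calls_per_state[[1]]$labels)))
  states <- names(calls_per_state)
  if (is.null(states)) states <- paste0("state", seq_len(ncol(labs)))
  colnames(labs) <- states
  complete <- rowSums(is.na(labs)) == 0
  n_excl <- sum(!complete)
  sub <- labs[complete, , drop = FALSE]
  nstep <- ncol(sub) - 1L
  classes <- matrix("", nrow(sub), nstep)
  for (s in seq_len(nstep))
    classes[, s] <- classify_transition(sub[, s], sub[, s + 1])
  colnames(classes) <- paste(states[-ncol(sub)], states[-1], sep = "->")
  summary <- do.call(rbind, lapply(seq_len(nstep), function(s) {
    tab <- table(factor(classes[, s],
                        levels = c("activation", "inactivation", "stable")))
    data.frame(step = colnames(classes)[s],
               activation = 100 * tab[["activation"]] / nrow(sub),
               inactivation = 100 * tab[["inactivation"]] / nrow(sub),
               stable = 100 * tab[["stable"]] / nrow(sub))
  }))
  dyn <- rowSums(classes != "stable") > 0
  out <- data.frame(bin = which(complete), sub, classes,
                    pattern = apply(sub, 1, paste, collapse = "-"),
                    check.names = FALSE)
  structure(list(table = out, summary = summary,
                 dynamic_fraction = mean(dyn),
                 n_path_complete = nrow(sub), n_excluded = n_excl),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("transition_table: %d path-complete bins (%d excluded), %.1f%% dynamic\n",
              x$n_path_complete, x$n_excluded, 100 * x$dynamic_fraction))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Compartment reversibility across a differentiation detour
#'
#' Measures how much of the genome returns to its starting compartment
#' after passing through an intermediate cell state: the fraction of
#' path-complete bins whose final label equals the initial one, and, among
#' bins activated at the intermediate state, the fraction reverting
#' (intermediate-to-final inactivation).
#'
#' @param initial,intermediate,final [call_compartments()] results on a
#'   shared grid (e.g. naive, germinal-center, memory B cells).
#' @return list with `overall_match_fraction`,
#'   `activated_reverting_fraction`, `n_path_complete`, `n_activated`.
#' @export
reversibility <- function(initial, intermediate, final) {
  l1 <- initial$labels; l2 <- intermediate$labels; l3 <- final$labels
  if (length(l1) != length(l2) || length(l2) != length(l3))
    stop("calls must share the grid")
  ok <- !is.na(l1) & !is.na(l2) & !is.na(l3)
  if (!any(ok)) stop("no path-complete bins")
  overall <- mean(l3[ok] == l1[ok])
  act <- rep(FALSE, length(l1))
  act[ok] <- classify_transition(l1[ok], l2[ok]) == "activation"
  revert <- if (any(act))
    mean(classify_transition(l2[act], l3[act]) == "inactivation")
  else NA_real_
  list(overall_match_fraction = overall,
       activated_reverting_fraction = revert,
       n_path_complete = sum(ok), n_activated = sum(act))
}

#' Chromatin-state-group fold change over a bin subset
#'
#' For each state group (A-related, I-related, B-related), the fold change
#' between two time points of the base-pair fraction the group occupies
#' within a set of bins: fc(g) = fraction at t2 / fraction at t1.  Groups
#' absent at t1 are undefined (NA).
#'
#' @param states_t1,states_t2 [state_segmentation()] objects covering the
#'   bins.
#' @param bins integer bin indices (or logical vector) into `grid`.
#' @param grid the [bin_grid()].
#' @return named numeric vector of fold changes for the three groups.
#' @export
state_group_foldchange <- function(states_t1, states_t2, bins, grid) {
  if (is.logical(bins)) bins <- which(bins)
  if (length(bins) == 0) stop("empty bin subset")
  groups <- c("A-related", "I-related", "B-related")
  frac <- function(seg) {
    bp <- .state_bp_by_bin(seg, grid)[bins, , drop = FALSE]
    gm <- chromatin_state_groups()[colnames(bp)]
    tot <- sum(bp)
    if (tot == 0) return(stats::setNames(rep(NA_real_, 3), groups))
    vapply(groups, function(g) sum(bp[, gm == g]) / tot, 0)
  }
  f1 <- frac(states_t1)
  f2 <- frac(states_t2)
  out <- ifelse(is.na(f1) | f1 == 0, NA_real_, f2 / f1)
  stats::setNames(out, groups)
}

#' Compartment and state dynamics of intermediate-compartment bins
#'
#' Selects bins that are I-type at the first time point and carry a given
#' chromatin state there (poised promoter or polycomb-repressed by
#' default), cross-tabulates their compartment at the second time point,
#' and computes the state-group fold change within each destination class.
#'
#' @param calls_t1,calls_t2 [call_compartments()] results.
#' @param seg_t1,seg_t2 [state_segmentation()] replicate for each time
#'   point.
#' @param grid the [bin_grid()].
#' @param states chromatin states selecting the bins at t1.
#' @return list with `destination` (table of t2 labels), `fold_change`
#'   (list per destination label of [state_group_foldchange()] results) and
#'   `bins` (the selected bin indices).
#' @export
intermediate_state_dynamics <- function(calls_t1, calls_t2, seg_t1, seg_t2,
                                        grid,
                                        states = c("PoisProm", "PolycombRepr")) {
  bp <- .state_bp_by_bin(seg_t1, grid)
  has_state <- rowSums(bp[, states, drop = FALSE]) > 0
  sel <- which(!is.na(calls_t1$labels) & calls_t1$labels == "I" & has_state)
  dest_lab <- calls_t2$labels[sel]
  keep <- !is.na(dest_lab)
  sel <- sel[keep]
  dest_lab <- dest_lab[keep]
  dest <- table(factor(dest_lab, levels = c("A", "I", "B")))
  fc <- lapply(stats::setNames(names(dest), names(dest)), function(L) {
    b <- sel[dest_lab == L]
    if (length(b) == 0) return(NULL)
    state_group_foldchange(seg_t1, seg_t2, b, grid)
  })
  list(destination = dest, fold_change = fc, bins = sel)
}
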