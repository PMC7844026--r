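#' Configuration of the synthetic Hi-C generator
#'
#' Defaults emulate the block structure of lymphoid 100-kb compartment
#' maps: blocky A/I/B segments with mean length 8 bins, A-A and B-B
#' contacts dominating, the intermediate compartment contacting all labels
#' promiscuously (its affinities are chosen so I self-interaction is weaker
#' than A-A and B-B), power-law distance decay, Poisson counting noise and
#' lognormal replicate-depth jitter.
#'
#' @param chrom_sizes named vector of chromosome lengths in bp.
#' @param resolution bin width in bp.
#' @param label_proportions probabilities of A, I, B segment labels
#'   (default 0.35/0.33/0.32, the relative abundances typical of mature B
#'   cell maps).
#' @param segment_length_mean mean compartment-segment length in bins.
#' @param affinity symmetric 3x3 label-pair contact multiplier matrix
#'   (rows/cols A, I, B).
#' @param decay_exponent power-law distance-decay exponent alpha.
#' @param depth expected contacts of a bin pair at distance 1 with unit
#'   affinity.
#' @param noise_sd sd of the lognormal per-matrix depth jitter.
#' @param ev_means mixture means of the per-label EV draws (B < I < A).
#' @param ev_sd per-sample EV noise sd.
#' @param activity_means per-label means of the simulated activity track.
#' @param activity_sd activity noise sd.
#' @param seed base RNG seed; every generator output is a pure function of
#'   (config, seed).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(chrom_sizes = c(chrS = 30e6),
                       resolution = 100000L,
                       label_proportions = c(A = 0.35, I = 0.33, B = 0.32),
                       segment_length_mean = 8,
                       affinity = default_affinity(),
                       decay_exponent = 1.0,
                       depth = 100,
                       noise_sd = 0.1,
                       ev_means = c(B = -0.65, I = 0, A = 0.70),
                       ev_sd = 0.08,
                       activity_means = c(A = 10, I = 5, B = 2),
                       activity_sd = 2,
                       seed = 1L) {
  if (abs(sum(label_proportions) - 1) > 1e-8)
    stop("label proportions must sum to 1")
  if (any(affinity != t(affinity)) || any(affinity < 0))
    stop("affinity must be symmetric and non-negative")
  if (depth < 0) stop("depth must be >= 0")
  structure(list(chrom_sizes = chrom_sizes, resolution = resolution,
                 label_proportions = label_proportions,
                 segment_length_mean = segment_length_mean,
                 affinity = affinity, decay_exponent = decay_exponent,
                 depth = depth, noise_sd = noise_sd, ev_means = ev_means,
                 ev_sd = ev_sd, activity_means = activity_means,
                 activity_sd = activity_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default label-pair contact affinities
#'
#' A-A and B-B self-affinity 1.0, I-I 0.6, A-I and B-I 0.5, A-B 0.2: the
#' intermediate compartment self-interacts less than A or B but mixes with
#' both, which makes its C-score emerge below the A and B scores.
#' @return 3x3 symmetric matrix with dimnames A, I, B.
#' @export
default_affinity <- function() {
  m <- matrix(c(1.0, 0.5, 0.2,
                0.5, 0.6, 0.5,
                0.2, 0.5, 1.0), 3, 3,
              dimnames = list(c("A", "I", "B"), c("A", "I", "B")))
  m
}

#' Simulate a planted compartment label map
#'
#' Alternating segments with geometric lengths (mean
#' `segment_length_mean`), each segment's label drawn from
#' `label_proportions`.  Deterministic given the config seed.
#'
#' @param cfg a [sim_config()].
#' @param seed overrides `cfg$seed` when given.
#' @return character vector of labels ("A"/"I"/"B"), one per grid bin of
#'   `bin_grid(cfg$chrom_sizes, cfg$resolution)`, with the grid attached as
#'   attribute `grid`.
#' @export
simulate_labels <- function(cfg, seed = cfg$seed) {
  grid <- bin_grid(cfg$chrom_sizes, cfg$resolution)
  rng <- .local_rng(seed)
  on.exit(rng$restore())
  n <- n_bins(grid)
  labels <- character(0)
  p <- 1 / cfg$segment_length_mean
  while (length(labels) < n) {
    len <- stats::rgeom(1, p) + 1L
    lab <- sample(names(cfg$label_proportions), 1,
                  prob = cfg$label_proportions)
    labels <- c(labels, rep(lab, len))
  }
  labels <- labels[seq_len(n)]
  attr(labels, "grid") <- grid
  labels
}

#' Simulate a contact matrix from planted labels
#'
#' Expected contacts: depth * |i-j|^-alpha * affinity(L_i, L_j) off the
#' diagonal and depth * affinity(L_i, L_i) on it, optionally multiplied by
#' a per-matrix lognormal depth jitter; observed counts are Poisson draws,
#' symmetrized by construction (the upper triangle is drawn and mirrored).
#'
#' @param labels planted label vector for one chromosome (from
#'   [simulate_labels()] or any character vector of A/I/B).
#' @param cfg a [sim_config()].
#' @param seed overrides `cfg$seed`.
#' @param jitter apply the lognormal replicate-depth jitter.
#' @return a [contact_matrix()].
#' @export
simulate_contact_matrix <- function(labels, cfg, seed = cfg$seed,
                                    jitter = TRUE) {
  grid <- attr(labels, "grid")
  if (is.null(grid))
    grid <- bin_grid(c(chrS = length(labels) * cfg$resolution),
                     cfg$resolution)
  n <- length(labels)
  rng <- .local_rng(seed)
  on.exit(rng$restore())
  aff <- cfg$affinity[cbind(rep(labels, n), rep(labels, each = n))]
  aff <- matrix(aff, n, n)
  d <- abs(outer(seq_len(n), seq_len(n), `-`))
  decay <- ifelse(d == 0, 1, d^(-cfg$decay_exponent))
  expected <- cfg$depth * decay * aff
  if (jitter) expected <- expected * exp(stats::rnorm(1, 0, cfg$noise_sd))
  up <- upper.tri(expected, diag = TRUE)
  counts <- matrix(0, n, n)
  counts[up] <- stats::rpois(sum(up), expected[up])
  counts <- counts + t(counts) - diag(diag(counts))
  contact_matrix(grid, counts)
}

#' Simulate activity and chromatin-state tracks from planted labels
#'
#' The activity track (an H3K4me1/ATAC-like signal) is Gaussian per label
#' with means decreasing from A to B.  The 200-bp state track draws states
#' from label-conditioned distributions: A bins concentrate A-related
#' states, I bins poised-promoter/polycomb-repressed, B bins the
#' heterochromatin states.  Intervals tile the bins exactly (consecutive
#' equal states are run-length merged).
#'
#' @inheritParams simulate_contact_matrix
#' @param state_resolution width of the state intervals in bp (default
#'   200).
#' @return list with `activity` (a [bin_track()]) and `states`
#'   (a [state_segmentation()]).
#' @export
simulate_tracks <- function(labels, cfg, seed = cfg$seed,
                            state_resolution = 200L) {
  grid <- attr(labels, "grid")
  if (is.null(grid))
    grid <- bin_grid(c(chrS = length(labels) * cfg$resolution),
                     cfg$resolution)
  rng <- .local_rng(seed)
  on.exit(rng$restore())
  activity <- stats::rnorm(length(labels),
                           cfg$activity_means[labels], cfg$activity_sd)
  act <- bin_track(grid, activity, "activity")
  probs <- .state_probs()
  alphabet <- chromatin_state_alphabet()
  segs <- list()
  for (ci in seq_along(grid$chrom_sizes)) {
    ch <- names(grid$chrom_sizes)[ci]
    rows <- which(grid$bins$chrom == ch)
    per_bin <- lapply(rows, function(b) {
      width <- grid$bins$end[b] - grid$bins$start[b]
      k <- max(1L, width %/% state_resolution)
      sample(alphabet, k, replace = TRUE, prob = probs[[labels[b]]])
    })
    states <- unlist(per_bin)
    starts <- unlist(lapply(seq_along(rows), function(i) {
      b <- rows[i]
      width <- grid$bins$end[b] - grid$bins$start[b]
      k <- max(1L, width %/% state_resolution)
      grid$bins$start[b] + seq(0L, by = state_resolution, length.out = k)
    }))
    ends <- c(starts[-1], grid$chrom_sizes[[ch]])
    r <- rle(states)
    last <- cumsum(r$lengths)
    first <- last - r$lengths + 1L
    segs[[ch]] <- data.frame(chrom = ch, start = starts[first],
                             end = ends[last], state = r$values,
                             stringsAsFactors = FALSE)
  }
  seg <- do.call(rbind, segs)
  rownames(seg) <- NULL
  list(activity = act, states = state_segmentation(seg))
}

# Label-conditioned state distributions over the 11-state alphabet.
.state_probs <- function() {
  gm <- chromatin_state_groups()
  alphabet <- names(gm)
  mk <- function(wA, wI, wB) {
    w <- c(`A-related` = wA, `I-related` = wI, `B-related` = wB)
    p <- w[gm] / table(gm)[gm]
    stats::setNames(as.numeric(p / sum(p)), alphabet)
  }
  list(A = mk(0.80, 0.10, 0.10),
       I = mk(0.20, 0.60, 0.20),
       B = mk(0.10, 0.10, 0.80))
}

#' Design of a synthetic differentiation / disease cohort
#'
#' Mirrors the structure of a B cell differentiation and neoplasia study:
#' four normal maturation states with replicates along the path
#' NBC - GCBC - MBC (MBC reverting toward NBC) plus PC, and two disease
#' entities with clinical subtypes carrying planted entity-specific and
#' subtype-specific compartment switches.
#'
#' @param states differentiation-path state names, in path order
#'   (first - second - third used as initial/intermediate/final for
#'   reversibility; extra states branch off the second).
#' @param replicates Hi-C replicates per normal state.
#' @param dynamic_fraction fraction of bins switching compartment at the
#'   first differentiation step.
#' @param activation_fraction among switching bins, fraction undergoing
#'   activation (the rest inactivate).
#' @param reversibility fraction of first-step-activated bins that revert
#'   at the third state.
#' @param diseases named list; each element
#'   `list(subtypes = c(name = n_samples, ...), n_specific = ...,
#'   n_subtype = ..., n_shared = ...)` giving planted entity-specific
#'   switch count, subtype-specific count, and the count shared with the
#'   other disease.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(states = c("NBC", "GCBC", "MBC", "PC"),
                          replicates = 3L,
                          dynamic_fraction = 0.30,
                          activation_fraction = 0.615,
                          reversibility = 0.75,
                          diseases = list(
                            CLL = list(subtypes = c(mCLL = 5L, uCLL = 2L),
                                       n_specific = 60L, n_subtype = 40L,
                                       n_shared = 15L),
                            MCL = list(subtypes = c(cMCL = 2L, nnMCL = 3L),
                                       n_specific = 30L, n_subtype = 40L,
                                       n_shared = 15L))) {
  stopifnot(length(states) >= 2, replicates >= 1,
            dynamic_fraction >= 0, dynamic_fraction <= 1,
            reversibility >= 0, reversibility <= 1)
  structure(list(states = states, replicates = as.integer(replicates),
                 dynamic_fraction = dynamic_fraction,
                 activation_fraction = activation_fraction,
                 reversibility = reversibility, diseases = diseases),
            class = "cohort_design")
}

# one activation / inactivation move from a label, seeded RNG in scope
.move_label <- function(lab, direction) {
  opts <- if (direction == "activation")
    switch(lab, B = c("I", "A"), I = "A", A = character(0))
  else
    switch(lab, A = c("I", "B"), I = "B", B = character(0))
  if (length(opts) == 0) return(NA_character_)
  if (length(opts) == 1) opts else sample(opts, 1)
}

#' Simulate a full cohort with planted truth
#'
#' Generates per-sample label maps and EV tracks (per-label Gaussian draws
#' around `cfg$ev_means`, clipped to [-1, 1]) for every normal-state
#' replicate and disease sample, plus an exhaustive truth record: planted
#' labels, dynamic bins and their transition patterns, reverting bins, and
#' entity/subtype-specific differential regions with direction.
#' Optionally also emits contact matrices and activity/state tracks per
#' sample.  Deterministic given (config, design, seed).
#'
#' @param cfg a [sim_config()].
#' @param design a [cohort_design()].
#' @param seed overrides `cfg$seed`.
#' @param matrices also simulate a contact matrix per sample (slower).
#' @param tracks also simulate activity/state tracks for the first
#'   replicate of each state.
#' @return list with `samples` (data.frame: sample, population, subtype,
#'   kind), `ev` (an [ev_matrix()] of all samples), `labels` (bins x
#'   populations planted label matrix), `truth` (list described above),
#'   `grid`, and optionally `matrices`, `tracks`.
#' @export
simulate_cohort <- function(cfg, design = cohort_design(), seed = cfg$seed,
                            matrices = FALSE, tracks = FALSE) {
  rng <- .local_rng(seed)
  on.exit(rng$restore())
  base <- simulate_labels(cfg, seed = seed + 1L)
  grid <- attr(base, "grid")
  n <- length(base)
  states <- design$states
  lab <- matrix(base, n, length(states),
                dimnames = list(NULL, states))
  # step 1: plant dynamic bins at the first step
  n_dyn <- round(design$dynamic_fraction * n)
  dyn <- sort(sample.int(n, n_dyn))
  pattern <- character(n_dyn)
  for (i in seq_along(dyn)) {
    b <- dyn[i]
    dir <- if (stats::runif(1) < design$activation_fraction)
      "activation" else "inactivation"
    to <- .move_label(lab[b, 1], dir)
    if (is.na(to)) {
      dir <- setdiff(c("activation", "inactivation"), dir)
      to <- .move_label(lab[b, 1], dir)
    }
    lab[b, 2] <- to
    pattern[i] <- dir
  }
  if (length(states) >= 3) {
    for (s in 3:length(states)) lab[, s] <- lab[, 2]
    # third state reverts a planted fraction of first-step-activated bins
    activated <- dyn[pattern == "activation"]
    n_rev <- round(design$reversibility * length(activated))
    reverted <- sort(sample(activated, n_rev))
    lab[reverted, 3] <- lab[reverted, 1]
  } else reverted <- integer(0)
  # disease label maps start from the first state
  disease_labels <- list()
  truth_dis <- list()
  shared_pool <- integer(0)
  stable_bins <- setdiff(seq_len(n), dyn)
  if (length(design$diseases)) {
    n_shared <- max(vapply(design$diseases, function(d)
      as.integer(d$n_shared %||% 0L), 0L))
    if (n_shared > 0) shared_pool <- sort(sample(stable_bins, n_shared))
    avail <- setdiff(stable_bins, shared_pool)
    for (dn in names(design$diseases)) {
      d <- design$diseases[[dn]]
      dl <- matrix(base, n, sum(d$subtypes > 0),
                   dimnames = list(NULL, names(d$subtypes)))
      spec <- sort(sample(avail, d$n_specific))
      avail <- setdiff(avail, spec)
      ent_bins <- c(spec, shared_pool[seq_len(min(d$n_shared %||% 0L,
                                                  length(shared_pool)))])
      ent_dir <- character(length(ent_bins))
      for (i in seq_along(ent_bins)) {
        b <- ent_bins[i]
        dir <- if (stats::runif(1) < 0.5) "activation" else "inactivation"
        to <- .move_label(base[b], dir)
        if (is.na(to)) {
          dir <- setdiff(c("activation", "inactivation"), dir)
          to <- .move_label(base[b], dir)
        }
        dl[b, ] <- to
        ent_dir[i] <- dir
      }
      sub_bins <- sort(sample(avail, d$n_subtype))
      avail <- setdiff(avail, sub_bins)
      sub_dir <- character(length(sub_bins))
      for (i in seq_along(sub_bins)) {
        b <- sub_bins[i]
        dir <- if (stats::runif(1) < 0.5) "activation" else "inactivation"
        to <- .move_label(base[b], dir)
        if (is.na(to)) {
          dir <- setdiff(c("activation", "inactivation"), dir)
          to <- .move_label(base[b], dir)
        }
        dl[b, 1] <- to  # first subtype carries the switch
        sub_dir[i] <- dir
      }
      disease_labels[[dn]] <- dl
      truth_dis[[dn]] <- list(specific_bins = ent_bins,
                              specific_direction = ent_dir,
                              subtype_bins = sub_bins,
                              subtype_direction = sub_dir,
                              subtype_carrier = names(d$subtypes)[1])
    }
  }
  # per-sample EV draws
  draw_ev <- function(labels)
    pmin(1, pmax(-1, stats::rnorm(n, cfg$ev_means[labels], cfg$ev_sd)))
  samples <- list(); ev_cols <- list()
  for (st in states) {
    for (r in seq_len(design$replicates)) {
      id <- sprintf("%s_rep%d", st, r)
      samples[[id]] <- data.frame(sample = id, population = st,
                                  subtype = NA_character_, kind = "normal")
      ev_cols[[id]] <- draw_ev(lab[, st])
    }
  }
  for (dn in names(disease_labels)) {
    d <- design$diseases[[dn]]
    for (sub in names(d$subtypes)) {
      for (r in seq_len(d$subtypes[[sub]])) {
        id <- sprintf("%s%d", sub, r)
        samples[[id]] <- data.frame(sample = id, population = dn,
                                    subtype = sub, kind = "disease")
        ev_cols[[id]] <- draw_ev(disease_labels[[dn]][, sub])
      }
    }
  }
  samples <- do.call(rbind, samples)
  rownames(samples) <- NULL
  evm <- ev_matrix(do.call(cbind, ev_cols),
                   stats::setNames(samples$population, samples$sample))
  out <- list(
    samples = samples, ev = evm, labels = lab, grid = grid,
    truth = list(base_labels = base, dynamic_bins = dyn,
                 dynamic_pattern = pattern, reverted_bins = reverted,
                 disease = truth_dis, disease_labels = disease_labels,
                 ev_means = cfg$ev_means, config = cfg, design = design))
  if (matrices) {
    out$matrices <- lapply(seq_len(nrow(samples)), function(i) {
      st <- samples$population[i]
      l <- if (st %in% states) lab[, st]
           else disease_labels[[st]][, samples$subtype[i]]
      attr(l, "grid") <- grid
      simulate_contact_matrix(l, cfg, seed = seed + 100L + i)
    })
    names(out$matrices) <- samples$sample
  }
  if (tracks) {
    out$tracks <- lapply(stats::setNames(states, states), function(st) {
      l <- lab[, st]
      attr(l, "grid") <- grid
      simulate_tracks(l, cfg, seed = seed + 500L + match(st, states))
    })
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
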