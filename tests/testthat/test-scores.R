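test_that("C-score is 1 without inter-label contacts", {
  g <- toy_grid(4)
  cm <- contact_matrix(g, random_symmetric(4, seed = 1))
  cs <- compartment_score(cm, toy_calls(rep("A", 4), g))
  expect_equal(cs$cscore, 1)

  block <- two_block_matrix(2, within = 5, between = 0)
  diag(block) <- 5
  cm2 <- contact_matrix(g, block)
  cs2 <- compartment_score(cm2, toy_calls(c("A", "A", "B", "B"), g))
  expect_equal(cs2$cscore, c(1, 1))
})

test_that("C-score matches the hand-summed 4-bin toy", {
  g <- toy_grid(4)
  cm <- contact_matrix(g, toy_cscore_matrix())
  cs <- compartment_score(cm, toy_calls(c("A", "A", "B", "B"), g))
  expect_equal(cs$intra_contacts[cs$label == "A"], 28)
  expect_equal(cs$total_contacts[cs$label == "A"], 32)
  expect_equal(cs$cscore[cs$label == "A"], 0.875)
  expect_equal(cs$cscore[cs$label == "B"], 0.875)
})

test_that("per-label intra plus cross contacts conserve the chromosome total", {
  g <- toy_grid(40)
  w <- random_symmetric(40, seed = 14)
  cm <- contact_matrix(g, w)
  set.seed(15)
  labs <- sample(c("A", "I", "B"), 40, replace = TRUE)
  cs <- compartment_score(cm, toy_calls(labs, g))
  total_once <- sum(w[upper.tri(w, diag = TRUE)])
  # sum over labels counts each cross pair twice and each intra pair once
  expect_equal(sum(cs$intra_contacts) +
                 (sum(cs$total_contacts) - sum(cs$intra_contacts)) / 2,
               total_once)
})

test_that("segment mode scores runs of equal labels against all same-label bins", {
  g <- toy_grid(4)
  cm <- contact_matrix(g, toy_cscore_matrix())
  seg <- compartment_score(cm, toy_calls(c("A", "A", "B", "B"), g),
                           mode = "segment")
  expect_equal(nrow(seg), 2)
  expect_equal(seg$cscore, c(0.875, 0.875))
  # single-segment-per-label reduces to per-label values; NA splits segments
  seg2 <- compartment_score(cm, toy_calls(c("A", NA, "A", "A"), g),
                            mode = "segment")
  expect_equal(nrow(seg2), 2)
  expect_true(all(seg2$label == "A"))
})

test_that("intermediate bins split into IA/IB by eigenvector sign", {
  calls <- toy_calls(c("A", "I", "I", "B"))
  sp <- split_intermediate(calls, c(0.8, 0.2, -0.3, -0.9))
  expect_equal(sp$labels, c("A", "IA", "IB", "B"))
  # boundary: ev exactly 0 goes to IA
  sp0 <- split_intermediate(toy_calls(c("I", "I", "I", "I")),
                            c(0, 0.1, -0.1, 0))
  expect_equal(sp0$labels, c("IA", "IA", "IB", "IA"))
})

test_that("planted intermediate compartment has the lowest C-score", {
  cfg <- sim_config(chrom_sizes = c(chrS = 40e6), seed = 2)
  labels <- simulate_labels(cfg)
  cm <- simulate_contact_matrix(labels, cfg)
  cs <- compartment_score(cm, toy_calls(labels, attr(labels, "grid")))
  sc <- setNames(cs$cscore, cs$label)
  expect_lt(sc[["I"]], sc[["A"]])
  expect_lt(sc[["I"]], sc[["B"]])
  # splitting I by EV sign must not rescue its score above A or B
  ev <- ifelse(labels == "A", 0.7, ifelse(labels == "B", -0.7,
                                          rep(c(0.1, -0.1), length.out = length(labels))))
  sp <- split_intermediate(toy_calls(labels, attr(labels, "grid")), ev)
  cs2 <- compartment_score(cm, sp)
  sc2 <- setNames(cs2$cscore, cs2$label)
  expect_lt(sc2[["IA"]], sc2[["A"]])
  expect_lt(sc2[["IB"]], sc2[["B"]])
})

test_that("state enrichment is zero for identical composition and matches the toy", {
  g <- bin_grid(c(cT = 400000), 100000)
  # two states, two groups; genome 50/50
  seg <- state_segmentation(data.frame(
    chrom = "cT",
    start = c(0, 100000, 200000, 300000),
    end = c(100000, 200000, 300000, 400000),
    state = c("PoisProm", "HetRepr", "PoisProm", "HetRepr")))
  groups_same <- c("g1", "g1", "g2", "g2")
  m <- state_enrichment(list(seg), groups_same, g)
  corr <- attr(m, "corrected")[[1]]
  expect_equal(unname(corr[, c("PoisProm", "HetRepr")]),
               matrix(1, 2, 2))
  expect_equal(unname(m[, c("PoisProm", "HetRepr")]), matrix(0, 2, 2))

  # group1 pure state1, group2 pure state2 -> corrected frequency 2 and 0
  seg2 <- state_segmentation(data.frame(
    chrom = "cT",
    start = c(0, 100000, 200000, 300000),
    end = c(100000, 200000, 300000, 400000),
    state = c("PoisProm", "PoisProm", "HetRepr", "HetRepr")))
  groups2 <- c("g1", "g1", "g2", "g2")
  corr2 <- attr(state_enrichment(list(seg2), groups2, g), "corrected")[[1]]
  expect_equal(unname(corr2["g1", "PoisProm"]), 2)
  expect_equal(unname(corr2["g1", "HetRepr"]), 0)
  expect_equal(unname(corr2["g2", "HetRepr"]), 2)

  expect_error(state_enrichment(list(seg), c("g1", "g1", "g1", "g1")[c(1, 2, 3)],
                                g), "one group per bin")
  expect_error(state_enrichment(list(seg2),
                                factor(c("g1", "g1", "g1", "g1"),
                                       levels = c("g1", "g2")), g),
               "zero bins")
})

test_that("identical replicates reduce the median to a single replicate", {
  g <- bin_grid(c(cT = 400000), 100000)
  seg <- state_segmentation(data.frame(
    chrom = "cT", start = c(0, 200000), end = c(200000, 400000),
    state = c("WeakTxn", "HetLowSign")))
  groups <- c("x", "x", "y", "y")
  one <- state_enrichment(list(seg), groups, g)
  three <- state_enrichment(list(seg, seg, seg), groups, g)
  expect_equal(three, one, ignore_attr = TRUE)
})

test_that("synthetic concordant tracks enrich each group's related states", {
  cfg <- sim_config(chrom_sizes = c(chrS = 30e6), seed = 4)
  labels <- simulate_labels(cfg)
  tr <- lapply(1:3, function(r) simulate_tracks(labels, cfg, seed = r)$states)
  m <- state_enrichment(tr, labels, attr(labels, "grid"))
  gm <- chromatin_state_groups()
  mean_score <- function(grp, rel)
    mean(m[grp, names(gm)[gm == rel]], na.rm = TRUE)
  expect_gt(mean_score("A", "A-related"), mean_score("A", "B-related"))
  expect_gt(mean_score("I", "I-related"), mean_score("I", "A-related"))
  expect_gt(mean_score("B", "B-related"), mean_score("B", "A-related"))
  # scaling contract: rows are z-scaled last
  expect_equal(unname(rowMeans(m)), rep(0, 3), tolerance = 1e-8)
  expect_equal(unname(apply(m, 1, sd)), rep(1, 3), tolerance = 1e-8)
})

test_that("log-ratio maps behave on identity, constant ratio and versus direct convolution", {
  g <- toy_grid(20)
  a <- random_symmetric(20, seed = 5, lambda = 50)
  cm_a <- contact_matrix(g, a)
  expect_equal(log_ratio_map(cm_a, cm_a), matrix(0, 20, 20))

  cm_2a <- contact_matrix(g, 2 * a)
  lr <- log_ratio_map(cm_2a, cm_a, compare_config(pseudocount = 1e-9))
  expect_equal(lr, matrix(1, 20, 20), tolerance = 1e-6)

  # independent direct separable convolution oracle with reflect padding
  cm_b <- contact_matrix(g, random_symmetric(20, seed = 6, lambda = 50))
  got <- log_ratio_map(cm_a, cm_b, compare_config(sigma = 1.0))
  r <- ceiling(4 * 1.0)
  kern <- dnorm(-r:r, sd = 1.0); kern <- kern / sum(kern)
  raw <- log2((a + 1) / (cm_b$values + 1))
  conv1 <- function(v) {
    n <- length(v)
    pad <- c(rev(v[1:r]), v, rev(v[(n - r + 1):n]))
    sapply(seq_len(n), function(i) sum(pad[i:(i + 2 * r)] * kern))
  }
  oracle <- apply(apply(raw, 2, conv1), 1, conv1)
  oracle <- t(oracle)
  expect_equal(got, oracle, tolerance = 1e-8)

  g2 <- toy_grid(21)
  expect_error(log_ratio_map(cm_a, contact_matrix(g2, random_symmetric(21))),
               "different grids")
})

test_that("masked bins are nearest-neighbor filled before the ratio", {
  g <- toy_grid(6)
  a <- random_symmetric(6, seed = 7, lambda = 30)
  b <- random_symmetric(6, seed = 8, lambda = 30)
  a[3, ] <- 0; a[, 3] <- 0
  cm_a <- contact_matrix(g, a)
  cm_b <- contact_matrix(g, b)
  lr <- log_ratio_map(cm_a, cm_b, compare_config(sigma = 0))
  expect_true(all(is.finite(lr)))
  # row 3 of A was filled from row 2 (nearest unmasked)
  expect_equal(lr[3, 6], log2((a[2, 6] + 1) / (b[3, 6] + 1)))
})
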