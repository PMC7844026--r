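make_evm <- function(values, groups) {
  colnames(values) <- names(groups)
  ev_matrix(values, groups)
}

test_that("identical case and control columns yield no significant regions", {
  set.seed(1)
  base <- matrix(rnorm(200 * 4, 0, 0.3), 200, 4)
  vals <- cbind(base, base)
  groups <- setNames(rep(c("case", "ctrl"), each = 4),
                     paste0("s", 1:8))
  dr <- differential_compartments(make_evm(vals, groups), "case", "ctrl")
  expect_equal(sum(dr$significant), 0)
})

test_that("planted shifts are recovered with controlled false positives", {
  set.seed(11)
  n <- 1000
  shift_idx <- sort(sample(n, 50))   # 5% of regions
  ctrl <- matrix(rnorm(n * 5, 0, 0.05), n, 5)
  case <- matrix(rnorm(n * 5, 0, 0.05), n, 5)
  case[shift_idx, ] <- case[shift_idx, ] + 0.8
  vals <- cbind(case, ctrl)
  groups <- setNames(rep(c("case", "ctrl"), each = 5), paste0("s", 1:10))
  dr <- differential_compartments(make_evm(vals, groups), "case", "ctrl")
  sig <- as.integer(dr$region[dr$significant])
  expect_gte(mean(shift_idx %in% sig), 0.95)
  null_idx <- setdiff(seq_len(n), shift_idx)
  expect_lte(mean(null_idx %in% sig), 0.05)
  expect_true(all(dr$direction[match(shift_idx, as.integer(dr$region))] ==
                    "activation"))
})

test_that("regions with any missing value among compared samples are removed", {
  set.seed(2)
  vals <- matrix(rnorm(40, 0, 0.2), 10, 4)
  vals[3, 2] <- NA
  groups <- setNames(c("a", "a", "b", "b"), paste0("s", 1:4))
  dr <- differential_compartments(make_evm(vals, groups), "a", "b")
  expect_equal(nrow(dr), 9)
  expect_false("3" %in% dr$region)
  expect_equal(attr(dr, "n_removed"), 1)
})

test_that("the vectorized Welch test matches stats::t.test per region", {
  set.seed(3)
  vals <- matrix(rnorm(20 * 7, 0, 0.3), 20, 7)
  groups <- setNames(c(rep("a", 4), rep("b", 3)), paste0("s", 1:7))
  dr <- differential_compartments(make_evm(vals, groups), "a", "b")
  for (i in c(1, 7, 20)) {
    tt <- t.test(vals[i, 1:4], vals[i, 5:7])
    expect_equal(dr$t_statistic[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(dr$p_value[i], tt$p.value, tolerance = 1e-10)
  }
  # Student variant
  drs <- differential_compartments(make_evm(vals, groups), "a", "b",
                                   var_equal = TRUE)
  tt2 <- t.test(vals[5, 1:4], vals[5, 5:7], var.equal = TRUE)
  expect_equal(drs$p_value[5], tt2$p.value, tolerance = 1e-10)
  expect_error(differential_compartments(
    make_evm(vals[, 1:3], setNames(c("a", "a", "b"), paste0("s", 1:3))),
    "a", "b"), "at least 2 samples")
})

test_that("BH adjustment is monotone in p rank and order-invariant", {
  set.seed(4)
  vals <- matrix(rnorm(100 * 6, 0, 0.2), 100, 6,
                 dimnames = list(paste0("r", 1:100), NULL))
  vals[1:10, 1:3] <- vals[1:10, 1:3] + 0.6
  groups <- setNames(rep(c("a", "b"), each = 3), paste0("s", 1:6))
  dr <- differential_compartments(make_evm(vals, groups), "a", "b")
  o <- order(dr$p_value)
  expect_true(all(diff(dr$p_adjusted[o]) >= -1e-12))
  perm <- sample(nrow(vals))
  dr2 <- differential_compartments(make_evm(vals[perm, ], groups), "a", "b")
  expect_setequal(dr2$region[dr2$significant], dr$region[dr$significant])
})

test_that("specificity partition reproduces the case-control set arithmetic", {
  # 348 entity-A regions, 82 entity-B regions, 31 shared
  a <- paste0("r", 1:348)
  b <- c(paste0("r", 1:31), paste0("q", 1:51))
  sp <- specificity_partition(a, b)
  expect_equal(unname(sp$counts["common"]), 31)
  expect_equal(unname(sp$counts["a_specific"]), 317)
  expect_equal(unname(sp$counts["b_specific"]), 51)
  # inclusion-exclusion holds exactly
  expect_equal(unname(sp$counts["a"] + sp$counts["b"] - sp$counts["common"]),
               unname(sp$counts["union"]))

  sp2 <- specificity_partition(c("x", "y"), c("u", "v"))
  expect_equal(sp2$common, character(0))
  expect_setequal(sp2$a_specific, c("x", "y"))
  sp3 <- specificity_partition(a, a)
  expect_equal(unname(sp3$counts["a_specific"]), 0)
  expect_setequal(sp3$common, a)
})

test_that("subtype regions apply homogenization then the mean-difference rule", {
  vals <- rbind(
    c(0.1, 0.6, 0.0, 0.0),    # subtype1 range 0.5 -> dropped
    c(0.3, 0.3, -0.2, -0.2),  # |delta| 0.5 -> significant, gain subtype1
    c(0.1, 0.1, 0.0, 0.0),    # |delta| 0.1 -> retained, not significant
    c(-0.5, -0.5, 0.1, 0.1))  # delta -0.6 -> significant, gain subtype2
  groups <- setNames(c("u", "u", "m", "m"), paste0("s", 1:4))
  sr <- subtype_regions(make_evm(vals, groups), "u", "m")
  expect_equal(nrow(sr), 3)
  expect_false("1" %in% sr$region)
  expect_equal(attr(sr, "retention"), 0.75)
  expect_equal(sr$significant, c(TRUE, FALSE, TRUE))
  expect_equal(sr$gain[1], "u")
  expect_equal(sr$gain[3], "m")
})

test_that("planted subtype differences are recovered with few false calls", {
  cfg <- sim_config(chrom_sizes = c(chr1 = 100e6, chr2 = 100e6), seed = 5)
  coh <- simulate_cohort(cfg, cohort_design(), seed = 5)
  mcl <- coh$samples$sample[coh$samples$population == "MCL"]
  evm <- ev_matrix(coh$ev$values[, mcl],
                   setNames(coh$samples$subtype[match(mcl, coh$samples$sample)],
                            mcl))
  sr <- subtype_regions(evm, "cMCL", "nnMCL")
  planted <- as.character(coh$truth$disease$MCL$subtype_bins)
  sig <- sr$region[sr$significant]
  expect_gte(mean(planted %in% sig), 0.95)
  nulls <- setdiff(sr$region, planted)
  expect_lte(mean(nulls %in% sig), 0.01)
  # planted carrier subtype is reported as the gaining/losing side correctly
  expect_true(all(sr$gain[sr$significant] %in% c("cMCL", "nnMCL")))
})

test_that("chromosome enrichment p-values hit the floor for extreme clustering", {
  g <- bin_grid(c(chr1 = 5e6, chr2 = 5e6), 100000)
  regions <- 1:50   # all 50 on chr1
  res <- chromosome_enrichment_mc(regions, g, n_perm = 10000, seed = 1)
  expect_equal(res$p_value[res$chrom == "chr1"], 1 / 10001)
  expect_gte(min(res$p_value), 1 / 10001)
  expect_lte(max(res$p_value), 1)
  expect_error(chromosome_enrichment_mc(regions, g, n_perm = 0), "n_perm")
  expect_error(chromosome_enrichment_mc(1:200, g), "more regions")
})

test_that("Monte-Carlo draws are bit-for-bit reproducible given the seed", {
  g <- bin_grid(c(c1 = 3e6, c2 = 4e6, c3 = 3e6), 100000)
  r1 <- chromosome_enrichment_mc(c(2, 5, 9, 33, 71), g, n_perm = 500, seed = 42)
  r2 <- chromosome_enrichment_mc(c(2, 5, 9, 33, 71), g, n_perm = 500, seed = 42)
  expect_identical(r1, r2)
  r3 <- chromosome_enrichment_mc(c(2, 5, 9, 33, 71), g, n_perm = 500, seed = 43)
  expect_false(identical(r1$p_value, r3$p_value))
})

test_that("gene-overlap enrichment covers floor, saturation and planted cases", {
  g <- bin_grid(c(cT = 10e6), 100000)
  genes <- data.frame(gene_id = paste0("g", 1:50),
                      chrom = "cT",
                      start = seq(0, 98e5, by = 2e5),
                      end = seq(0, 98e5, by = 2e5) + 1e5)
  # saturated: regions cover the whole genome
  res_sat <- region_gene_enrichment_mc(1:100, genes, paste0("g", 1:50), g,
                                       n_perm = 200, seed = 1)
  expect_equal(res_sat$p_value, 1)
  # floor: no flagged gene overlaps the regions
  far <- data.frame(gene_id = "gx", chrom = "cT", start = 0, end = 1e5)
  res0 <- region_gene_enrichment_mc(50:60, far, "gx", g,
                                    n_perm = 200, seed = 1)
  expect_equal(res0$observed, 0)
  expect_equal(res0$p_value, 1)
  # planted enrichment: flagged genes concentrated in the region set
  set.seed(9)
  flagged <- paste0("g", 1:10)     # genes 1..10 live in bins 1..20
  res_enr <- region_gene_enrichment_mc(1:20, genes, flagged, g,
                                       n_perm = 1000, seed = 2)
  expect_lte(res_enr$p_value, 0.01)
  expect_error(region_gene_enrichment_mc(1:5, genes[0, ], "g1", g), "empty")
})

test_that("conserved regions are those with identical labels everywhere", {
  g <- toy_grid(5)
  c1 <- toy_calls(c("A", "I", "B", "A", NA), g)
  c2 <- toy_calls(c("A", "I", "A", "A", "B"), g)
  c3 <- toy_calls(c("A", "I", "B", "A", "B"), g)
  cons <- conserved_compartment_regions(list(c1, c2, c3))
  expect_equal(as.integer(cons), c(1, 2, 4))
  expect_equal(attr(cons, "labels"), c("A", "I", "A"))
  expect_equal(attr(cons, "non_conserved"), 3L)  # bin 5 has an NA, excluded
  expect_error(conserved_compartment_regions(list(c1)), ">= 2")
})

test_that("all-null cohorts stay below the nominal significance rate", {
  set.seed(77)
  rates <- vapply(1:25, function(s) {
    set.seed(s)
    vals <- matrix(rnorm(300 * 10, 0, 0.08), 300, 10)
    groups <- setNames(rep(c("a", "b"), each = 5), paste0("s", 1:10))
    dr <- differential_compartments(make_evm(vals, groups), "a", "b")
    mean(dr$significant)
  }, 0)
  expect_lte(mean(rates), 0.05)
})
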