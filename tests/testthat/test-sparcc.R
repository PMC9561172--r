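test_that("sparcc output is a valid, deterministic correlation matrix", {
  cfg <- sim_config(seed = 2, n_species = 12, n_samples = 60)
  ab <- simulate_abundance(cfg)
  r1 <- suppressWarnings(sparcc_correlations(ab$table, seed = 7))
  r2 <- suppressWarnings(sparcc_correlations(ab$table, seed = 7))
  expect_identical(r1, r2)
  expect_equal(r1, t(r1))
  expect_true(all(diag(r1) == 1))
  expect_true(all(r1 >= -1 & r1 <= 1))
  r3 <- suppressWarnings(sparcc_correlations(ab$table, seed = 8))
  expect_false(identical(r1, r3))
})

test_that("degenerate inputs are rejected, never silently estimated", {
  x <- matrix(rpois(20 * 3, 50), 20, 3)
  expect_error(sparcc_correlations(x), "at least 4 taxa")
  expect_error(sparcc_correlations(matrix(rpois(8 * 6, 50), 8, 6)), "at least 10 samples")
})

test_that("independent taxa yield near-zero correlations, a planted pair is recovered", {
  cfg0 <- sim_config(seed = 3, n_species = 25, n_samples = 120)
  ab0 <- simulate_abundance(cfg0)
  r0 <- suppressWarnings(sparcc_correlations(ab0$table, seed = 3))
  expect_lt(mean(abs(r0[upper.tri(r0)])), 0.1)

  cfg1 <- sim_config(seed = 3, n_species = 25, n_samples = 200,
                     planted_correlations = data.frame(taxon_i = 4, taxon_j = 9, rho = 0.8))
  ab1 <- simulate_abundance(cfg1)
  r1 <- suppressWarnings(sparcc_correlations(ab1$table, seed = 3))
  expect_lt(abs(r1[4, 9] - 0.8), 0.15)
})

test_that("estimates are stable under taxon reordering", {
  cfg <- sim_config(seed = 6, n_species = 15, n_samples = 150,
                    planted_correlations = data.frame(taxon_i = 1, taxon_j = 5, rho = 0.7))
  ab <- simulate_abundance(cfg)$table
  perm <- rev(colnames(ab))
  r <- suppressWarnings(sparcc_correlations(ab, seed = 4))
  rp <- suppressWarnings(sparcc_correlations(ab[, perm], seed = 4))[colnames(ab), colnames(ab)]
  # resampling noise differs under reordering, the estimates must agree closely
  expect_lt(max(abs(r - rp)), 0.15)
  expect_lt(abs(r["taxon_01", "taxon_05"] - rp["taxon_01", "taxon_05"]), 0.1)
})

test_that("permutation p-values are bounded, deterministic, and detect the planted pair", {
  cfg <- sim_config(seed = 5, n_species = 15, n_samples = 120,
                    planted_correlations = data.frame(taxon_i = 2, taxon_j = 11, rho = 0.8))
  ab <- simulate_abundance(cfg)$table
  rho <- suppressWarnings(sparcc_correlations(ab, seed = 5))
  p <- edge_pvalues(ab, rho, n_boot = 100, seed = 5)
  off <- p[upper.tri(p)]
  expect_true(all(off > 0 & off <= 1))
  expect_gte(min(off), 1 / 101)              # add-one estimator floor
  expect_true(all(is.na(diag(p))))
  expect_lt(p[2, 11], 0.05)
  expect_identical(p, edge_pvalues(ab, rho, n_boot = 100, seed = 5))
})

test_that("network building applies the median floor and the alpha cut", {
  cfg <- sim_config(seed = 12, n_species = 15, n_samples = 100,
                    planted_correlations = data.frame(taxon_i = 3, taxon_j = 8, rho = 0.85))
  ab <- simulate_abundance(cfg)$table
  rho <- suppressWarnings(sparcc_correlations(ab, seed = 12))
  p <- edge_pvalues(ab, rho, n_boot = 100, seed = 12)
  net <- build_network(rho, p, ab)
  # the forced rare taxon is dropped by the <= 0.1% median filter
  expect_true("taxon_15" %in% net$dropped_taxa)
  expect_true(any(net$edges$taxon_i == "taxon_03" & net$edges$taxon_j == "taxon_08"))
  expect_true(all(net$edges$p < 0.05))

  expect_equal(nrow(build_network(rho, p, ab, alpha = 0)$edges), 0L)

  # a taxon with median exactly at the floor is dropped (inclusive rule)
  ab2 <- cbind(ab, at_floor = 0.001)
  ab2 <- ab2 / rowSums(ab2)
  ab2[, "at_floor"] <- 0.001  # force the median exactly onto the boundary
  rho2 <- rbind(cbind(rho, at_floor = 0), at_floor = c(rep(0, ncol(rho)), 1))
  colnames(rho2) <- rownames(rho2) <- c(colnames(rho), "at_floor")
  p2 <- rbind(cbind(p, at_floor = 1), at_floor = rep(1, ncol(rho) + 1))
  dimnames(p2) <- dimnames(rho2)
  expect_true("at_floor" %in% build_network(rho2, p2, ab2)$dropped_taxa)
})

test_that("a correlation present in one stratum only appears in that stratum's network", {
  pc <- data.frame(taxon_i = 2, taxon_j = 9, rho = 0.85)
  with_pair <- simulate_abundance(sim_config(seed = 21, n_species = 15, n_samples = 100,
                                             planted_correlations = pc))$table
  without <- simulate_abundance(sim_config(seed = 22, n_species = 15, n_samples = 100))$table
  build_stratum <- function(ab, seed) {
    rho <- suppressWarnings(sparcc_correlations(ab, seed = seed))
    p <- edge_pvalues(ab, rho, n_boot = 100, seed = seed)
    build_network(rho, p, ab)
  }
  netA <- build_stratum(with_pair, 1)
  netB <- build_stratum(without, 1)
  has_edge <- function(net) any(net$edges$taxon_i == "taxon_02" & net$edges$taxon_j == "taxon_09")
  expect_true(has_edge(netA))
  expect_false(has_edge(netB))
})

test_that("network export writes a stable edge list and GraphML", {
  cfg <- sim_config(seed = 13, n_species = 10, n_samples = 60)
  ab <- simulate_abundance(cfg)$table
  rho <- suppressWarnings(sparcc_correlations(ab, seed = 13))
  p <- edge_pvalues(ab, rho, n_boot = 50, seed = 13)
  net <- build_network(rho, p, ab)
  tsv <- tempfile(fileext = ".tsv"); gml <- tempfile(fileext = ".graphml")
  write_network(net, tsv, gml)
  expect_true(file.exists(tsv) && file.exists(gml))
  expect_identical(names(utils::read.delim(tsv)), c("taxon_i", "taxon_j", "rho", "p"))
  expect_silent(xml2::read_xml(gml))
})
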