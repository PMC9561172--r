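test_that("config validation rejects degenerate divergences and correlations", {
  expect_error(sim_config(between_species_divergence = 0.3), "0, 0.25")
  expect_error(sim_config(between_species_divergence = 0), "0, 0.25")
  expect_error(sim_config(within_species_divergence = 0.1, between_species_divergence = 0.08))
  expect_error(sim_config(genome_length = 5000), "10,000")
  expect_error(sim_config(planted_correlations = data.frame(taxon_i = 1, taxon_j = 2, rho = 1)),
               "rho")
  expect_error(sim_config(n_species = 10,
                          planted_correlations = data.frame(taxon_i = c(1, 2), taxon_j = c(2, 3),
                                                            rho = c(0.5, 0.5))),
               "disjoint")
  expect_silent(sim_config(within_species_divergence = 0))
})

test_that("zero within-species divergence makes strains byte-identical", {
  cfg <- sim_config(seed = 5, n_species = 3, strains_per_species = 3,
                    genome_length = 12000, within_species_divergence = 0)
  g <- simulate_genomes(cfg)
  seqs <- as.character(g$mags)
  for (sp in split(g$truth$genome$genome_id, g$truth$genome$species_id)) {
    expect_length(unique(seqs[sp]), 1L)
  }
})

test_that("observed pairwise divergence matches the planted rate", {
  L <- 100000
  d <- 0.05
  cfg <- suppressWarnings(sim_config(seed = 21, n_species = 3, strains_per_species = 1,
                                     genome_length = L, between_species_divergence = d,
                                     within_species_divergence = 0))
  g <- suppressWarnings(simulate_genomes(cfg))
  seqs <- as.character(g$mags)
  tol <- 3 * sqrt(d * (1 - d) / L)
  for (pair in combn(names(seqs), 2, simplify = FALSE)) {
    obs <- true_divergence(seqs[pair[1]], seqs[pair[2]])
    expect_lt(abs(obs - d), tol)
  }
})

test_that("the generator is deterministic: same seed, byte-identical FASTA", {
  cfg <- sim_config(seed = 9, n_species = 2, strains_per_species = 2, genome_length = 11000)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_genome_fasta(simulate_genomes(cfg)$mags, f1)
  write_genome_fasta(simulate_genomes(cfg)$mags, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # and a different seed actually changes the sequences
  cfg2 <- sim_config(seed = 10, n_species = 2, strains_per_species = 2, genome_length = 11000)
  expect_false(identical(as.character(simulate_genomes(cfg2)$mags),
                         as.character(simulate_genomes(cfg)$mags)))
})

test_that("planted quality tiers round-trip through the tier classifier", {
  cfg <- sim_config(seed = 3)
  q <- simulate_quality_table(cfg, simulate_genomes(cfg)$truth)
  expect_identical(as.character(assign_quality_tier(q$records)), q$records$planted_tier)
  expect_identical(as.character(assign_quality_tier(q$boundary)), q$boundary$planted_tier)
  # the battery really spans all four tiers and both boundary directions
  expect_setequal(unique(q$records$planted_tier), c("low", "medium", "near_complete", "high"))
  expect_true(any(q$boundary$completeness == 90))
  expect_true(any(q$boundary$contamination == 10))
})

test_that("abundance rows close to 1 and planted correlations are present in the basis", {
  cfg <- sim_config(seed = 4, n_species = 20, n_samples = 200,
                    planted_correlations = data.frame(taxon_i = 2, taxon_j = 7, rho = 0.8))
  ab <- simulate_abundance(cfg)
  expect_lt(max(abs(rowSums(ab$table) - 1)), 1e-9)
  expect_lt(abs(cor(log(ab$basis[, 2]), log(ab$basis[, 7])) - 0.8), 0.1)
  # a taxon below the 0.1% median floor is always present to exercise the filter
  expect_true(any(apply(ab$table, 2, median) <= 0.001))

  ab0 <- simulate_abundance(sim_config(seed = 4, n_species = 20, n_samples = 200))
  C <- cor(log(ab0$basis))
  expect_lt(mean(abs(C[upper.tri(C)])), 0.1)
})

test_that("planted BGC cases carry the geometry they claim", {
  cfg <- sim_config(seed = 6)
  tabs <- simulate_bgc_tables(cfg)
  a <- tabs$caller_a; b <- tabs$caller_b
  # every planted overlap-removal record overlaps some caller-A record by >= 30%
  for (id in tabs$truth$bgc_id[tabs$truth$expected_reason == "overlap_dedup"]) {
    r <- b[b$bgc_id == id, ]
    same <- a[a$genome_id == r$genome_id & a$contig_id == r$contig_id, ]
    ov <- pmax(0, pmin(same$end, r$end) - pmax(same$start, r$start))
    expect_true(any(ov / (same$end - same$start) >= 0.3 | ov / (r$end - r$start) >= 0.3))
  }
  # full catalog cascade reproduces the planted retention truth
  cat <- bgc_catalog(a, b)
  retained <- tabs$truth$bgc_id %in% cat$catalog$bgc_id
  expect_identical(retained, tabs$truth$expected_retained)
  reasons <- setNames(cat$removed$reason, cat$removed$bgc_id)
  exp_rm <- tabs$truth[!tabs$truth$expected_retained, ]
  expect_identical(unname(reasons[exp_rm$bgc_id]), exp_rm$expected_reason)
  # empty caller-B input passes through untouched
  empty <- bgc_catalog(a, b[0, , drop = FALSE])
  expect_identical(sort(empty$catalog$bgc_id), sort(a$bgc_id[!grepl("_rm_", a$bgc_id)]))
})

test_that("planted AMP truth covers the vote grid and round-trips through the screen", {
  cfg <- sim_config(seed = 8)
  v <- simulate_votes(cfg)
  expect_equal(nrow(v$table), 16 * 2 * 4)
  expect_setequal(unique(nchar(v$table$sequence)), c(10L, 11L, 199L, 200L))
  out <- amp_screen(v$table)
  expect_identical(out$amp_call, v$truth$planted_amp)
  # maximal case positive, over-length case negative
  full <- v$table$p1 & v$table$p2 & v$table$p3 & v$table$p4 & v$table$transporter_in_bgc
  expect_true(all(out$amp_call[full & nchar(v$table$sequence) == 11]))
  expect_false(any(out$amp_call[nchar(v$table$sequence) == 200]))
})
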