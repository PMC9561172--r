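qrec <- function(comp, cont, r5 = TRUE, r16 = TRUE, r23 = TRUE, trna = 18)
  data.frame(completeness = comp, contamination = cont, rrna_5s = r5, rrna_16s = r16,
             rrna_23s = r23, n_unique_trnas = trna)

test_that("quality tiers follow the MIMAG rules with strict boundaries", {
  expect_identical(as.character(assign_quality_tier(qrec(92, 4))), "high")
  expect_identical(as.character(assign_quality_tier(qrec(92, 4, r16 = FALSE))), "near_complete")
  expect_identical(as.character(assign_quality_tier(qrec(92, 4, trna = 17))), "near_complete")
  expect_identical(as.character(assign_quality_tier(qrec(90, 4))), "medium")   # needs > 90
  expect_identical(as.character(assign_quality_tier(qrec(92, 5))), "medium")   # needs < 5
  expect_identical(as.character(assign_quality_tier(qrec(50, 10))), "low")     # both boundaries fail
  expect_error(assign_quality_tier(qrec(101, 4)), "completeness")
  expect_error(assign_quality_tier(qrec(90, -1)), "contamination")
})

test_that("tier classifier agrees with an exhaustive boundary-grid truth table", {
  grid <- expand.grid(comp = seq(45, 95, by = 5), cont = 0:12,
                      r5 = c(TRUE, FALSE), r16 = c(TRUE, FALSE), r23 = c(TRUE, FALSE),
                      trna = c(17L, 18L))
  got <- as.character(assign_quality_tier(
    qrec(grid$comp, grid$cont, grid$r5, grid$r16, grid$r23, grid$trna)))
  want <- mapply(oracle_tier, grid$comp, grid$cont, grid$r5, grid$r16, grid$r23, grid$trna)
  expect_identical(got, unname(want))
  # exactly one tier per record, and high implies the near-complete criteria
  expect_false(anyNA(got))
  expect_true(all(grid$cont[got == "high"] < 5 & grid$comp[got == "high"] > 90))
})

test_that("N50/L50 match hand enumeration and a brute-force oracle", {
  s <- compute_assembly_stats(c(5, 4, 3, 2, 1))
  expect_equal(s$n50, 4); expect_equal(s$l50, 2)
  expect_equal(compute_assembly_stats(1234)$n50, 1234)
  expect_equal(compute_assembly_stats(rep(7, 9))$n50, 7)
  expect_equal(compute_assembly_stats("300,100,200")$n50, 300)  # comma-string input
  expect_error(compute_assembly_stats(numeric(0)), "empty")
  expect_error(compute_assembly_stats(c(5, 0)), "positive")

  set.seed(20)
  for (i in 1:200) {
    len <- sample.int(5000, sample(1:30, 1), replace = TRUE)
    srt <- sort(len, decreasing = TRUE)
    # oracle: smallest rank whose cumulative sum covers half the total
    k <- min(which(cumsum(srt) >= sum(srt) / 2))
    s <- compute_assembly_stats(len)
    expect_identical(s$n50, srt[k])
    expect_identical(s$l50, k)
  }
})

test_that("reference matching takes the minimum within 0.05 inclusive, ties lexicographic", {
  expect_identical(match_reference(c(r1 = 0.03, r2 = 0.04))$ref_id, "r1")
  expect_identical(match_reference(c(r1 = 0.05, r2 = 0.07))$ref_id, "r1")  # inclusive
  expect_null(match_reference(c(r1 = 0.051, r2 = 0.2)))
  expect_identical(match_reference(c(rB = 0.03, rA = 0.03))$ref_id, "rA")  # tie-break
})

test_that("SLC typing and naming follow the isolate/uncultivated/novel rules", {
  meta <- data.frame(
    genome_id = c("iso1", "mag1", "mag2", "mag3"),
    source_db = c("GTDB", "UHGG", "UHGG", "SGB"),
    is_isolate = c(TRUE, FALSE, FALSE, FALSE),
    species_name = c("s__alpha", "s__beta", "s__beta", "s__gamma"),
    stringsAsFactors = FALSE
  )
  m_iso <- list(list(ref_id = "iso1", distance = 0.02), list(ref_id = "mag1", distance = 0.01))
  ann <- classify_slc(m_iso, meta, "SLC007")
  expect_identical(ann$slc_type, "isolate")
  expect_identical(ann$best_match$ref_id, "mag1")  # global minimum distance

  m_unc <- list(list(ref_id = "mag1", distance = 0.03), NULL,
                list(ref_id = "mag2", distance = 0.04))
  expect_identical(classify_slc(m_unc, meta, "SLC001")$slc_type, "uncultivated")
  expect_identical(classify_slc(m_unc, meta, "SLC001")$assigned_name, "s__beta")  # majority

  ann_novel <- classify_slc(list(NULL, NULL), meta, "SLC009")
  expect_identical(ann_novel$slc_type, "novel")
  expect_identical(ann_novel$assigned_name, "SLC009 sp.")
  expect_null(ann_novel$best_match)

  # member order does not change the outcome; GTDB-backed names win count ties
  meta2 <- rbind(meta, data.frame(genome_id = "iso2", source_db = "GTDB", is_isolate = FALSE,
                                  species_name = "s__zeta"))
  m_tie <- list(list(ref_id = "mag1", distance = 0.03), list(ref_id = "iso2", distance = 0.03))
  expect_identical(classify_slc(m_tie, meta2, "S")$assigned_name, "s__zeta")
  expect_identical(classify_slc(rev(m_tie), meta2, "S")$assigned_name, "s__zeta")
})

test_that("strain novelty: a strain cluster is novel iff it contains no reference", {
  ids <- c("q1", "q2", "q3", "ref1")
  d <- matrix(0.2, 4, 4, dimnames = list(ids, ids))
  d["q1", "ref1"] <- d["ref1", "q1"] <- 0.005   # q1 sits within 99% ANI of ref1
  d["q2", "q3"] <- d["q3", "q2"] <- 0.002       # q2/q3 form an isolated strain
  diag(d) <- 0
  nv <- classify_strain_novelty(c("q1", "q2", "q3"), "ref1", d)
  got <- setNames(nv$genomes$novel, nv$genomes$genome_id)
  expect_false(got[["q1"]])
  expect_true(got[["q2"]]); expect_true(got[["q3"]])
  expect_identical(nv$genomes$strain_cluster[2], nv$genomes$strain_cluster[3])
  # with no references at all, every strain is novel
  nv0 <- classify_strain_novelty(c("q1", "q2", "q3"), character(0), d)
  expect_true(all(nv0$genomes$novel))
})
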