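mkrec <- function(id, start, end, genes = 2L, caller = "B", contig = "c1",
                  known = TRUE, dom = 1L, raw = "bacteriocin")
  data.frame(bgc_id = id, genome_id = "g1", contig_id = contig, start = start, end = end,
             caller = caller, n_genes = genes, raw_class = raw, has_known_class = known,
             n_biosynthetic_domains = dom, stringsAsFactors = FALSE)

test_that("basic filter removes only single-gene records under 2 kbp (conjunction)", {
  recs <- rbind(mkrec("short1", 0, 1500, genes = 1L),
                mkrec("long1", 0, 2500, genes = 1L),
                mkrec("short2", 0, 1500, genes = 3L),
                mkrec("exact2k", 0, 2000, genes = 1L))
  f <- filter_basic(recs)
  expect_setequal(f$retained$bgc_id, c("long1", "short2", "exact2k"))
  expect_identical(f$removed$reason, "basic_filter")
  expect_equal(nrow(f$retained) + nrow(f$removed), nrow(recs))
  # disjunction mode drops records failing either condition (here: all of them)
  expect_equal(nrow(filter_basic(recs, mode = "or")$retained), 0L)
  ok <- mkrec("ok", 0, 2500, genes = 3L)
  expect_identical(filter_basic(ok, mode = "or")$retained$bgc_id, "ok")
  empty <- filter_basic(recs[0, , drop = FALSE])
  expect_equal(nrow(empty$retained), 0L)
})

test_that("deep-candidate filter needs a known class and at least one domain", {
  recs <- rbind(mkrec("ok", 0, 5000, dom = 2L),
                mkrec("nodom", 10000, 15000, dom = 0L),
                mkrec("noclass", 20000, 25000, known = FALSE, dom = 3L))
  f <- filter_deep_candidates(recs)
  expect_identical(f$retained$bgc_id, "ok")
  expect_setequal(f$removed$reason, c("domain_filter", "class_filter"))
  expect_error(filter_deep_candidates(mkrec("a", 0, 5000, caller = "A")), "caller-B")
})

test_that("overlap dedup applies >= 30% of either interval on the shared contig only", {
  prim <- rbind(mkrec("p1", 0, 1000, caller = "A"), mkrec("p2", 10000, 13000, caller = "A"))
  sec <- rbind(
    mkrec("s_at30", 700, 2000),          # ov 300 = 30% of primary -> removed
    mkrec("s_below", 710, 2000),         # ov 290 = 29% / 22.5% -> retained
    mkrec("s_otherctg", 700, 2000, contig = "c9"),
    mkrec("s_inside", 100, 400)          # 100% of secondary -> removed
  )
  f <- dedup_overlap(prim, sec)
  expect_setequal(f$retained$bgc_id, c("s_below", "s_otherctg"))
  expect_setequal(f$removed$bgc_id, c("s_at30", "s_inside"))
  # idempotent and order-independent
  again <- dedup_overlap(prim, f$retained)
  expect_identical(again$retained$bgc_id, f$retained$bgc_id)
  shuf <- dedup_overlap(prim[2:1, ], sec[c(3, 1, 4, 2), ])
  expect_setequal(shuf$retained$bgc_id, f$retained$bgc_id)
})

test_that("overlap dedup matches the brute-force all-pairs oracle on random sets", {
  set.seed(30)
  for (i in 1:100) {
    prim <- random_interval_set(sample(3:12, 1), "A", "P")
    sec <- random_interval_set(sample(3:12, 1), "B", "S")
    f <- dedup_overlap(prim, sec)
    expect_identical(sec$bgc_id %in% f$removed$bgc_id, oracle_dedup_drop(prim, sec))
  }
})

test_that("class unification maps caller vocabularies and flags hybrids", {
  expect_identical(unify_class("bacteriocin;T1PKS"), "hybrid")
  expect_identical(unify_class("lassopeptide"), "RiPP")
  expect_identical(unify_class("T1PKS;T2PKS"), "PKS")   # same unified class: not a hybrid
  expect_identical(unify_class("foo"), "other")
  expect_identical(unify_class(c("NRPS", "saccharide", "terpene")),
                   c("NRPS", "saccharide", "other"))
})

test_that("GCF representatives are the smallest members, ties lexicographic", {
  recs <- rbind(mkrec("b5k", 0, 5000), mkrec("b3k", 0, 3000), mkrec("b8k", 0, 8000),
                mkrec("a3k", 100, 3100), mkrec("solo", 0, 700))
  mem <- data.frame(gcf_id = c("G1", "G1", "G1", "G2", "G2", "G3"),
                    bgc_id = c("b5k", "b3k", "b8k", "b3k", "a3k", "solo"))
  reps <- pick_gcf_representatives(mem, recs)
  expect_identical(reps$representative[reps$gcf_id == "G1"], "b3k")
  expect_identical(reps$representative[reps$gcf_id == "G2"], "a3k")  # 3000 bp tie -> lexicographic
  expect_identical(reps$representative[reps$gcf_id == "G3"], "solo")
  expect_error(pick_gcf_representatives(data.frame(gcf_id = "G", bgc_id = "ghost"), recs),
               "unknown member")
})

test_that("BGC novelty follows the two-step 80% similarity rule", {
  hits <- data.frame(
    bgc_id = c("b1", "b2", "b2", "b3"),
    target_db = c("curated", "curated", "annotated_reference", "annotated_reference"),
    percent_similarity = c(100, 79.9, 85, 20))
  cls <- classify_novelty(hits, bgc_ids = c("b1", "b2", "b3", "b4"))
  expect_identical(unname(cls), c("known_curated", "known_annotated", "novel", "novel"))
  expect_error(classify_novelty(data.frame(bgc_id = "x", target_db = "curated",
                                           percent_similarity = 120)), "0, 100")
})

test_that("the catalog conserves records and its count is the sum of both callers", {
  cfg <- sim_config(seed = 15)
  tabs <- simulate_bgc_tables(cfg)
  cat <- bgc_catalog(tabs$caller_a, tabs$caller_b)
  expect_equal(nrow(cat$catalog) + nrow(cat$removed),
               nrow(tabs$caller_a) + nrow(tabs$caller_b))
  expect_equal(unname(cat$counts["catalog"]),
               unname(cat$counts["a_retained"] + cat$counts["b_retained"]))
  expect_true(all(cat$catalog$unified_class %in%
                  c("RiPP", "NRPS", "PKS", "saccharide", "other", "hybrid")))
  expect_true(all(c("bgc_id", "reason") %in% names(cat$removed)))
})
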