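#' Validate a BGC record table
#'
#' Records are genomic intervals in 0-based half-open coordinates
#' (`0 <= start < end`) with a caller attribution (`"A"`: comparative
#' caller, `"B"`: deep-learning caller), a gene count, the caller's raw
#' product class string, a known-class flag and a biosynthetic-domain count.
#'
#' @param records data.frame of BGC records.
#' @return the validated records (invisibly usable).
#' @export
validate_bgc_records <- function(records) {
  req <- c("bgc_id", "genome_id", "contig_id", "start", "end", "caller", "n_genes")
  if (!all(req %in% names(records)))
    stop("missing columns: ", paste(setdiff(req, names(records)), collapse = ", "))
  if (any(records$start < 0 | records$start >= records$end))
    stop("intervals must satisfy 0 <= start < end (0-based half-open)")
  if (any(records$n_genes < 1)) stop("n_genes must be >= 1")
  if (anyDuplicated(records$bgc_id)) stop("duplicate bgc ids")
  records
}

#' @noRd
bgc_length <- function(records) records$end - records$start

#' Basic BGC filter: single-gene short records
#'
#' Removes records that have exactly one identified gene AND span less than
#' 2 kbp (the literal conjunction; set `mode = "or"` to drop records failing
#' either condition instead).
#'
#' @param records BGC record table (see [validate_bgc_records()]).
#' @param min_length length threshold in bp (default 2000).
#' @param mode `"and"` (conjunction, default) or `"or"`.
#' @return list with `retained` and `removed` (with a `reason` column).
#' @export
filter_basic <- function(records, min_length = 2000L, mode = c("and", "or")) {
  mode <- match.arg(mode)
  validate_bgc_records(records)
  single <- records$n_genes == 1L
  short <- bgc_length(records) < min_length
  drop <- if (mode == "and") single & short else single | short
  removed <- records[drop, , drop = FALSE]
  if (nrow(removed)) removed$reason <- "basic_filter"
  list(retained = records[!drop, , drop = FALSE], removed = removed)
}

#' Filter deep-learning BGC candidates
#'
#' Caller-B candidates are retained only when they carry a known product
#' class and contain at least one known biosynthetic protein domain.
#'
#' @param records caller-B records with `has_known_class` and
#'   `n_biosynthetic_domains`.
#' @return list with `retained` and `removed` (with a `reason` column).
#' @export
filter_deep_candidates <- function(records) {
  validate_bgc_records(records)
  if (any(records$caller != "B"))
    stop("filter_deep_candidates applies to caller-B records only")
  keep <- records$has_known_class & records$n_biosynthetic_domains >= 1L
  removed <- records[!keep, , drop = FALSE]
  if (nrow(removed))
    removed$reason <- ifelse(!removed$has_known_class, "class_filter", "domain_filter")
  list(retained = records[keep, , drop = FALSE], removed = removed)
}

#' Remove secondary BGC calls overlapping primary calls
#'
#' A secondary (caller-B) record is removed when, against any primary
#' (caller-A) record on the same genome and contig, the overlap length
#' reaches at least 30% of either interval's length (inclusive threshold;
#' strand is ignored, the calls are regions). The operation is idempotent
#' and independent of record order.
#'
#' @param primary caller-A records.
#' @param secondary caller-B records.
#' @param min_overlap overlap fraction threshold (default 0.30).
#' @return list with `retained` and `removed` secondary records.
#' @export
dedup_overlap <- function(primary, secondary, min_overlap = 0.30) {
  if (nrow(secondary) == 0L)
    return(list(retained = secondary, removed = secondary))
  if (nrow(primary) == 0L) {
    removed <- secondary[0, , drop = FALSE]
    return(list(retained = secondary, removed = removed))
  }
  key_p <- paste(primary$genome_id, primary$contig_id)
  key_s <- paste(secondary$genome_id, secondary$contig_id)
  len_p <- bgc_length(primary)
  len_s <- bgc_length(secondary)
  drop <- vapply(seq_len(nrow(secondary)), function(i) {
    j <- which(key_p == key_s[i])
    if (length(j) == 0L) return(FALSE)
    ov <- pmax(0, pmin(primary$end[j], secondary$end[i]) - pmax(primary$start[j], secondary$start[i]))
    any(ov / len_p[j] >= min_overlap | ov / len_s[i] >= min_overlap)
  }, logical(1))
  removed <- secondary[drop, , drop = FALSE]
  if (nrow(removed)) removed$reason <- "overlap_dedup"
  list(retained = secondary[!drop, , drop = FALSE], removed = removed)
}

#' Default raw-to-unified product class mapping
#'
#' Editable lookup covering the product-class vocabularies of both callers;
#' raw labels not in the table map to `"other"`.
#'
#' @return named character vector (raw label -> unified class).
#' @export
default_class_map <- function() {
  c(
    bacteriocin = "RiPP", lanthipeptide = "RiPP", lassopeptide = "RiPP",
    sactipeptide = "RiPP", thiopeptide = "RiPP", RiPP = "RiPP", LAP = "RiPP",
    `RiPP-like` = "RiPP", microviridin = "RiPP", cyanobactin = "RiPP",
    T1PKS = "PKS", T2PKS = "PKS", T3PKS = "PKS", `transAT-PKS` = "PKS",
    Polyketide = "PKS", PKS = "PKS", `PKS-like` = "PKS", hglE.KS = "PKS",
    NRPS = "NRPS", `NRPS-like` = "NRPS", NRP = "NRPS",
    saccharide = "saccharide", Saccharide = "saccharide", oligosaccharide = "saccharide",
    amglyccycl = "saccharide",
    terpene = "other", arylpolyene = "other", phosphonate = "other",
    betalactone = "other", siderophore = "other", ectoine = "other",
    Other = "other", other = "other"
  )
}

#' Unify raw product class labels
#'
#' Raw labels are `;`-separated lists of caller classes. Each part is mapped
#' through the class table (unmapped parts become `"other"`); labels whose
#' parts map to two or more distinct unified classes are `"hybrid"`.
#'
#' @param raw_class character vector of raw labels.
#' @param mapping named character vector, see [default_class_map()].
#' @return character vector over
#'   `{RiPP, NRPS, PKS, saccharide, other, hybrid}`.
#' @export
unify_class <- function(raw_class, mapping = default_class_map()) {
  vapply(raw_class, function(lab) {
    if (is.na(lab) || !nzchar(lab)) return("other")
    parts <- trimws(strsplit(lab, ";", fixed = TRUE)[[1]])
    uni <- unique(unname(ifelse(parts %in% names(mapping), mapping[parts], "other")))
    if (length(uni) > 1L) "hybrid" else uni
  }, character(1), USE.NAMES = FALSE)
}

#' Pick gene cluster family representatives
#'
#' The representative of a gene cluster family (GCF) is its smallest member
#' BGC; exact length ties are broken by lexicographically smallest bgc id.
#'
#' @param membership data.frame with `gcf_id`, `bgc_id`.
#' @param records BGC record table containing every member.
#' @return data.frame with `gcf_id`, `representative`, `n_members`,
#'   `unified_class` (the representative's class when present in `records`).
#' @export
pick_gcf_representatives <- function(membership, records) {
  missing_ids <- setdiff(membership$bgc_id, records$bgc_id)
  if (length(missing_ids))
    stop("unknown member ids: ", paste(missing_ids, collapse = ", "))
  rows <- records[match(membership$bgc_id, records$bgc_id), , drop = FALSE]
  rows$gcf_id <- membership$gcf_id
  rows$length <- bgc_length(rows)
  out <- do.call(rbind, lapply(split(rows, rows$gcf_id), function(g) {
    g <- g[order(g$length, g$bgc_id), , drop = FALSE]
    data.frame(gcf_id = g$gcf_id[1], representative = g$bgc_id[1], n_members = nrow(g),
               unified_class = if ("unified_class" %in% names(g)) g$unified_class[1] else NA_character_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$gcf_id), , drop = FALSE]
}

#' Classify BGC novelty from similarity hits
#'
#' Two-step rule: a BGC is `known_curated` when any hit against the curated
#' databases reaches the similarity threshold, otherwise `known_annotated`
#' when any hit against the annotated reference collection reaches it,
#' otherwise `novel` (including BGCs with no hits at all).
#'
#' @param hits data.frame with `bgc_id`, `target_db` (`"curated"` or
#'   `"annotated_reference"`), `percent_similarity` in `[0, 100]`.
#' @param bgc_ids ids to classify; defaults to those present in `hits`.
#' @param threshold percent similarity threshold (default 80).
#' @return named character vector over
#'   `{novel, known_curated, known_annotated}`.
#' @export
classify_novelty <- function(hits, bgc_ids = NULL, threshold = 80) {
  if (nrow(hits) && any(hits$percent_similarity < 0 | hits$percent_similarity > 100))
    stop("percent_similarity must lie in [0, 100]")
  bgc_ids <- bgc_ids %||% sort(unique(hits$bgc_id))
  vapply(bgc_ids, function(id) {
    h <- hits[hits$bgc_id == id, , drop = FALSE]
    if (any(h$target_db == "curated" & h$percent_similarity >= threshold)) "known_curated"
    else if (any(h$target_db == "annotated_reference" & h$percent_similarity >= threshold)) "known_annotated"
    else "novel"
  }, character(1))
}

#' Curate raw BGC calls from two callers into a catalog
#'
#' Applies the full curation cascade: the basic single-gene/short filter to
#' both callers, the known-class and biosynthetic-domain filters to the
#' deep-learning caller, overlap deduplication of caller-B records against
#' the retained caller-A records, and product-class unification. The final
#' catalog is the union of retained caller-A and caller-B records, so
#' `nrow(catalog) = |A after basic filter| + |B after all filters and
#' dedup|`, and every input record is accounted for in either `catalog` or
#' `removed`.
#'
#' @param caller_a,caller_b raw record tables from the two callers.
#' @param class_map raw-to-unified class mapping.
#' @param basic_mode passed to [filter_basic()].
#' @return list with `catalog` (records + `unified_class`), `removed`
#'   (records + `reason`) and `counts` (per-stage bookkeeping).
#' @export
bgc_catalog <- function(caller_a, caller_b, class_map = default_class_map(),
                        basic_mode = "and") {
  fa <- filter_basic(caller_a, mode = basic_mode)
  fb1 <- filter_basic(caller_b, mode = basic_mode)
  fb2 <- filter_deep_candidates(fb1$retained)
  fb3 <- dedup_overlap(fa$retained, fb2$retained)
  catalog <- rbind(fa$retained, fb3$retained)
  catalog$unified_class <- unify_class(catalog$raw_class, class_map)
  removed <- rbind(fa$removed, fb1$removed, fb2$removed, fb3$removed)
  list(catalog = catalog, removed = removed,
       counts = c(a_in = nrow(caller_a), b_in = nrow(caller_b),
                  a_retained = nrow(fa$retained), b_retained = nrow(fb3$retained),
                  catalog = nrow(catalog), removed = nrow(removed)))
}
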