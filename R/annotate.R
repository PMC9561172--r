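#' Assign MIMAG quality tiers
#'
#' Tiers follow the MIMAG-style rules used for MAG catalogs, with all
#' percentage inequalities strict as conventionally printed:
#' \describe{
#'   \item{high}{contamination < 5, completeness > 90, complete 5S, 16S and
#'     23S rRNA genes, and at least 18 unique tRNAs.}
#'   \item{near_complete}{contamination < 5 and completeness > 90, but
#'     missing the rRNA/tRNA requirements for high.}
#'   \item{medium}{contamination < 10 and completeness > 50.}
#'   \item{low}{everything else; low-quality bins are conventionally removed
#'     before clustering.}
#' }
#'
#' @param records data.frame with columns `completeness`, `contamination`
#'   (percent, in `[0, 100]`), `rrna_5s`, `rrna_16s`, `rrna_23s` (logical
#'   complete-gene flags) and `n_unique_trnas`.
#' @return factor of tiers (`low < medium < near_complete < high`), one per
#'   row.
#' @export
assign_quality_tier <- function(records) {
  req <- c("completeness", "contamination", "rrna_5s", "rrna_16s", "rrna_23s", "n_unique_trnas")
  if (!all(req %in% names(records)))
    stop("missing columns: ", paste(setdiff(req, names(records)), collapse = ", "))
  comp <- records$completeness; cont <- records$contamination
  if (any(!is.finite(comp) | comp < 0 | comp > 100)) stop("completeness must lie in [0, 100]")
  if (any(!is.finite(cont) | cont < 0 | cont > 100)) stop("contamination must lie in [0, 100]")
  if (any(records$n_unique_trnas < 0)) stop("n_unique_trnas must be >= 0")
  nc <- cont < 5 & comp > 90
  high <- nc & records$rrna_5s & records$rrna_16s & records$rrna_23s & records$n_unique_trnas >= 18
  med <- cont < 10 & comp > 50
  tier <- ifelse(high, "high", ifelse(nc, "near_complete", ifelse(med, "medium", "low")))
  factor(tier, levels = c("low", "medium", "near_complete", "high"), ordered = TRUE)
}

#' Assembly contiguity statistics
#'
#' N50 is the length of the first contig, in decreasing length order, at
#' which the cumulative length reaches half the assembly total; L50 is its
#' rank.
#'
#' @param contig_lengths positive contig lengths in bp (any order), or a
#'   comma-separated string of lengths.
#' @return list with `n50`, `l50`, `total_bp`, `n_contigs`.
#' @export
compute_assembly_stats <- function(contig_lengths) {
  if (is.character(contig_lengths))
    contig_lengths <- as.numeric(strsplit(contig_lengths, ",", fixed = TRUE)[[1]])
  if (length(contig_lengths) == 0L) stop("empty contig length list")
  if (any(!is.finite(contig_lengths) | contig_lengths <= 0)) stop("contig lengths must be positive")
  len <- sort(contig_lengths, decreasing = TRUE)
  total <- sum(len)
  l50 <- which(cumsum(len) >= total / 2)[1]
  list(n50 = len[l50], l50 = l50, total_bp = total, n_contigs = length(len))
}

#' Best reference match for a query genome
#'
#' Among references within the match threshold (Mash distance <= 0.05,
#' i.e. >= 95% ANI, inclusive as conventionally stated), returns the
#' minimum-distance match; exact distance ties are broken by
#' lexicographically smallest reference id. Returns `NULL` when no reference
#' qualifies.
#'
#' @param query a `genome_sketch`, or a named numeric vector of distances to
#'   the references.
#' @param references list of reference `genome_sketch` objects (ignored when
#'   `query` is a distance vector).
#' @param max_distance inclusive match threshold.
#' @return list with `ref_id` and `distance`, or `NULL`.
#' @export
match_reference <- function(query, references = NULL, max_distance = 0.05) {
  if (inherits(query, "genome_sketch")) {
    if (length(references) == 0L) return(NULL)
    d <- vapply(references, function(r) mash_distance(jaccard_estimate(query, r), query$k),
                numeric(1))
    names(d) <- vapply(references, function(r) r$genome_id, character(1))
  } else {
    d <- query
    if (is.null(names(d))) stop("distance vector must be named by reference id")
  }
  ok <- which(d <= max_distance)
  if (length(ok) == 0L) return(NULL)
  d <- d[ok]
  best <- names(d)[d == min(d)]
  ref <- sort(best)[1]
  list(ref_id = ref, distance = unname(d[ref]))
}

#' Type and name a species-level cluster from its members' reference matches
#'
#' A species-level cluster (SLC) is typed \emph{isolate} when any member
#' matches a reference flagged as an isolate, \emph{uncultivated} when
#' members match references but none is an isolate, and \emph{novel} when no
#' member matches anything. The assigned name is a majority vote over the
#' matched references' species names; count ties are broken in favour of
#' names backed by a GTDB reference, then lexicographically. Novel clusters
#' receive the placeholder `"<slc_id> sp."`.
#'
#' @param matches list of per-member results from [match_reference()]
#'   (`NULL` entries for members without a match).
#' @param ref_meta data.frame with `genome_id`, `source_db`, `is_isolate`,
#'   `species_name` for the reference collection.
#' @param slc_id cluster id, used for the placeholder name.
#' @return list with `slc_id`, `slc_type`, `assigned_name`, `best_match`
#'   (the minimum-distance match over all members, or `NULL`).
#' @export
classify_slc <- function(matches, ref_meta, slc_id = "SLC001") {
  hits <- Filter(Negate(is.null), matches)
  if (length(hits) == 0L)
    return(list(slc_id = slc_id, slc_type = "novel",
                assigned_name = sprintf("%s sp.", slc_id), best_match = NULL))
  ref_ids <- vapply(hits, `[[`, character(1), "ref_id")
  dists <- vapply(hits, `[[`, numeric(1), "distance")
  meta <- ref_meta[match(ref_ids, ref_meta$genome_id), , drop = FALSE]
  if (anyNA(meta$genome_id)) stop("matched reference missing from ref_meta")

  slc_type <- if (any(meta$is_isolate)) "isolate" else "uncultivated"

  counts <- table(meta$species_name)
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1L) {
    gtdb_backed <- unique(meta$species_name[meta$source_db == "GTDB"])
    if (any(top %in% gtdb_backed)) top <- top[top %in% gtdb_backed]
  }
  assigned <- sort(top)[1]

  best_i <- which(dists == min(dists))
  best_i <- best_i[order(ref_ids[best_i])][1]
  list(slc_id = slc_id, slc_type = slc_type, assigned_name = assigned,
       best_match = list(ref_id = ref_ids[best_i], distance = dists[best_i]))
}

#' Strain-level novelty against matched reference genomes
#'
#' Queries and the reference genomes of their matched species are clustered
#' jointly by single linkage at the strain threshold (99% ANI); a strain
#' cluster is novel exactly when it contains no reference genome — i.e. the
#' query strains sit below 99% ANI to every reference.
#'
#' @param query_ids,ref_ids genome ids of the queries and the (species-
#'   matched) references present in `D`.
#' @param D distance matrix covering queries and references jointly.
#' @param threshold strain merge threshold (default 0.01).
#' @return list with `genomes` (data.frame `genome_id`, `strain_cluster`,
#'   `novel` for the queries) and `clusters` (per-cluster novelty flags).
#' @export
classify_strain_novelty <- function(query_ids, ref_ids, D, threshold = 0.01) {
  d <- as_dist_matrix(D)
  all_ids <- c(query_ids, ref_ids)
  if (!all(all_ids %in% rownames(d))) stop("ids missing from distance matrix")
  if (length(ref_ids) == 0L) {
    sub <- d[query_ids, query_ids, drop = FALSE]
  } else {
    sub <- d[all_ids, all_ids, drop = FALSE]
  }
  comp <- threshold_components(sub, threshold)
  groups <- lapply(split(rownames(sub), comp), sort)
  groups <- groups[order(vapply(groups, min, character(1)))]
  names(groups) <- sprintf("STC%03d", seq_along(groups))
  novel_cluster <- vapply(groups, function(m) !any(m %in% ref_ids), logical(1))
  membership <- setNames(rep(names(groups), lengths(groups)), unlist(groups, use.names = FALSE))
  genomes <- data.frame(genome_id = query_ids,
                        strain_cluster = unname(membership[query_ids]),
                        novel = unname(novel_cluster[membership[query_ids]]),
                        stringsAsFactors = FALSE)
  list(genomes = genomes,
       clusters = data.frame(strain_cluster = names(groups), novel = unname(novel_cluster),
                             n_members = unname(lengths(groups)), stringsAsFactors = FALSE))
}
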