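#' Run the full catalog pipeline on a synthetic community
#'
#' Generates a synthetic community and pushes it through every stage:
#' MIMAG quality tiering (low-quality bins are removed before clustering),
#' MinHash sketching and Mash distances, species- and strain-level
#' single-linkage dereplication with eigenvector-centrality representatives,
#' reference matching with species typing/naming and strain novelty, BGC
#' catalog curation, AMP screening, incidence rarefaction and the SparCC
#' co-occurrence network. All randomness derives from `config$seed`; the
#' same seed reproduces every output byte-identically.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, every table, FASTA and the
#'   truth file are written there.
#' @param k,s sketch parameters (defaults 21, 10000).
#' @param species_threshold,strain_threshold Mash-distance cutoffs for the
#'   species (0.05 = 95% ANI) and strain (0.01 = 99% ANI) levels.
#' @param match_threshold reference match cutoff (0.05, inclusive).
#' @param quality_filter drop low-tier genomes before clustering?
#' @param n_boot permutation replicates for network p-values. The default
#'   200 keeps a full run to a few minutes; raise it for final analyses.
#' @param endpoint rarefaction extrapolation endpoint (default 300).
#' @return list with the simulated community (`sim`), per-stage results and,
#'   when `out_dir` is given, the written file paths (`files`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL, k = 21L, s = 10000L,
                         species_threshold = 0.05, strain_threshold = 0.01,
                         match_threshold = 0.05, quality_filter = TRUE,
                         n_boot = 200L, endpoint = 300L) {
  sim <- simulate_community(config)

  ## quality tiers + assembly stats
  qrec <- sim$quality$records
  qrec$tier <- as.character(assign_quality_tier(qrec))
  stats <- lapply(qrec$contig_lengths, compute_assembly_stats)
  qrec$n50 <- vapply(stats, `[[`, numeric(1), "n50")
  qrec$l50 <- vapply(stats, `[[`, numeric(1), "l50")
  qrec$total_bp <- vapply(stats, `[[`, numeric(1), "total_bp")
  kept_ids <- if (quality_filter) qrec$genome_id[qrec$tier != "low"] else qrec$genome_id

  ## sketches and joint distances (queries + references)
  mags <- sim$genomes$mags[kept_ids]
  refs <- sim$genomes$references
  sk <- c(
    lapply(names(mags), function(id) build_sketch(as.character(mags[[id]]), k, s, genome_id = id)),
    lapply(names(refs), function(id) build_sketch(as.character(refs[[id]]), k, s, genome_id = id))
  )
  D_all <- pairwise_distances(sk)
  d <- D_all$d
  ref_ids <- names(refs)
  d_mag <- d[kept_ids, kept_ids, drop = FALSE]

  ## dereplication
  species <- single_linkage_cluster(d_mag, species_threshold, level = "species")
  strains <- refine_to_strains(species, d_mag, strain_threshold)

  ## reference matching, species typing, strain novelty
  ref_meta <- sim$genomes$truth$reference
  matches <- lapply(kept_ids, function(id) match_reference(d[id, ref_ids], max_distance = match_threshold))
  names(matches) <- kept_ids
  annotation <- do.call(rbind, lapply(names(species$clusters), function(slc) {
    members <- species$clusters[[slc]]
    ann <- classify_slc(matches[members], ref_meta, slc)
    data.frame(slc_id = slc, slc_type = ann$slc_type, assigned_name = ann$assigned_name,
               best_match_id = ann$best_match$ref_id %||% NA_character_,
               best_match_distance = ann$best_match$distance %||% NA_real_,
               n_members = length(members),
               representative = species$representatives[[slc]],
               stringsAsFactors = FALSE)
  }))
  novelty <- do.call(rbind, lapply(names(species$clusters), function(slc) {
    members <- species$clusters[[slc]]
    slc_refs <- unique(unlist(lapply(matches[members], function(m) m$ref_id)))
    nv <- classify_strain_novelty(members, slc_refs %||% character(0), d, strain_threshold)
    cbind(slc_id = slc, nv$genomes)
  }))

  ## BGC catalog and AMP screen
  bgc <- bgc_catalog(sim$bgc$caller_a, sim$bgc$caller_b)
  amp <- amp_screen(sim$votes$table)

  ## ecology: rarefaction + co-occurrence network
  abund <- sim$abundance$table
  inc <- to_incidence(abund)
  curve <- rarefaction_curve(inc, endpoint = endpoint)
  coverage <- coverage_at(curve, inc$T)
  rho <- sparcc_correlations(abund, seed = config$seed)
  pmat <- edge_pvalues(abund, rho, n_boot = n_boot, seed = config$seed)
  network <- build_network(rho, pmat, abund)

  result <- list(
    config = config, sim = sim, quality = qrec, kept_ids = kept_ids,
    distances = D_all, species = species, strains = strains,
    matches = matches, annotation = annotation, strain_novelty = novelty,
    bgc = bgc, amp = amp,
    incidence = inc, rarefaction = curve, coverage = coverage,
    rho = rho, pvalues = pmat, network = network
  )
  if (!is.null(out_dir)) result$files <- write_pipeline_outputs(result, out_dir)
  result
}

#' @noRd
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(file.path(out_dir, "genomes"), recursive = TRUE, showWarnings = FALSE)
  sim <- result$sim
  files <- character(0)
  wf <- function(name, writer) { path <- file.path(out_dir, name); writer(path); files[[name]] <<- path }

  for (id in names(sim$genomes$mags))
    write_genome_fasta(sim$genomes$mags[id], file.path(out_dir, "genomes", paste0(id, ".fasta")))
  wf("references.fasta", function(p) write_genome_fasta(sim$genomes$references, p))
  wf("quality.tsv", function(p) write_tsv_file(result$quality, p))
  wf("distances.tsv", function(p) write_tsv_file(distance_table(result$distances), p))
  wf("membership.tsv", function(p) write_tsv_file(membership_table(result$species, result$strains), p))
  wf("annotation.tsv", function(p) write_tsv_file(result$annotation, p))
  wf("strain_novelty.tsv", function(p) write_tsv_file(result$strain_novelty, p))
  wf("bgc_catalog.tsv", function(p) write_tsv_file(result$bgc$catalog, p))
  wf("bgc_removed.tsv", function(p) write_tsv_file(result$bgc$removed, p))
  wf("amp_calls.tsv", function(p) write_tsv_file(result$amp, p))
  wf("abundance.tsv", function(p) write_abundance_tsv(sim$abundance$table, p))
  wf("rarefaction.tsv", function(p) write_tsv_file(result$rarefaction, p))
  wf("network_edges.tsv", function(p) write_network(result$network, p,
                                                    file.path(out_dir, "network.graphml")))
  wf("truth.json", function(p) jsonlite::write_json(list(
    genome = sim$genomes$truth$genome,
    reference = sim$genomes$truth$reference,
    species = sim$genomes$truth$species,
    bgc = sim$bgc$truth,
    peptides = sim$votes$truth,
    planted_correlations = sim$abundance$planted
  ), p, auto_unbox = TRUE, digits = NA))
  files
}
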