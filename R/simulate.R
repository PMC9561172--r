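#' Configuration for the synthetic community generator
#'
#' Defines the planted structure of a synthetic MAG community: species
#' separated by a chosen pairwise nucleotide divergence, strains nested within
#' species, a partially overlapping synthetic reference set, sample-wise
#' compositional abundances with optional planted correlations, and per-genome
#' quality metrics spanning every MIMAG tier boundary.
#'
#' Divergence parameters are *expected pairwise* substitution fractions
#' between sibling lineages: each sibling branch mutates independently at the
#' rate `r` solving `2r - (4/3)r^2 = d`, so that the expected pairwise
#' mismatch fraction (and hence `1 - ANI`) equals `d` exactly under the
#' substitution-only model.
#'
#' @param seed integer; fully determines every generated artifact.
#' @param n_species number of planted species.
#' @param strains_per_species number of strain lineages per species.
#' @param genome_length genome length in bp (single contig unless fragmented
#'   downstream); minimum 10,000.
#' @param between_species_divergence expected pairwise divergence between two
#'   species of the community, in `(0, 0.25)`.
#' @param within_species_divergence expected pairwise divergence between two
#'   strains of one species, in `[0, between_species_divergence)`.
#' @param n_samples number of metagenome samples for the abundance table.
#' @param abundance_log_sd per-taxon log-scale standard deviation of basis
#'   abundances.
#' @param planted_correlations data.frame (or list of 3-element vectors) with
#'   columns `taxon_i`, `taxon_j` (1-based taxon indices) and `rho`, the basis
#'   log-scale correlation planted between the pair.
#' @param n_reference_genomes size of the synthetic reference collection;
#'   defaults to the number of covered species plus two unrelated decoys.
#' @param reference_overlap_fraction fraction of planted species that also
#'   have a genome in the synthetic reference set.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_species = 20L,
                       strains_per_species = 3L,
                       genome_length = 100000L,
                       between_species_divergence = 0.08,
                       within_species_divergence = 0.005,
                       n_samples = 100L,
                       abundance_log_sd = 1,
                       planted_correlations = NULL,
                       n_reference_genomes = NULL,
                       reference_overlap_fraction = 0.5) {
  assert_scalar_number(seed, "seed")
  assert_scalar_number(genome_length, "genome_length")
  if (genome_length < 10000) stop("genome_length must be >= 10,000 bp")
  if (n_species < 1 || strains_per_species < 1) stop("need at least one species and one strain")
  d_b <- between_species_divergence
  d_w <- within_species_divergence
  if (!is.finite(d_b) || d_b <= 0 || d_b >= 0.25)
    stop("between_species_divergence must lie in (0, 0.25): the Jukes-Cantor model saturates beyond")
  if (!is.finite(d_w) || d_w < 0 || d_w >= d_b)
    stop("within_species_divergence must lie in [0, between_species_divergence)")
  if (reference_overlap_fraction < 0 || reference_overlap_fraction > 1)
    stop("reference_overlap_fraction must lie in [0, 1]")
  if (n_samples < 2) stop("n_samples must be >= 2")
  pc <- normalize_planted_correlations(planted_correlations, n_species)
  n_cov <- round(reference_overlap_fraction * n_species)
  n_ref <- as.integer(n_reference_genomes %||% (n_cov + 2L))
  structure(list(
    seed = as.integer(seed),
    n_species = as.integer(n_species),
    strains_per_species = as.integer(strains_per_species),
    genome_length = as.integer(genome_length),
    between_species_divergence = d_b,
    within_species_divergence = d_w,
    n_samples = as.integer(n_samples),
    abundance_log_sd = abundance_log_sd,
    planted_correlations = pc,
    n_reference_genomes = n_ref,
    reference_overlap_fraction = reference_overlap_fraction
  ), class = "sim_config")
}

#' @noRd
normalize_planted_correlations <- function(pc, n_taxa) {
  if (is.null(pc) || (is.data.frame(pc) && nrow(pc) == 0L) || length(pc) == 0L)
    return(data.frame(taxon_i = integer(), taxon_j = integer(), rho = numeric()))
  if (!is.data.frame(pc)) pc <- do.call(rbind.data.frame, lapply(pc, function(x) {
    setNames(as.list(x), c("taxon_i", "taxon_j", "rho"))
  }))
  pc <- data.frame(taxon_i = as.integer(pc$taxon_i), taxon_j = as.integer(pc$taxon_j),
                   rho = as.numeric(pc$rho))
  if (any(abs(pc$rho) >= 1)) stop("planted |rho| must be < 1")
  if (any(pc$taxon_i == pc$taxon_j)) stop("planted correlations must link distinct taxa")
  if (any(pc$taxon_i < 1 | pc$taxon_j < 1 | pc$taxon_i > n_taxa | pc$taxon_j > n_taxa))
    stop("planted correlation indices out of range")
  if (anyDuplicated(c(pc$taxon_i, pc$taxon_j)))
    stop("planted correlation pairs must be disjoint")
  pc
}

# branch substitution rate giving expected pairwise divergence d between two
# siblings mutated independently from their common ancestor
#' @noRd
branch_rate <- function(d) 0.75 * (1 - sqrt(1 - 4 * d / 3))

#' @noRd
random_codes <- function(L) sample.int(4L, L, replace = TRUE) - 1L

# independent per-site substitution to a uniformly chosen *different* base
#' @noRd
mutate_codes <- function(codes, rate) {
  if (rate <= 0) return(codes)
  hit <- which(runif(length(codes)) < rate)
  if (length(hit)) codes[hit] <- (codes[hit] + sample.int(3L, length(hit), replace = TRUE)) %% 4L
  codes
}

#' @noRd
codes_to_seq <- function(codes) paste(c("A", "C", "G", "T")[codes + 1L], collapse = "")

#' Simulate genomes with planted species/strain structure
#'
#' Draws one ancestral sequence uniformly over A/C/G/T, derives each species
#' from it and each strain from its species ancestor by independent point
#' substitutions (no indels, so true ANI is analytic), and builds a synthetic
#' reference collection: for a configured fraction of species a reference
#' genome is planted inside the species (a sibling strain), and the remaining
#' references are unrelated decoys. Genome ids are assigned in shuffled order
#' and encode nothing about the planted truth.
#'
#' The expected strain-level partition is derived analytically from the
#' config: strain lineages of one species belong to the same 99%-ANI strain
#' cluster exactly when the planted within-species divergence maps to a Mash
#' distance below 0.01. A warning is issued when a planted divergence falls
#' within 25% of a clustering threshold, where recovery is not determined.
#'
#' @param config a [sim_config()].
#' @return list with elements `mags` and `references`
#'   ([Biostrings::DNAStringSet]) and `truth` (per-genome, per-reference and
#'   per-species planted labels, plus the expected species- and strain-level
#'   cluster memberships).
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  r_b <- branch_rate(config$between_species_divergence)
  r_w <- branch_rate(config$within_species_divergence)
  n_sp <- config$n_species
  n_st <- config$strains_per_species
  n_cov <- min(round(config$reference_overlap_fraction * n_sp), config$n_reference_genomes)

  # Mash distance implied by a planted pairwise divergence d is ~ -log(1 - d);
  # flag configs whose planted distances hug a clustering threshold.
  d_strain <- -log(1 - config$within_species_divergence)
  d_species <- -log(1 - config$between_species_divergence)
  if (d_strain > 0.0075 && d_strain < 0.0125)
    warning("planted within-species divergence lies near the 99% ANI strain threshold; strain-cluster recovery is not determined")
  if (d_species > 0.0375 && d_species < 0.0625)
    warning("planted between-species divergence lies near the 95% ANI species threshold; species-cluster recovery is not determined")
  strains_merge <- d_strain < 0.01

  withr::with_seed(child_seed(config$seed, "genomes"), {
    root <- random_codes(config$genome_length)
    species_anc <- lapply(seq_len(n_sp), function(i) mutate_codes(root, r_b))
    strain_codes <- vector("list", n_sp * n_st)
    species_of <- integer(n_sp * n_st)
    strain_of <- character(n_sp * n_st)
    idx <- 0L
    for (i in seq_len(n_sp)) {
      for (j in seq_len(n_st)) {
        idx <- idx + 1L
        strain_codes[[idx]] <- mutate_codes(species_anc[[i]], r_w)
        species_of[idx] <- i
        strain_of[idx] <- sprintf("sp%02d_st%d", i, j)
      }
    }

    covered <- seq_len(n_cov)
    ref_codes <- vector("list", config$n_reference_genomes)
    ref_species <- rep(NA_integer_, config$n_reference_genomes)
    for (i in seq_len(config$n_reference_genomes)) {
      if (i <= n_cov) {
        ref_codes[[i]] <- mutate_codes(species_anc[[i]], r_w)
        ref_species[i] <- i
      } else {
        ref_codes[[i]] <- random_codes(config$genome_length)  # unrelated decoy
      }
    }

    perm <- sample.int(n_sp * n_st)
    ref_perm <- sample.int(config$n_reference_genomes)
  })

  mag_ids <- sprintf("MAG_%03d", seq_len(n_sp * n_st))
  mags <- Biostrings::DNAStringSet(vapply(strain_codes[perm], codes_to_seq, character(1)))
  names(mags) <- mag_ids
  genome_truth <- data.frame(
    genome_id = mag_ids,
    species_id = sprintf("sp%02d", species_of[perm]),
    strain_id = strain_of[perm],
    stringsAsFactors = FALSE
  )

  ref_ids <- sprintf("REF_%02d", seq_len(config$n_reference_genomes))
  references <- Biostrings::DNAStringSet(vapply(ref_codes[ref_perm], codes_to_seq, character(1)))
  names(references) <- ref_ids
  ref_sp <- ref_species[ref_perm]
  is_iso <- !is.na(ref_sp) & (ref_sp %% 2L == 1L)  # covered refs alternate isolate/MAG-only
  reference_truth <- data.frame(
    genome_id = ref_ids,
    species_id = ifelse(is.na(ref_sp), NA_character_, sprintf("sp%02d", ref_sp)),
    source_db = ifelse(is.na(ref_sp), "GTDB", ifelse(is_iso, "GTDB", "UHGG")),
    is_isolate = is_iso,
    species_name = ifelse(is.na(ref_sp), sprintf("s__decoy_%02d", ref_perm),
                          sprintf("s__synthetica_sp%02d", ref_sp)),
    stringsAsFactors = FALSE
  )

  sp_ids <- sprintf("sp%02d", seq_len(n_sp))
  sp_cov <- seq_len(n_sp) %in% covered
  species_truth <- data.frame(
    species_id = sp_ids,
    covered = sp_cov,
    expected_type = ifelse(!sp_cov, "novel",
                           ifelse(seq_len(n_sp) %% 2L == 1L, "isolate", "uncultivated")),
    expected_name = ifelse(sp_cov, sprintf("s__synthetica_sp%02d", seq_len(n_sp)), NA_character_),
    strains_novel = !(sp_cov & strains_merge),
    stringsAsFactors = FALSE
  )

  expected_species_cluster <- setNames(genome_truth$species_id, genome_truth$genome_id)
  expected_strain_cluster <- if (strains_merge) {
    setNames(genome_truth$species_id, genome_truth$genome_id)
  } else {
    setNames(genome_truth$strain_id, genome_truth$genome_id)
  }

  list(
    mags = mags,
    references = references,
    truth = list(
      genome = genome_truth,
      reference = reference_truth,
      species = species_truth,
      expected_species_cluster = expected_species_cluster,
      expected_strain_cluster = expected_strain_cluster,
      strains_merge = strains_merge
    )
  )
}

#' Exact pairwise mismatch fraction between two aligned genomes
#'
#' True substitution divergence of two equal-length sequences (the generator
#' emits no indels, so positions align 1:1). Used as the exact oracle against
#' Mash-estimated distances.
#'
#' @param a,b sequences (character or [Biostrings::DNAString]).
#' @return mismatch fraction in `[0, 1]`.
#' @export
true_divergence <- function(a, b) {
  .mismatch_fraction_cpp(as.character(a), as.character(b))
}

#' Simulate a MAG quality table spanning all MIMAG tiers
#'
#' Emits one quality record per planted genome, cycling through the four
#' tiers (high, near-complete, medium, low) with metrics drawn safely inside
#' each tier's region, plus a deterministic boundary battery (ids `BOUND_*`)
#' sitting at and adjacent to every tier boundary: completeness 50/90,
#' contamination 5/10, tRNA counts 17/18/19 and all eight rRNA flag
#' combinations. Boundary rows are pure classifier fixtures; they reference
#' no genome sequence.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element returned by [simulate_genomes()].
#' @return list with `records` (per-genome rows with `planted_tier`) and
#'   `boundary` (the boundary battery, same columns).
#' @export
simulate_quality_table <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  ids <- truth$genome$genome_id
  n <- length(ids)
  tiers <- rep(c("high", "near_complete", "medium", "low"), length.out = n)

  withr::with_seed(child_seed(config$seed, "quality"), {
    comp <- cont <- numeric(n)
    r5 <- r16 <- r23 <- logical(n)
    trna <- integer(n)
    for (i in seq_len(n)) {
      switch(tiers[i],
        high = {
          comp[i] <- runif(1, 91, 99); cont[i] <- runif(1, 0, 4.5)
          r5[i] <- r16[i] <- r23[i] <- TRUE
          trna[i] <- sample(18:24, 1)
        },
        near_complete = {
          comp[i] <- runif(1, 91, 99); cont[i] <- runif(1, 0, 4.5)
          if (i %% 2L == 0L) { # either an rRNA gene or the tRNA set is deficient
            r5[i] <- TRUE; r16[i] <- FALSE; r23[i] <- TRUE; trna[i] <- sample(18:24, 1)
          } else {
            r5[i] <- r16[i] <- r23[i] <- TRUE; trna[i] <- sample(0:17, 1)
          }
        },
        medium = {
          if (i %% 2L == 0L) { comp[i] <- runif(1, 55, 88); cont[i] <- runif(1, 0, 4.5)
          } else { comp[i] <- runif(1, 91, 99); cont[i] <- runif(1, 5.5, 9.5) }
          r5[i] <- r16[i] <- r23[i] <- sample(c(TRUE, FALSE), 1)
          trna[i] <- sample(0:24, 1)
        },
        low = {
          if (i %% 2L == 0L) { comp[i] <- runif(1, 20, 48); cont[i] <- runif(1, 0, 9)
          } else { comp[i] <- runif(1, 55, 95); cont[i] <- runif(1, 10.5, 25) }
          r5[i] <- r16[i] <- r23[i] <- FALSE
          trna[i] <- sample(0:17, 1)
        })
    }
    # fragment genomes into contigs so N50 computation is exercised
    contig_lengths <- vapply(seq_len(n), function(i) {
      k <- sample(1:12, 1)
      if (k == 1L) return(as.character(config$genome_length))
      cuts <- sort(sample.int(config$genome_length - 1L, k - 1L))
      paste(diff(c(0L, cuts, config$genome_length)), collapse = ",")
    }, character(1))
  })

  records <- data.frame(
    genome_id = ids, completeness = round(comp, 2), contamination = round(cont, 2),
    rrna_5s = r5, rrna_16s = r16, rrna_23s = r23, n_unique_trnas = trna,
    contig_lengths = contig_lengths, planted_tier = tiers,
    stringsAsFactors = FALSE
  )

  b <- function(comp, cont, r5, r16, r23, trna, tier)
    data.frame(completeness = comp, contamination = cont, rrna_5s = r5, rrna_16s = r16,
               rrna_23s = r23, n_unique_trnas = trna, contig_lengths = "100000",
               planted_tier = tier, stringsAsFactors = FALSE)
  rr <- expand.grid(r5 = c(TRUE, FALSE), r16 = c(TRUE, FALSE), r23 = c(TRUE, FALSE))
  boundary <- rbind(
    b(95, 4, TRUE, TRUE, TRUE, 18, "high"),
    b(95, 4, TRUE, TRUE, TRUE, 19, "high"),
    b(95, 4, TRUE, TRUE, TRUE, 17, "near_complete"),
    b(90, 4, TRUE, TRUE, TRUE, 18, "medium"),          # completeness must exceed 90
    b(90.01, 4.99, TRUE, TRUE, TRUE, 18, "high"),
    b(95, 5, TRUE, TRUE, TRUE, 18, "medium"),          # contamination must be below 5
    b(50, 4, TRUE, TRUE, TRUE, 18, "low"),             # completeness must exceed 50
    b(50.01, 9.99, FALSE, FALSE, FALSE, 0, "medium"),
    b(55, 10, FALSE, FALSE, FALSE, 0, "low"),          # contamination must be below 10
    do.call(rbind, lapply(seq_len(nrow(rr)), function(i)
      b(91, 4, rr$r5[i], rr$r16[i], rr$r23[i], 18,
        if (all(unlist(rr[i, ]))) "high" else "near_complete")))
  )
  boundary <- cbind(genome_id = sprintf("BOUND_%02d", seq_len(nrow(boundary))), boundary)
  list(records = records, boundary = boundary)
}

#' Simulate a compositional abundance table with planted correlations
#'
#' Per-sample basis abundances are log-normal: taxon i in sample s has
#' `log basis = mu_i + sd * Z_is` with `Z` standard normal, and each planted
#' pair drawn from a bivariate normal with the requested correlation. One
#' taxon is forced to a very low mean so the downstream median-abundance
#' filter (taxa at or below 0.1%) is always exercised. Basis abundances are
#' then closed to relative abundances (each sample row sums to one), which is
#' what induces the compositional bias the SparCC stage corrects for.
#'
#' @param config a [sim_config()].
#' @param truth optional; taxa are named after the planted species when given.
#' @return list with `table` (samples x taxa relative abundances), `basis`
#'   (pre-closure matrix, the ground truth for correlation recovery) and
#'   `planted` (the planted pair table with taxon names attached).
#' @export
simulate_abundance <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  p <- config$n_species
  taxa <- sprintf("taxon_%02d", seq_len(p))
  pc <- config$planted_correlations

  withr::with_seed(child_seed(config$seed, "abundance"), {
    mu <- rnorm(p, 0, 1.5)
    if (p >= 2) mu[p] <- -9  # guaranteed sub-0.1% taxon
    # planted pairs sit at typical abundance: a correlation planted on a taxon
    # below the sequencing depth would be unrecoverable by construction
    if (nrow(pc)) mu[c(pc$taxon_i, pc$taxon_j)] <- 0
    Z <- matrix(rnorm(n * p), n, p)
    if (nrow(pc)) for (k in seq_len(nrow(pc))) {
      i <- pc$taxon_i[k]; j <- pc$taxon_j[k]; rho <- pc$rho[k]
      Z[, j] <- rho * Z[, i] + sqrt(1 - rho^2) * rnorm(n)
    }
  })

  basis <- exp(sweep(config$abundance_log_sd * Z, 2, mu, "+"))
  dimnames(basis) <- list(sprintf("sample_%03d", seq_len(n)), taxa)
  closed <- basis / rowSums(basis)
  planted <- if (nrow(pc)) cbind(pc, taxon_i_id = taxa[pc$taxon_i], taxon_j_id = taxa[pc$taxon_j])
             else pc
  list(table = closed, basis = basis, planted = planted)
}

#' Simulate BGC call tables from two callers with planted filter outcomes
#'
#' Builds a caller-A (comparative-genomics style) and a caller-B
#' (deep-learning style) interval table containing every planted case the
#' curation rules must handle: single-gene short records, records missing a
#' known product class or biosynthetic domains, pairs overlapping just below,
#' exactly at, and above 30% of either interval, same coordinates on
#' different contigs, and clean disjoint records. Coordinates are 0-based
#' half-open.
#'
#' @param config a [sim_config()].
#' @return list with `caller_a`, `caller_b` (BGC record tables) and `truth`
#'   (`bgc_id`, `expected_retained`, `expected_reason`).
#' @export
simulate_bgc_tables <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rec <- function(id, genome, contig, start, end, caller, genes, raw, known = TRUE, dom = 2L)
    data.frame(bgc_id = id, genome_id = genome, contig_id = contig, start = start, end = end,
               caller = caller, n_genes = genes, raw_class = raw, has_known_class = known,
               n_biosynthetic_domains = dom, stringsAsFactors = FALSE)

  a <- rbind(
    rec("A_keep_01", "MAG_001", "c1", 0L, 5000L, "A", 5L, "bacteriocin"),
    rec("A_keep_02", "MAG_001", "c1", 10000L, 13000L, "A", 3L, "T1PKS"),
    rec("A_keep_03", "MAG_002", "c2", 0L, 4000L, "A", 4L, "NRPS"),
    rec("A_keep_04", "MAG_002", "c2", 30000L, 32500L, "A", 1L, "lassopeptide"),  # single gene but >= 2 kb
    rec("A_keep_05", "MAG_003", "c1", 0L, 6000L, "A", 6L, "bacteriocin;T1PKS"),
    rec("A_rm_short", "MAG_001", "c1", 20000L, 21500L, "A", 1L, "terpene")       # single gene and < 2 kb
  )
  b <- rbind(
    rec("B_keep_01", "MAG_001", "c1", 50000L, 56000L, "B", 6L, "RiPP"),
    rec("B_keep_02", "MAG_002", "c2", 50000L, 54000L, "B", 4L, "Polyketide"),
    rec("B_keep_diffcontig", "MAG_001", "c9", 0L, 5000L, "B", 5L, "RiPP"),       # caller-A coords, other contig
    rec("B_keep_below30", "MAG_001", "c1", 12130L, 16130L, "B", 4L, "NRP"),      # 29% of A, 21.75% of B
    rec("B_rm_ov_exact", "MAG_001", "c1", 3500L, 9000L, "B", 5L, "RiPP"),        # 1500/5000 = 30% of A
    rec("B_rm_ov_nested", "MAG_001", "c1", 1000L, 2000L, "B", 2L, "RiPP"),       # 100% of B inside A
    rec("B_rm_noclass", "MAG_003", "c3", 0L, 5000L, "B", 5L, "unknown", known = FALSE, dom = 3L),
    rec("B_rm_nodomain", "MAG_003", "c3", 10000L, 15000L, "B", 5L, "RiPP", dom = 0L),
    rec("B_rm_short", "MAG_003", "c3", 20000L, 21800L, "B", 1L, "RiPP")
  )

  withr::with_seed(child_seed(config$seed, "bgc"), {
    n_extra <- 10L
    extra <- do.call(rbind, lapply(seq_len(n_extra), function(i) {
      caller <- if (i %% 2L == 0L) "A" else "B"
      start <- sample.int(50000L, 1)
      rec(sprintf("%s_rand_%02d", caller, i), sprintf("MAG_%03d", 10L + i),
          sprintf("rc%02d", i), start, start + sample(2500:9000, 1), caller,
          sample(2:8, 1), sample(c("bacteriocin", "T3PKS", "NRPS", "saccharide", "terpene"), 1))
    }))
  })

  caller_a <- rbind(a, extra[extra$caller == "A", ])
  caller_b <- rbind(b, extra[extra$caller == "B", ])
  ids <- c(caller_a$bgc_id, caller_b$bgc_id)
  reason <- rep("retained", length(ids))
  reason[grepl("_rm_short", ids)] <- "basic_filter"
  reason[grepl("_rm_noclass", ids)] <- "class_filter"
  reason[grepl("_rm_nodomain", ids)] <- "domain_filter"
  reason[grepl("_rm_ov", ids)] <- "overlap_dedup"
  truth <- data.frame(bgc_id = ids, expected_retained = reason == "retained",
                      expected_reason = reason, stringsAsFactors = FALSE)
  list(caller_a = caller_a, caller_b = caller_b, truth = truth)
}

#' Simulate a peptide vote table covering the full ensemble truth table
#'
#' Emits every combination of the four predictor votes, transporter
#' presence/absence and the boundary peptide lengths 10, 11, 199 and 200
#' (128 rows), each with a random peptide sequence of the stated length.
#' The planted AMP label follows the ensemble rule: both core predictors
#' vote yes, at least one of the two auxiliary predictors votes yes, the
#' parent RiPP BGC carries a transporter gene, and the peptide length is
#' strictly between 10 and 200 residues.
#'
#' @param config a [sim_config()].
#' @return list with `table` (vote rows) and `truth` (`peptide_id`,
#'   `planted_amp`).
#' @export
simulate_votes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  grid <- expand.grid(p1 = c(TRUE, FALSE), p2 = c(TRUE, FALSE), p3 = c(TRUE, FALSE),
                      p4 = c(TRUE, FALSE), transporter_in_bgc = c(TRUE, FALSE),
                      length = c(10L, 11L, 199L, 200L))
  withr::with_seed(child_seed(config$seed, "votes"), {
    seqs <- vapply(grid$length, function(L) paste(sample(aa, L, replace = TRUE), collapse = ""),
                   character(1))
  })
  tab <- data.frame(
    peptide_id = sprintf("pep_%03d", seq_len(nrow(grid))),
    bgc_id = sprintf("bgcR_%02d", (seq_len(nrow(grid)) - 1L) %% 8L + 1L),
    sequence = seqs,
    p1 = grid$p1, p2 = grid$p2, p3 = grid$p3, p4 = grid$p4,
    transporter_in_bgc = grid$transporter_in_bgc,
    bgc_is_ripp = TRUE,
    stringsAsFactors = FALSE
  )
  planted <- grid$p1 & grid$p2 & (grid$p3 | grid$p4) & grid$transporter_in_bgc &
    grid$length > 10L & grid$length < 200L
  list(table = tab, truth = data.frame(peptide_id = tab$peptide_id, planted_amp = planted,
                                       stringsAsFactors = FALSE))
}

#' Simulate a complete synthetic community
#'
#' Runs every generator stage off one root seed (each stage draws from its
#' own deterministic child stream, so stages can be re-run independently).
#'
#' @param config a [sim_config()].
#' @return list with `config`, `genomes`, `quality`, `abundance`, `bgc`,
#'   `votes`.
#' @export
simulate_community <- function(config = sim_config()) {
  genomes <- simulate_genomes(config)
  list(
    config = config,
    genomes = genomes,
    quality = simulate_quality_table(config, genomes$truth),
    abundance = simulate_abundance(config, genomes$truth),
    bgc = simulate_bgc_tables(config),
    votes = simulate_votes(config)
  )
}
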