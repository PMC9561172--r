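# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route than the package (enumeration, brute force,
# or an established package), so agreement is evidence rather than tautology.

# exact canonical k-mer set of a sequence, by plain string manipulation
r_canonical_kmers <- function(seq, k = 21L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(character(0))
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  unique(pmin(kmers, rc))
}

# exact Jaccard of canonical k-mer sets
r_exact_jaccard <- function(a, b, k = 21L) {
  ka <- r_canonical_kmers(a, k); kb <- r_canonical_kmers(b, k)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

# connected components of the d < threshold graph, via igraph
igraph_partition <- function(d, threshold) {
  g <- igraph::graph_from_adjacency_matrix(d < threshold & upper.tri(d) | t(d < threshold & upper.tri(d)),
                                           mode = "undirected")
  igraph::components(g)$membership
}

# two labelings describe the same partition?
same_partition <- function(a, b) {
  isTRUE(all.equal(mclust::adjustedRandIndex(a, b), 1))
}

# brute-force all-pairs overlap dedup in exact integer arithmetic (f = 3/10)
oracle_dedup_drop <- function(primary, secondary) {
  drop <- logical(nrow(secondary))
  for (i in seq_len(nrow(secondary))) {
    for (j in seq_len(nrow(primary))) {
      if (secondary$genome_id[i] != primary$genome_id[j]) next
      if (secondary$contig_id[i] != primary$contig_id[j]) next
      ov <- max(0L, min(secondary$end[i], primary$end[j]) - max(secondary$start[i], primary$start[j]))
      len_p <- primary$end[j] - primary$start[j]
      len_s <- secondary$end[i] - secondary$start[i]
      if (10L * ov >= 3L * len_p || 10L * ov >= 3L * len_s) drop[i] <- TRUE
    }
  }
  drop
}

random_interval_set <- function(n, caller, prefix) {
  start <- sample(seq(0L, 2000L, by = 10L), n, replace = TRUE)
  len <- sample(seq(10L, 500L, by = 10L), n, replace = TRUE)
  data.frame(
    bgc_id = sprintf("%s%03d", prefix, seq_len(n)),
    genome_id = sample(c("g1", "g2"), n, replace = TRUE),
    contig_id = sample(c("c1", "c2"), n, replace = TRUE),
    start = start, end = start + len, caller = caller,
    n_genes = 2L, raw_class = "bacteriocin", has_known_class = TRUE,
    n_biosynthetic_domains = 1L, stringsAsFactors = FALSE
  )
}

# expected richness at t sampling units by exhaustive subset enumeration
oracle_rarefaction <- function(inc, t) {
  subs <- utils::combn(nrow(inc), t)
  mean(apply(subs, 2, function(ix) sum(colSums(inc[ix, , drop = FALSE]) > 0)))
}

# MIMAG tier by an independently structured decision path
oracle_tier <- function(comp, cont, r5, r16, r23, trna) {
  if (cont < 5 && comp > 90) {
    if (r5 && r16 && r23 && trna >= 18) return("high")
    return("near_complete")
  }
  if (cont < 10 && comp > 50) return("medium")
  "low"
}

# small symmetric random distance matrix with zero diagonal
random_dist_matrix <- function(n, ids = sprintf("g%02d", seq_len(n))) {
  d <- matrix(runif(n * n), n, n)
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  d
}
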