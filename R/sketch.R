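#' Build a bottom-s MinHash sketch of a genome
#'
#' Every window of length `k` consisting only of A/C/G/T (case-insensitive;
#' windows containing any other character are skipped) contributes its
#' canonical form — the lexicographic minimum of the k-mer and its reverse
#' complement — which is hashed with the package's fixed 64-bit mix
#' (splitmix64 over the 2-bit packed k-mer with a constant salt, truncated to
#' 53 bits so values are exact doubles). The `s` smallest distinct hash
#' values are retained. Defaults `k = 21`, `s = 10000` match common practice
#' for genome-scale ANI estimation.
#'
#' @param x sequences of one genome: a character vector, a
#'   [Biostrings::DNAStringSet], or the path of a FASTA file.
#' @param k k-mer length (1-31).
#' @param s sketch size.
#' @param genome_id identifier stored in the sketch; defaults to the FASTA
#'   file name or `"genome"`.
#' @return a `genome_sketch` object with fields `genome_id`, `k`, `s`,
#'   `hashes` (strictly increasing, length `min(s, n_distinct_kmers)`) and
#'   `n_distinct_kmers`.
#' @export
build_sketch <- function(x, k = 21L, s = 10000L, genome_id = NULL) {
  if (is.character(x) && length(x) == 1L && file.exists(x) && !grepl("^[ACGTNacgtn]+$", x)) {
    genome_id <- genome_id %||% sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(x))
    x <- read_genome_fasta(x)
  }
  if (inherits(x, c("DNAStringSet", "DNAString", "XStringSet"))) x <- as.character(x)
  if (!is.character(x) || length(x) == 0L) stop("x must contain at least one sequence")
  if (!any(nchar(x) >= k)) stop("need at least one sequence of length >= k")
  res <- .sketch_hashes_cpp(x, as.integer(k), as.integer(s))
  if (length(res$hashes) == 0L)
    stop("empty sketch: no window of length k contains only A/C/G/T bases")
  structure(list(
    genome_id = genome_id %||% "genome",
    k = as.integer(k), s = as.integer(s),
    hashes = res$hashes,
    n_distinct_kmers = res$n_distinct
  ), class = "genome_sketch")
}

#' @export
print.genome_sketch <- function(x, ...) {
  cat(sprintf("genome_sketch '%s': k=%d s=%d | %d hashes of %g distinct canonical k-mers\n",
              x$genome_id, x$k, x$s, length(x$hashes), x$n_distinct_kmers))
  invisible(x)
}

#' Mash Jaccard estimate between two sketches
#'
#' Merges the two bottom-s hash lists, takes the `s' = min(s, |union|)`
#' smallest values X of the merged stream, and returns
#' `|X shared by both sketches| / |X|` — the Mash estimator, which equals the
#' exact Jaccard index of the two canonical k-mer sets whenever `s` is at
#' least the number of distinct k-mers in the union.
#'
#' @param a,b `genome_sketch` objects with identical `k` and `s`.
#' @return estimated Jaccard index in `[0, 1]`.
#' @export
jaccard_estimate <- function(a, b) {
  stopifnot(inherits(a, "genome_sketch"), inherits(b, "genome_sketch"))
  if (a$k != b$k) stop("sketches have different k-mer lengths")
  if (a$s != b$s) stop("sketches have different sketch sizes")
  .jaccard_sorted_cpp(a$hashes, b$hashes, a$s)
}

#' Mash distance from a Jaccard estimate
#'
#' `d = -(1/k) * log(2j / (1 + j))`, capped at 1; a Jaccard of 0 maps to
#' distance 1 (rather than infinity) so distance matrices stay bounded for
#' clustering. `1 - d` is the ANI estimate.
#'
#' @param j Jaccard estimate(s) in `[0, 1]`.
#' @param k k-mer length used in the sketches.
#' @return Mash distance(s) in `[0, 1]`.
#' @export
mash_distance <- function(j, k = 21L) {
  if (any(j < 0 | j > 1, na.rm = TRUE)) stop("Jaccard estimates must lie in [0, 1]")
  d <- ifelse(j <= 0, 1, pmin(1, -(1 / k) * log(2 * j / (1 + j))))
  ifelse(j >= 1, 0, d)
}

#' All-pairs Mash distance matrix
#'
#' @param sketches list of `genome_sketch` objects with unique genome ids and
#'   homogeneous `k` and `s`.
#' @return a `mash_dist` object: `ids`, `d` (symmetric Mash distances, zero
#'   diagonal) and `jaccard` (the matching Jaccard estimates, unit diagonal).
#' @export
pairwise_distances <- function(sketches) {
  if (length(sketches) < 1L) stop("need at least one sketch")
  ids <- vapply(sketches, function(x) x$genome_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  ks <- vapply(sketches, function(x) x$k, integer(1))
  ss <- vapply(sketches, function(x) x$s, integer(1))
  if (length(unique(ks)) > 1L || length(unique(ss)) > 1L)
    stop("sketches must share k and s")
  n <- length(sketches)
  jac <- diag(1, n)
  for (i in seq_len(n)) for (jj in seq_len(i - 1L)) {
    jac[i, jj] <- jac[jj, i] <- .jaccard_sorted_cpp(sketches[[i]]$hashes, sketches[[jj]]$hashes, ss[1])
  }
  d <- matrix(mash_distance(jac, ks[1]), n, n)
  diag(d) <- 0
  dimnames(d) <- dimnames(jac) <- list(ids, ids)
  structure(list(ids = ids, d = d, jaccard = jac, k = ks[1], s = ss[1]), class = "mash_dist")
}

#' @export
print.mash_dist <- function(x, ...) {
  cat(sprintf("mash_dist: %d genomes (k=%d, s=%d), distances in [%.4g, %.4g]\n",
              length(x$ids), x$k, x$s, min(x$d), max(x$d)))
  invisible(x)
}

#' @rdname pairwise_distances
#' @param x a `mash_dist` object.
#' @param ... ignored.
#' @export
as.matrix.mash_dist <- function(x, ...) x$d

#' Long-format distance table
#'
#' @param D a `mash_dist` object.
#' @return data.frame with `id_a`, `id_b`, `distance`, `jaccard` for every
#'   unordered pair.
#' @export
distance_table <- function(D) {
  stopifnot(inherits(D, "mash_dist"))
  n <- length(D$ids)
  idx <- which(upper.tri(D$d), arr.ind = TRUE)
  data.frame(id_a = D$ids[idx[, 1]], id_b = D$ids[idx[, 2]],
             distance = D$d[idx], jaccard = D$jaccard[idx], stringsAsFactors = FALSE)
}

#' Serialize / read a sketch as JSON
#'
#' Hash values are written as unsigned decimal strings so the representation
#' is exact and portable.
#'
#' @param sketch a `genome_sketch`.
#' @param path output (input) file path.
#' @return `path` (invisibly) / the restored `genome_sketch`.
#' @export
write_sketch_json <- function(sketch, path) {
  stopifnot(inherits(sketch, "genome_sketch"))
  obj <- list(genome_id = sketch$genome_id, k = sketch$k, s = sketch$s,
              n_distinct_kmers = sketch$n_distinct_kmers,
              hashes = sprintf("%.0f", sketch$hashes))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = FALSE)
  invisible(path)
}

#' @rdname write_sketch_json
#' @export
read_sketch_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(genome_id = obj$genome_id, k = as.integer(obj$k), s = as.integer(obj$s),
                 hashes = as.numeric(obj$hashes), n_distinct_kmers = obj$n_distinct_kmers),
            class = "genome_sketch")
}
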