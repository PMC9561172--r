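#' Single-linkage clustering of genomes at a distance threshold
#'
#' Two genomes share a cluster exactly when they are connected by a path in
#' which every edge has distance strictly below `threshold` (the behaviour of
#' single-linkage agglomerative clustering cut at a distance threshold).
#' 95% ANI (`threshold = 0.05`) is the conventional species boundary, 99% ANI
#' (`threshold = 0.01`) the strain boundary. Cluster ids are assigned
#' deterministically in order of each cluster's lexicographically smallest
#' member, so outputs are diffable and invariant to input order.
#'
#' @param D distance matrix (a `mash_dist` or a symmetric numeric matrix with
#'   genome ids as dimnames and a zero diagonal).
#' @param threshold merge threshold in `(0, 1)`; edges with `d < threshold`
#'   (strict) connect genomes.
#' @param level label for the clustering level (`"species"` or `"strain"`).
#' @param id_prefix prefix for generated cluster ids; default `"SLC"` for
#'   species, `"STC"` for strain.
#' @param representatives compute eigenvector-centrality representatives
#'   (see [select_representative()])?
#' @return a `cluster_assignment`: `level`, `threshold`, `membership` (named
#'   genome -> cluster id), `clusters` (cluster id -> member ids) and
#'   `representatives` (cluster id -> genome id).
#' @export
single_linkage_cluster <- function(D, threshold, level = c("species", "strain"),
                                   id_prefix = NULL, representatives = TRUE) {
  level <- match.arg(level)
  d <- as_dist_matrix(D)
  if (nrow(d) == 0L) stop("empty distance matrix")
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  ids <- rownames(d)
  comp <- threshold_components(d, threshold)
  id_prefix <- id_prefix %||% if (level == "species") "SLC" else "STC"
  assignment_from_components(ids, comp, level, threshold, id_prefix,
                             similarity = if (representatives) 1 - d else NULL)
}

# union-find connected components of the graph with edges d < threshold
#' @noRd
threshold_components <- function(d, threshold) {
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges <- which(d < threshold & upper.tri(d), arr.ind = TRUE)
  for (e in seq_len(nrow(edges))) {
    ri <- find(edges[e, 1]); rj <- find(edges[e, 2])
    if (ri != rj) parent[ri] <- rj
  }
  vapply(seq_len(n), find, integer(1))
}

#' @noRd
assignment_from_components <- function(ids, comp, level, threshold, id_prefix, similarity = NULL) {
  groups <- lapply(split(ids, comp), sort)   # canonical member order
  groups <- groups[order(vapply(groups, min, character(1)))]
  cluster_ids <- sprintf("%s%03d", id_prefix, seq_along(groups))
  names(groups) <- cluster_ids
  membership <- setNames(rep(cluster_ids, lengths(groups)), unlist(groups, use.names = FALSE))
  membership <- membership[ids]
  reps <- if (!is.null(similarity)) {
    vapply(groups, function(m) select_representative(m, similarity[m, m, drop = FALSE]), character(1))
  } else NULL
  structure(list(level = level, threshold = threshold, membership = membership,
                 clusters = groups, representatives = reps),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment (%s, d < %g): %d genomes in %d clusters\n",
              x$level, x$threshold, length(x$membership), length(x$clusters)))
  invisible(x)
}

#' Refine a species-level clustering into strain-level clusters
#'
#' Re-clusters the same genomes at the strain threshold. Because the strain
#' threshold is smaller, its edge set is a subset of the species edge set and
#' the strain partition provably refines the species partition; strain
#' cluster ids are nested in the parent cluster id
#' (`SLC001_ST01`, `SLC001_ST02`, ...).
#'
#' @param species_assignment the species-level `cluster_assignment`.
#' @param D the same distance matrix that clustering was computed on.
#' @param threshold strain merge threshold (default 0.01, i.e. 99% ANI).
#' @return a strain-level `cluster_assignment` with an extra `parent` field
#'   (strain cluster id -> species cluster id).
#' @export
refine_to_strains <- function(species_assignment, D, threshold = 0.01) {
  stopifnot(inherits(species_assignment, "cluster_assignment"))
  if (threshold >= species_assignment$threshold)
    stop("strain threshold must be below the species threshold")
  d <- as_dist_matrix(D)
  ids <- names(species_assignment$membership)
  if (!all(ids %in% rownames(d))) stop("species assignment does not match this distance matrix")
  d <- d[ids, ids, drop = FALSE]
  comp <- threshold_components(d, threshold)

  membership <- character(length(ids)); names(membership) <- ids
  clusters <- list(); reps <- character(0); parent <- character(0)
  for (slc in names(species_assignment$clusters)) {
    members <- species_assignment$clusters[[slc]]
    sub <- lapply(split(members, comp[match(members, ids)]), sort)
    sub <- sub[order(vapply(sub, min, character(1)))]
    st_ids <- sprintf("%s_ST%02d", slc, seq_along(sub))
    names(sub) <- st_ids
    for (sid in st_ids) {
      membership[sub[[sid]]] <- sid
      reps[sid] <- select_representative(sub[[sid]], 1 - d[sub[[sid]], sub[[sid]], drop = FALSE])
      parent[sid] <- slc
    }
    clusters <- c(clusters, sub)
  }
  structure(list(level = "strain", threshold = threshold, membership = membership,
                 clusters = clusters, representatives = reps, parent = parent),
            class = "cluster_assignment")
}

#' Select a cluster representative by eigenvector centrality
#'
#' Builds the complete weighted graph on the members (edge weight = ANI
#' similarity `1 - d`, zero diagonal), computes eigenvector centrality by
#' power iteration (tolerance 1e-10, at most 10,000 iterations) and returns
#' the member with the highest centrality. Ties — including the fully
#' symmetric case where all weights are equal — are broken by
#' lexicographically smallest genome id.
#'
#' @param members character vector of member genome ids.
#' @param similarity symmetric non-negative weight matrix over the members
#'   (dimnames = member ids).
#' @return the representative genome id.
#' @export
select_representative <- function(members, similarity) {
  if (length(members) == 0L) stop("empty member set")
  if (length(members) == 1L) return(members)
  W <- similarity[members, members, drop = FALSE]
  if (any(W < 0)) stop("similarity weights must be non-negative")
  diag(W) <- 0
  n <- length(members)
  x <- rep(1 / sqrt(n), n)
  converged <- FALSE
  # iterate with W + I: same eigenvectors, but the Perron eigenvalue becomes
  # strictly dominant even on bipartite weight graphs (e.g. stars), whose
  # +/-lambda spectrum would otherwise make the plain iteration oscillate
  for (it in seq_len(10000L)) {
    y <- as.vector(W %*% x) + x
    ny <- sqrt(sum(y^2))
    if (ny == 0) { x <- rep(1 / sqrt(n), n); converged <- TRUE; break }
    y <- y / ny
    if (sqrt(sum((y - x)^2)) < 1e-10) { x <- y; converged <- TRUE; break }
    x <- y
  }
  if (!converged)
    stop(sprintf("eigenvector centrality did not converge for cluster {%s}",
                 paste(members, collapse = ", ")))
  best <- which(x > max(x) - 1e-9)
  sort(members[best])[1]
}

#' Cluster membership as a data.frame
#'
#' @param species species-level `cluster_assignment`.
#' @param strains optional strain-level `cluster_assignment` over the same
#'   genomes.
#' @return data.frame with `genome_id`, `species_cluster`, `strain_cluster`,
#'   `is_representative`.
#' @export
membership_table <- function(species, strains = NULL) {
  ids <- names(species$membership)
  out <- data.frame(genome_id = ids, species_cluster = unname(species$membership),
                    stringsAsFactors = FALSE)
  out$strain_cluster <- if (!is.null(strains)) unname(strains$membership[ids]) else NA_character_
  out$is_representative <- ids %in% species$representatives
  out[order(out$genome_id), , drop = FALSE]
}
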