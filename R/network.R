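#' Build a compositional co-occurrence network
#'
#' Taxa with median relative abundance at or below `median_floor` (default
#' 0.1%) are dropped before edge selection; edges are retained when their
#' permutation p-value is strictly below `alpha`. Stratified comparisons
#' (e.g. samples with vs without a gene cluster family) are expressed as two
#' `build_network()` calls on the sample subsets.
#'
#' @param rho correlation matrix from [sparcc_correlations()].
#' @param p p-value matrix from [edge_pvalues()], aligned with `rho`.
#' @param abundance samples x taxa relative-abundance matrix used for the
#'   median filter.
#' @param alpha edge retention threshold on p (default 0.05, strict).
#' @param median_floor median relative-abundance floor (default 0.001,
#'   inclusive: taxa exactly at the floor are dropped).
#' @return a `correlation_network`: `nodes`, `edges` (data.frame `taxon_i`,
#'   `taxon_j`, `rho`, `p`), `alpha`, `median_floor`, `dropped_taxa`.
#' @export
build_network <- function(rho, p, abundance, alpha = 0.05, median_floor = 0.001) {
  taxa <- colnames(abundance)
  if (is.null(taxa) || !all(taxa %in% colnames(rho)) || !all(taxa %in% colnames(p)))
    stop("rho, p and abundance must be aligned on named taxa")
  med <- apply(abundance, 2, median)
  keep <- taxa[med > median_floor]
  dropped <- setdiff(taxa, keep)
  r <- rho[keep, keep, drop = FALSE]
  pv <- p[keep, keep, drop = FALSE]
  idx <- which(upper.tri(r) & pv < alpha, arr.ind = TRUE)
  edges <- data.frame(taxon_i = keep[idx[, 1]], taxon_j = keep[idx[, 2]],
                      rho = r[idx], p = pv[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$taxon_i, edges$taxon_j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = keep, edges = edges, alpha = alpha,
                 median_floor = median_floor, dropped_taxa = dropped),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation_network: %d nodes, %d edges (p < %g; median floor %g)\n",
              length(x$nodes), nrow(x$edges), x$alpha, x$median_floor))
  invisible(x)
}

#' Convert a correlation network to an igraph graph
#'
#' @param net a `correlation_network`.
#' @return an undirected [igraph::graph] with `rho` and `p` edge attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "correlation_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Write a network as an edge-list TSV and GraphML
#'
#' @param net a `correlation_network`.
#' @param edge_path TSV output path (`taxon_i`, `taxon_j`, `rho`, `p`).
#' @param graphml_path optional GraphML output path.
#' @return `edge_path` invisibly.
#' @export
write_network <- function(net, edge_path, graphml_path = NULL) {
  stopifnot(inherits(net, "correlation_network"))
  write_tsv_file(net$edges, edge_path)
  if (!is.null(graphml_path))
    igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
  invisible(edge_path)
}
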