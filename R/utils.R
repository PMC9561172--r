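#' Derive a child seed for a named pipeline stage
#'
#' One root seed deterministically spawns an independent seed per stage, so a
#' stage can be re-run on its own and still reproduce the full-pipeline output.
#'
#' @param seed integer root seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  val <- ((abs(seed) %% 1e6) * 1009 + h * 97561) %% 2147483646
  as.integer(val) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

# Normalise the various distance-matrix representations to a plain numeric
# matrix with dimnames.
#' @noRd
as_dist_matrix <- function(D) {
  if (inherits(D, "mash_dist")) D <- D$d
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || !is.numeric(D)) stop("D must be a numeric distance matrix")
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (nrow(D) > 0L && is.null(rownames(D)))
    stop("distance matrix must carry genome ids as dimnames")
  if (!isTRUE(all.equal(unname(D), unname(t(D)), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal must be zero")
  D
}

#' @noRd
write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
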