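#' Convert relative abundances to presence/absence incidence
#'
#' A taxon is scored present in a sample when its relative abundance
#' strictly exceeds the detection threshold (default 0.05%).
#'
#' @param a samples x taxa matrix of relative abundances (each row sums
#'   to 1).
#' @param threshold presence threshold on the relative-abundance scale.
#' @return an `incidence_matrix`: logical samples x taxa matrix plus `T`
#'   (number of sampling units) and `Y` (per-taxon incidence frequencies).
#' @export
to_incidence <- function(a, threshold = 0.0005) {
  if (!is.matrix(a) || !is.numeric(a)) stop("a must be a numeric samples x taxa matrix")
  if (any(a < 0)) stop("relative abundances must be non-negative")
  rs <- rowSums(a)
  if (any(abs(rs - 1) > 1e-6))
    stop("rows must sum to 1 (relative abundances); worst deviation ",
         format(max(abs(rs - 1))))
  inc <- a > threshold
  structure(list(incidence = inc, T = nrow(a), Y = colSums(inc)), class = "incidence_matrix")
}

#' Incidence matrix from a binary matrix
#'
#' @param inc logical/0-1 samples x taxa matrix.
#' @return an `incidence_matrix`.
#' @export
as_incidence <- function(inc) {
  inc <- inc > 0
  structure(list(incidence = inc, T = nrow(inc), Y = colSums(inc)), class = "incidence_matrix")
}

#' Incidence-based rarefaction and extrapolation of species richness
#'
#' For `t <= T` sampling units the expected richness is the exact
#' hypergeometric interpolation
#' `S(t) = S_obs - sum_i C(T - Y_i, t) / C(T, t)`
#' over observed taxa. Beyond the reference sample the curve is extrapolated
#' with the incidence-based Chao2 estimate of undetected richness
#' `Q0_hat = ((T-1)/T) * Q1^2 / (2 Q2)` (small-sample form
#' `((T-1)/T) * Q1 (Q1 - 1) / 2` when no doubletons exist), where `Q1`, `Q2`
#' count taxa seen in exactly one and two samples:
#' `S(T + t*) = S_obs + Q0_hat * (1 - (1 - Q1 / (Q1 + T * Q0_hat))^t*)`.
#' With no singletons the extrapolated curve stays flat at `S_obs`.
#'
#' @param m an `incidence_matrix` (or binary matrix).
#' @param endpoint last number of sampling units to evaluate (default 300).
#' @return data.frame with `t`, `richness`, `method`
#'   (`"interpolated"`/`"extrapolated"`).
#' @export
rarefaction_curve <- function(m, endpoint = 300L) {
  if (!inherits(m, "incidence_matrix")) m <- as_incidence(m)
  if (m$T < 1) stop("need at least one sampling unit")
  if (endpoint < 1) stop("endpoint must be >= 1")
  Tn <- m$T
  Y <- m$Y[m$Y > 0]                      # all-zero taxa never enter S_obs
  S_obs <- length(Y)
  Q1 <- sum(Y == 1); Q2 <- sum(Y == 2)
  Q0_hat <- if (Q2 > 0) ((Tn - 1) / Tn) * Q1^2 / (2 * Q2)
            else ((Tn - 1) / Tn) * Q1 * (Q1 - 1) / 2

  t_all <- seq_len(endpoint)
  richness <- vapply(t_all, function(t) {
    if (t <= Tn) {
      # lchoose(n, k) is -Inf for k > n, so unseen terms vanish cleanly
      S_obs - sum(exp(lchoose(Tn - Y, t) - lchoose(Tn, t)))
    } else {
      if (Q1 == 0 || Q0_hat <= 0) S_obs
      else S_obs + Q0_hat * (1 - (1 - Q1 / (Q1 + Tn * Q0_hat))^(t - Tn))
    }
  }, numeric(1))
  data.frame(t = t_all, richness = richness,
             method = ifelse(t_all <= Tn, "interpolated", "extrapolated"))
}

#' Fraction of the asymptotic-endpoint richness recovered by t samples
#'
#' @param curve a [rarefaction_curve()] result.
#' @param t number of sampling units.
#' @return `S(t) / S(endpoint)` in `(0, 1]`.
#' @export
coverage_at <- function(curve, t) {
  stopifnot(is.data.frame(curve), all(c("t", "richness") %in% names(curve)))
  if (!t %in% curve$t) stop("t not on the computed curve")
  curve$richness[match(t, curve$t)] / curve$richness[which.max(curve$t)]
}
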