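AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' @noRd
check_peptide <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(chars), AA_STANDARD)
  if (length(bad))
    stop("non-standard residues in peptide sequence: ", paste(bad, collapse = ", "))
  chars
}

#' Peptide length eligibility for AMP screening
#'
#' Eligible peptides are strictly longer than 10 and strictly shorter than
#' 200 residues.
#'
#' @param x peptide sequence(s) (validated against the 20 standard amino
#'   acids) or numeric length(s).
#' @return logical vector.
#' @export
length_eligible <- function(x) {
  len <- if (is.character(x)) {
    vapply(x, function(s) length(check_peptide(s)), integer(1), USE.NAMES = FALSE)
  } else as.numeric(x)
  len > 10 & len < 200
}

#' Ensemble AMP vote
#'
#' A peptide is called an AMP candidate when both core predictors vote yes
#' (`p1`, `p2`), at least one auxiliary predictor votes yes (`p3` or `p4`),
#' and the parent BGC contains a transporter protein. The rule is monotone:
#' adding a positive vote can never revoke a call.
#'
#' @param p1,p2,p3,p4 logical predictor votes (vectorized).
#' @param transporter_in_bgc logical; transporter gene present in the BGC.
#' @return logical AMP decision vector.
#' @export
ensemble_vote <- function(p1, p2, p3, p4, transporter_in_bgc) {
  p1 & p2 & (p3 | p4) & transporter_in_bgc
}

#' Percentage hydrophobicity of a peptide
#'
#' Fraction of residues in the hydrophobic set, as a percentage reported to
#' one decimal. The default set {A, C, F, I, L, M, V, W} follows the common
#' APD-style convention and is configurable.
#'
#' @param sequence peptide sequence (standard alphabet).
#' @param hydrophobic character vector of hydrophobic residues.
#' @return percentage in `[0, 100]`.
#' @export
hydrophobic_fraction <- function(sequence,
                                 hydrophobic = c("A", "C", "F", "I", "L", "M", "V", "W")) {
  if (!nzchar(sequence)) stop("empty peptide sequence")
  chars <- check_peptide(sequence)
  round(100 * sum(chars %in% hydrophobic) / length(chars), 1)
}

#' Net charge of a peptide at neutral pH
#'
#' `(#K + #R) - (#D + #E)`; histidine is excluded by default and counted as
#' positive when `include_histidine = TRUE`.
#'
#' @param sequence peptide sequence (standard alphabet).
#' @param include_histidine count H as positive?
#' @return integer net charge.
#' @export
net_charge <- function(sequence, include_histidine = FALSE) {
  chars <- check_peptide(sequence)
  pos <- c("K", "R", if (include_histidine) "H")
  sum(chars %in% pos) - sum(chars %in% c("D", "E"))
}

#' Precision, recall and F1 of AMP decisions
#'
#' Standard confusion-matrix metrics. Degenerate denominators (no positive
#' calls, or no positive labels) yield `NA` rather than 0, so an undefined
#' metric is never silently reported as a bad one.
#'
#' @param decisions logical decision vector.
#' @param labels logical truth vector of the same length.
#' @return list with `precision`, `recall`, `f1`, and the confusion counts
#'   `tp`, `fp`, `fn`, `tn`.
#' @export
evaluate_ensemble <- function(decisions, labels) {
  if (length(decisions) != length(labels)) stop("decisions and labels differ in length")
  tp <- sum(decisions & labels); fp <- sum(decisions & !labels)
  fn <- sum(!decisions & labels); tn <- sum(!decisions & !labels)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(precision = precision, recall = recall, f1 = f1, tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Screen a peptide vote table for AMP candidates
#'
#' Applies length eligibility, the RiPP-BGC restriction and the ensemble
#' vote, and annotates each peptide with its physicochemical properties.
#'
#' @param table data.frame with `peptide_id`, `bgc_id`, `sequence`,
#'   `p1`..`p4`, `transporter_in_bgc`, `bgc_is_ripp`.
#' @param ... passed to [hydrophobic_fraction()] / [net_charge()].
#' @return the table with added `length`, `length_ok`, `amp_call`,
#'   `hydrophobic_pct`, `net_charge` columns.
#' @export
amp_screen <- function(table, ...) {
  req <- c("peptide_id", "sequence", "p1", "p2", "p3", "p4", "transporter_in_bgc", "bgc_is_ripp")
  if (!all(req %in% names(table)))
    stop("missing columns: ", paste(setdiff(req, names(table)), collapse = ", "))
  out <- table
  out$length <- nchar(out$sequence)
  out$length_ok <- length_eligible(out$sequence)
  out$amp_call <- out$bgc_is_ripp & out$length_ok &
    ensemble_vote(out$p1, out$p2, out$p3, out$p4, out$transporter_in_bgc)
  out$hydrophobic_pct <- vapply(out$sequence, hydrophobic_fraction, numeric(1), USE.NAMES = FALSE)
  out$net_charge <- vapply(out$sequence, net_charge, numeric(1), USE.NAMES = FALSE, ...)
  out
}
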