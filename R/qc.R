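#' Mask unreliable measurements by detection p-value
#'
#' Any cell whose detection p-value is strictly above \code{threshold} is
#' set to missing; all other cells are untouched. The operation is
#' idempotent.
#'
#' @param beta probes x samples beta matrix.
#' @param detp detection p-value matrix with identical dimnames.
#' @param threshold detection p-value cutoff (default 0.001).
#' @return list with \code{beta} (masked matrix) and \code{n_masked}.
#' @export
mask_by_detection <- function(beta, detp, threshold = 0.001) {
  validate_beta_matrix(beta)
  if (!identical(dimnames(beta), dimnames(detp)))
    stop("beta and detection p-value matrices have mismatched axes")
  mask <- !is.na(detp) & detp > threshold & !is.na(beta)
  beta[mask] <- NA_real_
  list(beta = beta, n_masked = sum(mask))
}

#' Filter probes and samples by missingness
#'
#' Probes whose missing fraction strictly exceeds \code{probe_max} are
#' removed first; then samples whose missing fraction, computed on the
#' probe-filtered matrix, strictly exceeds \code{sample_max} are removed.
#' The order matters: removing a bad probe can rescue a borderline sample.
#'
#' @param beta probes x samples beta matrix with NA for missing cells.
#' @param probe_max maximum tolerated probe missing fraction (default 0.05).
#' @param sample_max maximum tolerated sample missing fraction
#'   (default 0.05).
#' @return list with \code{beta} (filtered matrix) and \code{report}, a list
#'   recording dropped/retained probes and samples with their missing
#'   fractions.
#' @export
filter_missingness <- function(beta, probe_max = 0.05, sample_max = 0.05) {
  validate_beta_matrix(beta)
  probe_miss <- rowMeans(is.na(beta))
  drop_p <- probe_miss > probe_max
  kept <- beta[!drop_p, , drop = FALSE]
  if (nrow(kept) == 0L) stop("all probes removed by missingness filter")
  sample_miss <- colMeans(is.na(kept))
  drop_s <- sample_miss > sample_max
  out <- kept[, !drop_s, drop = FALSE]
  if (ncol(out) == 0L) stop("all samples removed by missingness filter")
  report <- list(
    n_cells_masked = sum(is.na(beta)),
    probes_dropped = data.frame(probe_id = rownames(beta)[drop_p],
                                missing_fraction = unname(probe_miss[drop_p]),
                                stringsAsFactors = FALSE),
    samples_dropped = data.frame(sample_id = colnames(kept)[drop_s],
                                 missing_fraction = unname(sample_miss[drop_s]),
                                 stringsAsFactors = FALSE),
    probes_retained = nrow(out),
    samples_retained = ncol(out)
  )
  list(beta = out, report = report)
}

#' Restrict several beta matrices to their common probe set
#'
#' Probes absent from any one dataset are excluded from all of them, so that
#' only probes measured everywhere enter joint normalisation and training.
#' Output matrices share an identical probe order (that of the first
#' matrix's surviving probes).
#'
#' @param mats list of >= 2 beta matrices.
#' @return list of matrices restricted to the common probes.
#' @export
intersect_probes <- function(mats) {
  if (!is.list(mats) || length(mats) < 2L)
    stop("need a list of >= 2 beta matrices")
  common <- Reduce(intersect, lapply(mats, rownames))
  if (length(common) == 0L) stop("empty probe intersection")
  common <- rownames(mats[[1L]])[rownames(mats[[1L]]) %in% common]
  lapply(mats, function(m) m[common, , drop = FALSE])
}
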