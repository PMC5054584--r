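#' Validate a beta-value matrix
#'
#' A beta matrix is a numeric matrix of methylation fractions (methylated
#' signal over total signal) with probes as rows and samples as columns.
#' Missing measurements are encoded as \code{NA}. Row and column names must
#' be unique, and every non-missing value must lie in \[0, 1\].
#'
#' @param beta numeric matrix, probes x samples, rownames = probe ids,
#'   colnames = sample ids.
#' @param what label used in error messages.
#' @return \code{beta}, invisibly, if valid; otherwise an error naming the
#'   offending probe/sample.
#' @export
validate_beta_matrix <- function(beta, what = "beta matrix") {
  if (!is.matrix(beta) || !is.numeric(beta))
    stop(what, " must be a numeric matrix")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop(what, " must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(beta)))
    stop(what, ": duplicate probe id '",
         rownames(beta)[duplicated(rownames(beta))][1L], "'")
  if (anyDuplicated(colnames(beta)))
    stop(what, ": duplicate sample id '",
         colnames(beta)[duplicated(colnames(beta))][1L], "'")
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(what, ": value ", format(beta[bad[1L, 1L], bad[1L, 2L]]),
         " outside [0,1] at probe '", rownames(beta)[bad[1L, 1L]],
         "', sample '", colnames(beta)[bad[1L, 2L]], "'")
  invisible(beta)
}

#' Read a beta-value or detection p-value matrix from delimited text
#'
#' Expects probe ids in the first column and sample ids in the header.
#' Empty fields (and any string in \code{na}) are read as missing.
#'
#' @param path file path.
#' @param sep field separator; \code{"\t"} (default) or \code{","}.
#' @param na character vector of missing-value sentinels in addition to the
#'   empty field.
#' @param what validation label: \code{"beta"} enforces values in \[0, 1\];
#'   \code{"detp"} likewise (detection p-values share the unit interval).
#' @return numeric matrix, probes x samples.
#' @export
read_beta_matrix <- function(path, sep = "\t", na = c("NA", "NaN"),
                             what = c("beta", "detp")) {
  what <- match.arg(what)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", na), check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2L)
    stop("malformed header: need a probe-id column plus >=1 sample column")
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  label <- if (what == "beta") "beta matrix" else "detection p-value matrix"
  validate_beta_matrix(m, what = label)
  m
}

#' Write a beta-value matrix to delimited text
#'
#' Inverse of [read_beta_matrix()]: probe ids in the first column
#' (\code{probe_id}), sample ids in the header, missing cells written as
#' empty fields.
#'
#' @param beta numeric probes x samples matrix.
#' @param path output path.
#' @param sep field separator.
#' @export
write_beta_matrix <- function(beta, path, sep = "\t") {
  validate_beta_matrix(beta)
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a sample sheet
#'
#' A CSV with one row per sample and columns \code{sample_id},
#' \code{clinical_ga_weeks}, \code{tissue} (\code{"cord"} or \code{"spot"}),
#' \code{days_to_sampling} (blood spots only), and optionally \code{sex},
#' \code{cohort}, \code{birthweight}, \code{birthweight_percentile},
#' \code{race}, \code{insurance}.
#'
#' @param path CSV path.
#' @return data.frame, validated by [validate_sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
  df
}

#' @rdname read_sample_sheet
#' @param sheet sample-sheet data.frame.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "clinical_ga_weeks", "tissue")
  miss <- setdiff(need, names(sheet))
  if (length(miss) > 0L)
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  if (!all(sheet$tissue %in% c("cord", "spot")))
    stop("tissue must be 'cord' or 'spot'")
  ga <- sheet$clinical_ga_weeks
  if (any(!is.na(ga) & (ga < 20 | ga > 46)))
    stop("clinical_ga_weeks outside plausibility window [20, 46]")
  spot <- sheet$tissue == "spot"
  if (any(spot)) {
    if (!"days_to_sampling" %in% names(sheet))
      stop("blood-spot samples present but no days_to_sampling column")
    d <- sheet$days_to_sampling[spot]
    if (any(is.na(d)) || any(d < 0))
      stop("days_to_sampling must be a non-negative number for every blood-spot sample")
  }
  invisible(sheet)
}

#' Effective gestational age at sampling
#'
#' Cord-blood samples are drawn at birth, so the clinical GA applies as-is.
#' Dried blood spots can be collected days after birth; their effective GA
#' is the clinical GA at birth plus the sampling delay in weeks
#' (\code{days_to_sampling / 7}).
#'
#' @param sheet sample-sheet data.frame (see [read_sample_sheet()]).
#' @return numeric vector of GA in decimal weeks, one per row, named by
#'   sample id.
#' @export
effective_ga <- function(sheet) {
  validate_sample_sheet(sheet)
  ga <- sheet$clinical_ga_weeks
  spot <- sheet$tissue == "spot"
  if (any(spot)) ga[spot] <- ga[spot] + sheet$days_to_sampling[spot] / 7
  stats::setNames(ga, sheet$sample_id)
}

#' Read a probe annotation table
#'
#' TSV with columns \code{probe_id}, \code{chromosome}, \code{position}
#' (1-based coordinate of the interrogated CpG) and optionally
#' \code{snp_in_probe} (logical: a genetic variant lies within the 50-bp
#' probe sequence).
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("probe_id", "chromosome", "position")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("probe annotation lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$probe_id)) stop("duplicate probe_id in annotation")
  if (any(df$position < 1)) stop("probe position must be >= 1")
  df
}
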