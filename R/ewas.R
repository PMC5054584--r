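#' Epigenome-wide association of methylation with gestational age
#'
#' Per-CpG ordinary least-squares regression of beta on GA, pooled across
#' cohorts as a fixed-effects meta-analysis: cohort indicator covariates are
#' included whenever more than one cohort is present (and dropped
#' automatically for single-cohort input), with estimated cell-type
#' proportions optionally added. All probes share one design matrix, so the
#' scan is a single QR decomposition followed by probe-wise residual
#' variances. GA is the effective GA at sampling (blood-spot delay
#' corrected).
#'
#' Constant probes (zero residual variance or zero beta variance) have an
#' undefined test statistic; they are flagged \code{degenerate} and excluded
#' from the significant-probe count.
#'
#' @param beta probes x samples matrix, QC'd/normalised, no missing values.
#' @param sheet sample sheet aligned to the columns of \code{beta}.
#' @param cells optional samples x cell-types proportion matrix; all but the
#'   first type enter as covariates when \code{adjust_cells = TRUE}.
#' @param adjust_cells include cell-composition covariates (default FALSE).
#' @param p_adjust multiple-testing correction for the \code{p_adj} column:
#'   \code{"none"} (default; nominal p-values are reported), or any method
#'   of [stats::p.adjust()].
#' @return object of class \code{"ewas_result"}: a data.frame (probe, slope
#'   in beta per week, se, t, p, p_adj, degenerate) with attributes
#'   \code{n_significant} (p < 0.05 among non-degenerate probes) and
#'   \code{n_samples}.
#' @export
ewas_ga <- function(beta, sheet, cells = NULL, adjust_cells = FALSE,
                    p_adjust = "none") {
  validate_beta_matrix(beta)
  stopifnot(ncol(beta) == nrow(sheet))
  if (anyNA(beta)) stop("beta contains missing values; impute first")
  ga <- unname(effective_ga(sheet)[colnames(beta)])
  if (anyNA(ga)) stop("sample sheet does not cover all samples")

  X <- cbind(`(Intercept)` = 1, ga = ga)
  if ("cohort" %in% names(sheet) && length(unique(sheet$cohort)) > 1L) {
    ch <- factor(sheet$cohort[match(colnames(beta), sheet$sample_id)])
    X <- cbind(X, stats::model.matrix(~ ch)[, -1L, drop = FALSE])
  }
  if (adjust_cells) {
    if (is.null(cells)) stop("adjust_cells = TRUE but no proportions given")
    cc <- cell_covariates(cells[colnames(beta), , drop = FALSE])
    X <- cbind(X, cc)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
  n <- nrow(X); q <- ncol(X)
  Y <- t(beta)                               # samples x probes
  cf <- qr.coef(qrX, Y)                      # q x probes
  res <- Y - X %*% cf
  sigma2 <- colSums(res^2) / (n - q)
  xtxinv_ga <- chol2inv(chol(crossprod(X)))[2L, 2L]  # (X'X)^-1, GA term
  se <- sqrt(sigma2 * xtxinv_ga)
  slope <- cf["ga", ]
  tval <- slope / se
  p <- 2 * stats::pt(-abs(tval), df = n - q)
  # a probe constant across samples has (numerically) zero residual variance
  degen <- !is.finite(tval) | sigma2 < 1e-20
  p[degen] <- NA_real_
  out <- data.frame(probe = rownames(beta), slope = unname(slope),
                    se = unname(se), t = unname(tval), p = unname(p),
                    degenerate = unname(degen), stringsAsFactors = FALSE)
  out$p_adj <- if (p_adjust == "none") out$p
               else stats::p.adjust(out$p, method = p_adjust)
  attr(out, "n_significant") <- sum(out$p < 0.05, na.rm = TRUE)
  attr(out, "n_samples") <- n
  class(out) <- c("ewas_result", "data.frame")
  out
}

#' Compare cell-adjusted and unadjusted EWAS statistics
#'
#' Pairs the per-probe t statistics of two scans over the same probe set and
#' reports their correlation: a correlation near 1 indicates the
#' associations are robust to cell-composition adjustment.
#'
#' @param results_unadj,results_adj two \code{"ewas_result"} objects on the
#'   same probes.
#' @return list: \code{pairs} (data.frame probe, t_unadj, t_adj) and
#'   \code{correlation}.
#' @export
compare_adjustment <- function(results_unadj, results_adj) {
  if (!identical(results_unadj$probe, results_adj$probe))
    stop("probe sets differ between the two EWAS results")
  pairs <- data.frame(probe = results_unadj$probe,
                      t_unadj = results_unadj$t, t_adj = results_adj$t,
                      stringsAsFactors = FALSE)
  ok <- is.finite(pairs$t_unadj) & is.finite(pairs$t_adj)
  list(pairs = pairs,
       correlation = stats::cor(pairs$t_unadj[ok], pairs$t_adj[ok]))
}
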