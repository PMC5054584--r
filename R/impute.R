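#' k-nearest-neighbour imputation of missing beta values
#'
#' For each missing cell (probe p, sample s) the k probes closest to p are
#' found by Euclidean distance computed over the samples where both probes
#' are observed and rescaled by the fraction of jointly observed samples
#' (so distances over different overlaps are comparable). Candidate
#' neighbours must be observed at sample s and share at least one observed
#' sample with p. The imputed value is the inverse-distance-weighted mean of
#' the k neighbours' values at s. Ties at equal distance are broken by
#' lexicographic probe id, making the result fully deterministic. A probe
#' with no eligible neighbour at some sample falls back to its own observed
#' mean, with a warning.
#'
#' @param beta probes x samples beta matrix with NA for missing cells;
#'   intended for post-QC matrices (every probe <= 5\% missing).
#' @param k number of neighbours (default 10, the standard choice for
#'   methylation and expression matrices).
#' @return beta matrix with no missing values; observed cells unchanged.
#' @export
knn_impute <- function(beta, k = 10L) {
  validate_beta_matrix(beta)
  if (nrow(beta) < k + 1L) stop("need at least k + 1 probes")
  miss <- is.na(beta)
  if (!any(miss)) return(beta)
  if (any(rowSums(!miss) == 0L))
    stop("probe with no observed values; filter before imputing")

  n_samp <- ncol(beta)
  O <- !miss                      # observed indicator
  X <- beta; X[miss] <- 0         # zero-filled values
  Om <- matrix(as.numeric(O), nrow(beta))
  X2 <- X^2

  need <- which(rowSums(miss) > 0L)
  # pairwise stats between probes-with-holes and all probes:
  # d2[i,j] = sum over jointly observed s of (x_i - x_j)^2
  cross_xx <- X[need, , drop = FALSE] %*% t(X)
  cross_x2o <- X2[need, , drop = FALSE] %*% t(Om)
  cross_ox2 <- Om[need, , drop = FALSE] %*% t(X2)
  njoint <- Om[need, , drop = FALSE] %*% t(Om)
  d2 <- cross_x2o + cross_ox2 - 2 * cross_xx
  d2 <- pmax(d2, 0)
  dist <- sqrt(d2 / pmax(njoint, 1) * n_samp)   # rescaled by fraction observed
  rownames(dist) <- rownames(beta)[need]

  out <- beta
  ids <- rownames(beta)
  fell_back <- character(0)
  for (ii in seq_along(need)) {
    p <- need[ii]
    for (s in which(miss[p, ])) {
      cand <- which(O[, s] & njoint[ii, ] > 0)
      cand <- cand[cand != p]
      if (length(cand) == 0L) {
        out[p, s] <- mean(beta[p, ], na.rm = TRUE)
        fell_back <- c(fell_back, ids[p])
        next
      }
      ord <- order(dist[ii, cand], ids[cand])
      nb <- cand[ord[seq_len(min(k, length(cand)))]]
      w <- 1 / (dist[ii, nb] + 1e-8)
      out[p, s] <- sum(w * beta[nb, s]) / sum(w)
    }
  }
  if (length(fell_back) > 0L)
    warning("no complete neighbour for probe(s) ",
            paste(unique(fell_back), collapse = ", "),
            "; probe mean used")
  out
}
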