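# Reference-based cell-composition estimation (constrained projection).
#
# A heterogeneous sample's methylation at cell-discriminating CpGs is
# modelled as a convex combination of purified cell-type reference profiles;
# the mixing weights are recovered by least squares under w >= 0 and
# sum(w) <= 1. The inequality (rather than equality) on the sum leaves room
# for cell types absent from the reference panel, as in cord blood.

#' Select cell-discriminating probes from purified reference data
#'
#' For each cell type, probes are ranked by the difference between that
#' type's mean beta and the mean of all other types; the top
#' \code{n_per_type} up-methylated and top \code{n_per_type} down-methylated
#' probes are taken, and the union over types forms the reference profile
#' set.
#'
#' @param reference_raw probes x cell-types matrix of mean beta per purified
#'   type (or a list of per-type replicate matrices, which are averaged).
#' @param n_per_type probes per direction per type (default 50).
#' @return list of class \code{"cell_reference"}: \code{profiles} (selected
#'   probes x types), \code{probe_ids}, \code{cell_types}.
#' @export
select_discriminating_probes <- function(reference_raw, n_per_type = 50L) {
  if (is.list(reference_raw) && !is.matrix(reference_raw))
    reference_raw <- sapply(reference_raw, rowMeans)
  R <- reference_raw
  if (ncol(R) < 2L) stop("need >= 2 cell types")
  sel <- character(0)
  for (k in seq_len(ncol(R))) {
    d <- R[, k] - rowMeans(R[, -k, drop = FALSE])
    if (all(d == 0))
      warning("cell type '", colnames(R)[k],
              "' is indistinguishable from the others")
    n_take <- min(n_per_type, nrow(R))
    if (n_per_type > nrow(R))
      warning("fewer probes than requested; taking all")
    up <- rownames(R)[order(-d, rownames(R))][seq_len(n_take)]
    dn <- rownames(R)[order(d, rownames(R))][seq_len(n_take)]
    sel <- union(sel, c(up, dn))
  }
  sel <- rownames(R)[rownames(R) %in% sel]
  structure(list(profiles = R[sel, , drop = FALSE], probe_ids = sel,
                 cell_types = colnames(R)),
            class = "cell_reference")
}

# Exact solver for min ||y - R w||^2 s.t. w >= 0, sum(w) <= 1.
# The QP is convex with few variables, so the optimum is found exactly by
# enumerating active sets: every subset of zeroed coordinates, with and
# without the sum constraint active, yields an equality-constrained least-
# squares candidate; the feasible candidate with the lowest objective is the
# solution.
solve_mixture_qp <- function(R, y) {
  k <- ncol(R)
  best_w <- rep(0, k)
  best_obj <- sum(y^2)            # objective at w = 0
  for (free_mask in seq_len(2^k) - 1L) {
    free <- which(bitwAnd(free_mask, bitwShiftL(1L, seq_len(k) - 1L)) > 0L)
    if (length(free) == 0L) next
    Rf <- R[, free, drop = FALSE]
    G <- crossprod(Rf)
    b <- crossprod(Rf, y)
    for (sum_active in c(FALSE, TRUE)) {
      w_free <- if (!sum_active) {
        sol <- tryCatch(solve(G, b), error = function(e) NULL)
        if (is.null(sol)) next
        as.numeric(sol)
      } else {
        ones <- rep(1, length(free))
        K <- rbind(cbind(2 * G, ones), c(ones, 0))
        sol <- tryCatch(solve(K, c(2 * b, 1)), error = function(e) NULL)
        if (is.null(sol)) next
        as.numeric(sol[seq_along(free)])
      }
      if (any(w_free < -1e-10) || sum(w_free) > 1 + 1e-10) next
      w <- rep(0, k); w[free] <- pmax(w_free, 0)
      obj <- sum((y - R %*% w)^2)
      if (obj < best_obj - 1e-12) { best_obj <- obj; best_w <- w }
    }
  }
  best_w
}

#' Estimate cell-type proportions by constrained projection
#'
#' Solves, per sample, \eqn{\min_w \|y - Rw\|^2} subject to \eqn{w \ge 0}
#' and \eqn{\sum w \le 1}, where \eqn{R} holds the reference profiles at the
#' discriminating probes and \eqn{y} the sample's betas at those probes.
#'
#' @param beta probes x samples beta matrix (or a single named vector).
#' @param reference a \code{"cell_reference"} from
#'   [select_discriminating_probes()], or a bare probes x types profile
#'   matrix.
#' @return samples x cell-types matrix of proportions (each >= 0, row sums
#'   <= 1).
#' @export
estimate_proportions <- function(beta, reference) {
  R <- if (inherits(reference, "cell_reference")) reference$profiles
       else reference
  if (is.null(dim(beta))) beta <- matrix(beta, ncol = 1L,
                                         dimnames = list(names(beta), "sample"))
  have <- intersect(rownames(R), rownames(beta))
  if (length(have) < 0.5 * nrow(R))
    stop("less than 50% of reference probes present in input")
  R <- R[have, , drop = FALSE]
  out <- matrix(NA_real_, ncol(beta), ncol(R),
                dimnames = list(colnames(beta), colnames(R)))
  for (j in seq_len(ncol(beta))) {
    y <- beta[have, j]
    ok <- !is.na(y)
    out[j, ] <- solve_mixture_qp(R[ok, , drop = FALSE], y[ok])
  }
  out
}
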