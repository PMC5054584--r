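# Gold-standard BMIQ calibration.
#
# Array-wide beta distributions are modelled as a 3-state beta mixture:
# unmethylated (U), hemimethylated (H), methylated (M). Each sample is
# calibrated to a reference ("gold standard") distribution by per-state
# quantile transport: U and M values are carried through the beta CDF of the
# sample state to the quantile function of the matching reference state; H
# values are mapped by the piecewise-linear dilation that keeps the state
# boundaries continuous.

BETA_EPS <- 1e-6

mom_beta_shapes <- function(x, w = NULL) {
  # weighted method-of-moments start values for a beta distribution
  if (is.null(w)) w <- rep(1, length(x))
  sw <- sum(w)
  m <- sum(w * x) / sw
  v <- sum(w * (x - m)^2) / sw
  v <- max(v, 1e-6)
  common <- max(m * (1 - m) / v - 1, 0.1)
  c(a = max(m * common, 0.05), b = max((1 - m) * common, 0.05))
}

# Weighted beta log-likelihood through its sufficient statistics
# (sw = sum w, slx = sum w*log x, sl1x = sum w*log(1-x)), so each
# evaluation inside the M-step is O(1) regardless of sample size.
wbeta_loglik_ss <- function(shape, sw, slx, sl1x) {
  (shape[1] - 1) * slx + (shape[2] - 1) * sl1x - sw * lbeta(shape[1], shape[2])
}

# Weighted ML for beta shapes by damped Newton on the sufficient statistics;
# step-halving guarantees the component objective never decreases, so the
# surrounding EM is a generalised EM with monotone log-likelihood.
wbeta_mle_ss <- function(shape, sw, slx, sl1x, n_steps = 8L) {
  cur <- wbeta_loglik_ss(shape, sw, slx, sl1x)
  for (i in seq_len(n_steps)) {
    a <- shape[1]; b <- shape[2]
    if (!is.finite(a) || !is.finite(b)) break
    g <- c(slx - sw * (digamma(a) - digamma(a + b)),
           sl1x - sw * (digamma(b) - digamma(a + b)))
    tab <- trigamma(a + b)
    H <- matrix(c(-sw * (trigamma(a) - tab), sw * tab,
                  sw * tab, -sw * (trigamma(b) - tab)), 2L)
    step <- tryCatch(-solve(H, g), error = function(e) g / sw)
    if (anyNA(step) || any(!is.finite(step))) break
    lam <- 1
    repeat {
      cand <- shape + lam * step
      if (isTRUE(all(cand > 1e-3 & cand < 1e7))) {
        val <- wbeta_loglik_ss(cand, sw, slx, sl1x)
        if (is.finite(val) && val >= cur) { shape <- cand; cur <- val; break }
      }
      lam <- lam / 2
      if (lam < 1e-4) break
    }
    if (isTRUE(sqrt(sum(g^2)) < 1e-8 * sw)) break
  }
  shape
}

#' Fit a three-state beta mixture to array beta values
#'
#' EM fit of a mixture of three beta distributions representing the
#' unmethylated, hemimethylated, and methylated states of an array-wide
#' beta-value distribution. Initialisation is deterministic: values are hard-
#' assigned by thresholds (U: beta < 0.25; H: 0.25--0.75; M: beta > 0.75)
#' and each component starts at its method-of-moments shapes. The M step
#' maximises each component's weighted beta log-likelihood numerically and
#' never accepts a downhill move, so the observed-data log-likelihood is
#' non-decreasing across iterations.
#'
#' @param x numeric vector of >= 100 beta values; values at 0/1 are clamped
#'   to \[1e-6, 1 - 1e-6\] before fitting.
#' @param max_iter maximum EM iterations (default 500).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param init optional \code{"beta_mixture_fit"} to warm-start from
#'   (e.g. the gold-standard fit when calibrating many similar arrays).
#' @return object of class \code{"beta_mixture_fit"}: \code{weights} (named
#'   U/H/M, summing to 1), \code{shapes} (3 x 2 matrix of beta parameters),
#'   \code{loglik} (final value), \code{loglik_trace}, \code{n_iter},
#'   \code{converged}.
#' @export
fit_beta_mixture <- function(x, max_iter = 500L, tol = 1e-6, init = NULL) {
  x <- x[!is.na(x)]
  if (length(x) < 100L) stop("need >= 100 finite values to fit the mixture")
  x <- clamp(x, BETA_EPS, 1 - BETA_EPS)
  n <- length(x)

  if (!is.null(init)) {
    stopifnot(inherits(init, "beta_mixture_fit"))
    shapes <- init$shapes
    weights <- init$weights
  } else {
    state0 <- cut(x, c(-Inf, 0.25, 0.75, Inf), labels = c("U", "H", "M"))
    shapes <- rbind(U = c(1, 9), H = c(5, 5), M = c(9, 1))
    colnames(shapes) <- c("a", "b")
    weights <- as.numeric(table(state0)) / n
    weights <- pmax(weights, 0.01); weights <- weights / sum(weights)
    names(weights) <- c("U", "H", "M")
    for (k in 1:3) {
      xs <- x[as.integer(state0) == k]
      if (length(xs) >= 5L) shapes[k, ] <- mom_beta_shapes(xs)
    }
  }

  L <- cbind(log(x), log1p(-x))
  lx0 <- L[, 1L]; l1x0 <- L[, 2L]
  comp_dens <- function() {
    # w_k * dbeta(x, a_k, b_k) from the precomputed logs, all components
    ld <- L %*% t(shapes - 1)
    ld <- sweep(ld, 2L, log(weights) - lbeta(shapes[, 1], shapes[, 2]), "+")
    pmax(exp(ld), 1e-300)
  }

  lx <- lx0; l1x <- l1x0
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  ll <- -Inf
  repeat {
    it <- it + 1L
    dens <- comp_dens()
    tot <- rowSums(dens)
    ll_new <- sum(log(tot))
    if (!is.finite(ll_new)) { ll_new <- ll; break }  # keep last valid state
    trace <- c(trace, ll_new)
    if (is.finite(ll) &&
        abs(ll_new - ll) < tol * (abs(ll) + tol)) { converged <- TRUE; break }
    ll <- ll_new
    if (it >= max_iter) break
    resp <- dens / tot
    weights <- colSums(resp) / n
    names(weights) <- c("U", "H", "M")
    for (k in 1:3) {
      rk <- resp[, k]
      sw <- sum(rk)
      if (sw < 1e-8) next
      slx <- sum(rk * lx); sl1x <- sum(rk * l1x)
      shapes[k, ] <- wbeta_mle_ss(shapes[k, ], sw, slx, sl1x)
    }
  }
  if (!converged)
    warning("beta-mixture EM did not converge in ", max_iter, " iterations")

  # relabel components: each is assigned to the state (U/H/M) whose
  # canonical beta anchor (0.1 / 0.5 / 0.9) it sits nearest, weighted by the
  # mixture weight so a dominant mid-range component is labelled H even when
  # the empty flanking components collapse onto it. For well-separated fits
  # this reduces to ordering by component mean (mean_U < mean_H < mean_M).
  mns <- shapes[, 1] / rowSums(shapes)
  anchors <- c(U = 0.1, H = 0.5, M = 0.9)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  cost <- vapply(perms, function(p)
    sum(weights[p] * abs(mns[p] - anchors)), numeric(1))
  tie <- vapply(perms, function(p) sum(abs(order(mns) - p)), numeric(1))
  ord <- perms[[order(cost, tie)[1L]]]
  shapes <- shapes[ord, , drop = FALSE]
  weights <- weights[ord]
  rownames(shapes) <- names(weights) <- c("U", "H", "M")

  structure(list(weights = weights, shapes = shapes,
                 loglik = ll_new, loglik_trace = trace,
                 n_iter = it, converged = converged),
            class = "beta_mixture_fit")
}

#' @export
print.beta_mixture_fit <- function(x, ...) {
  cat("3-state beta mixture fit\n")
  mns <- x$shapes[, 1] / rowSums(x$shapes)
  for (k in c("U", "H", "M"))
    cat(sprintf("  %s: w = %.3f, shape = (%.2f, %.2f), mean = %.3f\n",
                k, x$weights[k], x$shapes[k, 1], x$shapes[k, 2], mns[k]))
  cat(sprintf("  log-likelihood %.2f after %d iterations (%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

# Maximum-posterior state assignment; ties go to the lower-mean state
# because components are ordered U, H, M and max.col uses "first".
classify_states <- function(fit, x) {
  x <- clamp(x, BETA_EPS, 1 - BETA_EPS)
  post <- vapply(1:3, function(k)
    fit$weights[k] * stats::dbeta(x, fit$shapes[k, 1], fit$shapes[k, 2]),
    numeric(length(x)))
  if (length(x) == 1L) post <- matrix(post, nrow = 1L)
  c("U", "H", "M")[max.col(post, ties.method = "first")]
}

#' Build a gold-standard reference from training beta matrices
#'
#' The gold standard is the probe-wise mean beta across all samples of all
#' training datasets (missing cells ignored), together with its three-state
#' beta-mixture fit. Every training and test array is subsequently
#' calibrated against this single reference.
#'
#' @param mats list of beta matrices sharing an identical probe set (run
#'   [intersect_probes()] first).
#' @param ... passed to [fit_beta_mixture()].
#' @return object of class \code{"gold_standard"}: \code{probe_ids},
#'   \code{values} (named mean vector), \code{fit}.
#' @export
build_gold_standard <- function(mats, ...) {
  if (!is.list(mats) || length(mats) < 1L) stop("need a list of beta matrices")
  ids <- rownames(mats[[1L]])
  for (m in mats)
    if (!identical(rownames(m), ids))
      stop("probe mismatch: run intersect_probes() before building the gold standard")
  pooled <- do.call(cbind, mats)
  values <- rowMeans(pooled, na.rm = TRUE)
  structure(list(probe_ids = ids,
                 values = stats::setNames(values, ids),
                 fit = fit_beta_mixture(values, ...)),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("gold-standard reference over", length(x$probe_ids), "probes\n")
  print(x$fit)
  invisible(x)
}

transport_state <- function(x, from, to) {
  q <- stats::pbeta(clamp(x, BETA_EPS, 1 - BETA_EPS), from[1], from[2])
  stats::qbeta(q, to[1], to[2])
}

#' Calibrate one array to the gold standard (BMIQ transport)
#'
#' Each value is assigned to the U/H/M state with maximal posterior under
#' the sample's own mixture fit. U-state values are mapped by beta-CDF
#' quantile matching from the sample's U component to the gold standard's U
#' component; M-state values likewise. H-state values are mapped by the
#' linear dilation that carries the sample's U/H and H/M boundaries onto
#' their transported images, keeping the overall map continuous and
#' order-preserving within each state. Missing values pass through
#' untouched.
#'
#' @param x numeric vector of beta values aligned to the gold-standard
#'   probes (NAs allowed).
#' @param gold a \code{"gold_standard"} object (or a bare
#'   \code{"beta_mixture_fit"} to calibrate against directly).
#' @param sample_fit optional precomputed mixture fit for \code{x}; fitted
#'   from the observed values when \code{NULL}. If fitting fails the values
#'   are returned unchanged with a warning.
#' @param init,tol,max_iter passed to [fit_beta_mixture()] when the sample
#'   fit is computed here.
#' @return calibrated numeric vector in \[0, 1\], same length/names as
#'   \code{x}.
#' @export
bmiq_calibrate <- function(x, gold, sample_fit = NULL, init = NULL,
                           tol = 1e-6, max_iter = 500L) {
  gfit <- if (inherits(gold, "gold_standard")) gold$fit else gold
  if (!inherits(gfit, "beta_mixture_fit"))
    stop("gold must be a gold_standard or beta_mixture_fit object")
  obs <- which(!is.na(x))
  if (length(obs) == 0L) return(x)
  if (is.null(sample_fit)) {
    sample_fit <- tryCatch(fit_beta_mixture(x[obs], init = init,
                                            tol = tol, max_iter = max_iter),
                           error = function(e) {
      warning("mixture fit failed (", conditionMessage(e),
              "); returning values uncalibrated")
      NULL
    })
    if (is.null(sample_fit)) return(x)
  }
  v <- x[obs]
  st <- classify_states(sample_fit, v)
  out <- v

  if (any(st == "U"))
    out[st == "U"] <- transport_state(v[st == "U"],
                                      sample_fit$shapes["U", ],
                                      gfit$shapes["U", ])
  if (any(st == "M"))
    out[st == "M"] <- transport_state(v[st == "M"],
                                      sample_fit$shapes["M", ],
                                      gfit$shapes["M", ])
  if (any(st == "H")) {
    # anchors: top of the sample's U state and bottom of its M state
    Ls <- if (any(st == "U")) max(v[st == "U"]) else 0
    Rs <- if (any(st == "M")) min(v[st == "M"]) else 1
    Lt <- if (any(st == "U"))
      transport_state(Ls, sample_fit$shapes["U", ], gfit$shapes["U", ]) else 0
    Rt <- if (any(st == "M"))
      transport_state(Rs, sample_fit$shapes["M", ], gfit$shapes["M", ]) else 1
    if (Rs > Ls && Rt > Lt) {
      out[st == "H"] <- Lt + (v[st == "H"] - Ls) * (Rt - Lt) / (Rs - Ls)
    } # degenerate anchors: leave H values in place (still monotone)
  }
  x[obs] <- clamp(out, 0, 1)
  x
}

#' Calibrate every sample of a beta matrix to the gold standard
#'
#' Applies [bmiq_calibrate()] column-wise. Probes are aligned to the gold
#' standard by id; probes absent from the gold standard are dropped with a
#' warning.
#'
#' @param beta probes x samples beta matrix.
#' @param gold a \code{"gold_standard"} object.
#' @param tol per-sample EM tolerance; the matrix default (1e-5) is looser
#'   than the single-fit default because the transport map depends only
#'   weakly on the final digits of the shape parameters.
#' @param max_iter per-sample EM iteration cap.
#' @return calibrated beta matrix restricted to gold-standard probes.
#' @export
calibrate_to_gold <- function(beta, gold, tol = 1e-5, max_iter = 500L) {
  stopifnot(inherits(gold, "gold_standard"))
  keep <- rownames(beta) %in% gold$probe_ids
  if (!all(keep)) {
    warning(sum(!keep), " probe(s) absent from the gold standard dropped")
    beta <- beta[keep, , drop = FALSE]
  }
  if (nrow(beta) == 0L) stop("no probes overlap the gold standard")
  out <- beta
  # warm-starting each sample's EM from the gold fit saves most iterations
  for (j in seq_len(ncol(beta)))
    out[, j] <- bmiq_calibrate(beta[, j], gold, init = gold$fit,
                               tol = tol, max_iter = max_iter)
  out
}
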