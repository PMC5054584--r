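#' Cross-validated penalty selection for the elastic-net clock
#'
#' Samples are randomly partitioned into \code{nfolds} near-equal folds
#' (seeded). For each lambda on a shared path -- 100 values log-spaced from
#' the smallest lambda giving an all-zero solution down to 1e-4 of it -- the
#' model is refit on the out-of-fold samples and the mean squared error is
#' computed on the held-out fold; the per-lambda CV error is the average of
#' the fold-wise MSEs. The selected lambda minimises the mean CV MSE.
#'
#' @param x samples x probes predictor matrix, no missing values.
#' @param y gestational age in weeks, one value per sample.
#' @param alpha elastic-net mixing parameter in \[0, 1\] (default 0.5:
#'   equal contribution of the ridge and lasso penalties).
#' @param nfolds number of cross-validation folds (default 10).
#' @param seed integer seed for the fold partition.
#' @param standardize standardise predictors internally for fitting
#'   (coefficients are always reported on the original beta scale).
#' @param lambda optional lambda path; computed from the full data when
#'   \code{NULL}.
#' @return list: \code{lambda_min}, \code{lambda} (path), \code{cvm} (mean
#'   CV MSE per lambda), \code{cvm_folds} (folds x lambda MSE matrix),
#'   \code{foldid}.
#' @export
cv_lambda <- function(x, y, alpha = 0.5, nfolds = 10L, seed = 1L,
                      standardize = TRUE, lambda = NULL) {
  stopifnot(nrow(x) == length(y), nfolds >= 2L, alpha >= 0, alpha <= 1)
  if (nrow(x) < nfolds) stop("need at least nfolds samples")
  if (stats::var(y) == 0) stop("response has zero variance")
  if (anyNA(x)) stop("x contains missing values; impute first")

  if (is.null(lambda)) {
    full <- glmnet::glmnet(x, y, alpha = alpha, standardize = standardize,
                           nlambda = 100L, lambda.min.ratio = 1e-4)
    lambda <- full$lambda
  }
  n <- nrow(x)
  foldid <- with_seed(seed, sample(rep(seq_len(nfolds), length.out = n)))
  cvm_folds <- matrix(NA_real_, nfolds, length(lambda))
  for (f in seq_len(nfolds)) {
    inf <- foldid == f
    fit <- glmnet::glmnet(x[!inf, , drop = FALSE], y[!inf], alpha = alpha,
                          standardize = standardize, lambda = lambda)
    pred <- stats::predict(fit, x[inf, , drop = FALSE], s = lambda)
    cvm_folds[f, ] <- colMeans((pred - y[inf])^2)
  }
  cvm <- colMeans(cvm_folds)
  list(lambda_min = lambda[which.min(cvm)], lambda = lambda, cvm = cvm,
       cvm_folds = cvm_folds, foldid = foldid)
}

#' Fit a gestational-age epigenetic clock
#'
#' Elastic-net regression of gestational age on CpG beta values, following
#' the standard epigenetic-clock recipe: mixing parameter alpha = 0.5, the
#' penalty chosen by tenfold cross-validation as the lambda minimising the
#' mean held-out squared error, and no covariates besides the CpGs. The
#' returned clock keeps only the CpGs with nonzero coefficients.
#'
#' @param x samples x probes matrix of normalised, imputed beta values, or a
#'   probes x samples beta matrix (detected from dimnames when \code{y} is
#'   named -- the canonical orientation is samples in rows here).
#' @param y gestational age in weeks per sample.
#' @param alpha,nfolds,seed,standardize see [cv_lambda()].
#' @param gold optional \code{"gold_standard"} object; its probe means are
#'   stored so predictions can fall back on them when a clock CpG is absent
#'   from a new dataset.
#' @return object of class \code{"ga_clock"}: \code{intercept} (weeks),
#'   \code{coefficients} (named vector, weeks per unit beta, nonzero only),
#'   \code{lambda_min}, \code{alpha}, \code{cv} (the [cv_lambda()] result),
#'   \code{gold_means}, \code{training} (descriptor: n, probe count, GA
#'   range).
#' @seealso [predict.ga_clock()], [accuracy_metrics()], [ga_acceleration()]
#' @export
ga_clock <- function(x, y, alpha = 0.5, nfolds = 10L, seed = 1L,
                     standardize = TRUE, gold = NULL) {
  stopifnot(is.matrix(x), is.numeric(y))
  if (nrow(x) != length(y) && ncol(x) == length(y)) x <- t(x)
  stopifnot(nrow(x) == length(y))
  cv <- cv_lambda(x, y, alpha = alpha, nfolds = nfolds, seed = seed,
                  standardize = standardize)
  fit <- glmnet::glmnet(x, y, alpha = alpha, standardize = standardize,
                        lambda = cv$lambda)
  cf <- stats::coef(fit, s = cv$lambda_min)
  cf <- stats::setNames(as.numeric(cf), rownames(cf))
  coefs <- cf[-1L][cf[-1L] != 0]
  if (length(coefs) == 0L)
    stop("no CpGs selected at lambda_min; try a smaller lambda or alpha")
  gm <- if (!is.null(gold)) gold$values else NULL
  structure(list(intercept = unname(cf[1L]), coefficients = coefs,
                 lambda_min = cv$lambda_min, alpha = alpha, cv = cv,
                 gold_means = gm,
                 training = list(n = nrow(x), n_probes = ncol(x),
                                 ga_range = range(y)),
                 call = match.call()),
            class = "ga_clock")
}

#' @export
print.ga_clock <- function(x, ...) {
  cat("Gestational-age epigenetic clock\n")
  cat(sprintf("  %d CpGs (alpha = %.2f, lambda = %.4g)\n",
              length(x$coefficients), x$alpha, x$lambda_min))
  cat(sprintf("  intercept: %.3f weeks\n", x$intercept))
  if (!is.null(x$training))
    cat(sprintf("  trained on %d samples x %d probes, GA %.1f-%.1f weeks\n",
                x$training$n, x$training$n_probes,
                x$training$ga_range[1], x$training$ga_range[2]))
  invisible(x)
}

#' @export
coef.ga_clock <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
summary.ga_clock <- function(object, ...) {
  cf <- object$coefficients
  out <- list(n_cpgs = length(cf), intercept = object$intercept,
              alpha = object$alpha, lambda_min = object$lambda_min,
              coef_range = range(cf),
              n_positive = sum(cf > 0), n_negative = sum(cf < 0),
              cv_mse_min = min(object$cv$cvm))
  class(out) <- "summary.ga_clock"
  out
}

#' @export
print.summary.ga_clock <- function(x, ...) {
  cat(sprintf("GA clock: %d CpGs (%d +, %d -), intercept %.3f weeks\n",
              x$n_cpgs, x$n_positive, x$n_negative, x$intercept))
  cat(sprintf("  alpha %.2f, lambda_min %.4g, CV MSE %.4f\n",
              x$alpha, x$lambda_min, x$cv_mse_min))
  invisible(x)
}

#' @export
plot.ga_clock <- function(x, ...) {
  graphics::plot(log(x$cv$lambda), x$cv$cvm, type = "b", pch = 20,
                 xlab = "log(lambda)", ylab = "mean CV MSE (weeks^2)", ...)
  graphics::abline(v = log(x$lambda_min), lty = 2)
  invisible(x)
}

#' Predict DNAm gestational age
#'
#' The DNAm GA of a sample is the clock intercept plus the inner product of
#' the clock coefficients with the sample's beta values at the clock CpGs.
#' Clock CpGs absent from the input are filled with the gold-standard mean
#' for that probe (a warning lists them); if more than 20\% of the clock
#' CpGs are missing the prediction is deemed unreliable and an error is
#' raised.
#'
#' @param object a \code{"ga_clock"} (or clock read by [read_clock_model()]).
#' @param beta probes x samples beta matrix, normalised and imputed.
#' @param gold optional \code{"gold_standard"} overriding the means stored
#'   in the clock.
#' @param sheet optional sample sheet; when present, clinical GA (corrected
#'   for blood-spot sampling delay via [effective_ga()]) is attached.
#' @param ... unused.
#' @return data.frame with columns \code{sample_id}, \code{dnam_ga_weeks},
#'   and, when \code{sheet} is given, \code{clinical_ga_weeks}.
#' @export
predict.ga_clock <- function(object, beta, gold = NULL, sheet = NULL, ...) {
  cf <- object$coefficients
  probes <- names(cf)
  missing_p <- setdiff(probes, rownames(beta))
  if (length(missing_p) > 0.2 * length(probes))
    stop(length(missing_p), " of ", length(probes),
         " clock CpGs missing from input (> 20%); prediction unreliable")
  gm <- if (!is.null(gold)) gold$values else object$gold_means
  B <- matrix(NA_real_, length(probes), ncol(beta),
              dimnames = list(probes, colnames(beta)))
  have <- intersect(probes, rownames(beta))
  B[have, ] <- beta[have, ]
  if (length(missing_p) > 0L) {
    if (is.null(gm) || !all(missing_p %in% names(gm)))
      stop("clock CpGs missing and no gold-standard means available: ",
           paste(missing_p, collapse = ", "))
    warning("clock CpG(s) absent from input, gold-standard mean used: ",
            paste(missing_p, collapse = ", "))
    B[missing_p, ] <- gm[missing_p]
  }
  if (anyNA(B)) stop("missing beta values at clock CpGs; impute first")
  pred <- object$intercept + as.numeric(crossprod(B, cf))
  out <- data.frame(sample_id = colnames(beta), dnam_ga_weeks = pred,
                    stringsAsFactors = FALSE)
  if (!is.null(sheet)) {
    ega <- effective_ga(sheet)
    out$clinical_ga_weeks <- unname(ega[out$sample_id])
  }
  out
}

#' Prediction accuracy metrics
#'
#' Pearson correlation between predicted and clinical GA plus the median,
#' mean and SD of the absolute error in weeks.
#'
#' @param pred predicted GA (weeks), or the data.frame returned by
#'   [predict.ga_clock()] with a \code{clinical_ga_weeks} column.
#' @param clinical clinical GA (weeks); ignored when \code{pred} is a
#'   prediction data.frame carrying it.
#' @return list: \code{r}, \code{median_abs_err}, \code{mean_abs_err},
#'   \code{sd_abs_err}, \code{n}.
#' @export
accuracy_metrics <- function(pred, clinical = NULL) {
  if (is.data.frame(pred)) {
    clinical <- clinical %||% pred$clinical_ga_weeks
    pred <- pred$dnam_ga_weeks
  }
  ok <- !is.na(pred) & !is.na(clinical)
  pred <- pred[ok]; clinical <- clinical[ok]
  if (length(pred) < 3L) stop("need >= 3 paired values")
  err <- abs(pred - clinical)
  list(r = stats::cor(pred, clinical),
       median_abs_err = stats::median(err),
       mean_abs_err = mean(err),
       sd_abs_err = stats::sd(err),
       n = length(pred))
}

#' Read / write a clock coefficient file
#'
#' Clocks are serialised as a two-column CSV (\code{term},
#' \code{coefficient}) with exactly one \code{"(Intercept)"} row and one row
#' per CpG, the conventional shape for published clock coefficient tables.
#'
#' @param path CSV path.
#' @return [read_clock_model()]: a \code{"ga_clock"} object (without CV
#'   metadata).
#' @export
read_clock_model <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("term", "coefficient") %in% names(df)))
    stop("clock file needs columns 'term' and 'coefficient'")
  ic <- df$term == "(Intercept)"
  if (sum(ic) != 1L) stop("clock file must contain exactly one (Intercept) row")
  probes <- df$term[!ic]
  if (anyDuplicated(probes)) stop("duplicate probe in clock file")
  if (length(probes) == 0L) stop("clock file contains no CpG coefficients")
  intercept <- df$coefficient[ic]
  if (!is.finite(intercept)) stop("intercept must be finite")
  structure(list(intercept = intercept,
                 coefficients = stats::setNames(df$coefficient[!ic], probes),
                 lambda_min = NA_real_, alpha = NA_real_, cv = NULL,
                 gold_means = NULL, training = NULL, call = NULL),
            class = "ga_clock")
}

#' @rdname read_clock_model
#' @param model a \code{"ga_clock"} object.
#' @export
write_clock_model <- function(model, path) {
  stopifnot(inherits(model, "ga_clock"))
  df <- data.frame(term = c("(Intercept)", names(model$coefficients)),
                   # %.17g round-trips doubles exactly through text
                   coefficient = sprintf("%.17g",
                                         c(model$intercept,
                                           unname(model$coefficients))),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
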