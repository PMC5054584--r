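#' Gestational-age acceleration
#'
#' GA acceleration is the residual from an ordinary least-squares regression
#' of DNAm GA on clinical GA over the combined prediction set: positive
#' values mean the methylome looks "older" than the clinical estimate. By
#' construction the residuals sum to zero and are uncorrelated with clinical
#' GA.
#'
#' @param dnam_ga DNAm GA in weeks, or the data.frame from
#'   [predict.ga_clock()] carrying both columns.
#' @param clinical_ga clinical GA in weeks.
#' @return numeric vector of residuals (weeks), named by sample id when
#'   available.
#' @export
ga_acceleration <- function(dnam_ga, clinical_ga = NULL) {
  nm <- NULL
  if (is.data.frame(dnam_ga)) {
    clinical_ga <- clinical_ga %||% dnam_ga$clinical_ga_weeks
    nm <- dnam_ga$sample_id
    dnam_ga <- dnam_ga$dnam_ga_weeks
  }
  if (length(dnam_ga) < 3L) stop("need >= 3 paired values")
  if (stats::var(clinical_ga) == 0) stop("clinical GA has zero variance")
  res <- stats::resid(stats::lm(dnam_ga ~ clinical_ga))
  if (!is.null(nm)) names(res) <- nm else res <- unname(res)
  res
}

# Cell proportions enter association models as all-but-one components: the
# proportions sum to (at most) 1, so the full set is collinear with the
# intercept. The first column is dropped.
cell_covariates <- function(cells) {
  if (is.null(cells)) return(NULL)
  cells <- as.matrix(cells)
  if (ncol(cells) < 2L) return(cells)
  cells[, -1L, drop = FALSE]
}

build_assoc_frame <- function(accel, sheet, cells) {
  df <- data.frame(ga_acceleration = accel,
                   clinical_ga = effective_ga(sheet),
                   stringsAsFactors = FALSE)
  for (v in c("race", "cohort"))
    if (v %in% names(sheet) && length(unique(sheet[[v]])) > 1L)
      df[[v]] <- factor(sheet[[v]])
  cc <- cell_covariates(cells)
  if (!is.null(cc)) {
    colnames(cc) <- paste0("cell_", colnames(cc))
    df <- cbind(df, as.data.frame(cc))
  }
  df
}

#' Association of birthweight with GA acceleration
#'
#' Linear regression of birthweight (grams) or birthweight percentile on GA
#' acceleration with covariates for race, estimated cell-type proportions,
#' and cohort. Clinical GA is added as a covariate for birthweight in grams
#' but not for the percentile, which is already adjusted for clinical GA by
#' definition. Perfectly collinear covariates are dropped by the fit with a
#' warning.
#'
#' @param accel GA-acceleration residuals, aligned with \code{sheet} rows.
#' @param sheet sample sheet carrying \code{birthweight} /
#'   \code{birthweight_percentile} plus covariates.
#' @param outcome \code{"grams"} or \code{"percentile"}.
#' @param cells optional samples x cell-types proportion matrix; all but the
#'   first type enter as covariates (the proportions are simplex-valued).
#' @return list: \code{estimate}, \code{se}, \code{ci} (95\%), \code{p},
#'   \code{n}, \code{fit} (the \code{lm} object).
#' @export
assoc_birthweight <- function(accel, sheet, outcome = c("grams", "percentile"),
                              cells = NULL) {
  outcome <- match.arg(outcome)
  df <- build_assoc_frame(accel, sheet, cells)
  df$outcome <- if (outcome == "grams") sheet$birthweight
                else sheet$birthweight_percentile
  if (outcome == "percentile") df$clinical_ga <- NULL
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fit <- stats::lm(outcome ~ ., data = df)
  if (anyNA(stats::coef(fit)))
    warning("collinear covariate(s) dropped: ",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                  collapse = ", "))
  sm <- summary(fit)$coefficients
  est <- sm["ga_acceleration", ]
  ci <- stats::confint(fit, "ga_acceleration")
  list(estimate = unname(est["Estimate"]), se = unname(est["Std. Error"]),
       ci = unname(ci[1, ]), p = unname(est["Pr(>|t|)"]),
       n = nrow(df), fit = fit)
}

#' Association of insurance status with GA acceleration
#'
#' Logistic regression of maternal insurance status (Medicaid vs private, a
#' proxy for income) on GA acceleration, adjusting for clinical GA, race,
#' and estimated cell-type proportions. Complete or quasi-complete
#' separation is flagged (\code{separated = TRUE}, with a warning); the
#' reported coefficient is then glm's finite-iteration estimate and should
#' be interpreted with care.
#'
#' @param accel GA-acceleration residuals aligned with \code{sheet} rows.
#' @param sheet sample sheet with an \code{insurance} column containing
#'   exactly two levels among the non-missing values.
#' @param cells optional samples x cell-types proportion matrix.
#' @return list: \code{estimate} (log-odds per week of acceleration),
#'   \code{se}, \code{p} (Wald), \code{n}, \code{separated}, \code{fit}.
#' @export
assoc_insurance <- function(accel, sheet, cells = NULL) {
  df <- build_assoc_frame(accel, sheet, cells)
  ins <- sheet$insurance
  ins[ins == "unknown"] <- NA
  df$outcome <- factor(ins)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nlevels(droplevels(df$outcome)) != 2L)
    stop("insurance status must have exactly two observed levels")
  df$outcome <- droplevels(df$outcome)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(outcome ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) sep <- TRUE
  if (sep) warning("possible separation in insurance model; ",
                   "estimates may be unstable")
  sm <- summary(fit)$coefficients
  est <- sm["ga_acceleration", ]
  list(estimate = unname(est["Estimate"]), se = unname(est["Std. Error"]),
       p = unname(est["Pr(>|z|)"]), n = nrow(df), separated = sep, fit = fit)
}
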