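#' Simulate purified cell-type methylation reference profiles
#'
#' Builds a probes x cell-types matrix of mean beta values for purified cell
#' populations. A configurable fraction of probes discriminates between
#' types: at each such probe one randomly chosen type is shifted by
#' \code{delta} relative to the shared baseline, so the between-type beta
#' difference at discriminating probes is exactly \code{delta}. Remaining
#' probes carry the same baseline in every type, as in housekeeping regions.
#'
#' @param cell_types character vector of >= 2 cell-type labels, or a single
#'   integer count (labels are then \code{type1, type2, ...}).
#' @param n_probes number of probes.
#' @param seed integer seed; the result is deterministic given the seed.
#' @param discriminating_fraction fraction of probes with a between-type
#'   difference (default 0.2).
#' @param delta beta difference planted at discriminating probes
#'   (default 0.5).
#' @return numeric matrix probes x cell types, values in (0, 1), with
#'   attribute \code{"discriminating"} giving the planted probe ids.
#' @export
simulate_reference_profiles <- function(cell_types, n_probes, seed = 1L,
                                        discriminating_fraction = 0.2,
                                        delta = 0.5) {
  if (length(cell_types) == 1L && is.numeric(cell_types))
    cell_types <- paste0("type", seq_len(cell_types))
  if (length(cell_types) < 2L) stop("need >= 2 cell types")
  if (delta <= 0 || delta >= 0.9) stop("delta must be in (0, 0.9)")
  with_seed(seed, {
    probe_ids <- sprintf("cg%06d", seq_len(n_probes))
    base <- stats::runif(n_probes, 0.05, 0.95 - delta)
    ref <- matrix(base, nrow = n_probes, ncol = length(cell_types),
                  dimnames = list(probe_ids, cell_types))
    n_disc <- round(discriminating_fraction * n_probes)
    disc <- if (n_disc > 0L) sort(sample.int(n_probes, n_disc)) else integer(0)
    for (j in disc) {
      type <- sample.int(length(cell_types), 1L)
      ref[j, type] <- ref[j, type] + delta
    }
    attr(ref, "discriminating") <- probe_ids[disc]
    ref
  })
}

#' Default cord-blood cell-type mixture
#'
#' Mean proportions used by [simulate_dataset()]: the six white-blood-cell
#' subtypes profiled in purified reference panels plus nucleated red blood
#' cells (nRBC), with granulocytes dominant as in neonatal blood.
#'
#' @return named numeric vector summing to 1.
#' @export
cord_blood_cell_types <- function() {
  c(Gran = 0.45, CD4T = 0.15, CD8T = 0.10, Bcell = 0.10,
    NK = 0.07, Mono = 0.08, nRBC = 0.05)
}

#' Simulate a cord-blood-like methylation dataset with known ground truth
#'
#' Generates a beta matrix as a per-sample mixture of cell-type reference
#' profiles, adds a linear GA effect at a planted set of causal CpGs, a
#' per-cohort batch shift, and heteroskedastic noise on the logit scale, and
#' plants detection failures at a configurable rate. Blood-spot samples get
#' an integer post-birth sampling delay; their methylation reflects the GA
#' at sampling while the sample sheet records the clinical GA at birth, so
#' the blood-spot GA correction is exercised downstream.
#'
#' @param n_samples number of samples (default 450).
#' @param n_probes number of probes (default 2000).
#' @param n_causal number of GA-associated CpGs (default 50).
#' @param effect_size_range absolute beta change per week at causal probes;
#'   slopes are drawn uniformly from this range with random sign
#'   (default c(0.005, 0.03)).
#' @param ga_range_weeks GA range in weeks, within \[20, 46\]
#'   (default c(24, 44), the span covered by neonatal cohorts).
#' @param n_cohorts number of cohorts/batches (default 3).
#' @param cohort_shift_sd SD of the per-cohort, per-probe beta-scale shift
#'   (default 0.01).
#' @param cell_types named numeric vector of mean cell proportions (default
#'   [cord_blood_cell_types()]); \code{NULL} disables cell-mixture structure.
#' @param dirichlet_conc concentration of the Dirichlet from which per-sample
#'   proportions are drawn (default 40; larger = less variation).
#' @param noise_sd SD of logit-scale noise (default 0.3). With
#'   \code{noise_sd = 0} betas equal the noiseless mixture exactly.
#' @param detection_fail_rate fraction of cells with a failed detection
#'   p-value (default 0.005).
#' @param spot_fraction fraction of samples that are blood spots
#'   (default 0.2); spots get \code{days_to_sampling} in 0..39.
#' @param seed integer seed.
#' @return list with elements \code{beta} (probes x samples, failures as
#'   unreliable values), \code{detp} (detection p-values), \code{sheet}
#'   (sample sheet data.frame), and \code{truth} (list: \code{causal} named
#'   slope vector, \code{cell_proportions} samples x types,
#'   \code{true_ga} effective GA per sample, \code{reference} the profile
#'   matrix, \code{failed} logical matrix of planted failures).
#' @export
simulate_dataset <- function(n_samples = 450L, n_probes = 2000L,
                             n_causal = 50L,
                             effect_size_range = c(0.005, 0.03),
                             ga_range_weeks = c(24, 44),
                             n_cohorts = 3L, cohort_shift_sd = 0.01,
                             cell_types = cord_blood_cell_types(),
                             dirichlet_conc = 40,
                             noise_sd = 0.3,
                             detection_fail_rate = 0.005,
                             spot_fraction = 0.2,
                             seed = 1L) {
  stopifnot(n_causal <= n_probes,
            ga_range_weeks[1] >= 20, ga_range_weeks[2] <= 46,
            detection_fail_rate >= 0, detection_fail_rate <= 1,
            spot_fraction >= 0, spot_fraction <= 1)
  with_seed(seed, {
    sample_ids <- sprintf("s%04d", seq_len(n_samples))

    # cell-mixture backbone
    if (is.null(cell_types)) {
      ref <- simulate_reference_profiles(c("only", "only2"), n_probes,
                                         seed = seed + 1L,
                                         discriminating_fraction = 0)
      ref <- ref[, 1L, drop = FALSE]
      w <- matrix(1, n_samples, 1L, dimnames = list(sample_ids, "only"))
    } else {
      ref <- simulate_reference_profiles(names(cell_types), n_probes,
                                         seed = seed + 1L)
      w <- rdirichlet(n_samples, dirichlet_conc * cell_types)
      dimnames(w) <- list(sample_ids, names(cell_types))
    }
    probe_ids <- rownames(ref)
    mu <- ref %*% t(w)                       # probes x samples

    # GA: clinical GA at birth + sampling delay for blood spots
    ga_birth <- stats::runif(n_samples, ga_range_weeks[1], ga_range_weeks[2])
    tissue <- ifelse(stats::runif(n_samples) < spot_fraction, "spot", "cord")
    days <- ifelse(tissue == "spot", sample(0:39, n_samples, replace = TRUE),
                   NA_integer_)
    # keep effective GA inside the plausibility window
    ga_birth[tissue == "spot"] <- pmin(ga_birth[tissue == "spot"],
                                       44 - days[tissue == "spot"] / 7)
    ga <- ifelse(tissue == "spot", ga_birth + days / 7, ga_birth)
    ga_center <- mean(ga_range_weeks)

    # planted GA effects at causal probes; intermediate-methylation probes
    # are used so a linear beta-per-week slope survives the (0,1) bounds
    causal_idx <- if (n_causal > 0L) {
      mid <- which(rowMeans(mu) > 0.25 & rowMeans(mu) < 0.75)
      if (length(mid) < n_causal) mid <- order(abs(rowMeans(mu) - 0.5))[seq_len(n_causal)]
      sort(sample(mid, n_causal))
    } else integer(0)
    slopes <- stats::setNames(numeric(0), character(0))
    if (n_causal > 0L) {
      slopes <- stats::runif(n_causal, effect_size_range[1], effect_size_range[2]) *
        sample(c(-1, 1), n_causal, replace = TRUE)
      names(slopes) <- probe_ids[causal_idx]
      mu[causal_idx, ] <- mu[causal_idx, ] +
        outer(slopes, ga - ga_center)
    }

    # cohort batch shift (per cohort, per probe) on the beta scale
    cohort <- paste0("cohort", 1L + (seq_len(n_samples) - 1L) %% n_cohorts)
    if (cohort_shift_sd > 0 && n_cohorts > 1L) {
      shift <- matrix(stats::rnorm(n_probes * n_cohorts, 0, cohort_shift_sd),
                      n_probes, n_cohorts,
                      dimnames = list(probe_ids, unique(sort(cohort))))
      mu <- mu + shift[, cohort]
    }

    eps <- 1e-4
    mu <- clamp(mu, eps, 1 - eps)
    beta <- if (noise_sd > 0) {
      inv_logit(logit(mu) + stats::rnorm(length(mu), 0, noise_sd))
    } else mu
    dim(beta) <- dim(mu)
    dimnames(beta) <- list(probe_ids, sample_ids)

    # detection p-values: clean cells near zero, failures well above 0.001,
    # with the failed beta replaced by background-level noise
    detp <- matrix(stats::runif(length(beta), 0, 5e-4),
                   n_probes, n_samples, dimnames = dimnames(beta))
    failed <- matrix(stats::runif(length(beta)) < detection_fail_rate,
                     n_probes, n_samples, dimnames = dimnames(beta))
    if (any(failed)) {
      detp[failed] <- stats::runif(sum(failed), 0.01, 1)
      beta[failed] <- stats::runif(sum(failed))
    }

    bw_mu <- 3300 + 170 * (ga_birth - 40)
    birthweight <- round(bw_mu + stats::rnorm(n_samples, 0, 350))
    sheet <- data.frame(
      sample_id = sample_ids,
      clinical_ga_weeks = ga_birth,
      tissue = tissue,
      days_to_sampling = days,
      sex = sample(c("M", "F"), n_samples, replace = TRUE),
      cohort = cohort,
      birthweight = birthweight,
      birthweight_percentile =
        100 * stats::pnorm((birthweight - bw_mu) / 350),
      race = sample(c("black", "white"), n_samples, replace = TRUE),
      insurance = sample(c("medicaid", "private"), n_samples, replace = TRUE),
      stringsAsFactors = FALSE
    )
    validate_sample_sheet(sheet)

    list(beta = beta, detp = detp, sheet = sheet,
         truth = list(causal = slopes,
                      cell_proportions = w,
                      true_ga = stats::setNames(ga, sample_ids),
                      reference = ref,
                      failed = failed))
  })
}
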