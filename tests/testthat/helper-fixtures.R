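# Small fixtures built in code, shared across test files.

# a fully observed random beta matrix with unique ids
random_beta <- function(n_probes, n_samples, seed = 1) {
  set.seed(seed)
  m <- matrix(rbeta(n_probes * n_samples, 2, 2), n_probes, n_samples,
              dimnames = list(sprintf("cg%06d", seq_len(n_probes)),
                              sprintf("s%03d", seq_len(n_samples))))
  m
}

# a minimal valid sample sheet
toy_sheet <- function(n, ga = NULL, tissue = "cord", seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("s%03d", seq_len(n)),
             clinical_ga_weeks = ga %||% runif(n, 24, 44),
             tissue = rep_len(tissue, n),
             days_to_sampling = ifelse(rep_len(tissue, n) == "spot",
                                       sample(0:39, n, TRUE), NA),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
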