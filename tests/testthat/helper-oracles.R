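# Independent oracle: naive all-pairs kNN imputation, O(n^2) search.
knn_impute_oracle <- function(beta, k = 10L) {
  n_samp <- ncol(beta)
  ids <- rownames(beta)
  out <- beta
  for (p in seq_len(nrow(beta))) for (s in seq_len(n_samp)) {
    if (!is.na(beta[p, s])) next
    cand <- list()
    for (q in seq_len(nrow(beta))) {
      if (q == p || is.na(beta[q, s])) next
      joint <- !is.na(beta[p, ]) & !is.na(beta[q, ])
      if (!any(joint)) next
      d2 <- sum((beta[p, joint] - beta[q, joint])^2)
      d <- sqrt(d2 / (sum(joint) / n_samp))
      cand[[length(cand) + 1L]] <- list(q = q, d = d)
    }
    if (length(cand) == 0L) { out[p, s] <- mean(beta[p, ], na.rm = TRUE); next }
    dd <- vapply(cand, `[[`, numeric(1), "d")
    qq <- vapply(cand, `[[`, numeric(1), "q")
    ord <- order(dd, ids[qq])
    take <- ord[seq_len(min(k, length(qq)))]
    w <- 1 / (dd[take] + 1e-8)
    out[p, s] <- sum(w * beta[qq[take], s]) / sum(w)
  }
  out
}
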