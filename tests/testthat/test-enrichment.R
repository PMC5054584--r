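gr <- function(chr, start0, end0) {
  # convenience: build GRanges from 0-based half-open (BED-style) coordinates
  GenomicRanges::GRanges(chr, IRanges::IRanges(start0 + 1L, end0))
}
as_bed <- function(g) {
  data.frame(chr = as.character(GenomicRanges::seqnames(g)),
             start0 = GenomicRanges::start(g) - 1L,
             end0 = GenomicRanges::end(g))
}

test_that("shores and shelves follow the +/-1.5 kb rule", {
  isl <- gr("chr1", 10000, 10500)
  ss <- derive_shores_shelves(isl)
  expect_equal(as_bed(ss$shores),
               data.frame(chr = "chr1", start0 = c(8500, 10500),
                          end0 = c(10000, 12000)))
  expect_equal(as_bed(ss$shelves),
               data.frame(chr = "chr1", start0 = c(7000, 12000),
                          end0 = c(8500, 13500)))
})

test_that("island overlap is subtracted and coordinates clip at zero", {
  # two islands 1 kb apart: the inter-island gap is all shore, no island
  isl <- c(gr("chr2", 5000, 6000), gr("chr2", 7000, 8000))
  ss <- derive_shores_shelves(isl)
  expect_equal(sum(IRanges::width(GenomicRanges::intersect(ss$shores, isl))), 0)
  expect_equal(sum(IRanges::width(GenomicRanges::intersect(ss$shelves, isl))), 0)
  expect_equal(sum(IRanges::width(GenomicRanges::intersect(ss$shelves,
                                                           ss$shores))), 0)
  gap <- gr("chr2", 6000, 7000)
  expect_equal(sum(IRanges::width(GenomicRanges::intersect(ss$shores, gap))),
               1000)

  # island near the chromosome start: left shore clipped at 0
  isl0 <- gr("chr3", 200, 700)
  ss0 <- derive_shores_shelves(isl0)
  left <- as_bed(ss0$shores)[1, ]
  expect_equal(left$start0, 0)
  expect_equal(left$end0, 200)
})

test_that("interval derivation matches a brute-force base-level oracle", {
  set.seed(90)
  starts <- sort(sample(1:50000, 12)) * 10
  isl <- gr("chrT", starts, starts + sample(200:2000, 12, TRUE))
  ss <- derive_shores_shelves(isl)

  # oracle: per-base labels over the covered span
  span <- 1:600000
  in_isl <- rep(FALSE, length(span))
  for (i in seq_along(isl))
    in_isl[GenomicRanges::start(isl)[i]:GenomicRanges::end(isl)[i]] <- TRUE
  near <- function(dist) {
    out <- rep(FALSE, length(span))
    for (i in seq_along(isl)) {
      s <- max(1, GenomicRanges::start(isl)[i] - dist)
      e <- min(length(span), GenomicRanges::end(isl)[i] + dist)
      out[s:e] <- TRUE
    }
    out
  }
  oracle_shore <- near(1500) & !in_isl
  oracle_shelf <- near(3000) & !near(1500)

  got_shore <- rep(FALSE, length(span))
  for (i in seq_along(ss$shores))
    got_shore[GenomicRanges::start(ss$shores)[i]:GenomicRanges::end(ss$shores)[i]] <- TRUE
  got_shelf <- rep(FALSE, length(span))
  for (i in seq_along(ss$shelves))
    got_shelf[GenomicRanges::start(ss$shelves)[i]:GenomicRanges::end(ss$shelves)[i]] <- TRUE
  expect_identical(got_shore, oracle_shore)
  expect_identical(got_shelf, oracle_shelf)
})

test_that("probe annotation applies island > shore > shelf precedence", {
  isl <- gr("chr1", 10000, 10500)
  ss <- derive_shores_shelves(isl)
  ann <- data.frame(probe_id = c("p_isl", "p_shore", "p_shelf", "p_sea"),
                    chromosome = "chr1",
                    position = c(10251, 9001, 7501, 20001))
  lab <- annotate_probes(ann, list(island = isl, shore = ss$shores,
                                   shelf = ss$shelves))
  expect_equal(lab$island_context,
               c("island", "shore", "shelf", "open_sea"))

  # brute-force containment oracle on a random fixture
  set.seed(91)
  pos <- sample(1:30000, 200)
  ann2 <- data.frame(probe_id = paste0("p", seq_along(pos)),
                     chromosome = "chr1", position = pos)
  lab2 <- annotate_probes(ann2, list(island = isl, shore = ss$shores,
                                     shelf = ss$shelves))
  contains <- function(g, x) {
    any(GenomicRanges::start(g) <= x & x <= GenomicRanges::end(g))
  }
  oracle <- vapply(pos, function(x) {
    if (contains(isl, x)) "island"
    else if (contains(ss$shores, x)) "shore"
    else if (contains(ss$shelves, x)) "shelf"
    else "open_sea"
  }, character(1))
  expect_identical(lab2$island_context, oracle)

  ann_bad <- data.frame(probe_id = "p", chromosome = "1", position = 5)
  expect_error(annotate_probes(ann_bad, list(island = isl)), "mismatch")
})

test_that("Fisher enrichment matches hypergeometric enumeration", {
  # two-sided exact p by full enumeration over the hypergeometric support
  fisher_oracle <- function(a, b, c_, d) {
    m <- a + b; n_ <- c_ + d; k <- a + c_
    support <- max(0, k - n_):min(k, m)
    probs <- dhyper(support, m, n_, k)
    p_obs <- dhyper(a, m, n_, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  labels <- list(f = character(0))

  # balanced table: OR 1, p 1
  uni <- paste0("u", 1:20)
  pred <- uni[1:10]
  labels <- list(f = c(uni[1:5], uni[11:15]))
  r <- fisher_enrichment(pred, uni, labels)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p, 1)

  # perfectly separated table [[10,0],[0,10]]
  labels <- list(f = uni[1:10])
  r2 <- fisher_enrichment(pred, uni, labels)
  expect_equal(r2$p, fisher_oracle(10, 0, 0, 10), tolerance = 1e-10)

  # random tables with n <= 200 against the enumeration oracle
  set.seed(92)
  for (i in 1:50) {
    n_tot <- sample(8:200, 1)
    ids <- paste0("x", seq_len(n_tot))
    pred <- sample(ids, sample(1:(n_tot - 1), 1))
    feat <- sample(ids, sample(1:(n_tot - 1), 1))
    r <- fisher_enrichment(pred, ids, list(f = feat))
    a <- r$in_pred_in_feat; b <- r$in_pred_out_feat
    c_ <- r$out_pred_in_feat; d <- r$out_pred_out_feat
    expect_equal(a + b + c_ + d, n_tot)
    expect_equal(r$p, fisher_oracle(a, b, c_, d), tolerance = 1e-10)
  }

  # doubling all cells keeps the sample OR, shrinks p
  uni4 <- paste0("y", 1:40)
  p1 <- fisher_enrichment(uni4[1:10], uni4[1:20],
                          list(f = uni4[c(1:7, 11:13)]))
  big <- paste0("y", 1:40)
  p2 <- fisher_enrichment(big[1:20], big,
                          list(f = big[c(1:14, 21:26)]))
  expect_equal(p1$odds_ratio, p2$odds_ratio)
  expect_lt(p2$p, p1$p)

  # universe against itself: OR = 1 for every feature
  r_self <- fisher_enrichment(uni4, uni4, list(f = uni4[1:15]))
  expect_equal(r_self$odds_ratio, 1)

  expect_error(fisher_enrichment(character(0), uni4, list(f = uni4)),
               "empty")
  expect_error(fisher_enrichment("zzz", uni4, list(f = uni4)), "subset")
})
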