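# CpG island context and feature enrichment of clock CpGs.
#
# Intervals are handled as GRanges (1-based, closed), the Bioconductor
# convention; BED input (0-based, half-open) is converted exactly at the
# file boundary. Island context follows the standard definition: shores are
# the 1.5 kb flanks of islands, shelves the next 1.5 kb beyond the shores,
# each with any overlap of the inner categories subtracted.

#' Read a BED interval file as GRanges
#'
#' Uses rtracklayer when available (exact BED semantics); otherwise a
#' minimal three-column parser converting 0-based half-open coordinates to
#' 1-based closed GRanges.
#'
#' @param path BED file path.
#' @return \code{GRanges}.
#' @export
read_bed_features <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE))
    return(rtracklayer::import(path, format = "BED"))
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  GenomicRanges::GRanges(df[[1L]],
                         IRanges::IRanges(start = df[[2L]] + 1L,
                                          end = df[[3L]]))
}

#' Derive CpG shores and shelves from islands
#'
#' Shores are the 1.5 kb regions flanking each island on both sides, with
#' island bases subtracted; shelves are the next 1.5 kb beyond the shores,
#' with island and shore bases subtracted. Coordinates are clipped at the
#' chromosome start. Input islands are normalised (sorted, overlaps merged)
#' first.
#'
#' @param islands \code{GRanges} of CpG islands.
#' @return list with \code{GRanges} elements \code{shores} and
#'   \code{shelves}, disjoint from the islands and from each other.
#' @export
derive_shores_shelves <- function(islands) {
  islands <- GenomicRanges::reduce(islands)
  pad <- function(gr, bp) {
    ext <- GenomicRanges::resize(gr, width = GenomicRanges::width(gr) + 2L * bp,
                                 fix = "center")
    GenomicRanges::trim(GenomicRanges::restrict(ext, start = 1L))
  }
  ext1 <- GenomicRanges::reduce(pad(islands, 1500L))
  ext2 <- GenomicRanges::reduce(pad(islands, 3000L))
  shores <- GenomicRanges::setdiff(ext1, islands)
  shelves <- GenomicRanges::setdiff(GenomicRanges::setdiff(ext2, ext1), islands)
  list(shores = shores, shelves = shelves)
}

#' Assign island-context and feature labels to probes
#'
#' Each probe is labelled with every feature whose interval contains its
#' CpG position. For the mutually exclusive island-context label, islands
#' take precedence over shores, shores over shelves; probes outside all
#' three are \code{"open_sea"}.
#'
#' @param annotation probe annotation data.frame (\code{probe_id},
#'   \code{chromosome}, \code{position}, 1-based).
#' @param features named list of \code{GRanges} (for island context, supply
#'   names \code{island}, \code{shore}, \code{shelf}; additional features
#'   such as chromatin states are labelled by their list names).
#' @return data.frame: \code{probe_id}, one logical column per feature, and
#'   \code{island_context} when island-context features are supplied.
#' @export
annotate_probes <- function(annotation, features) {
  stopifnot(is.list(features), !is.null(names(features)))
  probes <- GenomicRanges::GRanges(annotation$chromosome,
                                   IRanges::IRanges(annotation$position,
                                                    annotation$position))
  feat_chr <- unique(unlist(lapply(features, function(g)
    as.character(GenomicRanges::seqnames(g)))))
  bad <- setdiff(unique(annotation$chromosome), feat_chr)
  if (length(bad) == length(unique(annotation$chromosome)))
    stop("chromosome naming mismatch; probe chromosome(s) not in features: ",
         paste(bad, collapse = ", "))
  out <- data.frame(probe_id = annotation$probe_id, stringsAsFactors = FALSE)
  for (nm in names(features))
    out[[nm]] <- IRanges::overlapsAny(probes, features[[nm]])
  ctx <- intersect(c("island", "shore", "shelf"), names(features))
  if (length(ctx) > 0L) {
    lab <- rep("open_sea", nrow(out))
    for (nm in rev(ctx)) lab[out[[nm]]] <- nm  # island wins over shore, shelf
    out$island_context <- lab
  }
  out
}

#' Fisher's exact enrichment of predictor CpGs in genomic features
#'
#' For each feature, the universe of eligible probes is cross-classified as
#' in/out of the predictor and in/out of the feature, and the 2x2 table is
#' tested with Fisher's exact test (two-sided). The reported odds ratio is
#' the sample (cross-product) estimate, with a Haldane 0.5 correction
#' applied only when a cell is zero; a table with a zero margin (both cross
#' products zero) carries no association information and reports OR = 1.
#'
#' @param predictor_probes character vector of predictor CpG ids (must be a
#'   subset of the universe).
#' @param universe_probes character vector of eligible CpG ids.
#' @param labels data.frame from [annotate_probes()] (logical feature
#'   columns keyed by \code{probe_id}), or a named list of character vectors
#'   of in-feature probe ids.
#' @return data.frame, one row per feature: counts (\code{in_pred_in_feat},
#'   \code{in_pred_out_feat}, \code{out_pred_in_feat},
#'   \code{out_pred_out_feat}), \code{odds_ratio}, \code{p}.
#' @export
fisher_enrichment <- function(predictor_probes, universe_probes, labels) {
  if (length(predictor_probes) == 0L || length(universe_probes) == 0L)
    stop("empty predictor or universe")
  if (!all(predictor_probes %in% universe_probes))
    stop("predictor probes must be a subset of the universe")
  if (is.data.frame(labels)) {
    cols <- setdiff(names(labels), c("probe_id", "island_context"))
    feat_sets <- lapply(cols, function(cn) labels$probe_id[labels[[cn]]])
    names(feat_sets) <- cols
  } else feat_sets <- labels

  rows <- lapply(names(feat_sets), function(nm) {
    in_feat <- universe_probes %in% feat_sets[[nm]]
    in_pred <- universe_probes %in% predictor_probes
    a <- sum(in_pred & in_feat);  b <- sum(in_pred & !in_feat)
    c_ <- sum(!in_pred & in_feat); d <- sum(!in_pred & !in_feat)
    p <- stats::fisher.test(matrix(c(a, c_, b, d), 2L))$p.value
    or <- if (a * d == 0L && b * c_ == 0L) {
      1  # a zero margin carries no association information
    } else if (any(c(a, b, c_, d) == 0L)) {
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    } else (a * d) / (b * c_)
    data.frame(feature = nm, in_pred_in_feat = a, in_pred_out_feat = b,
               out_pred_in_feat = c_, out_pred_out_feat = d,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
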