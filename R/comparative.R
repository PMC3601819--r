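#' Asymmetric pairwise DMR overlap matrix
#'
#' Entry (i, j) is the percentage of sample i's DMRs that overlap (by at
#' least 1 bp) at least one DMR of sample j. The matrix is deliberately
#' asymmetric; the diagonal is 100 for non-empty sets and `NA` entries mark
#' rows with no DMRs.
#'
#' @param dmr_sets Named list of DMR tibbles (columns `chrom`, `start`,
#'   `end`), each internally non-overlapping.
#' @return Numeric matrix (percent), rows = query sample, columns = subject
#'   sample.
#' @export
overlap_matrix <- function(dmr_sets) {
  stopifnot(length(dmr_sets) >= 1, !is.null(names(dmr_sets)))
  grs <- lapply(dmr_sets, intervals_to_granges)
  n <- length(grs)
  out <- matrix(NA_real_, n, n, dimnames = list(names(grs), names(grs)))
  for (i in seq_len(n)) {
    if (length(grs[[i]]) == 0) next
    for (j in seq_len(n)) {
      hits <- IRanges::overlapsAny(grs[[i]], grs[[j]])
      out[i, j] <- 100 * mean(hits)
    }
  }
  out
}

#' DMRs common to every sample
#'
#' Returns the DMRs of the *first* set that overlap (>= 1 bp) at least one
#' DMR in every other set; DMRs are sample-anchored entities, so the common
#' set is reported in the reference sample's coordinates.
#'
#' @param dmr_sets List (length >= 2) of DMR tibbles.
#' @return Tibble of intervals from the first set, sorted by position.
#' @export
common_dmrs <- function(dmr_sets) {
  if (length(dmr_sets) < 2) rlang::abort("need at least two DMR sets")
  ref <- dmr_sets[[1]]
  if (nrow(ref) == 0) return(ref)
  gr_ref <- intervals_to_granges(ref)
  keep <- rep(TRUE, nrow(ref))
  for (other in dmr_sets[-1]) {
    if (nrow(other) == 0) return(ref[0, ])
    keep <- keep & IRanges::overlapsAny(gr_ref, intervals_to_granges(other))
  }
  dplyr::arrange(ref[keep, , drop = FALSE], .data$chrom, .data$start)
}

#' Pooled methylation matrix over a set of regions
#'
#' For each region and sample, pools #C/(#C+#T) over all covered cytosines of
#' the context inside the region. Regions with zero coverage in a sample get
#' `NA`; rows containing any `NA` are flagged (and are removed before
#' clustering, following the heat-map convention of omitting rows with
#' missing values).
#'
#' @param regions Tibble of disjoint intervals (`chrom`, `start`, `end`).
#' @param samples Named list of methylome tibbles.
#' @inheritParams estimate_error_rate
#' @return List: `matrix` (rows = regions, columns = samples), `regions`
#'   (input with a `flagged_missing` column).
#' @export
methylation_matrix <- function(regions, samples, context) {
  check_context(context)
  stopifnot(!is.null(names(samples)))
  gr <- intervals_to_granges(regions)
  if (length(GenomicRanges::reduce(gr)) != length(gr)) {
    rlang::abort("regions must be disjoint")
  }
  mat <- matrix(NA_real_, nrow(regions), length(samples),
                dimnames = list(NULL, names(samples)))
  for (k in seq_along(samples)) {
    x <- dplyr::filter(samples[[k]], .data$context == .env$context,
                       .data$n_total > 0)
    if (nrow(x) == 0) next
    ov <- GenomicRanges::findOverlaps(sites_to_granges(x), gr)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    mC <- rowsum(x$n_meth[qh], sh)
    tot <- rowsum(x$n_total[qh], sh)
    idx <- as.integer(rownames(mC))
    mat[idx, k] <- mC[, 1] / tot[, 1]
  }
  regions$flagged_missing <- apply(mat, 1, anyNA)
  list(matrix = mat, regions = regions)
}

#' Complete-linkage hierarchical clustering of a methylation matrix
#'
#' Agglomerative clustering with Euclidean distance and complete linkage —
#' the scheme used for all heat maps here. Rows with missing values must be
#' removed first.
#'
#' @param mat Numeric matrix without missing values (rows = regions).
#' @return List: `order` (dendrogram row order), `heights` (merge heights),
#'   `hclust` (the full `stats::hclust` object), `newick` (the dendrogram as
#'   a Newick string).
#' @export
hierarchical_cluster <- function(mat) {
  if (anyNA(mat)) rlang::abort("matrix has missing values; drop flagged rows first")
  if (nrow(mat) < 2) rlang::abort("need at least two rows to cluster")
  rownames(mat) <- rownames(mat) %||% paste0("r", seq_len(nrow(mat)))
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "complete")
  phy <- ape::as.phylo(hc)
  list(order = hc$order, heights = hc$height, hclust = hc,
       newick = ape::write.tree(phy))
}

#' Classify transgenerational stability of T2 hypomethylation
#'
#' For each DMR defined in the T2 generation, pools CG methylation over the
#' region in wild type, T2, T4 and T6 and applies the half-of-wild-type rule:
#' a generation shows "loss" when its level is below half the wild-type
#' level, otherwise "gain" (equality counts as gain, the complement of the
#' strict "less than half" loss definition). Categories:
#' loss/loss = `stable_loss`, gain/gain = `recovered_T4`,
#' loss/gain = `recovered_T6_only`, gain/loss = `transient_T4`.
#'
#' @param dmrs Tibble of T2 hypomethylation DMRs (`chrom`, `start`, `end`).
#' @param wt,t2,t4,t6 Methylome tibbles of the four samples.
#' @param context Context whose pooled level is classified (default CG).
#' @return Tibble: the DMR columns plus `wt_level`, `t2_level`, `t4_level`,
#'   `t6_level` and `category`; DMRs with zero coverage in any generation get
#'   `category = "unclassifiable"`.
#' @export
classify_stability <- function(dmrs, wt, t2, t4, t6, context = "CG") {
  if (nrow(dmrs) == 0) {
    return(dplyr::mutate(dmrs, wt_level = numeric(0), t2_level = numeric(0),
                         t4_level = numeric(0), t6_level = numeric(0),
                         category = character(0)))
  }
  mm <- methylation_matrix(dmrs[, c("chrom", "start", "end")],
                           list(WT = wt, T2 = t2, T4 = t4, T6 = t6), context)
  lv <- mm$matrix
  status <- function(g) ifelse(lv[, g] < 0.5 * lv[, "WT"], "loss", "gain")
  s4 <- status("T4"); s6 <- status("T6")
  category <- dplyr::case_when(
    apply(lv, 1, anyNA) ~ "unclassifiable",
    s4 == "loss" & s6 == "loss" ~ "stable_loss",
    s4 == "gain" & s6 == "gain" ~ "recovered_T4",
    s4 == "loss" & s6 == "gain" ~ "recovered_T6_only",
    s4 == "gain" & s6 == "loss" ~ "transient_T4"
  )
  dplyr::bind_cols(
    dmrs,
    tibble(wt_level = lv[, "WT"], t2_level = lv[, "T2"],
           t4_level = lv[, "T4"], t6_level = lv[, "T6"], category = category)
  )
}
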