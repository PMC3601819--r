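#' Randomized interval sets matched in number and size
#'
#' Generates `n_sets` sets of random intervals mimicking both the number and
#' the size distribution of the observed DMRs: each set's lengths are exactly
#' the observed length multiset, each interval is placed uniformly over the
#' valid start positions of a chromosome drawn with probability proportional
#' to chromosome length (or on its source chromosome when
#' `match_chrom = TRUE`). Intervals within a set may overlap each other — the
#' simplest null that preserves number and size.
#'
#' @param dmrs Tibble of observed intervals (`chrom`, `start`, `end`).
#' @param chrom_sizes Named vector of (nuclear) chromosome lengths.
#' @param n_sets Number of randomized sets (default 100).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param match_chrom Keep each randomized interval on its source chromosome.
#' @return List of `n_sets` tibbles (`chrom`, `start`, `end`).
#' @export
randomize_dmrs <- function(dmrs, chrom_sizes, n_sets = 100, seed = 1,
                           match_chrom = FALSE) {
  stopifnot(n_sets >= 1)
  lens <- dmrs$end - dmrs$start
  if (any(lens > max(chrom_sizes))) {
    rlang::abort("an interval is longer than every chromosome")
  }
  set.seed(seed)
  chrom_names <- names(chrom_sizes)
  purrr::map(seq_len(n_sets), function(k) {
    if (length(lens) == 0) {
      return(tibble(chrom = character(), start = integer(), end = integer()))
    }
    if (match_chrom) {
      ch <- dmrs$chrom
    } else {
      ch <- character(length(lens))
      for (i in seq_along(lens)) {
        ok <- chrom_sizes >= lens[i]
        ch[i] <- sample(chrom_names[ok], 1, prob = chrom_sizes[ok])
      }
    }
    max_start <- unname(chrom_sizes[ch]) - lens
    start <- floor(runif(length(lens), 0, max_start + 1))
    tibble(chrom = ch, start = as.integer(start),
           end = as.integer(start + lens))
  })
}

#' Count intervals overlapping a feature class
#'
#' Number of query intervals overlapping, by at least 1 bp, any feature of
#' the given class; each interval is counted at most once.
#'
#' @param intervals Tibble of intervals (`chrom`, `start`, `end`).
#' @param features Feature tibble from [extract_features()].
#' @param feature_class One of the `feature_class` values in `features`.
#' @return Integer count.
#' @export
overlap_count <- function(intervals, features, feature_class) {
  f <- dplyr::filter(features, .data$feature_class == .env$feature_class)
  if (nrow(intervals) == 0 || nrow(f) == 0) return(0L)
  sum(overlaps_any_fast(intervals, interval_index(f)))
}

# sorted-start + running-max-end index for O(log n) any-overlap queries
interval_index <- function(intervals) {
  lapply(split(intervals[, c("start", "end")], intervals$chrom), function(x) {
    o <- order(x$start)
    list(start = x$start[o], maxend = cummax(x$end[o]))
  })
}

# logical: does each (half-open) query interval overlap >= 1 indexed interval
overlaps_any_fast <- function(ivs, index) {
  out <- logical(nrow(ivs))
  for (ch in unique(ivs$chrom)) {
    idx <- index[[ch]]
    sel <- which(ivs$chrom == ch)
    if (is.null(idx)) next
    k <- findInterval(ivs$end[sel] - 1, idx$start)
    out[sel] <- k >= 1 & idx$maxend[pmax(k, 1)] > ivs$start[sel]
  }
  out
}

#' Randomization test for genomic-feature enrichment of DMRs
#'
#' Compares the observed number of DMRs overlapping a feature class with the
#' counts obtained from randomized interval sets matched in number and size
#' ([randomize_dmrs()]). Empirical p-values use the add-one estimator
#' `p = (1 + #{random >= observed}) / (n_sets + 1)` (and `<=` for
#' depletion), so with 100 sets the smallest attainable p is 1/101 — an
#' enrichment call at p < 0.01 means the observation beat every
#' randomization.
#'
#' @inheritParams randomize_dmrs
#' @inheritParams overlap_count
#' @param feature_classes Character vector of classes to test (default: all
#'   classes present in `features`).
#' @param alpha Flagging threshold on the empirical p (default 0.01).
#' @return Object of class `enrichment_result`: tibble with one row per
#'   class — `feature_class`, `n_dmrs`, `observed`, `random_mean`,
#'   `random_sd`, `p_enrichment`, `p_depletion`, `enriched`, `depleted`.
#' @export
enrichment_test <- function(dmrs, features, chrom_sizes,
                            feature_classes = NULL, n_sets = 100, seed = 1,
                            alpha = 0.01, match_chrom = FALSE) {
  feature_classes <- feature_classes %||% unique(features$feature_class)
  rand_sets <- randomize_dmrs(dmrs, chrom_sizes, n_sets = n_sets, seed = seed,
                              match_chrom = match_chrom)
  # index each feature class once; count all classes per interval set
  feat_idx <- lapply(setNames(feature_classes, feature_classes), function(fc)
    interval_index(features[features$feature_class == fc, , drop = FALSE]))
  count_all <- function(ivs) {
    vapply(feat_idx, function(fi) sum(overlaps_any_fast(ivs, fi)), integer(1))
  }
  obs_counts <- count_all(dmrs)
  rand_counts <- vapply(rand_sets, count_all,
                        integer(length(feature_classes)))
  rand_counts <- matrix(rand_counts, nrow = length(feature_classes),
                        dimnames = list(feature_classes, NULL))
  rows <- purrr::map_dfr(feature_classes, function(fc) {
    obs <- obs_counts[[fc]]
    r <- rand_counts[fc, ]
    p_enr <- (1 + sum(r >= obs)) / (n_sets + 1)
    p_dep <- (1 + sum(r <= obs)) / (n_sets + 1)
    tibble(
      feature_class = fc, n_dmrs = nrow(dmrs), observed = obs,
      random_mean = mean(r), random_sd = stats::sd(r),
      p_enrichment = p_enr, p_depletion = p_dep,
      enriched = p_enr < alpha, depleted = p_dep < alpha
    )
  })
  structure(rows, class = c("enrichment_result", class(rows)))
}

#' @rdname enrichment_test
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname enrichment_test
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(
    n_classes = nrow(x),
    n_enriched = sum(x$enriched),
    n_depleted = sum(x$depleted),
    n_dmrs = x$n_dmrs[1]
  )
}

#' Signed distance from intervals to the nearest TSS
#'
#' Minimal distance from any point of each interval to a transcription start
#' site, with a strand-aware sign: negative means the interval lies upstream
#' of the TSS (promoter side), positive downstream; an interval containing
#' the TSS has distance 0. Ties between equidistant TSSs are broken by the
#' lexicographically smaller gene id.
#'
#' @param intervals Tibble (`chrom`, `start`, `end`).
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`, `strand`);
#'   TSS is `start` for `+` genes and `end - 1` for `-` genes.
#' @return Input tibble plus `nearest_gene` and `tss_distance` columns.
#' @export
distance_to_tss <- function(intervals, genes) {
  if (nrow(genes) == 0) rlang::abort("`genes` is empty")
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  res <- purrr::map_dfr(seq_len(nrow(intervals)), function(i) {
    iv <- intervals[i, ]
    same <- which(genes$chrom == iv$chrom)
    if (length(same) == 0) {
      return(tibble(nearest_gene = NA_character_, tss_distance = NA_real_))
    }
    t <- tss[same]
    # unsigned gap between the half-open interval and the TSS point
    d_abs <- pmax(0, pmax(iv$start - t, t - iv$end))
    ord <- order(d_abs, genes$gene_id[same])
    j <- same[ord[1]]
    d <- d_abs[ord[1]]
    if (d > 0) {
      upstream <- if (genes$strand[j] == "+") iv$end <= tss[j] else iv$start > tss[j]
      d <- if (upstream) -d else d
    }
    tibble(nearest_gene = genes$gene_id[j], tss_distance = d)
  })
  dplyr::bind_cols(intervals, res)
}
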