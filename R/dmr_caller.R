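#' DMR-calling parameters
#'
#' Bundles every threshold of the binned DMR definition: Fisher's exact test
#' on pooled #C/#T counts in fixed-width bins against a wild-type control,
#' Benjamini-Hochberg FDR control, per-context absolute methylation-difference
#' thresholds, an informative-cytosine eligibility filter, and merging of
#' nearby significant bins.
#'
#' @param bin_size Bin width in bp (default 100).
#' @param fdr BH-adjusted significance cutoff (default 0.01).
#' @param min_abs_diff Named numeric vector of minimum absolute pooled
#'   methylation differences per context; defaults `c(CG = 0.7, CHG = 0.5,
#'   CHH = 0.1)`.
#' @param min_informative Minimum number of informative cytosines of the
#'   tested context a bin must contain in *both* sample and control
#'   (default 10).
#' @param min_reads Read depth defining an informative cytosine (default 4).
#' @param merge_gap Maximum gap in bp between significant same-direction bins
#'   that are merged into one DMR (default 100; adjacent bins always merge).
#' @param filter_stage When `"pre"` (default) ineligible bins are removed
#'   before testing and contribute no hypothesis to the BH family; `"post"`
#'   tests all covered bins and applies the eligibility filter after
#'   significance, the literal reading of applying the filter last.
#' @return A list of class `dmr_params`.
#' @export
dmr_params <- function(bin_size = 100, fdr = 0.01,
                       min_abs_diff = c(CG = 0.7, CHG = 0.5, CHH = 0.1),
                       min_informative = 10, min_reads = 4, merge_gap = 100,
                       filter_stage = c("pre", "post")) {
  stopifnot(
    bin_size > 0, fdr > 0, fdr <= 1, min_informative > 0, min_reads > 0,
    merge_gap >= 0, all(min_abs_diff > 0), all(min_abs_diff <= 1),
    all(CONTEXTS %in% names(min_abs_diff))
  )
  structure(
    list(
      bin_size = as.integer(bin_size), fdr = fdr,
      min_abs_diff = min_abs_diff[CONTEXTS],
      min_informative = as.integer(min_informative),
      min_reads = as.integer(min_reads), merge_gap = as.integer(merge_gap),
      filter_stage = match.arg(filter_stage)
    ),
    class = "dmr_params"
  )
}

#' Estimate the bisulfite non-conversion error rate
#'
#' Pools methylation calls over the naturally unmethylated organelle
#' (chloroplast) chromosomes of a sample: any apparent methylation there is
#' conversion failure, so the pooled #C/(#C+#T) estimates the per-read error
#' rate for that context.
#'
#' @param calls Methylome tibble whose `organelle_chroms` attribute names the
#'   control chromosome(s) (see [read_cytosine_calls()]).
#' @param context Cytosine context, one of `"CG"`, `"CHG"`, `"CHH"`.
#' @return Single numeric error rate, or `NA` (with a warning) when the
#'   sample has no covered organelle cytosine of that context.
#' @export
estimate_error_rate <- function(calls, context) {
  check_context(context)
  org <- organelle_chroms(calls)
  if (length(org) == 0) rlang::abort("methylome has no organelle_chroms set")
  x <- dplyr::filter(calls, .data$chrom %in% org, .data$context == .env$context,
                     .data$n_total > 0)
  if (nrow(x) == 0) {
    rlang::warn(sprintf("no covered organelle %s cytosines; error rate undefined", context))
    return(NA_real_)
  }
  sum(x$n_meth) / sum(x$n_total)
}

#' Two-sided Fisher's exact test for 2x2 count tables
#'
#' Exact two-sided p-value for the table `[[a, b], [c, d]]`, computed by
#' summing all hypergeometric point probabilities (at fixed margins) that do
#' not exceed the observed one, with a relative tie tolerance of 1e-7 for the
#' discreteness of the null. Vectorised over tables. Tables with a zero
#' margin give p = 1.
#'
#' @param a,b,c,d Non-negative integer vectors: `a`,`b` is the first row
#'   (e.g. sample #C, sample #T), `c`,`d` the second (control #C, #T).
#' @return Numeric vector of two-sided p-values.
#' @examples
#' fisher_exact_two_sided(10, 0, 0, 10)
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  .fisher2x2_cpp(rep_len(as.numeric(a), n), rep_len(as.numeric(b), n),
                 rep_len(as.numeric(c), n), rep_len(as.numeric(d), n))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with `m` hypotheses and order statistics
#' `p_(1) <= ... <= p_(m)`, `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1
#' and returned in input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted values (q-values), same length.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) rlang::abort("p-values must be in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

#' Pool methylation counts into genomic bins
#'
#' Tiles each nuclear chromosome with fixed-width bins and pools, separately
#' for sample and control, the methylated and unmethylated read counts over
#' all cytosines of the requested context (both strands). A bin is `eligible`
#' for testing when both sides contain at least `min_informative` cytosines
#' covered by at least `min_reads` reads.
#'
#' @param sample,control Methylome tibbles on the same genome.
#' @param params A [dmr_params()] object.
#' @inheritParams estimate_error_rate
#' @param chrom_sizes Named vector of nuclear chromosome lengths; organelle
#'   chromosomes are excluded from binning.
#' @return Tibble of covered bins: `chrom`, `start`, `end`, `context`,
#'   pooled counts `mC_sample`, `uC_sample`, `mC_control`, `uC_control`,
#'   `frac_sample`, `frac_control`, `diff`, informative-cytosine counts and
#'   `eligible`.
#' @export
bin_counts <- function(sample, control, params, context, chrom_sizes) {
  check_context(context)
  chroms <- setdiff(names(chrom_sizes),
                    union(organelle_chroms(sample), organelle_chroms(control)))
  s <- dplyr::filter(sample, .data$context == .env$context, .data$chrom %in% chroms)
  c_ <- dplyr::filter(control, .data$context == .env$context, .data$chrom %in% chroms)
  bad <- setdiff(unique(c(s$chrom, c_$chrom)), names(chrom_sizes))
  if (length(bad) > 0) {
    rlang::abort(sprintf("calls on chromosome(s) absent from chrom_sizes: %s",
                         paste(bad, collapse = ", ")))
  }
  bs <- params$bin_size
  # numeric bin keys: chromosome index folded with the within-chromosome bin
  nbins_max <- floor(max(chrom_sizes) / bs) + 1
  pool <- function(x) {
    if (nrow(x) == 0) {
      return(tibble(key = numeric(), mC = numeric(), uC = numeric(), inf = numeric()))
    }
    key <- (match(x$chrom, chroms) - 1) * nbins_max + x$pos %/% bs
    agg <- rowsum(
      cbind(mC = x$n_meth, uC = x$n_total - x$n_meth,
            inf = as.numeric(x$n_total >= params$min_reads)),
      key, reorder = FALSE
    )
    tibble(key = as.numeric(rownames(agg)), mC = agg[, "mC"],
           uC = agg[, "uC"], inf = agg[, "inf"])
  }
  ps <- pool(s); pc <- pool(c_)
  all_keys <- union(ps$key, pc$key)
  if (length(all_keys) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(), context = character(),
      mC_sample = numeric(), uC_sample = numeric(), mC_control = numeric(),
      uC_control = numeric(), frac_sample = numeric(), frac_control = numeric(),
      diff = numeric(), n_informative_sample = integer(),
      n_informative_control = integer(), eligible = logical()
    ))
  }
  is_ <- match(all_keys, ps$key); ic <- match(all_keys, pc$key)
  grab <- function(tab, idx, col) ifelse(is.na(idx), 0, tab[[col]][idx])
  chrom <- chroms[all_keys %/% nbins_max + 1]
  bin <- as.integer(all_keys %% nbins_max)
  out <- tibble(
    chrom = chrom,
    start = bin * bs,
    end = pmin(bin * bs + bs, unname(chrom_sizes[chrom])),
    context = context,
    mC_sample = grab(ps, is_, "mC"), uC_sample = grab(ps, is_, "uC"),
    mC_control = grab(pc, ic, "mC"), uC_control = grab(pc, ic, "uC"),
    n_informative_sample = as.integer(grab(ps, is_, "inf")),
    n_informative_control = as.integer(grab(pc, ic, "inf"))
  )
  out <- dplyr::mutate(
    out,
    frac_sample = fractional_methylation(.data$mC_sample, .data$mC_sample + .data$uC_sample),
    frac_control = fractional_methylation(.data$mC_control, .data$mC_control + .data$uC_control),
    diff = .data$frac_sample - .data$frac_control,
    eligible = .data$n_informative_sample >= params$min_informative &
      .data$n_informative_control >= params$min_informative
  )
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Call differentially methylated regions against a wild-type control
#'
#' The full binned DMR pipeline for one context: (1) pool counts into
#' fixed-width bins ([bin_counts()]); (2) Fisher's exact test per eligible bin
#' on the 2x2 table of pooled methylated/unmethylated reads; (3) BH adjustment
#' across all eligible bins of the context genome-wide; (4) a bin is
#' significant when `q < fdr` and its absolute pooled methylation difference
#' reaches the per-context threshold (ties at the threshold pass); (5)
#' significant bins are split by sign into hypo-/hypermethylated and merged
#' with same-direction neighbours no more than `merge_gap` bp away; pooled
#' methylation levels are recomputed over each merged region.
#'
#' @inheritParams bin_counts
#' @return An object of class `dmr_result`: a list with `dmrs` (tibble of
#'   merged regions: `chrom`, `start`, `end`, `context`, `direction`,
#'   `frac_sample`, `frac_control`, `diff`, `n_bins`, `sample_id`,
#'   `control_id`), `bins` (the per-bin test table with `p_value`/`q_value`),
#'   and the parameters. Use [tidy()] for the DMR tibble and [glance()] for a
#'   one-row summary.
#' @export
call_dmrs <- function(sample, control, params = dmr_params(), context,
                      chrom_sizes) {
  if (identical(sample, control)) {
    rlang::warn("sample and control are the identical object; no DMRs can be called")
  }
  bins <- bin_counts(sample, control, params, context, chrom_sizes)
  test_set <- if (params$filter_stage == "pre") bins$eligible else
    (bins$mC_sample + bins$uC_sample > 0) & (bins$mC_control + bins$uC_control > 0)
  bins$p_value <- NA_real_
  bins$q_value <- NA_real_
  if (any(test_set)) {
    bins$p_value[test_set] <- fisher_exact_two_sided(
      bins$mC_sample[test_set], bins$uC_sample[test_set],
      bins$mC_control[test_set], bins$uC_control[test_set]
    )
    bins$q_value[test_set] <- bh_adjust(bins$p_value[test_set])
  }
  sig <- !is.na(bins$q_value) & bins$q_value < params$fdr &
    abs(bins$diff) >= params$min_abs_diff[[context]] & bins$eligible
  dmrs <- merge_significant_bins(bins[sig, , drop = FALSE], params)
  if (nrow(dmrs) > 0) {
    dmrs$context <- context
    dmrs$sample_id <- sample_id(sample) %||% "sample"
    dmrs$control_id <- sample_id(control) %||% "control"
  } else {
    dmrs <- empty_dmr_tibble(context, sample_id(sample), sample_id(control))
  }
  structure(
    list(dmrs = dmrs, bins = bins, params = params, context = context,
         sample_id = sample_id(sample), control_id = sample_id(control)),
    class = "dmr_result"
  )
}

empty_dmr_tibble <- function(context = character(0), sid = NULL, cid = NULL) {
  tibble(
    chrom = character(), start = integer(), end = integer(),
    context = character(), direction = character(), frac_sample = numeric(),
    frac_control = numeric(), diff = numeric(), n_bins = integer(),
    sample_id = character(), control_id = character()
  )
}

# merge same-direction significant bins whose gap is <= merge_gap
merge_significant_bins <- function(sig, params) {
  if (nrow(sig) == 0) return(empty_dmr_tibble())
  sig$direction <- ifelse(sig$diff < 0, "hypo", "hyper")
  sig <- dplyr::arrange(sig, .data$chrom, .data$start)
  new_run <- c(TRUE, sig$chrom[-1] != sig$chrom[-nrow(sig)] |
                 sig$direction[-1] != sig$direction[-nrow(sig)] |
                 sig$start[-1] - sig$end[-nrow(sig)] > params$merge_gap)
  sig$run <- cumsum(new_run)
  out <- sig |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom),
      start = min(.data$start), end = max(.data$end),
      direction = dplyr::first(.data$direction),
      frac_sample = sum(.data$mC_sample) / sum(.data$mC_sample + .data$uC_sample),
      frac_control = sum(.data$mC_control) / sum(.data$mC_control + .data$uC_control),
      n_bins = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(diff = .data$frac_sample - .data$frac_control) |>
    dplyr::select(-"run") |>
    dplyr::arrange(.data$chrom, .data$start)
  out
}

#' @export
print.dmr_result <- function(x, ...) {
  cat(sprintf(
    "<dmr_result> %s vs %s, context %s: %d DMRs (%d hypo, %d hyper) from %d eligible bins\n",
    x$sample_id %||% "sample", x$control_id %||% "control", x$context,
    nrow(x$dmrs), sum(x$dmrs$direction == "hypo"),
    sum(x$dmrs$direction == "hyper"), sum(x$bins$eligible)
  ))
  print(x$dmrs, ...)
  invisible(x)
}

#' Fraction of the genome covered by a DMR set
#'
#' @param dmrs Tibble of DMRs (columns `chrom`, `start`, `end`); must be
#'   non-overlapping, as produced by [call_dmrs()].
#' @param genome_size Total genome size in bp.
#' @return Fraction in `[0, 1]`.
#' @export
dmr_genome_coverage <- function(dmrs, genome_size) {
  stopifnot(genome_size > 0)
  if (nrow(dmrs) == 0) return(0)
  gr <- intervals_to_granges(dmrs)
  if (length(GenomicRanges::reduce(gr)) != length(gr)) {
    rlang::abort("DMR set contains overlapping intervals")
  }
  sum(dmrs$end - dmrs$start) / genome_size
}

#' Distribution of DMR sizes
#'
#' @inheritParams dmr_genome_coverage
#' @return Tibble `size` (bp), `n`, sorted by size; the minimum possible size
#'   equals the bin width.
#' @export
dmr_size_histogram <- function(dmrs) {
  if (nrow(dmrs) == 0) return(tibble(size = integer(), n = integer()))
  dplyr::count(tibble(size = dmrs$end - dmrs$start), .data$size, name = "n")
}

#' Write DMRs as BED6
#'
#' Name is `context:direction`, score is `round(1000 * |diff|)`, strand `"."`.
#'
#' @inheritParams dmr_genome_coverage
#' @param path Output file.
#' @export
write_dmrs_bed <- function(dmrs, path) {
  df <- data.frame(
    dmrs$chrom, dmrs$start, dmrs$end,
    paste0(dmrs$context, ":", dmrs$direction),
    round(1000 * abs(dmrs$diff)), "."
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname call_dmrs
#' @param x A `dmr_result`.
#' @param ... Unused.
#' @method tidy dmr_result
#' @export
tidy.dmr_result <- function(x, ...) x$dmrs

#' @rdname call_dmrs
#' @method glance dmr_result
#' @export
glance.dmr_result <- function(x, ...) {
  tibble(
    sample_id = x$sample_id %||% NA_character_,
    control_id = x$control_id %||% NA_character_,
    context = x$context,
    n_dmrs = nrow(x$dmrs),
    n_hypo = sum(x$dmrs$direction == "hypo"),
    n_hyper = sum(x$dmrs$direction == "hyper"),
    n_bins_eligible = sum(x$bins$eligible),
    median_size = if (nrow(x$dmrs)) stats::median(x$dmrs$end - x$dmrs$start) else NA_real_
  )
}
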