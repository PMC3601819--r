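#' @keywords internal
CONTEXTS <- c("CG", "CHG", "CHH")

# internal: assert a data frame has the given columns
check_columns <- function(x, cols, what = deparse(substitute(x))) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "`%s` is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(x)
}

check_context <- function(context) {
  if (!is.character(context) || length(context) != 1 || !context %in% CONTEXTS) {
    rlang::abort('`context` must be one of "CG", "CHG", "CHH"')
  }
  context
}

# internal: tibble of intervals -> GRanges (0-based half-open in, 1-based in GRanges)
intervals_to_granges <- function(x) {
  check_columns(x, c("chrom", "start", "end"), "intervals")
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# internal: site positions -> GRanges of width 1
sites_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$pos + 1L, width = 1L)
  )
}

#' Fractional methylation
#'
#' The pooled methylation level #C / (#C + #T). Sites (or pools) with zero
#' coverage are undefined and return `NA`, which is distinct from an observed
#' level of 0.
#'
#' @param n_meth Number of reads calling the cytosine methylated (#C).
#' @param n_total Total reads covering the site (#C + #T).
#' @return Numeric vector of methylation fractions in `[0, 1]`, `NA` where
#'   `n_total` is 0.
#' @examples
#' fractional_methylation(3, 10)
#' fractional_methylation(c(0, 5), c(7, 0))
#' @export
fractional_methylation <- function(n_meth, n_total) {
  stopifnot(all(n_total >= 0, na.rm = TRUE))
  if (any(n_meth > n_total & n_total > 0, na.rm = TRUE)) {
    rlang::abort("`n_meth` may not exceed `n_total`")
  }
  ifelse(n_total > 0, n_meth / n_total, NA_real_)
}

# internal: derive a stream of sub-seeds from one user seed, staying < 2^31
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
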