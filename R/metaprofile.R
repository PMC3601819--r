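#' Average scaled profile over regions with equal-length flanks
#'
#' Computes the classic methylation/coverage metaplot: each region is
#' length-normalized into `n_windows_body` windows, flanked on both sides by
#' regions of *equal length* to the body split into `n_windows_flank`
#' windows. Methylation per window is the pooled #C/(#C+#T) over the
#' cytosines falling in it; density signals (e.g. small-RNA reads) are
#' summed and divided by the window's bp span, with absent positions
#' counting as zero. Per-bp data are distributed across windows by
#' fractional overlap, so regions shorter than the window count are handled
#' exactly. The final profile averages, per window, over the regions that
#' contribute data there. For `strand_aware = TRUE`, windows of `-` strand
#' regions are reversed so the profile reads 5' to 3'.
#'
#' @param regions Tibble of intervals (`chrom`, `start`, `end`, optional
#'   `strand`).
#' @param signal For `mode = "methylation"`: tibble `chrom`, `pos`,
#'   `n_meth`, `n_total` (filter to one context first). For
#'   `mode = "density"`: tibble `chrom`, `pos`, `value`.
#' @param n_windows_body,n_windows_flank Window counts (defaults 20/20).
#' @param strand_aware Reverse the window order for `-` strand regions.
#' @param mode `"methylation"` (pooled fraction) or `"density"` (per-bp
#'   mean, missing positions = 0).
#' @param chrom_sizes Optional named vector; flanks running off a chromosome
#'   end are truncated to the available span and the region is flagged.
#' @return Tibble of class `scaled_profile`: `window_index`, `zone`
#'   (`upstream`/`body`/`downstream`), `value`, `n_regions`; attribute
#'   `truncated_regions` gives the number of edge-truncated regions.
#' @export
scaled_profile <- function(regions, signal, n_windows_body = 20,
                           n_windows_flank = 20, strand_aware = FALSE,
                           mode = c("methylation", "density"),
                           chrom_sizes = NULL) {
  mode <- match.arg(mode)
  stopifnot(nrow(regions) > 0, n_windows_body >= 1, n_windows_flank >= 0)
  if (mode == "methylation") {
    check_columns(signal, c("chrom", "pos", "n_meth", "n_total"), "signal")
  } else {
    check_columns(signal, c("chrom", "pos", "value"), "signal")
  }
  nb <- n_windows_body; nf <- n_windows_flank
  n_win <- nb + 2 * nf
  sig_split <- split(signal, signal$chrom)
  sig_split <- lapply(sig_split, function(s) s[order(s$pos), , drop = FALSE])

  num <- matrix(0, nrow(regions), n_win)    # pooled numerator per window
  den <- matrix(0, nrow(regions), n_win)    # denominator per window
  truncated <- logical(nrow(regions))

  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    L <- r$end - r$start
    size <- if (!is.null(chrom_sizes)) unname(chrom_sizes[r$chrom]) else Inf
    zones <- list(
      list(zs = r$start - L, n = nf, off = 0),
      list(zs = r$start, n = nb, off = nf),
      list(zs = r$end, n = nf, off = nf + nb)
    )
    s <- sig_split[[r$chrom]]
    for (z in zones) {
      if (z$n == 0) next
      lo <- max(0, z$zs); hi <- min(size, z$zs + L)
      if (lo > z$zs || hi < z$zs + L) truncated[i] <- TRUE
      if (hi <= lo) next
      a <- z$n / L                           # windows per bp
      if (!is.null(s)) {
        k0 <- findInterval(lo - 1L, s$pos) + 1L
        k1 <- findInterval(hi - 1L, s$pos)
        idx <- if (k1 >= k0) seq(k0, k1) else integer(0)
      } else idx <- integer(0)
      if (length(idx) > 0) {
        x0 <- (s$pos[idx] - z$zs) * a
        x1 <- x0 + a
        if (mode == "methylation") {
          v_num <- s$n_meth[idx]; v_den <- s$n_total[idx]
        } else {
          v_num <- s$value[idx]; v_den <- NULL
        }
        for (o in 0:ceiling(a)) {
          k <- floor(x0) + o
          w <- pmax(0, pmin(x1, k + 1) - pmax(x0, k)) / a
          ok <- w > 0 & k >= 0 & k < z$n
          if (!any(ok)) next
          cols <- z$off + k[ok] + 1
          num[i, ] <- num[i, ] + rowsum_into(v_num[ok] * w[ok], cols, n_win)
          if (mode == "methylation") {
            den[i, ] <- den[i, ] + rowsum_into(v_den[ok] * w[ok], cols, n_win)
          }
        }
      }
      if (mode == "density") {
        # denominator: bp span of each window inside the available zone
        k <- seq_len(z$n) - 1
        wlo <- z$zs + k / a; whi <- z$zs + (k + 1) / a
        den[i, z$off + k + 1] <- pmax(0, pmin(whi, hi) - pmax(wlo, lo))
      }
    }
    if (strand_aware && "strand" %in% names(regions) &&
        identical(r$strand, "-")) {
      num[i, ] <- rev(num[i, ]); den[i, ] <- rev(den[i, ])
    }
  }
  with_data <- den > 0
  vals <- ifelse(with_data, num / pmax(den, .Machine$double.eps), NA_real_)
  out <- tibble(
    window_index = seq_len(n_win),
    zone = rep(c("upstream", "body", "downstream"), c(nf, nb, nf)),
    value = colMeans(vals, na.rm = TRUE),
    n_regions = colSums(with_data)
  )
  out$value[out$n_regions == 0] <- NA_real_
  attr(out, "truncated_regions") <- sum(truncated)
  class(out) <- c("scaled_profile", class(out))
  out
}

# scatter-add values into a fixed-length vector by index
rowsum_into <- function(v, idx, n) {
  out <- numeric(n)
  agg <- rowsum(v, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' @rdname scaled_profile
#' @param object A `scaled_profile`.
#' @param ... Unused.
#' @method autoplot scaled_profile
#' @export
autoplot.scaled_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$window_index, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(
      xintercept = range(object$window_index[object$zone == "body"]) +
        c(-0.5, 0.5),
      linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "scaled position (windows)", y = "mean signal") +
    ggplot2::theme_minimal()
}
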