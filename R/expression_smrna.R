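#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count / (gene_length/1000) / (library_size/1e6)`.
#'
#' @param count Raw read count(s).
#' @param gene_length_bp Gene model length in bp (> 0).
#' @param library_size Uniquely mapped reads in the library (> 0).
#' @return Numeric RPKM value(s).
#' @examples
#' rpkm(10, 2000, 1e6)
#' @export
rpkm <- function(count, gene_length_bp, library_size) {
  if (any(gene_length_bp <= 0)) rlang::abort("gene length must be positive")
  if (any(library_size <= 0)) rlang::abort("library size must be positive")
  count / (gene_length_bp / 1000) / (library_size / 1e6)
}

#' Call differentially expressed genes against a control sample
#'
#' Genes with zero counts in both samples are excluded
#' (`status = "excluded_zero"`). Each remaining gene is tested with a
#' two-sided Fisher's exact test on
#' `[[count_s, lib_s - count_s], [count_c, lib_c - count_c]]` with BH
#' adjustment across tested genes; the fold change is the ratio of
#' pseudocounted normalized abundances `((count + 0.5)/lib)`. A gene is
#' `up` when `fold >= fold_cut` and `q < fdr`, `down` symmetrically
#' (`fold <= 1/fold_cut`), otherwise `unchanged`.
#'
#' @param counts Tibble with columns `gene_id`, `count_sample`,
#'   `count_control` (same gene universe on both sides).
#' @param lib_sample,lib_control Library sizes (uniquely mapped read totals,
#'   supplied — not recomputed).
#' @param fold_cut Fold-change cutoff (default 4).
#' @param fdr BH FDR cutoff (default 0.01).
#' @param gene_lengths Optional named vector of gene lengths; when given,
#'   per-sample RPKM columns are added.
#' @return Tibble: `gene_id`, counts, `fold_change`, `p_value`, `q_value`,
#'   `status` in `c("up", "down", "unchanged", "excluded_zero")`, and RPKM
#'   columns when lengths are supplied.
#' @export
call_de <- function(counts, lib_sample, lib_control, fold_cut = 4, fdr = 0.01,
                    gene_lengths = NULL) {
  check_columns(counts, c("gene_id", "count_sample", "count_control"))
  if (anyDuplicated(counts$gene_id)) rlang::abort("duplicate gene ids")
  stopifnot(lib_sample > 0, lib_control > 0)
  out <- as_tibble(counts)
  zero <- out$count_sample == 0 & out$count_control == 0
  out$fold_change <- ((out$count_sample + 0.5) / lib_sample) /
    ((out$count_control + 0.5) / lib_control)
  out$p_value <- NA_real_
  out$q_value <- NA_real_
  t_ <- !zero
  if (any(t_)) {
    out$p_value[t_] <- fisher_exact_two_sided(
      out$count_sample[t_], lib_sample - out$count_sample[t_],
      out$count_control[t_], lib_control - out$count_control[t_]
    )
    out$q_value[t_] <- bh_adjust(out$p_value[t_])
  }
  out$status <- dplyr::case_when(
    zero ~ "excluded_zero",
    out$q_value < fdr & out$fold_change >= fold_cut ~ "up",
    out$q_value < fdr & out$fold_change <= 1 / fold_cut ~ "down",
    TRUE ~ "unchanged"
  )
  if (!is.null(gene_lengths)) {
    gl <- unname(gene_lengths[out$gene_id])
    out$rpkm_sample <- rpkm(out$count_sample, gl, lib_sample)
    out$rpkm_control <- rpkm(out$count_control, gl, lib_control)
  }
  out
}

#' Deregulation frequency by distance to the TSS
#'
#' For promoter hypomethylation DMRs annotated with their nearest TSS
#' ([distance_to_tss()]), computes per distance bin the fraction of
#' DMR-proximal genes whose expression status is `up` or `down`;
#' `excluded_zero` genes are left out of the denominator.
#'
#' @param dmr_genes Tibble with columns `nearest_gene` and `tss_distance`
#'   (one row per DMR), as from [distance_to_tss()].
#' @param de_records A [call_de()] result.
#' @param breaks Distance bin edges in bp applied to `abs(tss_distance)`
#'   (default `c(0, 500, 1000, 2000)`).
#' @return Tibble: `bin`, `n_genes`, `n_deregulated`, `fraction`; bins with
#'   no genes get `NA` fraction.
#' @export
deregulation_by_distance <- function(dmr_genes, de_records,
                                     breaks = c(0, 500, 1000, 2000)) {
  check_columns(dmr_genes, c("nearest_gene", "tss_distance"))
  labs <- paste0("[", utils::head(breaks, -1), ",", utils::tail(breaks, -1), ")")
  x <- dmr_genes |>
    dplyr::left_join(dplyr::select(de_records, gene_id = "gene_id", "status"),
                     by = c(nearest_gene = "gene_id")) |>
    dplyr::filter(!is.na(.data$status), .data$status != "excluded_zero") |>
    dplyr::distinct(.data$nearest_gene, .keep_all = TRUE) |>
    dplyr::mutate(bin = cut(abs(.data$tss_distance), breaks = breaks,
                            labels = labs, right = FALSE, include.lowest = FALSE))
  res <- x |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::group_by(.data$bin, .drop = FALSE) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_deregulated = sum(.data$status %in% c("up", "down")),
      .groups = "drop"
    ) |>
    dplyr::mutate(fraction = ifelse(.data$n_genes > 0,
                                    .data$n_deregulated / .data$n_genes, NA_real_))
  res$bin <- as.character(res$bin)
  res
}

#' Filter small-RNA records by read length
#'
#' @param records Tibble with columns `chrom`, `start`, `length`, `count`.
#' @param length Read length in nt to keep (default 24, the siRNA species
#'   guiding CHH methylation).
#' @return The matching records.
#' @export
filter_by_length <- function(records, length = 24) {
  check_columns(records, c("chrom", "start", "length", "count"))
  dplyr::filter(records, .data$length == .env$length)
}

#' Per-position small-RNA coverage signal
#'
#' Expands window-level records to a per-position signal tibble usable by
#' [scaled_profile()]: each record contributes `count / width` per bp over
#' `[start, start + width)`.
#'
#' @inheritParams filter_by_length
#' @param width Window width the record counts cover (default 100 bp,
#'   matching the simulator's emission resolution).
#' @return Tibble `chrom`, `pos`, `value`.
#' @export
smrna_position_signal <- function(records, width = 100) {
  if (nrow(records) == 0) return(tibble(chrom = character(), pos = integer(),
                                        value = numeric()))
  idx <- rep(seq_len(nrow(records)), each = width)
  tibble(
    chrom = records$chrom[idx],
    pos = records$start[idx] + rep(seq_len(width) - 1L, nrow(records)),
    value = records$count[idx] / width
  ) |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(value = sum(.data$value), .groups = "drop")
}
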