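#' Run the full analysis pipeline on a (simulated) dataset
#'
#' Executes the stages in order: chloroplast error-rate estimation, per-
#' context DMR calling of every non-control sample against the wild type,
#' cross-sample comparison (overlap matrix, common DMRs, stability
#' classification when T2/T4/T6 are present), genomic-feature enrichment of
#' the CG hypomethylation DMRs, differential expression of each regenerant
#' against wild type, and the scaled methylation metaprofile over CG
#' hypomethylation DMRs. All outputs are written as tab-separated text plus
#' BED for DMRs, and listed in a manifest with md5 checksums.
#'
#' @param ds A [simulate_dataset()] result (or a list with the same shape:
#'   `genome`, `samples`, `mrna`).
#' @param out_dir Output directory.
#' @param params [dmr_params()] for the caller.
#' @param contexts Contexts to call (default all three).
#' @return A list with the in-memory results (`error_rates`, `dmr_results`,
#'   `overlap`, `common`, `stability`, `enrichment`, `de`, `profiles`) and
#'   `manifest`, a tibble of written files with checksums.
#' @export
run_pipeline <- function(ds, out_dir, params = dmr_params(),
                         contexts = CONTEXTS) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  chrom_sizes <- ds$genome$chrom_sizes
  nuclear <- chrom_sizes[setdiff(names(chrom_sizes), ds$genome$organelle)]
  samples <- ds$samples
  wt <- samples$WT
  if (is.null(wt)) rlang::abort("pipeline expects a `WT` control sample")
  test_samples <- setdiff(names(samples), "WT")
  files <- character()
  emit <- function(x, f) {
    path <- file.path(out_dir, f)
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
    path
  }

  # stage 1: error rates
  error_rates <- purrr::map_dfr(names(samples), function(nm) {
    tibble(sample = nm, context = contexts,
           error_rate = vapply(contexts, function(cx)
             estimate_error_rate(samples[[nm]], cx), numeric(1)))
  })
  emit(error_rates, "error_rates.tsv")

  # stage 2: DMR calling per sample x context
  dmr_results <- list()
  for (nm in test_samples) {
    for (cx in contexts) {
      res <- call_dmrs(samples[[nm]], wt, params, cx, nuclear)
      dmr_results[[paste(nm, cx, sep = ".")]] <- res
      if (nrow(res$dmrs) > 0) {
        bed <- file.path(out_dir, sprintf("dmrs_%s_%s.bed", nm, cx))
        write_dmrs_bed(res$dmrs, bed)
        files <- c(files, bed)
      }
    }
  }
  all_dmrs <- purrr::map_dfr(dmr_results, tidy)
  emit(all_dmrs, "dmrs_all.tsv")

  # stage 3: comparative analyses on CG hypomethylation DMRs
  cg_hypo <- lapply(test_samples, function(nm) {
    d <- dmr_results[[paste(nm, "CG", sep = ".")]]
    if (is.null(d)) return(NULL)
    dplyr::filter(d$dmrs, .data$direction == "hypo")
  })
  names(cg_hypo) <- test_samples
  cg_hypo <- cg_hypo[!vapply(cg_hypo, is.null, logical(1))]
  regen <- setdiff(names(cg_hypo), "callus")
  overlap <- if (length(cg_hypo) >= 2) overlap_matrix(cg_hypo) else NULL
  if (!is.null(overlap)) {
    emit(as.data.frame(overlap), "overlap_matrix.tsv")
  }
  common <- if (length(regen) >= 2) common_dmrs(cg_hypo[regen]) else NULL
  if (!is.null(common) && nrow(common) > 0) emit(common, "common_dmrs.tsv")

  stability <- NULL
  if (all(c("T2", "T4", "T6") %in% names(samples)) &&
      !is.null(cg_hypo$T2) && nrow(cg_hypo$T2) > 0) {
    stability <- classify_stability(cg_hypo$T2, wt, samples$T2, samples$T4,
                                    samples$T6)
    emit(stability, "stability.tsv")
  }

  # stage 4: feature enrichment of pooled regenerant CG hypo DMRs
  features <- extract_features(ds$genome$genes, chrom_sizes,
                               exons = ds$genome$exons)
  pooled <- dplyr::bind_rows(cg_hypo[regen])
  enrichment <- NULL
  if (nrow(pooled) > 0) {
    enrichment <- enrichment_test(pooled, features, nuclear, seed = 1)
    emit(tidy(enrichment), "enrichment.tsv")
  }

  # stage 5: differential expression vs WT
  de <- NULL
  if (!is.null(ds$mrna)) {
    cts <- tidyr::pivot_wider(ds$mrna$counts, names_from = "sample",
                              values_from = "count")
    libs <- setNames(ds$mrna$library_sizes$library_size,
                     ds$mrna$library_sizes$sample)
    de <- purrr::map(
      intersect(test_samples, setdiff(colnames(cts), "gene_id")),
      function(nm) {
        call_de(
          tibble(gene_id = cts$gene_id, count_sample = cts[[nm]],
                 count_control = cts$WT),
          libs[[nm]], libs[["WT"]]
        )
      })
    names(de) <- intersect(test_samples, setdiff(colnames(cts), "gene_id"))
    de_long <- dplyr::bind_rows(de, .id = "sample")
    emit(de_long, "de_calls.tsv")
  }

  # stage 6: metaprofiles of CG methylation over pooled CG hypo DMRs
  profiles <- NULL
  if (nrow(pooled) > 0) {
    sig <- function(s) dplyr::filter(s, .data$context == "CG",
                                     .data$chrom %in% names(nuclear))
    profiles <- list(
      WT = scaled_profile(pooled, sig(wt), chrom_sizes = chrom_sizes),
      regenerant = scaled_profile(pooled, sig(samples[[regen[1]]]),
                                  chrom_sizes = chrom_sizes)
    )
    emit(dplyr::bind_rows(profiles, .id = "sample"), "metaprofile_cg.tsv")
  }

  manifest <- tibble(file = files, md5 = unname(tools::md5sum(files)))
  emit(manifest, "manifest.tsv")
  list(error_rates = error_rates, dmr_results = dmr_results,
       overlap = overlap, common = common, stability = stability,
       enrichment = enrichment, de = de, profiles = profiles,
       manifest = manifest)
}
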