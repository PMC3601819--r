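test_that("the simulator is a pure function of config and seed", {
  cfg <- sim_config(seed = 9, chrom_length = 3e5, chloroplast_length = 2e4,
                    n_genes = 20, n_te_genes = 8,
                    n_planted_dmrs = c(CG = 3, CHG = 2, CHH = 2),
                    n_regenerants = 1, n_callus_hyper = 3)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$genome$genome, b$genome$genome)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth$planted, b$truth$planted)
  expect_identical(a$smrna, b$smrna)
  expect_identical(a$mrna$counts, b$mrna$counts)
  c_ <- simulate_dataset(cfg, seed = 10)
  expect_false(identical(a$samples$WT$n_meth, c_$samples$WT$n_meth))
})

test_that("degenerate configurations behave as stated", {
  cfg <- sim_config(chrom_length = 8e4, chloroplast_length = 1e4, n_genes = 0,
                    n_te_genes = 5,
                    n_planted_dmrs = c(CG = 0, CHG = 0, CHH = 0))
  g <- simulate_genome(cfg)
  expect_true(all(g$genes$type == "TE_gene"))
  expect_error(
    simulate_genome(sim_config(chrom_length = 5e4, n_genes = 40)),
    "too short"
  )
})

test_that("genome composition and annotation are structurally sound", {
  ds <- small_ds()
  g <- ds$genome
  gc <- sum(strsplit(g$genome[["chr1"]], "")[[1]] %in% c("G", "C")) /
    nchar(g$genome[["chr1"]])
  expect_equal(gc, 0.43, tolerance = 0.02)
  genes <- dplyr::arrange(g$genes, .data$chrom, .data$start)
  by_chr <- split(genes, genes$chrom)
  for (x in by_chr) {
    expect_true(all(utils::head(x$end, -1) <= utils::tail(x$start, -1)))
  }
  expect_true(all(g$exons$start >= 0))
  expect_equal(g$organelle, "chrPt")
})

test_that("wild-type methylation marginals match the configured landscape", {
  ds <- small_ds()
  tr <- ds$truth
  wt <- ds$samples$WT
  cfg <- ds$config
  for (cx in c("CG", "CHG", "CHH")) {
    sel <- tr$site_levels$context == cx &
      tr$site_levels$chrom != tr$organelle
    p_true <- tr$site_levels$p_wt[sel]
    expected <- mean(p_true) + (1 - mean(p_true)) * cfg$error_rate
    x <- wt[wt$context == cx & wt$chrom != tr$organelle, ]
    obs <- sum(x$n_meth) / sum(x$n_total)
    se <- sqrt(expected * (1 - expected) / sum(x$n_total))
    expect_lt(abs(obs - expected), 3 * se + 1e-4)
  }
})

test_that("planted regions overlap enough context cytosines to be callable", {
  ds <- small_ds()
  planted <- ds$truth$planted
  sl <- ds$truth$site_levels
  expect_gt(nrow(planted), 0)
  for (i in seq_len(nrow(planted))) {
    d <- planted[i, ]
    n_ctx <- sum(sl$chrom == d$chrom & sl$context == d$context &
                   sl$pos >= d$start & sl$pos < d$end)
    expect_gte(n_ctx, 10)
  }
  # planted regions stay inside the genome and apart from each other
  expect_true(all(planted$end <= ds$genome$chrom_sizes[planted$chrom]))
  pl <- dplyr::arrange(planted, .data$chrom, .data$start)
  by_chr <- split(pl, pl$chrom)
  for (x in by_chr) {
    if (nrow(x) > 1) {
      expect_true(all(utils::tail(x$start, -1) >= utils::head(x$end, -1)))
    }
  }
})

test_that("hypomethylation losses and inheritance follow the stated rules", {
  cfg <- sim_config(seed = 4, chrom_length = 3.5e5, chloroplast_length = 2e4,
                    n_genes = 25, n_te_genes = 10,
                    n_planted_dmrs = c(CG = 4, CHG = 0, CHH = 0),
                    shared_site_fraction = 1, n_regenerants = 2,
                    include_callus = FALSE)
  sim <- simulate_genome(cfg)
  ms <- simulate_methylomes(sim, cfg)
  tr <- ms$truth
  # shared_site_fraction = 1: every line loses every susceptible region
  expect_true(all(tr$loss$lost))
  # T4/T6 loss state is consistent with the drawn inheritance category
  cat <- tr$inheritance$category
  expect_equal(tr$lost_in$T4, cat %in% c("stable_loss", "recovered_T6_only"))
  expect_equal(tr$lost_in$T6, cat %in% c("stable_loss", "transient_T4"))
  # lost level realises the configured drop
  expect_equal(tr$planted$p0 - tr$planted$lost_level,
               unname(cfg$dmr_delta[tr$planted$context]))
})

test_that("callus gains CHH methylation at promoters that regenerants lack", {
  ds <- small_ds()
  tr <- ds$truth
  expect_gt(nrow(tr$callus_hyper), 0)
  # callus-specific: CHH sites inside hyper promoters are raised only in callus
  m_callus <- tr$mods$callus
  expect_gt(nrow(m_callus), 0)
  sl <- tr$site_levels
  idx <- m_callus$site
  expect_true(all(sl$context[idx] == "CHH"))
  expect_equal(m_callus$p, pmin(1, sl$p_wt[idx] + ds$config$callus_chh_gain))
  for (nm in setdiff(names(tr$mods), "callus")) {
    expect_length(intersect(tr$mods[[nm]]$site, idx), 0)
  }
})

test_that("small-RNA tables couple 24-nt reads to CHH methylation", {
  ds <- small_ds()
  sm <- ds$smrna
  expect_false("callus" %in% names(sm))
  for (tab in sm) {
    expect_setequal(unique(tab$length), c(21L, 24L))
    expect_true(all(tab$count >= 1))
  }
  # wild type carries more 24-nt signal than a regenerant over its lost DMRs
  tr <- ds$truth
  lost <- tr$planted[tr$lost_in$T2 & tr$planted$context == "CHH", ]
  if (nrow(lost) > 0) {
    count_in <- function(tab, reg) {
      x <- filter_by_length(tab, 24)
      sum(x$count[x$chrom %in% reg$chrom &
                    x$start >= min(reg$start) - 100 &
                    x$start < max(reg$end)])
    }
    tot_wt <- sum(vapply(seq_len(nrow(lost)), function(i)
      count_in(sm$WT, lost[i, ]), numeric(1)))
    tot_t2 <- sum(vapply(seq_len(nrow(lost)), function(i)
      count_in(sm$T2, lost[i, ]), numeric(1)))
    expect_gt(tot_wt, tot_t2)
  }
  # windows with zero true CHH methylation only ever see background 21-mers
  sl <- tr$site_levels
  zero_win <- setdiff(
    unique(sl$pos[sl$chrom == "chr1" & sl$context == "CHH" & sl$p_wt == 0] %/% 100),
    unique(sl$pos[sl$chrom == "chr1" & sl$context == "CHH" & sl$p_wt > 0] %/% 100)
  )
  w24 <- filter_by_length(sm$WT[sm$WT$chrom == "chr1", ], 24)
  expect_length(intersect(zero_win, w24$start %/% 100), 0)
})

test_that("mRNA counts place fourfold effects at hypomethylated promoters", {
  cfg <- sim_config(seed = 12, chrom_length = 5e5, chloroplast_length = 2e4,
                    n_genes = 40, n_te_genes = 12,
                    n_planted_dmrs = c(CG = 8, CHG = 0, CHH = 0),
                    promoter_enrichment_fraction = 1,
                    shared_site_fraction = 1, n_regenerants = 0,
                    generations = "T2", include_callus = FALSE,
                    responsiveness = 1)
  sim <- simulate_genome(cfg)
  ms <- simulate_methylomes(sim, cfg)
  mr <- simulate_mrna(ms, sim, cfg)
  de_t2 <- mr$truth_de[mr$truth_de$sample == "T2", ]
  expect_gte(nrow(de_t2), 8)   # every promoter-planted DMR drives its gene
  cts <- tidyr::pivot_wider(mr$counts, names_from = "sample",
                            values_from = "count")
  de_mean <- mean(cts$T2[cts$gene_id %in% de_t2$gene_id])
  bg_mean <- mean(cts$T2[!cts$gene_id %in% de_t2$gene_id])
  expect_gt(de_mean / bg_mean, 2.5)

  cfg0 <- sim_config(seed = 12, chrom_length = 5e5, chloroplast_length = 2e4,
                     n_genes = 40, n_te_genes = 12,
                     n_planted_dmrs = c(CG = 8, CHG = 0, CHH = 0),
                     promoter_enrichment_fraction = 1,
                     shared_site_fraction = 1, n_regenerants = 0,
                     generations = "T2", include_callus = FALSE,
                     responsiveness = 0)
  ms0 <- simulate_methylomes(simulate_genome(cfg0), cfg0)
  mr0 <- simulate_mrna(ms0, simulate_genome(cfg0), cfg0)
  expect_equal(nrow(mr0$truth_de), 0)
})

test_that("a dataset round-trips through its on-disk text formats", {
  ds <- small_ds()
  dir <- withr::local_tempdir()
  manifest <- write_sim_dataset(ds, dir)
  expect_true(all(file.exists(manifest$file)))
  g <- read_genome_fasta(file.path(dir, "genome.fa"))
  expect_identical(g, ds$genome$genome)
  wt <- read_cytosine_calls(file.path(dir, "calls_WT.tsv.gz"),
                            organelle_chroms = "chrPt")
  expect_equal(wt$pos, ds$samples$WT$pos)
  expect_equal(wt$n_meth, ds$samples$WT$n_meth)
  expect_equal(wt$context, ds$samples$WT$context)
})
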