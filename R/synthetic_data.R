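#' Configuration of the synthetic methylome world
#'
#' Collects every parameter of the simulator: genome layout, the per-context
#' methylation landscape, sequencing depth and non-conversion error, the
#' planted differentially methylated regions (DMRs) and their stochastic
#' sharing across regenerant lines, transgenerational inheritance, the
#' callus-specific CHH hypermethylation, and the coupled small-RNA and mRNA
#' layers. Defaults emulate a down-scaled rice tissue-culture experiment:
#' ~15x coverage, high CG / intermediate CHG / low CHH methylation at
#' methylated loci, ~1.2% non-conversion, promoter-enriched hypomethylation
#' shared stochastically between regenerants, and fourfold upregulation at a
#' subset of promoter-hypomethylated genes.
#'
#' @param seed Integer seed; every simulator output is a pure function of
#'   `(config, seed)`.
#' @param n_chroms,chrom_length Nuclear chromosome count and length (bp).
#' @param chloroplast_length Length of the unmethylated organelle chromosome
#'   used for error-rate estimation.
#' @param n_genes,n_te_genes Protein-coding and transposable-element gene
#'   counts (split across chromosomes).
#' @param gc_content Genome GC fraction (default 0.43, rice-like).
#' @param baseline_meth Named per-context true methylation at methylated loci
#'   (default `c(CG = 0.85, CHG = 0.55, CHH = 0.07)`).
#' @param unmeth_level True methylation at unmethylated loci (default 0).
#' @param gene_body_cg Two values: CG gene-body gradient from TSS to TTS.
#' @param chh_island_level True CHH level inside planted CHH regions
#'   (RdDM-island-like; default 0.25, so a multiplicative loss can remove the
#'   full configured CHH delta).
#' @param meth_promoter_fraction Fraction of promoters carrying methylation
#'   (the substrate eligible for hypomethylation planting).
#' @param coverage_mean Mean reads per cytosine (Poisson; default 15).
#' @param error_rate Non-conversion probability: a truly unmethylated read is
#'   called methylated at this rate (default 0.012).
#' @param n_planted_dmrs Named per-context counts of planted hypomethylated
#'   regions.
#' @param dmr_delta Named per-context absolute methylation drop at planted
#'   regions in samples that lose them (defaults `c(CG = 0.8, CHG = 0.6,
#'   CHH = 0.15)`).
#' @param dmr_length_range List of per-context length ranges (bp) for planted
#'   regions.
#' @param promoter_enrichment_fraction Fraction of planted DMRs placed in
#'   promoters (the rest go to TE-class loci).
#' @param shared_site_fraction Probability that any given regenerant line
#'   loses methylation at a susceptible (planted) region.
#' @param n_regenerants Number of independent regenerant lines (`R1`, `R2`,
#'   ...) besides the multi-generation line.
#' @param generations Generations simulated for the multi-generation line,
#'   a subset of `c("T2", "T4", "T6")`.
#' @param recovery_probs Per-DMR probabilities that a T2 loss recovers in T4
#'   (and stays), recovers only in T6, or recovers in T4 transiently; the
#'   remainder is stably lost.
#' @param include_callus,n_callus_hyper,callus_chh_gain Whether to simulate a
#'   callus sample, how many (unmethylated) promoters it CHH-hypermethylates,
#'   and the absolute CHH gain (capped at 1).
#' @param smrna_per_chh Expected 24-nt siRNA reads per unit of summed true
#'   CHH methylation in a 100-bp window.
#' @param smrna_bg_21 Expected 21-nt background reads per 100-bp window,
#'   independent of methylation.
#' @param mrna_mean,mrna_dispersion Negative-binomial baseline mean and
#'   dispersion of per-gene mRNA counts.
#' @param library_size Reported mRNA library size (uniquely mapped reads).
#' @param de_fold Expression fold effect at hypomethylated promoters.
#' @param responsiveness Probability that a gene responds to promoter
#'   hypomethylation (only some genes do; default 0.3).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 1, chrom_length = 1e6,
                       chloroplast_length = 150000,
                       n_genes = 100, n_te_genes = 30,
                       gc_content = 0.43,
                       baseline_meth = c(CG = 0.85, CHG = 0.55, CHH = 0.07),
                       unmeth_level = 0,
                       gene_body_cg = c(0.2, 0.6),
                       chh_island_level = 0.25,
                       meth_promoter_fraction = 0.25,
                       coverage_mean = 15,
                       error_rate = 0.012,
                       n_planted_dmrs = c(CG = 20, CHG = 12, CHH = 12),
                       dmr_delta = c(CG = 0.8, CHG = 0.6, CHH = 0.15),
                       dmr_length_range = list(CG = c(300, 900),
                                               CHG = c(300, 900),
                                               CHH = c(400, 900)),
                       promoter_enrichment_fraction = 0.5,
                       shared_site_fraction = 0.5,
                       n_regenerants = 2,
                       generations = c("T2", "T4", "T6"),
                       recovery_probs = c(recovered_T4 = 0.10,
                                          recovered_T6_only = 0.044,
                                          transient_T4 = 0.02),
                       include_callus = TRUE,
                       n_callus_hyper = 20,
                       callus_chh_gain = 0.2,
                       smrna_per_chh = 0.4,
                       smrna_bg_21 = 0.2,
                       mrna_mean = 200,
                       mrna_dispersion = 0.05,
                       library_size = 1e6,
                       de_fold = 4,
                       responsiveness = 0.3) {
  cfg <- as.list(environment())
  probs <- c(cfg$promoter_enrichment_fraction, cfg$shared_site_fraction,
             cfg$error_rate, cfg$responsiveness, cfg$meth_promoter_fraction,
             cfg$recovery_probs)
  stopifnot(
    all(probs >= 0 & probs <= 1), sum(cfg$recovery_probs) <= 1,
    cfg$coverage_mean > 0, cfg$chrom_length > 0, cfg$n_chroms >= 1,
    all(cfg$baseline_meth >= 0 & cfg$baseline_meth <= 1),
    all(CONTEXTS %in% names(cfg$baseline_meth)),
    all(CONTEXTS %in% names(cfg$n_planted_dmrs)),
    all(CONTEXTS %in% names(cfg$dmr_delta)),
    cfg$chh_island_level >= cfg$dmr_delta[["CHH"]],
    cfg$de_fold > 0, cfg$mrna_mean > 0, cfg$library_size > 0,
    "T2" %in% cfg$generations || length(cfg$generations) == 0
  )
  structure(cfg, class = "sim_config")
}

# planted-region methylation level per context: CG/CHG use the methylated-
# locus baseline; CHH regions are elevated RdDM-like islands so that a
# multiplicative loss can realise the full configured delta
plant_level <- function(config, context) {
  if (context == "CHH") config$chh_island_level else config$baseline_meth[[context]]
}

#' Simulate a genome with gene and TE annotation
#'
#' Generates random chromosome sequence at the configured GC content,
#' non-overlapping protein-coding genes with exon/intron structure,
#' TE genes, and a separate short "chloroplast" chromosome flagged as the
#' unmethylated organelle control. Deterministic given `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return List of class `sim_genome`: `genome` (named character vector),
#'   `genes`, `exons` (tibbles), `chrom_sizes`, `organelle`.
#' @export
simulate_genome <- function(config = sim_config(), seed = config$seed) {
  set.seed(seed)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  base_codes <- utf8ToInt("ACGT")
  base_prob <- c((1 - config$gc_content) / 2, config$gc_content / 2,
                 config$gc_content / 2, (1 - config$gc_content) / 2)
  rand_seq <- function(L) {
    intToUtf8(base_codes[sample.int(4L, L, replace = TRUE, prob = base_prob)])
  }
  genome <- setNames(
    c(lapply(chroms, function(ch) rand_seq(config$chrom_length)),
      list(rand_seq(config$chloroplast_length))),
    c(chroms, "chrPt")
  )
  genome <- vapply(genome, identity, character(1))
  chrom_sizes <- setNames(
    c(rep(config$chrom_length, config$n_chroms), config$chloroplast_length),
    c(chroms, "chrPt")
  )

  # place genes and TE genes unit by unit with a promoter-sized minimum gap
  units <- tibble(
    gene_id = c(sprintf("g%04d", seq_len(config$n_genes)),
                sprintf("te%03d", seq_len(config$n_te_genes))),
    type = rep(c("gene", "TE_gene"), c(config$n_genes, config$n_te_genes)),
    len = c(round(runif(config$n_genes, 2000, 6000)),
            round(runif(config$n_te_genes, 1000, 4000)))
  )
  units <- units[sample.int(nrow(units)), ]
  units$chrom <- chroms[rep_len(seq_along(chroms), nrow(units))]
  placed <- purrr::map_dfr(chroms, function(ch) {
    u <- units[units$chrom == ch, ]
    n <- nrow(u)
    if (n == 0) return(NULL)
    min_gap <- 2500
    slack <- config$chrom_length - sum(u$len) - (n + 1) * min_gap
    if (slack < 0) {
      rlang::abort("chromosome too short to place the requested genes")
    }
    cuts <- sort(runif(n, 0, slack))
    extra <- diff(c(0, cuts, slack))
    gap <- min_gap + extra[seq_len(n)]
    start <- cumsum(gap) + cumsum(c(0, u$len[-n]))
    dplyr::mutate(u, start = round(start), end = round(start) + .data$len,
                  strand = sample(c("+", "-"), n, replace = TRUE))
  })
  genes <- dplyr::select(placed, "gene_id", "chrom", "start", "end",
                         "strand", "type")
  exons <- purrr::map_dfr(which(genes$type == "gene"), function(i) {
    g <- genes[i, ]
    L <- g$end - g$start
    n_ex <- sample(2:5, 1)
    w <- runif(2 * n_ex - 1, 0.5, 1.5)
    seg <- round(L * w / sum(w))
    seg[length(seg)] <- L - sum(seg[-length(seg)])
    bounds <- g$start + c(0, cumsum(seg))
    tibble(
      gene_id = g$gene_id, chrom = g$chrom,
      start = bounds[seq(1, 2 * n_ex - 1, by = 2)],
      end = bounds[seq(2, 2 * n_ex, by = 2)]
    )
  })
  structure(
    list(genome = genome, genes = genes, exons = exons,
         chrom_sizes = chrom_sizes, organelle = "chrPt"),
    class = "sim_genome"
  )
}

# promoter intervals of a gene table (0-based half-open, strand-aware)
promoter_intervals <- function(genes, chrom_sizes, flank_bp = 2000) {
  tibble(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = pmax(0, ifelse(genes$strand == "+", genes$start - flank_bp, genes$end)),
    end = pmin(unname(chrom_sizes[genes$chrom]),
               ifelse(genes$strand == "+", genes$start, genes$end + flank_bp)),
    strand = genes$strand
  )
}

#' Simulate multi-sample methylomes with a truth ledger
#'
#' Builds the true per-cytosine methylation landscape (TE-class loci high,
#' CG-only gene-body gradient, promoters mostly unmethylated with a
#' methylated subset), plants hypomethylated regions enriched in promoters,
#' assigns stochastic per-line losses and transgenerational inheritance,
#' optionally adds callus-specific CHH hypermethylation, and draws observed
#' counts as `n_total ~ Poisson(coverage)`,
#' `n_meth ~ Binomial(n_total, p + (1 - p) * error_rate)`. The chloroplast is
#' unmethylated everywhere (`p = 0`), so its apparent methylation estimates
#' the error rate.
#'
#' @param sim A [simulate_genome()] result.
#' @inheritParams simulate_genome
#' @return List of class `sim_methylomes`: `samples` (named list of methylome
#'   tibbles: `WT`, generations of the multi-generation line, independent
#'   regenerants `R*`, and `callus`), and `truth` (class `sim_truth`) holding
#'   the planted regions, per-line loss indicators, inheritance categories,
#'   callus-hypermethylated promoters, and true site-level methylation.
#' @export
simulate_methylomes <- function(sim, config = sim_config(), seed = config$seed) {
  seeds <- derive_seeds(seed, 20)
  set.seed(seeds[1])
  sites <- find_cytosines(sim$genome)
  n_sites <- nrow(sites)
  p <- rep(config$unmeth_level, n_sites)
  nuclear <- sites$chrom != sim$organelle
  sites_gr <- sites_to_granges(sites)

  # TE-class loci (TE genes +- 500 bp flank): methylated in all contexts
  te <- dplyr::filter(sim$genes, .data$type == "TE_gene")
  if (nrow(te) > 0) {
    te_fl <- dplyr::mutate(te, start = pmax(0, .data$start - 500),
                           end = pmin(unname(sim$chrom_sizes[.data$chrom]),
                                      .data$end + 500))
    hit <- S4Vectors::queryHits(GenomicRanges::findOverlaps(
      sites_gr, intervals_to_granges(te_fl)))
    hit <- unique(hit)
    p[hit] <- config$baseline_meth[sites$context[hit]]
  }

  # methylated promoter subset: substrate for promoter DMR planting
  pc <- dplyr::filter(sim$genes, .data$type == "gene")
  proms <- promoter_intervals(pc, sim$chrom_sizes)
  n_meth_prom <- round(nrow(proms) * config$meth_promoter_fraction)
  meth_prom <- proms[sample.int(nrow(proms), n_meth_prom), ]
  if (nrow(meth_prom) > 0) {
    hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(
      sites_gr, intervals_to_granges(meth_prom))))
    p[hit] <- config$baseline_meth[sites$context[hit]]
  }

  # CG-only gene-body gradient along transcription direction
  if (nrow(pc) > 0) {
    ov <- GenomicRanges::findOverlaps(sites_gr, intervals_to_granges(pc))
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    keep <- sites$context[qh] == "CG"
    qh <- qh[keep]; sh <- sh[keep]
    tfrac <- (sites$pos[qh] - pc$start[sh]) / (pc$end[sh] - pc$start[sh])
    tfrac <- ifelse(pc$strand[sh] == "-", 1 - tfrac, tfrac)
    p[qh] <- config$gene_body_cg[1] +
      tfrac * (config$gene_body_cg[2] - config$gene_body_cg[1])
  }

  # plant hypomethylated regions (promoter-enriched, context-dense substrate)
  set.seed(seeds[2])
  planted <- place_planted_dmrs(sites, meth_prom, te, config)
  region_sites <- planted$region_sites
  planted <- planted$planted
  for (i in seq_len(nrow(planted))) {
    p[region_sites[[i]]] <- planted$p0[i]
  }

  # per-line stochastic loss + inheritance of the multi-generation line
  set.seed(seeds[3])
  lines <- c(if (length(config$generations) > 0) "T2",
             if (config$n_regenerants > 0) paste0("R", seq_len(config$n_regenerants)))
  n_dmr <- nrow(planted)
  lost <- matrix(runif(n_dmr * length(lines)) < config$shared_site_fraction,
                 nrow = n_dmr, dimnames = list(NULL, lines))
  cat_levels <- c("stable_loss", "recovered_T4", "recovered_T6_only", "transient_T4")
  probs <- c(1 - sum(config$recovery_probs),
             config$recovery_probs[["recovered_T4"]],
             config$recovery_probs[["recovered_T6_only"]],
             config$recovery_probs[["transient_T4"]])
  category <- rep(NA_character_, n_dmr)
  if ("T2" %in% lines) {
    t2_lost <- which(lost[, "T2"])
    category[t2_lost] <- sample(cat_levels, length(t2_lost),
                                replace = TRUE, prob = probs)
  }

  lost_in <- function(sample_name) {
    if (n_dmr == 0) return(logical(0))
    switch(sample_name,
      WT = rep(FALSE, n_dmr),
      callus = rep(FALSE, n_dmr),
      T2 = lost[, "T2"],
      T4 = lost[, "T2"] & category %in% c("stable_loss", "recovered_T6_only"),
      T6 = lost[, "T2"] & category %in% c("stable_loss", "transient_T4"),
      lost[, sample_name]
    )
  }

  sample_names <- c("WT", intersect(c("T2", "T4", "T6"), config$generations),
                    if (config$n_regenerants > 0) paste0("R", seq_len(config$n_regenerants)),
                    if (config$include_callus) "callus")

  # callus CHH hypermethylation at a distinct, unmethylated promoter subset
  callus_hyper <- tibble(gene_id = character(), chrom = character(),
                         start = integer(), end = integer())
  callus_chh_idx <- integer(0)
  if (config$include_callus && config$n_callus_hyper > 0) {
    free_prom <- proms[!proms$gene_id %in% meth_prom$gene_id, ]
    k <- min(config$n_callus_hyper, nrow(free_prom))
    callus_hyper <- free_prom[sample.int(nrow(free_prom), k),
                              c("gene_id", "chrom", "start", "end")]
    hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(
      sites_gr, intervals_to_granges(callus_hyper))))
    callus_chh_idx <- hit[sites$context[hit] == "CHH"]
  }

  p_for_sample <- function(sample_name) {
    ps <- p
    li <- lost_in(sample_name)
    for (i in which(li)) {
      ps[region_sites[[i]]] <- planted$lost_level[i]
    }
    if (sample_name == "callus" && length(callus_chh_idx) > 0) {
      ps[callus_chh_idx] <- pmin(1, ps[callus_chh_idx] + config$callus_chh_gain)
    }
    ps
  }

  samples <- list()
  mods <- list()
  for (k in seq_along(sample_names)) {
    nm <- sample_names[k]
    ps <- p_for_sample(nm)
    samples[[nm]] <- draw_methylome_counts(
      sites, ps, coverage_mean = config$coverage_mean,
      error_rate = config$error_rate, seed = seeds[4] + k,
      sample_id = nm, organelle = sim$organelle
    )
    changed <- which(ps != p)
    mods[[nm]] <- tibble(site = changed, p = ps[changed])
  }

  loss_tbl <- if (n_dmr > 0 && length(lines) > 0) {
    tidyr::pivot_longer(
      dplyr::bind_cols(tibble(dmr_id = planted$dmr_id), as_tibble(lost)),
      -"dmr_id", names_to = "line", values_to = "lost"
    )
  } else tibble(dmr_id = character(), line = character(), lost = logical())

  truth <- structure(
    list(
      planted = planted,
      loss = loss_tbl,
      lost_in = setNames(lapply(sample_names, lost_in), sample_names),
      inheritance = tibble(dmr_id = planted$dmr_id, category = category),
      callus_hyper = callus_hyper,
      meth_promoters = meth_prom,
      site_levels = dplyr::bind_cols(sites, tibble(p_wt = p)),
      mods = mods,
      chrom_sizes = sim$chrom_sizes,
      organelle = sim$organelle,
      config = config
    ),
    class = "sim_truth"
  )
  structure(list(samples = samples, truth = truth), class = "sim_methylomes")
}

#' Draw observed bisulfite counts over a site table
#'
#' The simulator's observation model as a standalone step: per site,
#' `n_total ~ Poisson(coverage_mean)` and
#' `n_meth ~ Binomial(n_total, p + (1 - p) * error_rate)` — non-conversion
#' only inflates apparent methylation, mirroring how chloroplast-based error
#' estimation works. Useful for drawing independent count noise over a fixed
#' true methylation landscape (e.g. null-calibration experiments).
#'
#' @param sites Tibble `chrom`, `pos`, `strand`, `context` (see
#'   [find_cytosines()]).
#' @param p True methylation probability per site (recycled if length 1).
#' @param coverage_mean,error_rate Observation parameters.
#' @param seed Integer seed.
#' @param sample_id,organelle Metadata attached to the returned methylome.
#' @return A methylome tibble.
#' @export
draw_methylome_counts <- function(sites, p, coverage_mean = 15,
                                  error_rate = 0.012, seed = 1,
                                  sample_id = "sim", organelle = character()) {
  n <- nrow(sites)
  p <- rep_len(p, n)
  set.seed(seed)
  n_total <- rpois(n, coverage_mean)
  n_meth <- rbinom(n, n_total, p + (1 - p) * error_rate)
  as_methylome(
    dplyr::bind_cols(sites[, c("chrom", "pos", "strand", "context")],
                     tibble(n_meth = n_meth, n_total = n_total)),
    sample_id, organelle
  )
}

# choose planted-DMR intervals: promoter-enriched, non-overlapping, and with
# at least two 100-bp bins holding >= 10 cytosines of the target context
place_planted_dmrs <- function(sites, meth_prom, te, config,
                               min_sites_per_bin = 10, min_dense_bins = 2) {
  pos_by <- list()
  for (ctx in CONTEXTS) {
    sel <- sites$context == ctx
    pos_by[[ctx]] <- split(which(sel), sites$chrom[sel])
  }
  used <- tibble(chrom = character(), start = numeric(), end = numeric())
  prom_pool <- if (nrow(meth_prom) > 0) meth_prom[sample.int(nrow(meth_prom)), ] else meth_prom
  te_pool <- if (nrow(te) > 0) te[sample.int(nrow(te)), ] else te
  prom_i <- 1L; te_i <- 1L
  out <- list(); region_sites <- list()
  dmr_no <- 0L

  dense_enough <- function(idx_pos, s, e) {
    if (length(idx_pos) < min_sites_per_bin) return(FALSE)
    first_bin <- ceiling(s / 100); last_bin <- floor(e / 100) - 1
    if (last_bin < first_bin) return(FALSE)
    counts <- tabulate(idx_pos %/% 100 - first_bin + 1L,
                       nbins = last_bin - first_bin + 1L)
    sum(counts >= min_sites_per_bin) >= min_dense_bins
  }

  for (ctx in CONTEXTS) {
    n_want <- config$n_planted_dmrs[[ctx]]
    if (n_want == 0) next
    n_prom <- round(n_want * config$promoter_enrichment_fraction)
    rng <- config$dmr_length_range[[ctx]]
    for (j in seq_len(n_want)) {
      in_prom <- j <= n_prom
      placed_one <- FALSE
      while (!placed_one) {
        host <- if (in_prom) {
          if (prom_i > nrow(prom_pool)) {
            rlang::abort(sprintf(
              "ran out of methylated promoters while planting %s DMRs; increase n_genes or meth_promoter_fraction", ctx))
          }
          h <- prom_pool[prom_i, ]; prom_i <- prom_i + 1L; h
        } else {
          if (te_i > nrow(te_pool)) {
            rlang::abort(sprintf(
              "ran out of TE loci while planting %s DMRs; increase n_te_genes", ctx))
          }
          h <- te_pool[te_i, ]; te_i <- te_i + 1L; h
        }
        host_len <- host$end - host$start
        ctx_pos_all <- sites$pos[pos_by[[ctx]][[host$chrom]] %||% integer(0)]
        for (try in seq_len(40)) {
          len <- round(runif(1, rng[1], rng[2]))
          if (host_len < len) break
          s <- host$start + floor(runif(1, 0, host_len - len + 1))
          e <- s + len
          clash <- any(used$chrom == host$chrom & used$start < e + 300 &
                         used$end + 300 > s)
          if (clash) next
          idx_rel <- pos_by[[ctx]][[host$chrom]]
          inside <- idx_rel[sites$pos[idx_rel] >= s & sites$pos[idx_rel] < e]
          if (!dense_enough(sites$pos[inside], s, e)) next
          dmr_no <- dmr_no + 1L
          p0 <- plant_level(config, ctx)
          delta <- config$dmr_delta[[ctx]]
          out[[dmr_no]] <- tibble(
            dmr_id = sprintf("dmr_%s_%03d", ctx, dmr_no),
            chrom = host$chrom, start = s, end = e, context = ctx,
            p0 = p0, delta = delta,
            lost_level = max(0, p0 * (1 - delta / p0)),
            in_promoter = in_prom
          )
          region_sites[[dmr_no]] <- inside
          used <- dplyr::bind_rows(used, tibble(chrom = host$chrom,
                                                start = s, end = e))
          placed_one <- TRUE
          break
        }
      }
    }
  }
  planted <- if (length(out) > 0) dplyr::bind_rows(out) else
    tibble(dmr_id = character(), chrom = character(), start = integer(),
           end = integer(), context = character(), p0 = numeric(),
           delta = numeric(), lost_level = numeric(), in_promoter = logical())
  list(planted = planted, region_sites = region_sites)
}

#' Simulate small-RNA read tables coupled to CHH methylation
#'
#' 24-nt siRNA counts per 100-bp window are Poisson with rate proportional to
#' the window's summed true CHH methylation in that sample, so losses at
#' planted regions eliminate the local siRNAs; 21-nt reads form a
#' methylation-independent background.
#'
#' @param msim A [simulate_methylomes()] result.
#' @inheritParams simulate_genome
#' @param samples Sample names to emit (default: all non-callus samples).
#' @return Named list of tibbles `chrom`, `start` (0-based window start),
#'   `length` (nt), `count`.
#' @export
simulate_smrna <- function(msim, config = sim_config(), seed = config$seed,
                           samples = NULL) {
  truth <- msim$truth
  samples <- samples %||% setdiff(names(msim$samples), "callus")
  sl <- truth$site_levels
  nuclear <- sl$chrom != truth$organelle
  chh <- which(nuclear & sl$context == "CHH")
  win_key <- paste0(sl$chrom[chh], ":", sl$pos[chh] %/% 100)
  seeds <- derive_seeds(seed, length(samples))
  out <- list()
  for (k in seq_along(samples)) {
    nm <- samples[k]
    p <- sl$p_wt
    m <- truth$mods[[nm]]
    if (!is.null(m) && nrow(m) > 0) p[m$site] <- m$p
    agg <- rowsum(p[chh], win_key, reorder = FALSE)
    keys <- rownames(agg)
    set.seed(seeds[k])
    lam24 <- config$smrna_per_chh * agg[, 1]
    c24 <- rpois(length(lam24), lam24)
    km <- stringr::str_match(keys, "^(.*):(\\d+)$")
    tab24 <- tibble(chrom = km[, 2], start = as.integer(km[, 3]) * 100L,
                    length = 24L, count = c24)[c24 > 0, ]
    # 21-nt background over all windows of the nuclear genome
    nuc_sizes <- truth$chrom_sizes[setdiff(names(truth$chrom_sizes), truth$organelle)]
    bg <- purrr::map_dfr(names(nuc_sizes), function(ch) {
      nw <- ceiling(nuc_sizes[[ch]] / 100)
      cts <- rpois(nw, config$smrna_bg_21)
      tibble(chrom = ch, start = (seq_len(nw) - 1L) * 100L,
             length = 21L, count = cts)[cts > 0, ]
    })
    out[[nm]] <- dplyr::arrange(dplyr::bind_rows(tab24, bg),
                                .data$chrom, .data$start, .data$length)
  }
  out
}

#' Simulate per-gene mRNA counts with promoter-hypomethylation effects
#'
#' Baseline counts are negative-binomial; a gene whose promoter overlaps a
#' planted DMR is "responsive" with the configured probability, and in each
#' sample where that DMR is lost its mean is multiplied by `de_fold`.
#'
#' @inheritParams simulate_smrna
#' @param sim The [simulate_genome()] result (for gene and promoter
#'   coordinates).
#' @return List: `counts` (tibble `gene_id`, `sample`, `count`),
#'   `library_sizes` (tibble `sample`, `library_size`), `truth_de` (tibble
#'   `gene_id`, `sample`, `direction`).
#' @export
simulate_mrna <- function(msim, sim, config = sim_config(), seed = config$seed) {
  truth <- msim$truth
  pc <- dplyr::filter(sim$genes, .data$type == "gene")
  proms <- promoter_intervals(pc, sim$chrom_sizes)
  planted <- truth$planted
  samples <- names(msim$samples)
  set.seed(derive_seeds(seed, 1))
  responsive <- setNames(runif(nrow(pc)) < config$responsiveness, pc$gene_id)
  gene_dmrs <- if (nrow(planted) > 0) {
    ov <- GenomicRanges::findOverlaps(intervals_to_granges(proms),
                                      intervals_to_granges(planted))
    tibble(gene_id = proms$gene_id[S4Vectors::queryHits(ov)],
           dmr_idx = S4Vectors::subjectHits(ov))
  } else tibble(gene_id = character(), dmr_idx = integer())

  counts <- list(); de <- list()
  seeds <- derive_seeds(seed + 1, length(samples))
  for (k in seq_along(samples)) {
    nm <- samples[k]
    li <- truth$lost_in[[nm]]
    de_genes <- unique(gene_dmrs$gene_id[li[gene_dmrs$dmr_idx]])
    de_genes <- de_genes[responsive[de_genes]]
    mu <- rep(config$mrna_mean, nrow(pc))
    mu[pc$gene_id %in% de_genes] <- mu[pc$gene_id %in% de_genes] * config$de_fold
    set.seed(seeds[k])
    cts <- rnbinom(nrow(pc), mu = mu, size = 1 / config$mrna_dispersion)
    counts[[nm]] <- tibble(gene_id = pc$gene_id, sample = nm, count = cts)
    if (length(de_genes) > 0) {
      de[[nm]] <- tibble(gene_id = de_genes, sample = nm, direction = "up")
    }
  }
  list(
    counts = dplyr::bind_rows(counts),
    library_sizes = tibble(sample = samples,
                           library_size = config$library_size),
    truth_de = if (length(de) > 0) dplyr::bind_rows(de) else
      tibble(gene_id = character(), sample = character(), direction = character())
  )
}

#' Simulate a complete synthetic dataset
#'
#' Runs [simulate_genome()], [simulate_methylomes()], [simulate_smrna()] and
#' [simulate_mrna()] from one seed.
#'
#' @inheritParams simulate_genome
#' @return List of class `sim_dataset` with elements `genome` (`sim_genome`),
#'   `samples`, `truth`, `smrna`, `mrna`, `config`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = config$seed) {
  seeds <- derive_seeds(seed, 4)
  sim <- simulate_genome(config, seeds[1])
  msim <- simulate_methylomes(sim, config, seeds[2])
  smrna <- simulate_smrna(msim, config, seeds[3])
  mrna <- simulate_mrna(msim, sim, config, seeds[4])
  structure(
    list(genome = sim, samples = msim$samples, truth = msim$truth,
         smrna = smrna, mrna = mrna, config = config),
    class = "sim_dataset"
  )
}

#' Write a simulated dataset to disk in the package's text formats
#'
#' Emits the genome FASTA, per-sample cytosine call tables (gzip), the gene
#' and exon annotation, small-RNA and mRNA tables, the truth ledger (planted
#' regions with per-line loss indicators, versioned header) and the
#' configuration as a key=value file.
#'
#' @param ds A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Tibble manifest of the files written (`file`, `md5`), invisibly.
#' @export
write_sim_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(dir, ...)
  files <- character()
  write_genome_fasta(ds$genome$genome, pth("genome.fa"))
  files <- c(files, pth("genome.fa"))
  wt <- function(x, f) {
    utils::write.table(x, pth(f), sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, pth(f))
  }
  wt(ds$genome$genes, "genes.tsv")
  wt(ds$genome$exons, "exons.tsv")
  for (nm in names(ds$samples)) {
    f <- pth(sprintf("calls_%s.tsv.gz", nm))
    write_cytosine_calls(ds$samples[[nm]], f)
    files <- c(files, f)
  }
  for (nm in names(ds$smrna)) wt(ds$smrna[[nm]], sprintf("smrna_%s.tsv", nm))
  wt(ds$mrna$counts, "mrna_counts.tsv")
  wt(ds$mrna$library_sizes, "library_sizes.tsv")
  truth_file <- pth("truth_planted.tsv")
  con <- file(truth_file, "w")
  writeLines("# methregen truth ledger v1", con)
  loss_wide <- tidyr::pivot_wider(ds$truth$loss, names_from = "line",
                                  values_from = "lost", names_prefix = "lost_")
  truth_tab <- dplyr::left_join(ds$truth$planted, loss_wide, by = "dmr_id") |>
    dplyr::left_join(ds$truth$inheritance, by = "dmr_id")
  suppressWarnings(utils::write.table(truth_tab, con, sep = "\t",
                                      quote = FALSE, row.names = FALSE))
  close(con)
  files <- c(files, truth_file)
  cfgv <- vapply(unclass(ds$config), function(v)
    paste(format(v, digits = 15, trim = TRUE), collapse = ","), character(1))
  writeLines(paste0(names(cfgv), "=", cfgv), pth("config.txt"))
  files <- c(files, pth("config.txt"))
  invisible(tibble(file = files, md5 = unname(tools::md5sum(files))))
}
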