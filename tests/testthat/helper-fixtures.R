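# shared fixtures, built in code once per test run

# hand-built methylome: one context, sites at given positions on one chrom
make_methylome <- function(pos, n_meth, n_total, context = "CG",
                           chrom = "chr1", strand = "+", sample_id = "s",
                           organelle = character()) {
  methregen:::as_methylome(
    tibble::tibble(
      chrom = chrom, pos = as.integer(pos), strand = strand,
      context = context,
      n_meth = as.integer(rep_len(n_meth, length(pos))),
      n_total = as.integer(rep_len(n_total, length(pos)))
    ),
    sample_id, organelle
  )
}

# a small complete simulated dataset, cached across test files
.fixture_env <- new.env(parent = emptyenv())

small_sim_config <- function(...) {
  sim_config(
    seed = 42, chrom_length = 6e5, chloroplast_length = 60000,
    n_genes = 50, n_te_genes = 18,
    n_planted_dmrs = c(CG = 8, CHG = 5, CHH = 5),
    n_regenerants = 2, n_callus_hyper = 8, ...
  )
}

small_ds <- function() {
  if (is.null(.fixture_env$ds)) {
    .fixture_env$ds <- simulate_dataset(small_sim_config())
  }
  .fixture_env$ds
}

nuclear_sizes <- function(ds) {
  ds$genome$chrom_sizes[setdiff(names(ds$genome$chrom_sizes),
                                ds$genome$organelle)]
}

# the 10-Mb recovery world: 50 planted DMRs per context at 15x, one T2 line
recovery_config <- function() {
  sim_config(
    seed = 5, chrom_length = 1e7, chloroplast_length = 150000,
    n_genes = 600, n_te_genes = 200,
    n_planted_dmrs = c(CG = 50, CHG = 50, CHH = 50),
    generations = "T2", n_regenerants = 0, include_callus = FALSE
  )
}

recovery_ds <- function() {
  if (is.null(.fixture_env$rec)) {
    cfg <- recovery_config()
    sim <- simulate_genome(cfg)
    .fixture_env$rec <- list(
      cfg = cfg, sim = sim, msim = simulate_methylomes(sim, cfg)
    )
  }
  .fixture_env$rec
}

# 1-bp overlap matching of called intervals against truth intervals
overlap_frac <- function(query, subject) {
  if (nrow(query) == 0) return(NA_real_)
  mean(IRanges::overlapsAny(
    IRanges::IRanges(query$start + 1L, query$end),
    IRanges::IRanges(subject$start + 1L, subject$end)
  ))
}
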