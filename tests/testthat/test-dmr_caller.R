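# R-level oracle: two-sided Fisher p by direct hypergeometric enumeration
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  supp <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(supp, m, n, k)
  sum(dens[dens <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}

test_that("two-sided Fisher's exact test matches enumeration and fisher.test", {
  expect_equal(fisher_exact_two_sided(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_two_sided(3, 7, 3, 7), 1)
  expect_equal(fisher_exact_two_sided(0, 0, 0, 0), 1)

  set.seed(3)
  tabs <- matrix(rpois(4 * 200, 8), ncol = 4)
  p_mine <- fisher_exact_two_sided(tabs[, 1], tabs[, 2], tabs[, 3], tabs[, 4])
  p_oracle <- apply(tabs, 1, function(x) fisher_oracle(x[1], x[2], x[3], x[4]))
  expect_equal(p_mine, p_oracle, tolerance = 1e-9)
  p_ref <- apply(tabs, 1, function(x)
    stats::fisher.test(matrix(x, 2, byrow = TRUE))$p.value)
  expect_equal(p_mine, p_ref, tolerance = 1e-7)
  # large-margin tables (the DE use case)
  expect_equal(fisher_exact_two_sided(100, 1e6 - 100, 5, 1e6 - 5),
               stats::fisher.test(matrix(c(100, 1e6 - 100, 5, 1e6 - 5),
                                         2, byrow = TRUE))$p.value,
               tolerance = 1e-6)
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_adjust(c(0.001, 0.01, 0.02, 0.8)),
               c(0.004, 0.02, 0.02 * 4 / 3, 0.8), tolerance = 1e-12)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:400, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
  # monotone transform preserving p-value order
  p <- runif(100)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("error-rate estimation pools organelle counts", {
  m <- make_methylome(seq(0, 990, 10), n_meth = 0, n_total = 10,
                      chrom = "chrPt", organelle = "chrPt")
  expect_equal(estimate_error_rate(m, "CG"), 0)
  m2 <- make_methylome(seq(0, 990, 10), n_meth = c(1, rep(0, 9)),
                       n_total = 10, chrom = "chrPt", organelle = "chrPt")
  expect_equal(estimate_error_rate(m2, "CG"), 10 / 1000)
  expect_warning(r <- estimate_error_rate(m, "CHH"), "undefined")
  expect_true(is.na(r))
})

test_that("bins tile half-open, pool both strands, and gate on informativeness", {
  params <- dmr_params()
  sizes <- c(chr1 = 1000)
  s <- make_methylome(c(99, 100, seq(110, 190, 10)), n_meth = 9, n_total = 10)
  ctrl <- make_methylome(c(99, 100, seq(110, 190, 10)), n_meth = 0, n_total = 10)
  b <- bin_counts(s, ctrl, params, "CG", sizes)
  expect_equal(b$start, c(0, 100))
  # pos 99 alone in [0,100): 1 informative cytosine -> ineligible
  expect_equal(b$n_informative_sample, c(1L, 10L))
  expect_equal(b$eligible, c(FALSE, TRUE))
  expect_equal(b$frac_sample, c(0.9, 0.9))
  expect_equal(b$diff, c(0.9, 0.9))

  # 9 informative on one side is not enough even with 12 on the other
  s9 <- make_methylome(seq(0, 80, 10), n_meth = 9, n_total = 10)
  c12 <- make_methylome(seq(0, 88, 8), n_meth = 0, n_total = 10)
  b2 <- bin_counts(s9, c12, params, "CG", sizes)
  expect_equal(b2$n_informative_sample, 9L)
  expect_equal(b2$n_informative_control, 12L)
  expect_false(b2$eligible[1])

  # both strands pooled into the same bin
  two <- methregen:::as_methylome(
    tibble::tibble(chrom = "chr1", pos = c(10L, 11L), strand = c("+", "-"),
                   context = "CG", n_meth = c(5L, 0L), n_total = c(10L, 10L)),
    "s", character()
  )
  b3 <- bin_counts(two, two, params, "CG", sizes)
  expect_equal(b3$mC_sample, 5)
  expect_equal(b3$frac_sample, 0.25)
})

test_that("DMR calling merges same-direction bins across gaps <= merge_gap", {
  params <- dmr_params()
  sizes <- c(chr1 = 2000)
  # strong hypomethylation in bins [0,100) and [200,300); nothing in between
  pos <- c(seq(0, 95, 5), seq(200, 295, 5))
  s <- make_methylome(pos, n_meth = 0, n_total = 15, sample_id = "mut")
  ctrl <- make_methylome(pos, n_meth = 15, n_total = 15, sample_id = "wt")
  res <- call_dmrs(s, ctrl, params, "CG", sizes)
  expect_s3_class(res, "dmr_result")
  expect_equal(nrow(res$dmrs), 1)
  expect_equal(res$dmrs$start, 0)
  expect_equal(res$dmrs$end, 300)
  expect_equal(res$dmrs$direction, "hypo")
  expect_equal(res$dmrs$n_bins, 2)
  expect_equal(res$dmrs$frac_sample, 0)
  expect_equal(res$dmrs$frac_control, 1)
  expect_equal(res$dmrs$sample_id, "mut")

  # bins further apart than merge_gap stay separate DMRs
  pos2 <- c(seq(0, 95, 5), seq(300, 395, 5))
  s2 <- make_methylome(pos2, n_meth = 0, n_total = 15)
  c2 <- make_methylome(pos2, n_meth = 15, n_total = 15)
  res2 <- call_dmrs(s2, c2, params, "CG", sizes)
  expect_equal(nrow(res2$dmrs), 2)
  expect_equal(res2$dmrs$end - res2$dmrs$start, c(100, 100))

  # opposite directions are never merged
  pos3 <- c(seq(0, 95, 5), seq(100, 195, 5))
  s3 <- make_methylome(pos3, n_meth = rep(c(0L, 15L), each = 20), n_total = 15)
  c3 <- make_methylome(pos3, n_meth = rep(c(15L, 0L), each = 20), n_total = 15)
  res3 <- call_dmrs(s3, c3, params, "CG", sizes)
  expect_equal(nrow(res3$dmrs), 2)
  expect_setequal(res3$dmrs$direction, c("hypo", "hyper"))

  # identical sample and control: warning, zero DMRs
  expect_warning(res4 <- call_dmrs(s, s, params, "CG", sizes), "identical")
  expect_equal(nrow(res4$dmrs), 0)

  expect_equal(glance(res)$n_dmrs, 1)
  expect_equal(tidy(res), res$dmrs)
})

test_that("raising the difference threshold never yields more DMRs", {
  ds <- small_ds()
  nuc <- nuclear_sizes(ds)
  n_prev <- Inf
  for (cut in c(0.2, 0.5, 0.7, 0.9)) {
    p <- dmr_params(min_abs_diff = c(CG = cut, CHG = 0.5, CHH = 0.1))
    n <- nrow(call_dmrs(ds$samples$T2, ds$samples$WT, p, "CG", nuc)$dmrs)
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("genome coverage and size summaries follow from interval arithmetic", {
  dmrs <- tibble::tibble(chrom = "chr1", start = c(0L, 500L),
                         end = c(100L, 800L))
  expect_equal(dmr_genome_coverage(dmrs, 372e6), 400 / 372e6)
  expect_equal(dmr_genome_coverage(dmrs[0, ], 1000), 0)
  expect_equal(dmr_genome_coverage(
    tibble::tibble(chrom = "c", start = 0L, end = 1000L), 1000), 1)
  overlapping <- tibble::tibble(chrom = "chr1", start = c(0L, 50L),
                                end = c(100L, 150L))
  expect_error(dmr_genome_coverage(overlapping, 1000), "overlap")

  h <- dmr_size_histogram(dmrs)
  expect_equal(h$size, c(100, 300))
  expect_equal(h$n, c(1L, 1L))
})

test_that("DMR BED export encodes context, direction and scaled difference", {
  d <- tibble::tibble(chrom = "chr1", start = 0L, end = 300L, context = "CG",
                      direction = "hypo", diff = -0.8)
  f <- withr::local_tempfile(fileext = ".bed")
  write_dmrs_bed(d, f)
  bed <- utils::read.table(f, sep = "\t")
  expect_equal(bed$V2, 0)
  expect_equal(bed$V4, "CG:hypo")
  expect_equal(bed$V5, 800)
})
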