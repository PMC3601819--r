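test_that("cytosine call files parse, filter, and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# comment header",
    "chr1\t100\t+\tCG\t3\t10",
    "chr1\t205\t-\tCHH\t0\t7"
  ), f)
  m <- read_cytosine_calls(f, sample_id = "toy", organelle_chroms = "chrPt")
  expect_equal(nrow(m), 2)
  # 1-based file position 100 becomes 0-based 99
  expect_equal(m$pos, c(99L, 204L))
  expect_equal(m$context, c("CG", "CHH"))
  expect_equal(m$n_meth, c(3L, 0L))
  expect_equal(sample_id(m), "toy")
  expect_equal(organelle_chroms(m), "chrPt")

  expect_equal(nrow(read_cytosine_calls(f, min_total = 8)), 1)
  expect_equal(nrow(read_cytosine_calls(f, min_total = 11)), 0)

  out <- withr::local_tempfile(fileext = ".tsv.gz")
  write_cytosine_calls(m, out)
  m2 <- read_cytosine_calls(out, sample_id = "toy", organelle_chroms = "chrPt")
  expect_equal(as.data.frame(m2), as.data.frame(m))
})

test_that("malformed call records are rejected with their line numbers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t100\t+\tCG\t3\t10", "chr1\t200\t+\tCG\t12\t10"), f)
  expect_error(read_cytosine_calls(f), "line 2")
  writeLines(c("chr1\t100\t+\tCG\t3"), f)
  expect_error(read_cytosine_calls(f), "6 tab-separated columns")
  expect_error(read_cytosine_calls(tempfile()), "not found")
})

test_that("context classification follows the trinucleotide rules on both strands", {
  expect_equal(classify_context(c(chr = "ACGT"), "chr", 1, "+"), "CG")
  expect_equal(classify_context(c(chr = "ACAGT"), "chr", 1, "+"), "CHG")
  expect_equal(classify_context(c(chr = "ACG"), "chr", 2, "-"), "CG")
  expect_equal(classify_context(c(chr = "ACTT"), "chr", 1, "+"), "CHH")
  # not a cytosine on the requested strand; N anywhere in the triplet
  expect_equal(classify_context(c(chr = "ACGT"), "chr", 0, "+"), "not_cytosine")
  expect_equal(classify_context(c(chr = "ACNT"), "chr", 1, "+"), "not_cytosine")
  expect_equal(classify_context(c(chr = "ACANT"), "chr", 1, "+"), "not_cytosine")
  # chromosome-end fallback
  expect_equal(classify_context(c(chr = "AAC"), "chr", 2, "+"), "CHH")
  expect_equal(classify_context(c(chr = "ACA"), "chr", 1, "+"), "CHH")
  expect_error(classify_context(c(chr = "ACGT"), "chr", 9, "+"), "range")
})

test_that("every cytosine of a random genome gets exactly one context", {
  set.seed(11)
  seq <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
               collapse = "")
  genome <- c(chrX = seq)
  sites <- find_cytosines(genome)
  expect_true(all(sites$context %in% c("CG", "CHG", "CHH")))
  # oracle: direct trinucleotide inspection, written independently
  b <- strsplit(seq, "")[[1]]
  n_c_plus <- sum(b == "C")
  n_c_minus <- sum(b == "G")
  expect_equal(nrow(sites), n_c_plus + n_c_minus)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  oracle <- function(pos, strand) {
    tri <- if (strand == "+") b[(pos + 1):min(pos + 3, length(b))] else
      rev(comp[b[max(1, pos - 1):(pos + 1)]])
    if (length(tri) < 2 || is.na(tri[2])) return("CHH")
    if (tri[2] == "G") return("CG")
    if (length(tri) < 3 || is.na(tri[3])) return("CHH")
    if (tri[3] == "G") "CHG" else "CHH"
  }
  idx <- sample(nrow(sites), 300)
  expect_equal(
    sites$context[idx],
    vapply(idx, function(i) oracle(sites$pos[i], sites$strand[i]), character(1))
  )
  # a palindromic CG dinucleotide carries one cytosine per strand
  cg <- find_cytosines(c(p = "ACGT"))
  expect_equal(sum(cg$context == "CG"), 2)
  expect_setequal(cg$strand[cg$context == "CG"], c("+", "-"))
})

test_that("fractional methylation distinguishes zero from undefined", {
  expect_equal(fractional_methylation(3, 10), 0.3)
  expect_equal(fractional_methylation(0, 7), 0)
  expect_true(is.na(fractional_methylation(5, 0)))
  expect_error(fractional_methylation(5, 4), "exceed")
})

test_that("feature extraction derives strand-aware promoters and gene parts", {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB", "gC", "teA"),
    chrom = "chr1",
    start = c(5000L, 20000L, 300L, 40000L),
    end = c(9000L, 26000L, 1300L, 42000L),
    strand = c("+", "-", "+", "+"),
    type = c("gene", "gene", "gene", "TE_gene")
  )
  exons <- tibble::tibble(
    gene_id = c("gA", "gA", "gA"),
    chrom = "chr1",
    start = c(5000L, 6500L, 8000L),
    end = c(6000L, 7000L, 9000L)
  )
  fs <- extract_features(genes, c(chr1 = 50000), exons = exons)
  prom <- function(g) fs[fs$feature_class == "promoter" & fs$gene_id == g, ]
  expect_equal(c(prom("gA")$start, prom("gA")$end), c(3000, 5000))
  expect_equal(c(prom("gB")$start, prom("gB")$end), c(26000, 28000))
  # truncated at the chromosome start
  expect_equal(c(prom("gC")$start, prom("gC")$end), c(0, 300))
  expect_equal(fs$feature_class[fs$gene_id == "teA"], "TE_gene")

  introns <- fs[fs$feature_class == "intron" & fs$gene_id == "gA", ]
  expect_equal(introns$start, c(6000, 7000))
  expect_equal(introns$end, c(6500, 8000))

  # promoter and gene body disjoint; CDS and intron inside the gene body
  body <- fs[fs$feature_class == "gene_body" & fs$gene_id == "gA", ]
  pa <- prom("gA")
  expect_true(pa$end <= body$start || pa$start >= body$end)
  parts <- fs[fs$feature_class %in% c("CDS", "intron") & fs$gene_id == "gA", ]
  expect_true(all(parts$start >= body$start & parts$end <= body$end))
})

test_that("GFF3 annotation imports into the gene/exon tables", {
  skip_if_not_installed("rtracklayer")
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1001\t4000\t.\t+\t.\tID=gA;biotype=protein_coding",
    "chr1\tsrc\tmRNA\t1001\t4000\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\tsrc\texon\t1001\t2000\t.\t+\t.\tID=gA.1.e1;Parent=gA.1",
    "chr1\tsrc\texon\t3001\t4000\t.\t+\t.\tID=gA.1.e2;Parent=gA.1",
    "chr1\tsrc\tgene\t9001\t10000\t.\t-\t.\tID=teB;biotype=transposable_element"
  ), f)
  ann <- read_annotation_gff3(f)
  expect_equal(ann$genes$gene_id, c("gA", "teB"))
  expect_equal(ann$genes$start, c(1000L, 9000L))   # converted to 0-based
  expect_equal(ann$genes$end, c(4000L, 10000L))
  expect_equal(ann$genes$type, c("gene", "TE_gene"))
  expect_equal(ann$exons$gene_id, c("gA", "gA"))
  expect_equal(ann$exons$start, c(1000L, 3000L))
  fs <- extract_features(ann$genes, c(chr1 = 20000), exons = ann$exons)
  expect_equal(fs$start[fs$feature_class == "intron"], 2000)
  expect_equal(fs$end[fs$feature_class == "intron"], 3000)
})
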