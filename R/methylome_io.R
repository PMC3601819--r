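#' Read per-cytosine methylation calls
#'
#' Reads a tab-separated per-cytosine call file into a tidy methylome table.
#' The file format is six columns — `chrom`, `pos` (1-based), `strand`
#' (`+`/`-`), `context` (`CG`/`CHG`/`CHH`), `n_meth` (#C), `n_total` (#C+#T) —
#' with optional `#`-prefixed comment lines; gzip-compressed files are read
#' transparently. Positions are converted to 0-based on read; all package
#' internals use 0-based half-open coordinates.
#'
#' @param path Path to the call file (optionally `.gz`).
#' @param min_total Minimum read coverage; sites with `n_total < min_total`
#'   are dropped. Default 0 keeps everything.
#' @param sample_id Sample label stored as the `sample_id` attribute;
#'   defaults to the file name without extension.
#' @param organelle_chroms Character vector of chromosome names to be treated
#'   as naturally unmethylated organelle controls (e.g. the chloroplast),
#'   stored as the `organelle_chroms` attribute.
#' @return A tibble with columns `chrom`, `pos` (0-based), `strand`,
#'   `context`, `n_meth`, `n_total`, carrying `sample_id` and
#'   `organelle_chroms` attributes.
#' @seealso [write_cytosine_calls()], [fractional_methylation()]
#' @export
read_cytosine_calls <- function(path, min_total = 0, sample_id = NULL,
                                organelle_chroms = character()) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("call file not found: %s", path))
  }
  stopifnot(min_total >= 0)
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    out <- tibble(
      chrom = character(), pos = integer(), strand = character(),
      context = character(), n_meth = integer(), n_total = integer()
    )
    return(as_methylome(out, sample_id %||% strip_ext(path), organelle_chroms))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L)) {
    bad <- line_no[nf != 6L]
    rlang::abort(sprintf(
      "expected 6 tab-separated columns; line(s) %s of %s malformed",
      paste(utils::head(bad, 5), collapse = ", "), path
    ))
  }
  m <- matrix(unlist(parts), ncol = 6, byrow = TRUE)
  pos1 <- suppressWarnings(as.integer(m[, 2]))
  n_meth <- suppressWarnings(as.integer(m[, 5]))
  n_total <- suppressWarnings(as.integer(m[, 6]))
  bad <- is.na(pos1) | is.na(n_meth) | is.na(n_total) | pos1 < 1L |
    n_meth < 0L | n_meth > n_total | !m[, 3] %in% c("+", "-") |
    !m[, 4] %in% CONTEXTS
  if (any(bad)) {
    rlang::abort(sprintf(
      "invalid record(s) at line %s of %s (check counts, strand, context)",
      paste(utils::head(line_no[bad], 5), collapse = ", "), path
    ))
  }
  out <- tibble(
    chrom = m[, 1], pos = pos1 - 1L, strand = m[, 3], context = m[, 4],
    n_meth = n_meth, n_total = n_total
  )
  out <- dplyr::filter(out, .data$n_total >= .env$min_total)
  as_methylome(out, sample_id %||% strip_ext(path), organelle_chroms)
}

strip_ext <- function(path) {
  sub("\\.(txt|tsv|cx)(\\.gz)?$", "", basename(path))
}

# internal constructor: attach sample metadata, check uniqueness invariant
as_methylome <- function(x, sample_id, organelle_chroms = character()) {
  check_columns(x, c("chrom", "pos", "strand", "context", "n_meth", "n_total"),
                "methylome")
  key <- (match(x$chrom, unique(x$chrom)) * 2 +
            (x$strand == "+")) * 2^31 + x$pos
  if (anyDuplicated(key)) {
    rlang::abort("duplicate (chrom, pos, strand) records in methylome")
  }
  attr(x, "sample_id") <- sample_id
  attr(x, "organelle_chroms") <- organelle_chroms
  x
}

#' @rdname read_cytosine_calls
#' @param calls A methylome tibble as returned by [read_cytosine_calls()].
#' @export
write_cytosine_calls <- function(calls, path) {
  check_columns(calls, c("chrom", "pos", "strand", "context", "n_meth", "n_total"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample=%s", attr(calls, "sample_id") %||% "NA"), con)
  utils::write.table(
    data.frame(calls$chrom, calls$pos + 1L, calls$strand, calls$context,
               calls$n_meth, calls$n_total),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Sample id and organelle chromosomes of a methylome table
#' @param calls A methylome tibble.
#' @return `sample_id()`: the sample label; `organelle_chroms()`: character
#'   vector of organelle (control) chromosome names.
#' @export
sample_id <- function(calls) attr(calls, "sample_id")

#' @rdname sample_id
#' @export
organelle_chroms <- function(calls) attr(calls, "organelle_chroms") %||% character()

#' Classify cytosine sequence context
#'
#' Determines the methylation context (CG, CHG or CHH, with H = A, T or C) of
#' positions in a genome, on either strand. For `-` strand sites the rule is
#' applied to the reverse complement. Positions that are not a cytosine on the
#' requested strand, or whose defining bases include an ambiguity code (N),
#' are classified `not_cytosine`. Cytosines too close to the chromosome end to
#' have a complete trinucleotide fall back to `CHH`.
#'
#' @param genome Named character vector of chromosome sequences
#'   (uppercase A/C/G/T/N), as returned by [read_genome_fasta()].
#' @param chrom,pos,strand Vectors (recycled to common length) giving the
#'   0-based position and strand of each query.
#' @return Character vector in `c("CG", "CHG", "CHH", "not_cytosine")`.
#' @examples
#' classify_context(c(chr = "ACGT"), "chr", 1, "+")
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(chrom, n); pos <- rep_len(as.integer(pos), n)
  strand <- rep_len(strand, n)
  out <- character(n)
  for (ch in unique(chrom)) {
    if (!ch %in% names(genome)) rlang::abort(sprintf("unknown chromosome: %s", ch))
    sel <- chrom == ch
    out[sel] <- classify_context_chrom(genome[[ch]], pos[sel], strand[sel])
  }
  out
}

# context of positions on one chromosome; vectorised over pos/strand
classify_context_chrom <- function(seq, pos, strand) {
  b <- utf8ToInt(seq)
  L <- length(b)
  if (any(pos < 0L | pos >= L)) rlang::abort("position out of chromosome range")
  C <- utf8ToInt("C"); G <- utf8ToInt("G")
  A <- utf8ToInt("A"); T_ <- utf8ToInt("T")
  is_h <- function(x) x %in% c(A, T_, C)          # H = A, T or C (+ strand)
  is_h_rc <- function(x) x %in% c(T_, A, G)       # complement is H
  out <- rep("not_cytosine", length(pos))
  p1 <- pos + 1L  # 1-based index

  plus <- strand == "+"
  idx <- which(plus & b[p1] == C)
  if (length(idx) > 0) {
    p <- p1[idx]
    n1 <- ifelse(p + 1L <= L, b[pmin(p + 1L, L)], NA_integer_)
    n2 <- ifelse(p + 2L <= L, b[pmin(p + 2L, L)], NA_integer_)
    res <- rep("CHH", length(idx))                 # chromosome-end fallback
    has1 <- !is.na(n1)
    res[has1 & n1 == G] <- "CG"
    mid <- has1 & is_h(n1)
    has2 <- mid & !is.na(n2)
    res[has2 & n2 == G] <- "CHG"
    res[has1 & !(n1 == G | is_h(n1))] <- "not_cytosine"       # N after C
    res[has2 & !(n2 == G | is_h(n2))] <- "not_cytosine"       # N at third base
    out[idx] <- res
  }
  minus <- strand == "-"
  idx <- which(minus & b[p1] == G)                 # C on the - strand
  if (length(idx) > 0) {
    p <- p1[idx]
    n1 <- ifelse(p - 1L >= 1L, b[pmax(p - 1L, 1L)], NA_integer_)
    n2 <- ifelse(p - 2L >= 1L, b[pmax(p - 2L, 1L)], NA_integer_)
    res <- rep("CHH", length(idx))
    has1 <- !is.na(n1)
    res[has1 & n1 == C] <- "CG"                    # complement of C is G
    mid <- has1 & is_h_rc(n1)
    has2 <- mid & !is.na(n2)
    res[has2 & n2 == C] <- "CHG"
    res[has1 & !(n1 == C | is_h_rc(n1))] <- "not_cytosine"
    res[has2 & !(n2 == C | is_h_rc(n2))] <- "not_cytosine"
    out[idx] <- res
  }
  out
}

#' Enumerate all cytosine sites of a genome
#'
#' Finds every cytosine on both strands and classifies its context; the
#' backbone site table used by the simulator.
#'
#' @inheritParams classify_context
#' @return Tibble with columns `chrom`, `pos` (0-based), `strand`, `context`,
#'   excluding `not_cytosine` sites.
#' @export
find_cytosines <- function(genome) {
  purrr::map_dfr(names(genome), function(ch) {
    b <- utf8ToInt(genome[[ch]])
    fwd <- which(b == utf8ToInt("C")) - 1L
    rev <- which(b == utf8ToInt("G")) - 1L
    res <- tibble(
      chrom = ch,
      pos = c(fwd, rev),
      strand = rep(c("+", "-"), c(length(fwd), length(rev)))
    )
    res$context <- classify_context_chrom(genome[[ch]], res$pos, res$strand)
    res <- dplyr::filter(res, .data$context != "not_cytosine")
    dplyr::arrange(res, .data$pos, .data$strand)
  })
}

#' Read / write genome FASTA
#'
#' Thin wrappers around Biostrings giving the named-character-vector genome
#' representation the rest of the package uses.
#'
#' @param path FASTA file path.
#' @return `read_genome_fasta()`: named character vector of uppercase
#'   sequences; `write_genome_fasta()`: the path, invisibly.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(ss)), names(ss))
}

#' @rdname read_genome_fasta
#' @param genome Named character vector of sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Derive genomic feature intervals from a gene annotation
#'
#' Expands a gene table into the feature classes used by the enrichment
#' analyses: `gene_body` (the transcribed region), `promoter` (the 2 kb
#' upstream of the TSS, strand-aware), `downstream3p` (the 2 kb downstream of
#' the TTS), `CDS` and `intron` (from the exon structure of protein-coding
#' genes), and `TE_gene` (transposable-element gene models). Promoter and
#' downstream intervals are truncated at chromosome edges.
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open transcribed region in forward coordinates), `strand`,
#'   `type` (`"gene"` or `"TE_gene"`).
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param exons Optional tibble (`gene_id`, `chrom`, `start`, `end`) of coding
#'   exons; introns are the gene-body complement of the exons.
#' @param flank_bp Promoter / downstream extent in bp (default 2000).
#' @return Tibble `chrom`, `start`, `end`, `strand`, `feature_class`,
#'   `gene_id`, one row per feature interval.
#' @export
extract_features <- function(genes, chrom_sizes, exons = NULL, flank_bp = 2000) {
  check_columns(genes, c("gene_id", "chrom", "start", "end", "strand", "type"))
  if (!all(genes$strand %in% c("+", "-"))) rlang::abort("invalid strand in annotation")
  if (any(genes$start >= genes$end)) rlang::abort("gene start must be < end")
  sz <- chrom_sizes[genes$chrom]
  if (any(is.na(sz)) || any(genes$end > sz)) {
    rlang::abort("gene coordinates outside chrom_sizes")
  }
  te <- dplyr::filter(genes, .data$type == "TE_gene")
  pc <- dplyr::filter(genes, .data$type != "TE_gene")

  feat <- list()
  feat$te <- tibble(
    chrom = te$chrom, start = te$start, end = te$end, strand = te$strand,
    feature_class = "TE_gene", gene_id = te$gene_id
  )
  feat$body <- tibble(
    chrom = pc$chrom, start = pc$start, end = pc$end, strand = pc$strand,
    feature_class = "gene_body", gene_id = pc$gene_id
  )
  up_start <- ifelse(pc$strand == "+", pc$start - flank_bp, pc$end)
  up_end <- ifelse(pc$strand == "+", pc$start, pc$end + flank_bp)
  feat$prom <- tibble(
    chrom = pc$chrom, start = up_start, end = up_end, strand = pc$strand,
    feature_class = "promoter", gene_id = pc$gene_id
  )
  dn_start <- ifelse(pc$strand == "+", pc$end, pc$start - flank_bp)
  dn_end <- ifelse(pc$strand == "+", pc$end + flank_bp, pc$start)
  feat$down <- tibble(
    chrom = pc$chrom, start = dn_start, end = dn_end, strand = pc$strand,
    feature_class = "downstream3p", gene_id = pc$gene_id
  )
  if (!is.null(exons) && nrow(exons) > 0) {
    check_columns(exons, c("gene_id", "chrom", "start", "end"))
    ex <- dplyr::inner_join(
      exons, dplyr::select(pc, "gene_id", gene_strand = "strand"), by = "gene_id"
    )
    feat$cds <- tibble(
      chrom = ex$chrom, start = ex$start, end = ex$end, strand = ex$gene_strand,
      feature_class = "CDS", gene_id = ex$gene_id
    )
    feat$intron <- intron_intervals(pc, exons)
  }
  out <- dplyr::bind_rows(feat)
  # truncate at chromosome edges, drop anything emptied by truncation
  out$start <- pmax(out$start, 0)
  out$end <- pmin(out$end, unname(chrom_sizes[out$chrom]))
  out <- dplyr::filter(out, .data$start < .data$end)
  dplyr::arrange(out, .data$chrom, .data$start, .data$feature_class)
}

#' Read gene and TE annotation from GFF3
#'
#' Imports `gene`/`mRNA`/`exon` records and returns the gene and exon
#' tibbles consumed by [extract_features()] (0-based half-open coordinates).
#' TE genes are recognised by a configurable attribute/value pair.
#'
#' @param path GFF3 file.
#' @param te_attribute,te_value Attribute name and regular expression
#'   flagging TE gene records (default: a `biotype` matching
#'   `"transposable|TE"`).
#' @return List with `genes` (`gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `type`) and `exons` (`gene_id`, `chrom`, `start`, `end`).
#' @export
read_annotation_gff3 <- function(path, te_attribute = "biotype",
                                 te_value = "transposable|TE") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    rlang::abort("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  is_gene <- md$type == "gene"
  te_flag <- if (te_attribute %in% names(md)) {
    !is.na(md[[te_attribute]]) & grepl(te_value, md[[te_attribute]])
  } else rep(FALSE, length(gr))
  genes <- tibble(
    gene_id = as.character(md$ID[is_gene]),
    chrom = as.character(GenomicRanges::seqnames(gr)[is_gene]),
    start = GenomicRanges::start(gr)[is_gene] - 1L,
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr)[is_gene]),
    type = ifelse(te_flag[is_gene], "TE_gene", "gene")
  )
  is_exon <- md$type == "exon"
  parent <- as.character(S4Vectors::unstrsplit(md$Parent[is_exon]))
  # exon Parent is usually the mRNA; map transcripts back to their gene
  is_mrna <- md$type == "mRNA"
  tx2gene <- setNames(as.character(S4Vectors::unstrsplit(md$Parent[is_mrna])),
                      as.character(md$ID[is_mrna]))
  gene_of <- ifelse(parent %in% names(tx2gene), tx2gene[parent], parent)
  exons <- tibble(
    gene_id = unname(gene_of),
    chrom = as.character(GenomicRanges::seqnames(gr)[is_exon]),
    start = GenomicRanges::start(gr)[is_exon] - 1L,
    end = GenomicRanges::end(gr)[is_exon]
  )
  list(genes = genes, exons = dplyr::filter(exons, .data$gene_id %in% genes$gene_id))
}

# gene-body complement of the exons, per gene
intron_intervals <- function(pc, exons) {
  ex_split <- split(exons, exons$gene_id)
  purrr::map_dfr(seq_len(nrow(pc)), function(i) {
    g <- pc[i, ]
    ex <- ex_split[[g$gene_id]]
    if (is.null(ex) || nrow(ex) < 2) return(NULL)
    ex <- dplyr::arrange(ex, .data$start)
    tibble(
      chrom = g$chrom,
      start = utils::head(ex$end, -1),
      end = utils::tail(ex$start, -1),
      strand = g$strand, feature_class = "intron", gene_id = g$gene_id
    ) |> dplyr::filter(.data$start < .data$end)
  })
}
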