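rand_contig <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

as_dss <- function(s, name = "chr1") {
  g <- Biostrings::DNAStringSet(s)
  names(g) <- name
  g
}

test_that("GTF parsing keeps deduplicated protein-coding exons with strand", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t10\t50\t.\t+\t.\tgene_id "A"; transcript_id "A1"; gene_type "protein_coding";',
    'chr1\tsrc\texon\t10\t50\t.\t+\t.\tgene_id "A"; transcript_id "A2"; gene_type "protein_coding";',
    'chr1\tsrc\texon\t100\t160\t.\t-\t.\tgene_id "B"; transcript_id "B1"; gene_type "protein_coding";',
    'chr1\tsrc\texon\t200\t260\t.\t+\t.\tgene_id "L"; transcript_id "L1"; gene_type "lncRNA";'
  ), gtf)
  ex <- parse_protein_coding_exons(gtf)
  expect_equal(nrow(ex), 2L)  # shared exon collapsed, lncRNA dropped
  expect_setequal(ex$gene_id, c("A", "B"))
  expect_identical(ex$strand[ex$gene_id == "B"], "-")
  ex2 <- parse_protein_coding_exons(gtf, dedup = FALSE)
  expect_equal(sum(ex2$gene_id == "A"), 2L)
})

test_that("plus-strand boundary windows are hand-indexed around the anchor", {
  contig <- rand_contig(60, seed = 11)
  genome <- as_dss(contig)
  exons <- data.frame(chrom = "chr1", start = 10L, end = 20L, strand = "+",
                      gene_id = "g", transcript_id = "t", gene_type = "protein_coding")
  ds <- extract_boundary_dataset(genome, exons, flank = 5L, kind = "dataset_I",
                                 internal_only = FALSE)
  # anchor is the exon-end base; bases 15..25, position 0 = base 20
  expect_equal(ds$seq, substr(contig, 15, 25))
  expect_equal(nchar(ds$seq), 11L)
  expect_equal(ds$anchor, 20L)
  ds2 <- extract_boundary_dataset(genome, exons, flank = 5L, kind = "dataset_II",
                                  internal_only = FALSE)
  expect_equal(ds2$seq, substr(contig, 5, 15))  # anchored at exon start
})

test_that("minus-strand windows read 5'->3' in gene orientation", {
  contig <- rand_contig(60, seed = 12)
  genome <- as_dss(contig)
  exons <- data.frame(chrom = "chr1", start = 30L, end = 45L, strand = "-",
                      gene_id = "g", transcript_id = "t", gene_type = "protein_coding")
  # on '-', the exon's last transcribed base is the genomic start
  ds <- extract_boundary_dataset(genome, exons, flank = 5L, kind = "dataset_I",
                                 internal_only = FALSE)
  expect_equal(ds$anchor, 30L)
  expect_equal(ds$seq, revcomp(substr(contig, 25, 35)))
  # naive mode ignores strand entirely
  ds_naive <- extract_boundary_dataset(genome, exons, flank = 5L,
                                       kind = "dataset_I", stranded = FALSE,
                                       internal_only = FALSE)
  expect_equal(ds_naive$anchor, 45L)
  expect_equal(ds_naive$seq, substr(contig, 40, 50))
})

test_that("control windows are centred in long exons, short exons excluded", {
  contig <- rand_contig(3000, seed = 13)
  genome <- as_dss(contig)
  exons <- data.frame(chrom = "chr1",
                      start = c(100L, 1500L), end = c(1098L, 2500L),
                      strand = "+", gene_id = c("short", "long"),
                      transcript_id = c("s1", "l1"),
                      gene_type = "protein_coding")
  ds <- extract_control_dataset(genome, exons, min_exon_length = 1000L,
                                window_length = 401L)
  expect_equal(nrow(ds), 1L)  # the 999-nt exon fails the > 1000 filter
  expect_equal(ds$anchor, 2000L)  # 501st base of a 1001-nt exon
  expect_equal(nchar(ds$seq), 401L)
  expect_equal(ds$seq, substr(contig, 1800, 2200))
  expect_error(extract_control_dataset(genome, exons, min_exon_length = 400L,
                                       window_length = 401L),
               class = "splicescape_invalid_input")
})

test_that("windows falling off the contig are skipped and counted", {
  contig <- rand_contig(100, seed = 14)
  genome <- as_dss(contig)
  exons <- data.frame(chrom = "chr1", start = c(2L, 40L), end = c(8L, 60L),
                      strand = "+", gene_id = c("edge", "mid"),
                      transcript_id = c("e1", "m1"),
                      gene_type = "protein_coding")
  ds <- extract_boundary_dataset(genome, exons, flank = 10L,
                                 kind = "dataset_II", internal_only = FALSE)
  skipped <- attr(ds, "skipped")
  expect_equal(nrow(ds) + unname(skipped["n_skipped"]), nrow(exons))
  expect_equal(unname(skipped["contig_edge"]), 1)
})

test_that("FASTA/BED persistence round-trips and the BED re-extracts the FASTA", {
  tg <- make_toy_genome(seed = 3)
  ex <- parse_protein_coding_exons(tg$gtf)
  ds <- extract_boundary_dataset(tg$genome, ex, flank = 15L, kind = "dataset_I")
  fa <- withr::local_tempfile(fileext = ".fa")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_dataset(ds, fa, bed)
  back <- read_dataset(fa)
  expect_identical(back$seq, ds$seq)
  expect_identical(back$kind, ds$kind)
  expect_identical(back$flank, ds$flank)
  expect_identical(back$anchor, ds$anchor)
  expect_identical(back$strand, ds$strand)
  gr <- rtracklayer::import(bed)
  expect_true(all(GenomicRanges::width(gr) == 31L))
  # re-extracting the BED intervals reproduces the FASTA byte-exactly
  again <- as.character(Biostrings::DNAStringSet(
    tg$genome[[1]], start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)))
  neg <- as.character(GenomicRanges::strand(gr)) == "-"
  again[neg] <- revcomp(again[neg])
  m <- match(S4Vectors::mcols(gr)$name, ds$id)
  expect_identical(unname(again), ds$seq[m])
  # plain FASTA without metadata needs the kind supplied
  plain <- withr::local_tempfile(fileext = ".fa")
  x <- Biostrings::DNAStringSet(ds$seq)
  names(x) <- sprintf("seq%d", seq_along(x))
  Biostrings::writeXStringSet(x, plain)
  expect_error(read_dataset(plain), class = "splicescape_header_dialect")
  rd <- read_dataset(plain, kind = "dataset_I")
  expect_identical(rd$kind, rep("dataset_I", nrow(ds)))
  expect_identical(rd$flank, rep(15L, nrow(ds)))
})

test_that("transcript-terminal boundaries are excluded unless asked for", {
  tg <- make_toy_genome(seed = 4)
  ex <- parse_protein_coding_exons(tg$gtf)
  internal <- extract_boundary_dataset(tg$genome, ex, flank = 15L,
                                       kind = "dataset_I")
  all_b <- extract_boundary_dataset(tg$genome, ex, flank = 15L,
                                    kind = "dataset_I", internal_only = FALSE)
  # 3 exons/transcript: 2 internal exon-ends, plus 1 terminal when included
  expect_equal(nrow(internal), 4L)
  expect_equal(nrow(all_b), 6L)
})
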