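#' Build a small annotated toy genome with known junction truth
#'
#' Constructs a single-contig genome carrying multi-exon protein-coding
#' genes on both strands (introns bounded by GT..AG in gene orientation)
#' plus one single-exon lncRNA used to exercise biotype filtering. Each
#' gene's sequence is assembled 5'->3' in gene orientation and the truth
#' windows around every internal exon boundary are recorded from that
#' construction, independently of any coordinate arithmetic — extraction
#' from the emitted FASTA/GTF must reproduce them byte-exactly.
#'
#' @param dir output directory for `toy_genome.fa` and `toy_genome.gtf`
#'   (default a fresh temporary directory).
#' @param flank half-width of the recorded truth windows (default 15).
#' @param n_genes number of protein-coding genes, alternating +/- strand.
#' @param exons_per_gene exons per gene (default 3, giving 2 internal
#'   boundaries per gene).
#' @param exon_length,intron_length,pad segment sizes in nucleotides; all
#'   must be at least `flank` so truth windows stay inside the contig.
#' @param seed integer seed.
#' @return list with `fasta`, `gtf` (paths), `genome`
#'   ([Biostrings::DNAStringSet]), `exons` (the annotation as a
#'   data.frame) and `truth` (data.frame: `gene_id`, `strand`, `kind`,
#'   `anchor` genomic coordinate, `window` sequence in gene orientation).
#' @export
make_toy_genome <- function(dir = tempfile("toygenome"), flank = 15L,
                            n_genes = 2L, exons_per_gene = 3L,
                            exon_length = 60L, intron_length = 70L,
                            pad = 80L, seed = 1L) {
  flank <- as.integer(flank)
  stopifnot(exons_per_gene >= 2L, exon_length >= flank, intron_length >= flank,
            pad >= flank)
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  contig_parts <- character(0)
  gtf_lines <- character(0)
  truth <- list()
  exon_rows <- list()
  offset <- 0L  # genomic length emitted so far
  rand_seq <- function(len) paste(sample(BASES, len, replace = TRUE),
                                  collapse = "")
  for (g in seq_len(n_genes)) {
    strand <- if (g %% 2L == 1L) "+" else "-"
    gene_id <- sprintf("G%d", g)
    exons <- replicate(exons_per_gene, rand_seq(exon_length))
    introns <- replicate(exons_per_gene - 1L, {
      body <- rand_seq(intron_length)
      paste0("GT", substr(body, 3L, intron_length - 2L), "AG")
    })
    # gene block in gene orientation: pad | e1 i1 e2 ... eN | pad
    pieces <- c(rand_seq(pad),
                as.vector(rbind(exons, c(introns, "")))[seq_len(2L * exons_per_gene - 1L)],
                rand_seq(pad))
    block <- paste(pieces, collapse = "")
    block_len <- nchar(block)
    # exon offsets within the block (1-based, gene orientation)
    e_start <- pad + 1L + (seq_len(exons_per_gene) - 1L) *
      (exon_length + intron_length)
    e_end <- e_start + exon_length - 1L
    # truth windows around internal boundaries, from the block itself
    for (i in seq_len(exons_per_gene)) {
      if (i < exons_per_gene) {  # exon end -> intron (dataset_I anchor)
        b <- e_end[i]
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = gene_id, strand = strand, kind = "dataset_I",
          block_pos = b, window = substr(block, b - flank, b + flank))
      }
      if (i > 1L) {  # intron -> exon start (dataset_II anchor)
        b <- e_start[i]
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = gene_id, strand = strand, kind = "dataset_II",
          block_pos = b, window = substr(block, b - flank, b + flank))
      }
    }
    # place the block on the contig
    genomic_block <- if (strand == "+") block else revcomp(block)
    contig_parts <- c(contig_parts, genomic_block)
    block_start <- offset + 1L
    offset <- offset + block_len
    # genomic coordinates of exons and anchors
    to_genomic <- function(p) {
      if (strand == "+") block_start + p - 1L else block_start + block_len - p
    }
    for (i in seq_len(exons_per_gene)) {
      gs <- sort(c(to_genomic(e_start[i]), to_genomic(e_end[i])))
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        chrom = "chrT", start = gs[1], end = gs[2], strand = strand,
        gene_id = gene_id, transcript_id = paste0(gene_id, "T1"),
        gene_type = "protein_coding")
    }
    k <- vapply(truth, function(t) t$gene_id == gene_id, logical(1))
    for (j in which(k)) {
      if (is.null(truth[[j]]$anchor)) {
        truth[[j]]$anchor <- to_genomic(truth[[j]]$block_pos)
      }
    }
    tx_range <- range(unlist(lapply(exon_rows[k <- vapply(
      exon_rows, function(e) e$gene_id == gene_id, logical(1))],
      function(e) c(e$start, e$end))))
    for (feat in c("gene", "transcript")) {
      gtf_lines <- c(gtf_lines, sprintf(
        'chrT\ttoy\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%sT1"; gene_type "protein_coding";',
        feat, tx_range[1], tx_range[2], strand, gene_id, gene_id))
    }
  }
  # one lncRNA exon to exercise biotype filtering
  lnc <- rand_seq(2L * flank + 21L)
  contig_parts <- c(contig_parts, lnc)
  lnc_start <- offset + 11L
  lnc_end <- offset + nchar(lnc) - 10L
  offset <- offset + nchar(lnc)
  gtf_lines <- c(gtf_lines, sprintf(
    'chrT\ttoy\texon\t%d\t%d\t.\t+\t.\tgene_id "LNC1"; transcript_id "LNC1T1"; gene_type "lncRNA";',
    lnc_start, lnc_end))
  exons <- do.call(rbind, exon_rows)
  for (e in seq_len(nrow(exons))) {
    gtf_lines <- c(gtf_lines, sprintf(
      'chrT\ttoy\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_type "protein_coding";',
      exons$start[e], exons$end[e], exons$strand[e], exons$gene_id[e],
      exons$transcript_id[e]))
  }
  genome <- Biostrings::DNAStringSet(paste(contig_parts, collapse = ""))
  names(genome) <- "chrT"
  fasta <- file.path(dir, "toy_genome.fa")
  gtf <- file.path(dir, "toy_genome.gtf")
  Biostrings::writeXStringSet(genome, fasta)
  writeLines(gtf_lines, gtf)
  truth_df <- do.call(rbind, truth)
  truth_df$flank <- flank
  truth_df <- truth_df[order(truth_df$kind, truth_df$gene_id,
                             truth_df$block_pos), ]
  rownames(truth_df) <- NULL
  list(fasta = fasta, gtf = gtf, genome = genome, exons = exons,
       truth = truth_df)
}
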