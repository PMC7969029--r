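#' Parse protein-coding exons from a GTF annotation
#'
#' Reads a GENCODE-dialect GTF via [rtracklayer::import()] and keeps exon
#' features of protein-coding genes (attribute `gene_type` or
#' `gene_biotype`). Records lacking a biotype attribute are excluded with a
#' warning.
#'
#' @param annotation_file path to a GTF file.
#' @param dedup if `TRUE` (default), deduplicate on
#'   (chrom, start, end, strand); transcript-level duplicates of shared
#'   exons then collapse to one record.
#' @return data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `strand`, `gene_id`, `transcript_id`, `gene_type`.
#' @export
parse_protein_coding_exons <- function(annotation_file, dedup = TRUE) {
  gr <- rtracklayer::import(annotation_file, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  gr <- gr[!is.na(mc$type) & mc$type == "exon"]
  mc <- S4Vectors::mcols(gr)
  biotype <- if ("gene_type" %in% names(mc)) {
    mc$gene_type
  } else if ("gene_biotype" %in% names(mc)) {
    mc$gene_biotype
  } else {
    rep(NA_character_, length(gr))
  }
  if (anyNA(biotype)) {
    ss_warn(sprintf("%d exon record(s) lack a gene_type/gene_biotype attribute and are excluded",
                    sum(is.na(biotype))), "missing_biotype")
  }
  keep <- !is.na(biotype) & biotype == "protein_coding"
  gr <- gr[keep]
  mc <- S4Vectors::mcols(gr)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = if ("gene_id" %in% names(mc)) as.character(mc$gene_id) else NA_character_,
    transcript_id = if ("transcript_id" %in% names(mc)) as.character(mc$transcript_id) else NA_character_,
    gene_type = as.character(biotype[keep]),
    stringsAsFactors = FALSE
  )
  if (any(out$strand %in% c("*", "?"))) {
    ss_warn("exon record(s) without strand excluded", "missing_strand")
    out <- out[!out$strand %in% c("*", "?"), , drop = FALSE]
  }
  if (dedup) {
    out <- out[!duplicated(out[c("chrom", "start", "end", "strand")]), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  stopifnot(inherits(genome, "DNAStringSet"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

new_boundary_dataset <- function(id, kind, seq, flank, chrom, anchor, strand) {
  data.frame(id = id, kind = kind, seq = seq, flank = flank,
             chrom = chrom, anchor = anchor, strand = strand,
             stringsAsFactors = FALSE)
}

# Strand-aware window extraction around 1-based genomic anchors. Windows
# falling off a contig are skipped and counted; the skip tally is returned
# in attr(, "skipped").
extract_windows <- function(genome, chrom, anchor, strand, flank, kind, ids,
                            stranded = TRUE) {
  genome <- as_genome(genome)
  n <- length(anchor)
  seqs <- character(n)
  ok <- logical(n)
  reasons <- character(0)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (!ch %in% names(genome)) {
      reasons <- c(reasons, rep("unknown_contig", length(idx)))
      next
    }
    contig <- genome[[ch]]
    st <- anchor[idx] - flank
    en <- anchor[idx] + flank
    good <- st >= 1L & en <= length(contig)
    if (any(!good)) reasons <- c(reasons, rep("contig_edge", sum(!good)))
    gi <- idx[good]
    if (length(gi) > 0L) {
      v <- Biostrings::DNAStringSet(contig,
                                    start = anchor[gi] - flank,
                                    end = anchor[gi] + flank)
      if (stranded) {
        neg <- strand[gi] == "-"
        if (any(neg)) v[neg] <- Biostrings::reverseComplement(v[neg])
      }
      seqs[gi] <- as.character(v)
      ok[gi] <- TRUE
    }
  }
  flagged <- ok & grepl("[^ACGTN]", seqs)
  ds <- new_boundary_dataset(ids[ok], kind, seqs[ok], flank,
                             chrom[ok], anchor[ok], strand[ok])
  ds$flagged <- flagged[ok]
  attr(ds, "skipped") <- c(n_skipped = sum(!ok),
                           table(factor(reasons, levels = c("unknown_contig", "contig_edge"))))
  ds
}

# Drop transcript-terminal boundaries: for kind I the last exon of each
# transcript has no downstream intron; for kind II the first exon has no
# upstream intron. Terminal status is judged in transcription order.
drop_terminal_boundaries <- function(exons, kind) {
  if (!all(c("transcript_id") %in% names(exons)) || all(is.na(exons$transcript_id))) {
    return(exons)
  }
  keep <- rep(TRUE, nrow(exons))
  for (tx in unique(exons$transcript_id)) {
    i <- which(exons$transcript_id == tx)
    if (length(i) < 2L) { keep[i] <- FALSE; next }
    plus <- exons$strand[i[1]] == "+"
    if (kind == "dataset_I") {
      terminal <- if (plus) i[which.max(exons$end[i])] else i[which.min(exons$start[i])]
    } else {
      terminal <- if (plus) i[which.min(exons$start[i])] else i[which.max(exons$end[i])]
    }
    keep[terminal] <- FALSE
  }
  exons[keep, , drop = FALSE]
}

#' Extract boundary windows around exon starts or ends
#'
#' Builds fixed-width windows of `2 * flank + 1` nucleotides centred on
#' exon-end anchors (`dataset_I`: exon occupies positions -flank..0, the
#' downstream intron +1..+flank) or exon-start anchors (`dataset_II`:
#' upstream intron -flank..-1, exon 0..+flank). Extraction is strand-aware
#' by default: for minus-strand genes the genomic window is
#' reverse-complemented so every sequence reads 5'->3' in gene orientation
#' and splice dinucleotides appear as GT/AG.
#'
#' @param genome a [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param exons exon records as from [parse_protein_coding_exons()].
#' @param flank half-width in nucleotides (default 200, i.e. 401-nt windows).
#' @param kind `"dataset_I"` (exon to intron) or `"dataset_II"` (intron to
#'   exon).
#' @param stranded `FALSE` reproduces naive reference-strand extraction.
#' @param internal_only if `TRUE` (default) boundaries without an adjacent
#'   intron (transcript-terminal exon ends/starts) are dropped before
#'   anchor deduplication; requires `transcript_id` in `exons`.
#' @return A boundary dataset data.frame (`id`, `kind`, `seq`, `flank`,
#'   `chrom`, `anchor`, `strand`, `flagged`); skipped-window counts are in
#'   `attr(, "skipped")`.
#' @export
extract_boundary_dataset <- function(genome, exons, flank = 200L,
                                     kind = c("dataset_I", "dataset_II"),
                                     stranded = TRUE, internal_only = TRUE) {
  kind <- match.arg(kind)
  stopifnot(flank >= 1L)
  if (internal_only) exons <- drop_terminal_boundaries(exons, kind)
  if (nrow(exons) == 0L) ss_stop("no exons left to extract from", "invalid_input")
  anchor <- if (kind == "dataset_I") {
    if (stranded) ifelse(exons$strand == "+", exons$end, exons$start) else exons$end
  } else {
    if (stranded) ifelse(exons$strand == "+", exons$start, exons$end) else exons$start
  }
  dup <- duplicated(data.frame(exons$chrom, anchor, exons$strand))
  exons <- exons[!dup, , drop = FALSE]
  anchor <- anchor[!dup]
  ids <- sprintf("%s_%s_%s:%d:%s", kind, exons$gene_id, exons$chrom, anchor,
                 exons$strand)
  extract_windows(genome, exons$chrom, anchor, exons$strand, flank, kind, ids,
                  stranded = stranded)
}

#' Extract exon-interior control windows
#'
#' One window per exon longer than `min_exon_length`, centred on the exon
#' midpoint (gene-orientation midpoint for minus-strand exons), mirroring a
#' coding-sequence control set: same width as the boundary windows but far
#' from any splice site.
#'
#' @inheritParams extract_boundary_dataset
#' @param min_exon_length exons must be strictly longer than this (default
#'   1000).
#' @param window_length odd window width (default 401).
#' @return A boundary dataset data.frame of kind `"control"`.
#' @export
extract_control_dataset <- function(genome, exons, min_exon_length = 1000L,
                                    window_length = 401L, stranded = TRUE) {
  if (window_length %% 2L != 1L) ss_stop("window_length must be odd", "invalid_input")
  if (min_exon_length <= window_length) {
    ss_stop("min_exon_length must exceed window_length", "invalid_input")
  }
  len <- exons$end - exons$start + 1L
  exons <- exons[len > min_exon_length, , drop = FALSE]
  if (nrow(exons) == 0L) ss_stop("no exons longer than min_exon_length", "invalid_input")
  dup <- duplicated(exons[c("chrom", "start", "end", "strand")])
  exons <- exons[!dup, , drop = FALSE]
  half <- (window_length - 1L) %/% 2L
  mid_off <- (exons$end - exons$start) %/% 2L
  anchor <- ifelse(exons$strand == "+" | !stranded,
                   exons$start + mid_off, exons$end - mid_off)
  ids <- sprintf("control_%s_%s:%d:%s", exons$gene_id, exons$chrom, anchor,
                 exons$strand)
  extract_windows(genome, exons$chrom, anchor, exons$strand, half, "control",
                  ids, stranded = stranded)
}

#' Persist and reload boundary datasets
#'
#' FASTA headers use the dialect `id|kind|flank|chrom:anchor:strand`
#' (`origin` is the literal `synthetic` for simulated records). An optional
#' companion BED6 file records the genomic source intervals (0-based
#' half-open, width `2*flank+1`) for genome-derived records.
#'
#' @param dataset a boundary dataset data.frame.
#' @param fasta output FASTA path.
#' @param bed optional output BED path.
#' @return `write_dataset()` returns the FASTA path invisibly;
#'   `read_dataset()` returns a boundary dataset data.frame.
#' @export
write_dataset <- function(dataset, fasta, bed = NULL) {
  origin <- ifelse(is.na(dataset$chrom), "synthetic",
                   sprintf("%s:%d:%s", dataset$chrom, dataset$anchor,
                           dataset$strand))
  headers <- sprintf("%s|%s|%d|%s", dataset$id, dataset$kind, dataset$flank,
                     origin)
  x <- Biostrings::DNAStringSet(dataset$seq)
  names(x) <- headers
  Biostrings::writeXStringSet(x, fasta)
  if (!is.null(bed)) {
    g <- dataset[!is.na(dataset$chrom), , drop = FALSE]
    if (nrow(g) > 0L) {
      gr <- GenomicRanges::GRanges(
        seqnames = g$chrom,
        ranges = IRanges::IRanges(start = g$anchor - g$flank,
                                  end = g$anchor + g$flank),
        strand = g$strand)
      S4Vectors::mcols(gr)$name <- g$id
      S4Vectors::mcols(gr)$score <- 0L
      rtracklayer::export(gr, bed, format = "bed")
    }
  }
  invisible(fasta)
}

#' @rdname write_dataset
#' @param kind dataset kind to assume when reading a plain FASTA whose
#'   headers do not carry the metadata dialect.
#' @export
read_dataset <- function(fasta, kind = NULL) {
  x <- Biostrings::readDNAStringSet(fasta)
  headers <- names(x)
  seqs <- as.character(x)
  has_meta <- grepl("\\|", headers)
  if (all(has_meta)) {
    parts <- strsplit(headers, "|", fixed = TRUE)
    bad <- lengths(parts) != 4L
    if (any(bad)) ss_stop("FASTA header(s) not matching the dataset dialect",
                          "header_dialect")
    id <- vapply(parts, `[[`, "", 1L)
    knd <- vapply(parts, `[[`, "", 2L)
    flank <- as.integer(vapply(parts, `[[`, "", 3L))
    origin <- vapply(parts, `[[`, "", 4L)
    op <- strsplit(origin, ":", fixed = TRUE)
    synth <- origin == "synthetic"
    chrom <- ifelse(synth, NA_character_, vapply(op, `[`, "", 1L))
    anchor <- ifelse(synth, NA_integer_,
                     suppressWarnings(as.integer(vapply(op, `[`, "", 2L))))
    strand <- ifelse(synth, NA_character_, vapply(op, `[`, "", 3L))
  } else {
    if (is.null(kind)) {
      ss_stop("plain FASTA without metadata headers: supply kind=", "header_dialect")
    }
    id <- headers
    knd <- kind
    flank <- (nchar(seqs) - 1L) %/% 2L
    chrom <- NA_character_
    anchor <- NA_integer_
    strand <- NA_character_
  }
  new_boundary_dataset(id, knd, seqs, flank, chrom, anchor, strand)
}
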