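BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Canonical dinucleotide step labels
#'
#' The 16 dinucleotides collapse into 10 reverse-complement equivalence
#' classes, because a duplex step read 5'->3' on one strand is the reverse
#' complement step read 5'->3' on the other. Structural and energetic
#' parameters of duplex DNA are properties of the step, not the strand, so
#' lookup tables are keyed by these 10 canonical labels.
#'
#' @return Character vector of the 10 canonical labels, alphabetically the
#'   smaller member of each reverse-complement pair.
#' @export
#' @examples
#' canonical_steps()
canonical_steps <- function() {
  c("AA", "AC", "AG", "AT", "CA", "CC", "CG", "GA", "GC", "TA")
}

#' All 16 dinucleotides in lexicographic order
#' @return Character vector of length 16.
#' @export
all_dinucleotides <- function() {
  paste0(rep(BASES, each = 4L), rep(BASES, times = 4L))
}

#' Reverse complement of plain character sequences
#'
#' Small strand-flip helper for character vectors over A/C/G/T/N; heavier
#' lifting on whole contigs goes through [Biostrings::reverseComplement()].
#'
#' @param x character vector of sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  flipped <- chartr("ACGTN", "TGCAN", toupper(x))
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Map a dinucleotide to its canonical step class
#'
#' `canonical_step(d)` equals `canonical_step(reverse_complement(d))` for
#' every dinucleotide, and is the identity on the 10 canonical labels.
#'
#' @param dinuc character vector of 2-letter strings over A/C/G/T.
#' @return character vector of canonical class labels.
#' @export
#' @examples
#' canonical_step("TT")  # "AA"
#' canonical_step("AT")  # palindromic step is its own class
canonical_step <- function(dinuc) {
  d <- toupper(as.character(dinuc))
  bad <- !grepl("^[ACGT]{2}$", d)
  if (any(bad)) {
    ss_stop(sprintf("invalid dinucleotide(s) outside the A/C/G/T alphabet: %s",
                    paste(unique(d[bad]), collapse = ", ")),
            "invalid_alphabet")
  }
  rc <- paste0(COMPLEMENT[substring(d, 2L, 2L)], COMPLEMENT[substring(d, 1L, 1L)])
  unname(pmin(d, rc))
}

#' Dinucleotide step classes
#'
#' @return Named list: canonical label -> member dinucleotides (reverse
#'   complement closed; palindromic steps have a single member).
#' @export
dinucleotide_classes <- function() {
  dn <- all_dinucleotides()
  split(dn, canonical_step(dn))
}

# Expand a 10-class value vector to all 16 dinucleotides (named, lexicographic).
expand_step_values <- function(v10) {
  dn <- all_dinucleotides()
  out <- v10[canonical_step(dn)]
  names(out) <- dn
  out
}
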