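range_to_positions <- function(range) {
  stopifnot(length(range) == 2L, range[1] <= range[2])
  seq.int(as.integer(range[1]), as.integer(range[2]))
}

#' Position-wise base frequencies around the junction
#'
#' Counts A/C/G/T at each signed position of a boundary dataset over the
#' requested range; ambiguous bases (N) are excluded from the denominator
#' and tallied in `excluded`.
#'
#' @param dataset a boundary dataset data.frame (or character vector of
#'   equal-length windows, in which case the flank is inferred).
#' @param range integer vector `c(from, to)` of signed positions
#'   (default `c(-30, 30)`).
#' @return data.frame of class `freq_matrix`: `position`, `A`, `C`, `G`,
#'   `T`, `excluded`, `n` (total sequences). Frequencies at each position
#'   sum to 1 over the counted bases.
#' @export
position_frequencies <- function(dataset, range = c(-30L, 30L)) {
  if (is.character(dataset)) {
    flank <- (nchar(dataset[1]) - 1L) %/% 2L
    seqs <- toupper(dataset)
  } else {
    flank <- dataset$flank[1]
    seqs <- toupper(dataset$seq)
  }
  check_alphabet(seqs)
  pos <- range_to_positions(range)
  if (min(pos) < -flank || max(pos) > flank) {
    ss_stop(sprintf("requested range %d..%d outside window coverage -%d..+%d",
                    min(pos), max(pos), flank, flank), "coverage")
  }
  n <- length(seqs)
  cols <- pos + flank + 1L
  out <- data.frame(position = pos, A = 0, C = 0, G = 0, T = 0,
                    excluded = 0L, n = n)
  for (i in seq_along(pos)) {
    ch <- substring(seqs, cols[i], cols[i])
    counts <- table(factor(ch, levels = c(BASES, "N")))
    counted <- sum(counts[BASES])
    out$excluded[i] <- n - counted
    if (counted > 0L) {
      out[i, BASES] <- as.numeric(counts[BASES]) / counted
    } else {
      out[i, BASES] <- NA_real_
    }
  }
  class(out) <- c("freq_matrix", "data.frame")
  out
}

#' Information content per position
#'
#' Logo-style column heights: `IC(p) = 2 - H(p)` bits, where `H` is the
#' Shannon entropy of the base distribution at position `p`. The optional
#' small-sample correction subtracts `e(n) = 3 / (2 * ln(2) * n)` with `n`
#' the number of counted (non-ambiguous) bases.
#'
#' @param freq a `freq_matrix` from [position_frequencies()].
#' @param correction apply the small-sample correction (default `FALSE`;
#'   intended sample sizes are large).
#' @return data.frame `position`, `ic` (bits; `NA` for zero-coverage
#'   positions).
#' @export
information_content <- function(freq, correction = FALSE) {
  f <- as.matrix(freq[, BASES])
  h <- apply(f, 1L, function(p) {
    if (anyNA(p)) return(NA_real_)
    nz <- p[p > 0]
    -sum(nz * log2(nz))
  })
  ic <- 2 - h
  if (correction) {
    n_eff <- freq$n - freq$excluded
    ic <- ic - 3 / (2 * log(2) * n_eff)
  }
  data.frame(position = freq$position, ic = ic)
}

IUPAC_PAIRS <- c(AC = "m", AG = "r", AT = "w", CG = "s", CT = "y", GT = "k")

#' Degenerate consensus string from a frequency matrix
#'
#' Per position: the base itself (upper case) if its frequency reaches
#' `majority_threshold`; otherwise the lower-case IUPAC code of the top two
#' bases if they jointly reach it; otherwise `'n'`.
#'
#' @param freq a `freq_matrix`.
#' @param majority_threshold frequency threshold (default 0.7).
#' @return single character string, one symbol per position.
#' @export
consensus_string <- function(freq, majority_threshold = 0.7) {
  f <- as.matrix(freq[, BASES])
  symbols <- apply(f, 1L, function(p) {
    if (anyNA(p)) return("n")
    ord <- order(p, decreasing = TRUE)
    if (p[ord[1]] >= majority_threshold) return(BASES[ord[1]])
    if (p[ord[1]] + p[ord[2]] >= majority_threshold) {
      pair <- paste(sort(BASES[ord[1:2]]), collapse = "")
      return(unname(IUPAC_PAIRS[pair]))
    }
    "n"
  })
  paste(symbols, collapse = "")
}
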