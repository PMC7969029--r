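#' Profiling configuration
#'
#' @param window_bp sliding-window width in base pairs; a window of `w` bp
#'   covers `w - 1` dinucleotide steps (default 25 bp / 24 steps).
#' @param ambiguity how steps containing `N` are handled: `"mask"` (value
#'   excluded from window means; windows with no usable step become `NA`)
#'   or `"impute"` (replaced by the parameter's mean over all 16
#'   dinucleotides).
#' @param alignment which base position a smoothed value is assigned to:
#'   `"center"` (default; window start + floor((window_bp - 1) / 2)),
#'   `"left"` or `"right"`.
#' @return A list of class `profiling_config`.
#' @export
profiling_config <- function(window_bp = 25L,
                             ambiguity = c("mask", "impute"),
                             alignment = c("center", "left", "right")) {
  window_bp <- as.integer(window_bp)
  if (is.na(window_bp) || window_bp < 2L) {
    ss_stop("window_bp must be an integer >= 2", "invalid_input")
  }
  structure(list(window_bp = window_bp,
                 window_steps = window_bp - 1L,
                 ambiguity = match.arg(ambiguity),
                 alignment = match.arg(alignment)),
            class = "profiling_config")
}

check_alphabet <- function(seqs) {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    ss_stop(sprintf("%d sequence(s) contain characters outside A/C/G/T/N",
                    sum(bad)), "invalid_alphabet")
  }
}

# Character matrix (n x L) -> per-step value matrix (n x L-1) for one
# parameter; N-containing steps become NA (mask) or the table-wide mean.
encode_matrix <- function(char_mat, table, parameter, ambiguity = "mask") {
  v16 <- expand_step_values(step_values(table, parameter))
  n <- nrow(char_mat)
  L <- ncol(char_mat)
  idx <- matrix(match(char_mat, BASES), nrow = n)  # N -> NA
  first <- idx[, -L, drop = FALSE]
  second <- idx[, -1L, drop = FALSE]
  code <- (first - 1L) * 4L + second
  vals <- matrix(v16[code], nrow = n)
  if (ambiguity == "impute" && anyNA(vals)) {
    vals[is.na(vals)] <- mean(v16)
  }
  vals
}

#' Encode a sequence as a raw dinucleotide step series
#'
#' Value `i` of the result is the table value of the step formed by bases
#' `i` and `i + 1`, looked up via [canonical_step()]. For a sequence of
#' length `L` the series has length `L - 1`.
#'
#' @param seq a single nucleotide string over A/C/G/T/N.
#' @param table a `property_table`.
#' @param parameter parameter name present in the table.
#' @param ambiguity `"mask"` (N-steps -> `NA`) or `"impute"`.
#' @return numeric vector of length `nchar(seq) - 1`.
#' @export
#' @examples
#' tab <- property_table(matrix(1:10, nrow = 1,
#'                              dimnames = list("Toy", canonical_steps())))
#' encode_sequence("AAAAA", tab, "Toy")
encode_sequence <- function(seq, table, parameter,
                            ambiguity = c("mask", "impute")) {
  ambiguity <- match.arg(ambiguity)
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  check_alphabet(seq)
  if (nchar(seq) < 2L) ss_stop("sequence must have length >= 2", "invalid_input")
  m <- matrix(strsplit(seq, "", fixed = TRUE)[[1]], nrow = 1L)
  as.vector(encode_matrix(m, table, parameter, ambiguity))
}

# Row-wise windowed mean via running sums; NA-aware through parallel counts.
moving_average_matrix <- function(mat, window_steps, na_rm = TRUE) {
  m <- ncol(mat)
  if (m < window_steps) {
    ss_stop(sprintf("series length %d shorter than window of %d steps", m,
                    window_steps), "insufficient_length")
  }
  isna <- is.na(mat)
  x <- mat
  x[isna] <- 0
  cnt <- 1 - isna
  for (j in seq_len(m)[-1]) {
    x[, j] <- x[, j] + x[, j - 1L]
    cnt[, j] <- cnt[, j] + cnt[, j - 1L]
  }
  out_len <- m - window_steps + 1L
  hi <- seq.int(window_steps, m)
  lo <- seq.int(0L, m - window_steps)
  sums <- x[, hi, drop = FALSE]
  counts <- cnt[, hi, drop = FALSE]
  if (window_steps < m) {
    nz <- lo > 0L
    sums[, nz] <- sums[, nz] - x[, lo[nz], drop = FALSE]
    counts[, nz] <- counts[, nz] - cnt[, lo[nz], drop = FALSE]
  }
  res <- sums / counts
  res[counts == 0L] <- NA_real_
  if (!na_rm) res[counts < window_steps] <- NA_real_
  matrix(res, ncol = out_len)
}

#' Sliding-window moving average
#'
#' Element `j` of the output is the arithmetic mean of
#' `series[j .. j + window_steps - 1]`; the window slides by one step, so
#' the output has length `length(series) - window_steps + 1`.
#'
#' @param series numeric vector (a raw step series).
#' @param window_steps window width in steps (default 24, i.e. a 25-bp
#'   window).
#' @param na_rm if `TRUE` (default) `NA` steps are excluded from each
#'   window mean; all-`NA` windows yield `NA`.
#' @return numeric vector.
#' @export
moving_average <- function(series, window_steps = 24L, na_rm = TRUE) {
  stopifnot(is.numeric(series))
  as.vector(moving_average_matrix(matrix(series, nrow = 1L),
                                  as.integer(window_steps), na_rm = na_rm))
}

#' Map smoothed values to signed window positions
#'
#' A window of `2 * flank + 1` bases is labelled -flank..+flank with 0 at
#' the anchor. Smoothed value `j` derives from the `window_bp`-base window
#' starting at base `j`; `"center"` alignment (default) assigns it the
#' window's central base, `"left"` the first, `"right"` the last.
#'
#' @param values numeric vector of smoothed values (or a matrix with one
#'   row per sequence).
#' @param flank window half-width in bases.
#' @param window_bp sliding-window width used to produce `values`.
#' @param alignment `"center"`, `"left"` or `"right"`.
#' @return data.frame `position`, `value` for a vector input; for a matrix
#'   input the matrix with positions as column names.
#' @export
assign_positions <- function(values, flank, window_bp = 25L,
                             alignment = c("center", "left", "right")) {
  alignment <- match.arg(alignment)
  off <- switch(alignment,
                left = 0L,
                center = (as.integer(window_bp) - 1L) %/% 2L,
                right = as.integer(window_bp) - 1L)
  n_out <- if (is.matrix(values)) ncol(values) else length(values)
  positions <- seq_len(n_out) - 1L - as.integer(flank) + off
  if (is.matrix(values)) {
    colnames(values) <- positions
    values
  } else {
    data.frame(position = positions, value = as.vector(values))
  }
}

#' Numeric profiles for a whole dataset
#'
#' Composes encoding, moving average and position assignment for every
#' sequence and every requested parameter. Sequences must share one length
#' (one flank), as boundary datasets do.
#'
#' @param dataset a boundary dataset data.frame (or character vector of
#'   equal-length sequences).
#' @param table a `property_table`.
#' @param parameters parameter names to profile; default all in the table.
#' @param config a [profiling_config()].
#' @param offset optional data.frame `position`, `delta` (and optionally
#'   `parameter`): a table-value shift added to the raw step series at the
#'   steps whose first base sits at `position`, before smoothing. Used to
#'   plant profile bumps in table space.
#' @return An object of class `profile_set`: list with `profiles` (named
#'   list of n-by-positions matrices), `positions`, `parameters`, `ids`,
#'   `kind`, `flank`, `config`.
#' @export
profile_dataset <- function(dataset, table, parameters = NULL,
                            config = profiling_config(), offset = NULL) {
  if (is.character(dataset)) {
    dataset <- new_boundary_dataset(
      id = sprintf("seq_%06d", seq_along(dataset)), kind = "unknown",
      seq = dataset, flank = (nchar(dataset[1]) - 1L) %/% 2L,
      chrom = NA_character_, anchor = NA_integer_, strand = NA_character_)
  }
  seqs <- toupper(dataset$seq)
  check_alphabet(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) ss_stop("sequences must share one length", "invalid_input")
  flank <- dataset$flank[1]
  if (is.null(parameters)) parameters <- table_parameters(table)
  char_mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                     nrow = length(seqs), byrow = TRUE)
  step_pos <- seq_len(L - 1L) - 1L - flank  # first-base position of each step
  profiles <- vector("list", length(parameters))
  names(profiles) <- parameters
  for (p in parameters) {
    raw <- encode_matrix(char_mat, table, p, config$ambiguity)
    if (!is.null(offset)) {
      off_p <- offset
      if ("parameter" %in% names(off_p)) {
        off_p <- off_p[off_p$parameter == p, , drop = FALSE]
      }
      if (nrow(off_p) > 0L) {
        j <- match(off_p$position, step_pos)
        keep <- !is.na(j)
        if (any(keep)) {
          raw[, j[keep]] <- sweep(raw[, j[keep], drop = FALSE], 2L,
                                  off_p$delta[keep], "+")
        }
      }
    }
    sm <- moving_average_matrix(raw, config$window_steps)
    profiles[[p]] <- assign_positions(sm, flank, config$window_bp,
                                      config$alignment)
  }
  structure(list(profiles = profiles,
                 positions = as.integer(colnames(profiles[[1]])),
                 parameters = parameters,
                 ids = dataset$id,
                 kind = dataset$kind[1],
                 flank = flank,
                 config = config),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("<profile_set> %d sequence(s) x %d parameter(s), positions %d..%d (kind %s)\n",
              length(x$ids), length(x$parameters), min(x$positions),
              max(x$positions), x$kind))
  invisible(x)
}

#' Pool profiles into a positionwise average with SEM
#'
#' @param profiles a `profile_set`, or a numeric matrix (sequences in rows,
#'   positions in columns, positions as column names).
#' @param sem sd flavour for the standard error of the mean: `"sample"`
#'   (n - 1 denominator, default) or `"population"`.
#' @return data.frame `parameter` (for profile sets), `position`, `mean`,
#'   `sem`, `n`, where `sem = sd / sqrt(n)` with `n` the number of
#'   non-missing observations at that position.
#' @export
average_profiles <- function(profiles, sem = c("sample", "population")) {
  sem <- match.arg(sem)
  if (inherits(profiles, "profile_set")) {
    out <- lapply(profiles$parameters, function(p) {
      a <- average_profiles(profiles$profiles[[p]], sem = sem)
      cbind(parameter = p, a)
    })
    return(do.call(rbind, out))
  }
  mat <- as.matrix(profiles)
  if (is.null(colnames(mat))) colnames(mat) <- seq_len(ncol(mat))
  n <- colSums(!is.na(mat))
  mu <- colMeans(mat, na.rm = TRUE)
  centred <- sweep(mat, 2L, mu)
  ss <- colSums(centred^2, na.rm = TRUE)
  denom <- if (sem == "sample") pmax(n - 1L, 1L) else pmax(n, 1L)
  sdv <- sqrt(ss / denom)
  sdv[n < 2L & sem == "sample"] <- NA_real_
  data.frame(position = as.integer(colnames(mat)),
             mean = unname(mu),
             sem = unname(sdv / sqrt(n)),
             n = unname(n))
}

#' Min-max normalisation to the unit interval
#'
#' Subtracts the minimum and divides by the range, mapping the minimum to 0
#' and the maximum to 1 so that profiles of parameters with different units
#' can share one axis. A zero-range input returns all 0.5 with a warning.
#'
#' @param values numeric vector.
#' @return numeric vector in `[0, 1]`.
#' @export
#' @examples
#' minmax_normalize(c(2, 4, 6))
minmax_normalize <- function(values) {
  stopifnot(is.numeric(values), length(values) > 0L)
  rng <- range(values, na.rm = TRUE)
  if (!all(is.finite(rng))) ss_stop("no finite values to normalise", "invalid_input")
  if (rng[2] == rng[1]) {
    ss_warn("degenerate range (max == min): returning constant 0.5",
            "degenerate_range")
    out <- rep(0.5, length(values))
    out[is.na(values)] <- NA_real_
    return(out)
  }
  (values - rng[1]) / (rng[2] - rng[1])
}
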