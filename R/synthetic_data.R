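norm_comp <- function(comp, what) {
  if (is.null(names(comp)) || !setequal(names(comp), BASES)) {
    ss_stop(sprintf("%s must be a named 4-vector over A/C/G/T", what),
            "invalid_spec")
  }
  comp <- comp[BASES]
  if (any(comp < 0) || abs(sum(comp) - 1) > 1e-8) {
    ss_stop(sprintf("%s must be non-negative and sum to 1", what),
            "invalid_spec")
  }
  comp / sum(comp)
}

#' Default splice-site consensus model
#'
#' Per-position base probabilities for the degenerate consensus around
#' each splice site, with tunable strength. For exon-to-intron windows
#' (`dataset_I`) the model covers positions -3..+6 around the 5' splice
#' site in a MAG|GTRAGT-like pattern with near-certain GT at +1/+2. For
#' intron-to-exon windows (`dataset_II`) it covers -5..0 with a
#' pyrimidine-rich run into YAG| and near-certain AG at -2/-1. `strength`
#' interpolates linearly between the background-free consensus
#' (`strength = 1`) and the uniform distribution (`strength = 0`).
#'
#' @param kind `"dataset_I"` or `"dataset_II"`.
#' @param strength scalar in `[0, 1]` (default 1).
#' @return 4-by-positions probability matrix; columns named by signed
#'   position, rows A/C/G/T; columns sum to 1.
#' @export
default_splice_consensus <- function(kind = c("dataset_I", "dataset_II"),
                                     strength = 1) {
  kind <- match.arg(kind)
  stopifnot(strength >= 0, strength <= 1)
  if (kind == "dataset_I") {
    m <- cbind(
      `-3` = c(0.35, 0.35, 0.18, 0.12),
      `-2` = c(0.60, 0.13, 0.13, 0.14),
      `-1` = c(0.09, 0.04, 0.79, 0.08),
      `0`  = c(0.25, 0.25, 0.25, 0.25),
      `1`  = c(0.004, 0.003, 0.990, 0.003),
      `2`  = c(0.015, 0.015, 0.015, 0.955),
      `3`  = c(0.60, 0.05, 0.25, 0.10),
      `4`  = c(0.70, 0.08, 0.12, 0.10),
      `5`  = c(0.07, 0.06, 0.80, 0.07),
      `6`  = c(0.17, 0.19, 0.19, 0.45))
  } else {
    m <- cbind(
      `-5` = c(0.10, 0.35, 0.10, 0.45),
      `-4` = c(0.15, 0.30, 0.10, 0.45),
      `-3` = c(0.06, 0.60, 0.04, 0.30),
      `-2` = c(0.990, 0.003, 0.004, 0.003),
      `-1` = c(0.003, 0.003, 0.990, 0.004),
      `0`  = c(0.25, 0.10, 0.50, 0.15))
  }
  rownames(m) <- BASES
  strength * m + (1 - strength) * 0.25
}

#' Specify a synthetic boundary-sequence experiment
#'
#' Bundles every knob of the generator: sample size, window geometry, the
#' distinct exon/intron base compositions, the splice-site consensus
#' model, the branch-point and polypyrimidine-tract models planted on the
#' intron side of intron-to-exon windows, an optional property bump, and
#' the mandatory seed.
#'
#' @param kind `"dataset_I"`, `"dataset_II"` or `"control"`.
#' @param n number of sequences.
#' @param seed integer seed; required so every dataset is reproducible.
#' @param flank window half-width (default 200 -> 401-nt windows).
#' @param exon_comp,intron_comp named base-probability 4-vectors. Defaults
#'   give GC-richer exons (52%) and AT/pyrimidine-richer introns (43% GC).
#' @param consensus per-position probability matrix as returned by
#'   [default_splice_consensus()]; `NULL` for none.
#' @param bs branch-point model: list with `min_offset`, `max_offset`
#'   (nucleotides upstream of the 3' splice site; default 18..40) and
#'   `base` (default `"A"`).
#' @param pyt polypyrimidine-tract model: list with `comp` (base
#'   probabilities; default 85% pyrimidine) and `gap` (tract ends this
#'   many nucleotides before the intron end; default 4, leaving the YAG
#'   consensus region untouched).
#' @param bump optional planted property bump: list with `parameters`
#'   (names in the table passed at generation time), `span` (default
#'   `c(-30, 30)`), `amplitude` (table-value shift; `NULL` for the default
#'   0.75 of the achievable headroom) and `mechanism`
#'   (`"composition"`/`"offset"`). See [plant_property_bump()].
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(kind = c("dataset_I", "dataset_II", "control"),
                           n = 1000L, seed, flank = 200L,
                           exon_comp = c(A = 0.23, C = 0.27, G = 0.25, T = 0.25),
                           intron_comp = c(A = 0.26, C = 0.21, G = 0.22, T = 0.31),
                           consensus = NULL,
                           bs = list(min_offset = 18L, max_offset = 40L, base = "A"),
                           pyt = list(comp = c(A = 0.08, C = 0.36, G = 0.07, T = 0.49),
                                      gap = 4L),
                           bump = NULL) {
  kind <- match.arg(kind)
  if (missing(seed) || is.null(seed)) ss_stop("seed is mandatory", "invalid_spec")
  n <- as.integer(n)
  flank <- as.integer(flank)
  stopifnot(n >= 1L, flank >= 10L)
  exon_comp <- norm_comp(exon_comp, "exon_comp")
  intron_comp <- norm_comp(intron_comp, "intron_comp")
  if (is.null(consensus) && kind != "control") {
    consensus <- default_splice_consensus(kind)
  }
  if (!is.null(consensus)) {
    stopifnot(is.matrix(consensus), nrow(consensus) == 4L)
    cp <- as.integer(colnames(consensus))
    if (anyNA(cp) || min(cp) < -flank || max(cp) > flank) {
      ss_stop("consensus positions must be named, signed and within the window",
              "invalid_spec")
    }
    if (any(abs(colSums(consensus) - 1) > 1e-8)) {
      ss_stop("consensus columns must sum to 1", "invalid_spec")
    }
  }
  if (kind == "dataset_II") {
    bs$min_offset <- as.integer(bs$min_offset)
    bs$max_offset <- as.integer(bs$max_offset)
    if (bs$min_offset > bs$max_offset || bs$min_offset < 1L ||
        bs$max_offset > flank) {
      ss_stop("branch-point offsets must satisfy 1 <= min <= max <= flank",
              "invalid_spec")
    }
    pyt$comp <- norm_comp(pyt$comp, "pyt$comp")
    pyt$gap <- as.integer(pyt$gap)
    if (pyt$gap >= bs$min_offset) {
      ss_stop("polypyrimidine gap must be smaller than the minimum branch-point offset",
              "invalid_spec")
    }
  }
  if (!is.null(bump)) {
    bump$span <- as.integer(bump$span %||% c(-30L, 30L))
    if (length(bump$span) != 2L || bump$span[1] >= bump$span[2] ||
        bump$span[1] < -flank || bump$span[2] > flank) {
      ss_stop("bump span must be an increasing pair within the window",
              "invalid_spec")
    }
    bump$mechanism <- bump$mechanism %||% "composition"
    if (!bump$mechanism %in% c("composition", "offset")) {
      ss_stop("bump mechanism must be 'composition' or 'offset'", "invalid_spec")
    }
    if (is.null(bump$parameters)) {
      ss_stop("bump needs a 'parameters' field", "invalid_spec")
    }
  }
  structure(list(kind = kind, n = n, seed = as.integer(seed), flank = flank,
                 exon_comp = exon_comp, intron_comp = intron_comp,
                 consensus = consensus, bs = bs, pyt = pyt, bump = bump),
            class = "synthetic_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sample_base_matrix <- function(n, width, comp) {
  matrix(sample(BASES, n * width, replace = TRUE, prob = comp),
         nrow = n, ncol = width)
}

sample_position <- function(n, probs) {
  sample(BASES, n, replace = TRUE, prob = probs)
}

#' Generate a synthetic junction dataset with ground truth
#'
#' Builds boundary-like windows matching the spec: exon-composition bases
#' on the exon side, intron composition on the intron side, the consensus
#' model overlaid around the splice site (GT entering the intron for
#' `dataset_I`, AG leaving it for `dataset_II`), and — for `dataset_II` —
#' a branch-point base at a random offset 18..40 nt upstream of the 3'
#' splice site with a polypyrimidine tract between the branch point and
#' the acceptor. Fully deterministic given the spec's seed.
#'
#' @param spec a [synthetic_spec()] of kind `dataset_I` or `dataset_II`.
#' @param table a `property_table`; required only when the spec plants a
#'   property bump.
#' @return list with `sequences` (boundary dataset data.frame) and `truth`
#'   (per-sequence data.frame of planted element coordinates plus the
#'   generator spec in `attr(, "spec")`).
#' @export
generate_junction_dataset <- function(spec, table = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$kind == "control") ss_stop("use generate_control_dataset() for controls",
                                      "invalid_spec")
  set.seed(spec$seed)
  n <- spec$n
  F <- spec$flank
  width <- 2L * F + 1L
  pos_of <- function(p) p + F + 1L
  exon_cols <- if (spec$kind == "dataset_I") pos_of(seq.int(-F, 0L)) else pos_of(seq.int(0L, F))
  intron_cols <- setdiff(seq_len(width), exon_cols)
  M <- matrix("", nrow = n, ncol = width)
  M[, exon_cols] <- sample(BASES, n * length(exon_cols), replace = TRUE,
                           prob = spec$exon_comp)
  M[, intron_cols] <- sample(BASES, n * length(intron_cols), replace = TRUE,
                             prob = spec$intron_comp)
  truth <- data.frame(id = sprintf("sim_%s_%06d", spec$kind, seq_len(n)))
  if (spec$kind == "dataset_II") {
    offsets <- sample(seq.int(spec$bs$min_offset, spec$bs$max_offset), n,
                      replace = TRUE)
    bs_pos <- -offsets  # 3' splice site = last intron base at position -1
    pyt_end <- -(spec$pyt$gap + 1L)
    for (p in seq.int(-(spec$bs$max_offset - 1L), pyt_end)) {
      rows <- which(bs_pos < p)
      if (length(rows) > 0L) {
        M[rows, pos_of(p)] <- sample_position(length(rows), spec$pyt$comp)
      }
    }
    M[cbind(seq_len(n), pos_of(bs_pos))] <- spec$bs$base
    truth$bs_position <- bs_pos
    truth$pyt_start <- bs_pos + 1L
    truth$pyt_end <- pyt_end
    truth$splice_dinuc_start <- -2L
  } else {
    truth$splice_dinuc_start <- 1L
  }
  if (!is.null(spec$consensus)) {
    cpos <- as.integer(colnames(spec$consensus))
    for (i in seq_along(cpos)) {
      M[, pos_of(cpos[i])] <- sample_position(n, spec$consensus[, i])
    }
  }
  ds <- new_boundary_dataset(truth$id, spec$kind,
                             do.call(paste0, as.data.frame(M)),
                             F, NA_character_, NA_integer_, NA_character_)
  if (!is.null(spec$bump)) {
    if (is.null(table)) ss_stop("planting a bump requires a property table",
                                "invalid_spec")
    planted <- plant_property_bump(ds, table, spec$bump)
    ds <- planted$sequences
    truth$bump_start <- spec$bump$span[1]
    truth$bump_end <- spec$bump$span[2]
    attr(truth, "bump") <- planted$truth
  }
  attr(truth, "spec") <- spec
  list(sequences = ds, truth = truth)
}

#' Generate a flat control dataset
#'
#' I.i.d. draws from the exon composition at every position: no splice
#' consensus, branch point, tract or bump — the null against which
#' junction structure is judged.
#'
#' @param spec a [synthetic_spec()]; its `exon_comp`, `n`, `flank` and
#'   `seed` are used.
#' @return boundary dataset data.frame of kind `"control"`.
#' @export
generate_control_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  width <- 2L * spec$flank + 1L
  M <- sample_base_matrix(spec$n, width, spec$exon_comp)
  new_boundary_dataset(sprintf("sim_control_%06d", seq_len(spec$n)), "control",
                       do.call(paste0, as.data.frame(M)),
                       spec$flank, NA_character_, NA_integer_, NA_character_)
}

# Stationary distribution and expected step value of the exponentially
# tilted first-order chain P(b|a) ~ q_b * exp(beta * V(ab)).
tilted_chain <- function(q, V16, beta) {
  V <- matrix(V16, nrow = 4L, byrow = TRUE, dimnames = list(BASES, BASES))
  E <- beta * V
  E <- sweep(E, 1L, apply(E, 1L, max))  # row-wise shift for exp() stability
  P <- sweep(exp(E), 2L, q, "*")
  P <- P / rowSums(P)
  s <- rep(0.25, 4L)
  for (i in 1:400) s <- as.vector(s %*% P)
  s <- s / sum(s)
  list(P = P, stationary = s, expected = sum(s * rowSums(P * V)))
}

#' Plant a property bump into existing sequences
#'
#' Rewrites the bases of each sequence inside `span` so that the expected
#' encoded value of the target parameter(s) within the span shifts by
#' `amplitude` table units relative to the sequences as supplied
#' (mechanism `"composition"`): span bases are resampled from a first-order
#' Markov chain exponentially tilted toward high-value dinucleotide steps,
#' with the tilt solved numerically to hit the requested shift. Amplitude 0
#' reduces to the untilted chain. The alternative mechanism `"offset"`
#' leaves the sequences untouched and instead returns an additive
#' table-space offset track understood by [profile_dataset()]'s `offset`
#' argument.
#'
#' @param sequences a boundary dataset data.frame.
#' @param table a `property_table`.
#' @param bump list with `parameters` (averaged if several), `span`,
#'   `amplitude` (`NULL` -> 0.75 of the achievable headroom) and
#'   `mechanism`.
#' @return list with `sequences` (modified or original) and `truth` (span,
#'   amplitude, mechanism, solved tilt `beta` and the chain, or the offset
#'   track).
#' @export
plant_property_bump <- function(sequences, table, bump) {
  span <- as.integer(bump$span %||% c(-30L, 30L))
  mechanism <- bump$mechanism %||% "composition"
  params <- bump$parameters
  v10 <- Reduce(`+`, lapply(params, function(p) step_values(table, p))) /
    length(params)
  V16 <- unname(expand_step_values(v10))
  flank <- sequences$flank[1]
  cols <- (span[1]:span[2]) + flank + 1L
  seqs <- toupper(sequences$seq)
  char_mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                     nrow = length(seqs), byrow = TRUE)
  span_mat <- char_mat[, cols, drop = FALSE]
  idx <- matrix(match(span_mat, BASES), nrow = nrow(span_mat))
  first <- idx[, -ncol(span_mat), drop = FALSE]
  second <- idx[, -1L, drop = FALSE]
  baseline <- mean(V16[(first - 1L) * 4L + second], na.rm = TRUE)
  if (mechanism == "offset") {
    amplitude <- bump$amplitude %||% (0.75 * (max(V16) - baseline))
    offs <- expand.grid(position = span[1]:(span[2] - 1L), parameter = params,
                        stringsAsFactors = FALSE)
    offs$delta <- amplitude
    return(list(sequences = sequences,
                truth = list(span = span, amplitude = amplitude,
                             mechanism = "offset", offset = offs)))
  }
  q <- prop.table(table(factor(span_mat, levels = BASES)))
  q <- pmax(as.numeric(q), 1e-6)
  q <- q / sum(q)
  lo <- tilted_chain(q, V16, -40)$expected
  hi <- tilted_chain(q, V16, 40)$expected
  amplitude <- bump$amplitude %||% (0.75 * (hi - baseline))
  target <- baseline + amplitude
  if (target <= lo + 1e-9 || target >= hi - 1e-9) {
    if (abs(amplitude) > 1e-12) {
      ss_stop(sprintf("bump amplitude %.4g unachievable: attainable span shift is (%.4g, %.4g)",
                      amplitude, lo - baseline, hi - baseline),
              "unachievable_amplitude")
    }
  }
  beta <- if (abs(amplitude) < 1e-12) 0 else {
    stats::uniroot(function(b) tilted_chain(q, V16, b)$expected - target,
                   interval = c(-40, 40), tol = 1e-10)$root
  }
  chain <- tilted_chain(q, V16, beta)
  n <- nrow(char_mat)
  new_span <- matrix("", nrow = n, ncol = length(cols))
  state <- sample.int(4L, n, replace = TRUE, prob = chain$stationary)
  new_span[, 1L] <- BASES[state]
  for (j in 2:length(cols)) {
    prev <- state
    for (st in 1:4) {
      rows <- which(prev == st)
      if (length(rows) > 0L) {
        nxt <- sample.int(4L, length(rows), replace = TRUE,
                          prob = chain$P[st, ])
        state[rows] <- nxt
        new_span[rows, j] <- BASES[nxt]
      }
    }
  }
  char_mat[, cols] <- new_span
  sequences$seq <- do.call(paste0, as.data.frame(char_mat))
  list(sequences = sequences,
       truth = list(span = span, amplitude = amplitude,
                    mechanism = "composition", beta = beta,
                    baseline = baseline, target = target,
                    transition = chain$P, stationary = chain$stationary))
}
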