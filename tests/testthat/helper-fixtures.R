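# Shared fixtures: tiny property tables and independent oracle helpers.

make_table <- function(..., descriptors = NULL) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- canonical_steps()
  rownames(m) <- names(rows)
  property_table(m, descriptors = descriptors)
}

rand_table <- function(params, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(length(params) * 10, -5, 5), nrow = length(params),
              dimnames = list(params, canonical_steps()))
  property_table(m)
}

# A spike table: one step carries all the contrast. Used for planted-signal
# work where a large, known table-value headroom is needed.
spike_table <- function(n_extra = 0L) {
  rows <- list(Spike = c(10, rep(0, 9)))
  if (n_extra > 0L) {
    set.seed(99)
    for (i in seq_len(n_extra)) {
      rows[[sprintf("Aux%d", i)]] <- runif(10, -2, 2)
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- canonical_steps()
  property_table(m)
}

# Smallest signed difference between two angles in degrees.
ang_diff <- function(a, b) ((a - b + 180) %% 360) - 180

# Brute-force oracles, deliberately loop-based and independent of the
# package's vectorised implementations.
oracle_circular_mean <- function(angles) {
  sx <- 0; sy <- 0
  for (a in angles) {
    sx <- sx + cos(a * pi / 180)
    sy <- sy + sin(a * pi / 180)
  }
  atan2(sy, sx) * 180 / pi
}

oracle_moving_average <- function(series, w) {
  n <- length(series) - w + 1
  out <- numeric(n)
  for (j in seq_len(n)) out[j] <- mean(series[j:(j + w - 1)])
  out
}

oracle_area <- function(v1, v2) {
  a <- 0
  for (i in seq_len(length(v1) - 1)) {
    d1 <- abs(v1[i] - v2[i])
    d2 <- abs(v1[i + 1] - v2[i + 1])
    a <- a + (d1 + d2) / 2
  }
  a
}

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_sem <- function(x) {
  m <- mean(x)
  sqrt(sum((x - m)^2) / (length(x) - 1)) / sqrt(length(x))
}

# Long average-profile data.frame builder for correlation/grouping tests.
make_avg <- function(values_by_param, positions) {
  do.call(rbind, lapply(names(values_by_param), function(p) {
    data.frame(parameter = p, position = positions,
               mean = values_by_param[[p]], sem = 0,
               n = 2L, stringsAsFactors = FALSE)
  }))
}
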