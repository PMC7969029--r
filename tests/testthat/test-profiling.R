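test_that("dinucleotide encoding looks up canonical step classes", {
  tab <- make_table(Toy = 1:10)
  x <- step_values(tab, "Toy")
  expect_equal(encode_sequence("AAAAA", tab, "Toy"), rep(x[["AA"]], 4))
  expect_equal(encode_sequence("AT", tab, "Toy"), x[["AT"]])
  # GT maps to AC's class
  expect_equal(encode_sequence("ACGT", tab, "Toy"),
               unname(c(x["AC"], x["CG"], x["AC"])))
  expect_error(encode_sequence("ACGX", tab, "Toy"),
               class = "splicescape_invalid_alphabet")
  # ambiguity: masked N-steps are NA, imputation fills the 16-dinucleotide mean
  masked <- encode_sequence("ANAA", tab, "Toy")
  expect_identical(is.na(masked), c(TRUE, TRUE, FALSE))
  imputed <- encode_sequence("ANAA", tab, "Toy", ambiguity = "impute")
  v16 <- x[canonical_step(all_dinucleotides())]
  expect_equal(imputed[1:2], rep(mean(v16), 2))
})

test_that("moving average matches the brute-force windowed mean", {
  set.seed(21)
  for (i in 1:300) {
    w <- sample(2:30, 1)
    len <- w + sample(0:80, 1)
    s <- rnorm(len)
    expect_equal(moving_average(s, w), oracle_moving_average(s, w),
                 tolerance = 1e-12)
  }
  expect_equal(moving_average(1:10, 3), 2:9)
  expect_equal(moving_average(rep(7, 100), 24), rep(7, 77))
  expect_error(moving_average(1:10, 24),
               class = "splicescape_insufficient_length")
  # NA handling: masked steps are excluded from the window mean
  s <- c(1, NA, 3, 5)
  expect_equal(moving_average(s, 2), c(1, 3, 4))
  expect_equal(moving_average(s, 2, na_rm = FALSE), c(NA, NA, 4))
})

test_that("window positions follow the documented alignment arithmetic", {
  vals <- numeric(377)
  centre <- assign_positions(vals, flank = 200, window_bp = 25)
  expect_equal(range(centre$position), c(-188, 188))
  left <- assign_positions(vals, flank = 200, window_bp = 25,
                           alignment = "left")
  expect_equal(range(left$position), c(-200, 176))
  expect_true(all(seq(-30, 30) %in% centre$position))
  expect_true(all(seq(-30, 30) %in% left$position))
})

test_that("a 401-nt window yields 377 profile points and homopolymers are flat", {
  tab <- make_table(Toy = seq(0.5, 5, by = 0.5))
  seqs <- c(strrep("A", 401), strrep("C", 401))
  ps <- profile_dataset(seqs, tab)
  expect_equal(ncol(ps$profiles$Toy), 377L)
  expect_equal(ps$positions, seq(-188L, 188L))
  expect_equal(unique(as.vector(ps$profiles$Toy[1, ])),
               unname(step_values(tab, "Toy")["AA"]))
  expect_equal(unique(as.vector(ps$profiles$Toy[2, ])),
               unname(step_values(tab, "Toy")["CC"]))
  # convexity: smoothed values stay within the table's range
  set.seed(31)
  rand_seqs <- vapply(1:20, function(i) {
    paste(sample(c("A", "C", "G", "T"), 401, replace = TRUE), collapse = "")
  }, character(1))
  psr <- profile_dataset(rand_seqs, tab)
  rng <- range(step_values(tab, "Toy"))
  expect_true(all(psr$profiles$Toy >= rng[1] & psr$profiles$Toy <= rng[2]))
  # profile equals the encode -> smooth -> position composition
  manual <- assign_positions(
    moving_average(encode_sequence(rand_seqs[1], tab, "Toy"), 24),
    flank = 200)
  expect_equal(as.vector(psr$profiles$Toy[1, ]), manual$value)
})

test_that("profile pooling computes mean and sample SEM per position", {
  m <- rbind(c(1, 1, 1), c(3, 2, 1))
  colnames(m) <- c(-1, 0, 1)
  avg <- average_profiles(m)
  expect_equal(avg$mean, c(2, 1.5, 1))
  expect_equal(avg$sem, c(sd(c(1, 3)) / sqrt(2), sd(c(1, 2)) / sqrt(2), 0))
  expect_equal(avg$sem[1], 1)  # {1,3}: sd sqrt(2), sem sqrt(2)/sqrt(2)
  m3 <- matrix(c(1, 2, 3), ncol = 1)
  colnames(m3) <- 0
  expect_equal(average_profiles(m3)$sem, 1 / sqrt(3), tolerance = 1e-4)
  # identical profiles pool to themselves with zero SEM
  ident <- rbind(c(5, 6), c(5, 6))
  colnames(ident) <- c(0, 1)
  expect_equal(average_profiles(ident)$sem, c(0, 0))
  # permutation invariance and the population-sd option
  set.seed(41)
  mm <- matrix(rnorm(50), nrow = 10)
  colnames(mm) <- 1:5
  expect_equal(average_profiles(mm), average_profiles(mm[sample(1:10), ]))
  pop <- average_profiles(mm, sem = "population")
  expect_equal(pop$sem[1],
               sqrt(mean((mm[, 1] - mean(mm[, 1]))^2)) / sqrt(10))
  # oracle agreement for the sample-sd flavour
  expect_equal(average_profiles(mm)$sem[3], oracle_sem(mm[, 3]),
               tolerance = 1e-12)
})

test_that("min-max normalisation hits 0 and 1 and is affine-invariant", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  set.seed(51)
  x <- rnorm(100)
  nx <- minmax_normalize(x)
  expect_equal(min(nx), 0)
  expect_equal(max(nx), 1)
  expect_equal(minmax_normalize(3 * x - 7), nx, tolerance = 1e-12)
  expect_warning(res <- minmax_normalize(rep(2, 5)),
                 class = "splicescape_degenerate_range")
  expect_equal(res, rep(0.5, 5))
})

test_that("table-space offsets plant profile shifts at the requested positions", {
  tab <- make_table(Toy = rep(1, 10))
  seqs <- rep(strrep("A", 101), 3)
  off <- data.frame(position = -10:9, delta = 2)
  ps <- profile_dataset(seqs, tab, config = profiling_config(window_bp = 5),
                        offset = off)
  avg <- average_profiles(ps$profiles$Toy)
  inside <- avg$position %in% (-8:8)   # windows fully inside the offset span
  outside <- avg$position <= -12 | avg$position >= 12
  expect_true(all(avg$mean[inside] == 3))
  expect_true(all(avg$mean[outside] == 1))
})
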