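test_that("generation is fully deterministic under a fixed seed", {
  spec <- synthetic_spec("dataset_II", n = 60, seed = 91)
  a <- generate_junction_dataset(spec)
  b <- generate_junction_dataset(spec)
  expect_identical(a$sequences$seq, b$sequences$seq)
  expect_identical(a$truth, b$truth)
  expect_identical(generate_control_dataset(spec)$seq,
                   generate_control_dataset(spec)$seq)
  # and FASTA persistence is byte-identical across runs
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_dataset(a$sequences, f1)
  write_dataset(b$sequences, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a certain consensus is planted verbatim", {
  cons <- default_splice_consensus("dataset_I")
  cons[, "1"] <- c(0, 0, 1, 0)  # G
  cons[, "2"] <- c(0, 0, 0, 1)  # T
  spec <- synthetic_spec("dataset_I", n = 50, seed = 92, consensus = cons)
  ds <- generate_junction_dataset(spec)$sequences
  plus1 <- substr(ds$seq, 202, 203)  # positions +1, +2 of a 401-nt window
  expect_true(all(plus1 == "GT"))
})

test_that("large samples recover the generator's probabilities within binomial error", {
  spec <- synthetic_spec("dataset_II", n = 3000, seed = 93)
  g <- generate_junction_dataset(spec)
  f <- position_frequencies(g$sequences, range = c(-5, 0))
  for (p in colnames(spec$consensus)) {
    got <- as.numeric(f[f$position == as.integer(p), c("A", "C", "G", "T")])
    expect_lt(max(abs(got - spec$consensus[, p])), 0.05)
  }
  # intron composition away from all planted elements
  f_far <- position_frequencies(g$sequences, range = c(-150, -150))
  expect_lt(max(abs(as.numeric(f_far[, c("A", "C", "G", "T")]) -
                      spec$intron_comp)), 0.05)
  # branch-point adenine where the truth says it is
  bs <- g$truth$bs_position
  expect_true(all(bs >= -40 & bs <= -18))
  at_bs <- substr(g$sequences$seq, bs + 201, bs + 201)
  expect_true(all(at_bs == "A"))
  # polypyrimidine tract is pyrimidine-rich between BS and acceptor
  f_pyt <- position_frequencies(g$sequences, range = c(-15, -6))
  expect_gt(min(f_pyt$C + f_pyt$T), 0.75)
})

test_that("controls are flat and carry no donor enrichment", {
  spec <- synthetic_spec("control", n = 400, seed = 94)
  ctrl <- generate_control_dataset(spec)
  f <- position_frequencies(ctrl, range = c(-2, 2))
  expect_lt(max(abs(f$G - spec$exon_comp[["G"]])), 0.08)
  # average profile range is far narrower than a junction dataset's
  tab <- make_table(Toy = runif(10, 0, 4))
  ctrl_avg <- average_profiles(profile_dataset(ctrl, tab))
  jn <- generate_junction_dataset(synthetic_spec("dataset_I", n = 400,
                                                 seed = 95))$sequences
  jn_avg <- average_profiles(profile_dataset(jn, tab))
  expect_lt(diff(range(ctrl_avg$mean)), diff(range(jn_avg$mean)))
  # per-sequence base composition matches the spec across positions
  overall <- position_frequencies(ctrl, range = c(-200, 200))
  expect_lt(max(abs(colMeans(overall[, c("A", "C", "G", "T")]) -
                      spec$exon_comp)), 0.01)
})

test_that("bump planting hits the requested table-value shift and degenerates cleanly", {
  tab <- spike_table()
  spec <- synthetic_spec("dataset_I", n = 500, seed = 96)
  ds <- generate_junction_dataset(spec)$sequences
  planted <- plant_property_bump(ds, tab, list(parameters = "Spike",
                                               span = c(-30, 30),
                                               amplitude = 4))
  expect_equal(planted$truth$span, c(-30, 30))
  expect_equal(planted$truth$amplitude, 4)
  # realised mean step value inside the span is close to baseline + amplitude
  flank <- 200L
  span_cols <- (-30:30) + flank + 1L
  span_seqs <- substr(planted$sequences$seq, min(span_cols), max(span_cols))
  v16 <- step_values(tab, "Spike")[canonical_step(all_dinucleotides())]
  names(v16) <- all_dinucleotides()
  steps <- unlist(lapply(span_seqs, function(s) {
    substring(s, 1:(nchar(s) - 1), 2:nchar(s))
  }))
  expect_equal(mean(v16[steps]), planted$truth$target, tolerance = 0.1)
  # amplitude 0 reduces to the untilted chain: every row equals the base
  # composition, so planting is distributionally a no-op
  null_plant <- plant_property_bump(ds, tab, list(parameters = "Spike",
                                                  span = c(-30, 30),
                                                  amplitude = 0))
  expect_equal(null_plant$truth$beta, 0)
  P <- null_plant$truth$transition
  for (i in 1:4) expect_equal(unname(P[i, ]), unname(P[1, ]), tolerance = 1e-12)
  # unattainable shifts are refused
  expect_error(plant_property_bump(ds, tab, list(parameters = "Spike",
                                                 span = c(-30, 30),
                                                 amplitude = 1000)),
               class = "splicescape_unachievable_amplitude")
  # the offset mechanism leaves sequences untouched and emits a track
  off <- plant_property_bump(ds, tab, list(parameters = "Spike",
                                           span = c(-30, 30), amplitude = 2,
                                           mechanism = "offset"))
  expect_identical(off$sequences$seq, ds$seq)
  expect_equal(unique(off$truth$offset$delta), 2)
})

test_that("invalid synthetic specs are rejected", {
  expect_error(synthetic_spec("dataset_I", n = 10), class = "splicescape_invalid_spec")
  expect_error(synthetic_spec("dataset_I", n = 10, seed = 1,
                              exon_comp = c(A = 0.5, C = 0.5, G = 0.2, T = 0.2)),
               class = "splicescape_invalid_spec")
  expect_error(synthetic_spec("dataset_II", n = 10, seed = 1,
                              bs = list(min_offset = 50, max_offset = 18, base = "A")),
               class = "splicescape_invalid_spec")
  expect_error(synthetic_spec("dataset_II", n = 10, seed = 1,
                              pyt = list(comp = c(A = 0.25, C = 0.25, G = 0.25,
                                                  T = 0.25), gap = 30)),
               class = "splicescape_invalid_spec")
  expect_error(synthetic_spec("dataset_I", n = 10, seed = 1,
                              bump = list(span = c(-30, 30))),
               class = "splicescape_invalid_spec")
})

test_that("the toy genome has the expected junction census and GT..AG orientation", {
  tg <- make_toy_genome(seed = 7)
  # 2 genes x 3 exons -> 2 internal boundaries each, per dataset kind
  expect_equal(sum(tg$truth$kind == "dataset_I"), 4L)
  expect_equal(sum(tg$truth$kind == "dataset_II"), 4L)
  expect_setequal(unique(tg$truth$strand), c("+", "-"))
  flank <- tg$truth$flank[1]
  d1 <- tg$truth[tg$truth$kind == "dataset_I", ]
  expect_true(all(substr(d1$window, flank + 2, flank + 3) == "GT"))
  d2 <- tg$truth[tg$truth$kind == "dataset_II", ]
  expect_true(all(substr(d2$window, flank - 1, flank) == "AG"))
})
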