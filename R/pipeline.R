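#' Configuration for a full pipeline run
#'
#' Defaults reproduce the reference settings throughout the package:
#' flank 200 (401-nt windows), 25-bp sliding window, junction vectors over
#' -30..+30, control vectors offset 150 positions toward the exon, and a
#' detection threshold of mean - 2 sd.
#'
#' @param out_dir output directory (created if absent).
#' @param genome,annotation paths to a genome FASTA and GTF for real-data
#'   runs; leave `NULL` when simulating.
#' @param property_table a `property_table` or a path loadable by
#'   [load_table()]; `NULL` uses [default_property_table()].
#' @param parameters parameter subset to profile (default: all in the
#'   table).
#' @param flank window half-width.
#' @param window_bp sliding-window width.
#' @param junction_half_span junction-vector half-width.
#' @param control_offset control-vector displacement.
#' @param k detection threshold multiplier.
#' @param seed integer seed for simulation.
#' @param simulate `NULL` for real-data runs, otherwise a list with
#'   `n_junction` and `n_control` sequence counts.
#' @param plots emit PNG figures (default `FALSE`).
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, genome = NULL, annotation = NULL,
                       property_table = NULL, parameters = NULL,
                       flank = 200L, window_bp = 25L,
                       junction_half_span = 30L, control_offset = 150L,
                       k = 2, seed = 1L, simulate = NULL, plots = FALSE) {
  if (is.null(simulate) && (is.null(genome) || is.null(annotation))) {
    ss_stop("either simulate= or both genome= and annotation= are required",
            "invalid_input")
  }
  structure(list(out_dir = out_dir, genome = genome, annotation = annotation,
                 property_table = property_table, parameters = parameters,
                 flank = as.integer(flank), window_bp = as.integer(window_bp),
                 junction_half_span = as.integer(junction_half_span),
                 control_offset = as.integer(control_offset), k = k,
                 seed = as.integer(seed), simulate = simulate,
                 plots = isTRUE(plots)),
            class = "run_config")
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the whole boundary-characterisation workflow
#'
#' Chains the stages end to end: obtain Datasets I, II and a control set
#' (simulated with known truth, or extracted from a genome + GTF), encode
#' and smooth numeric profiles, pool them with SEM, min-max normalise for
#' the joint view, score per-sequence junction signals, tabulate base
#' frequencies / information content / consensus, compute the
#' position-specific correlation matrix and the two-group parameter
#' clustering, and write every artifact plus a machine-readable manifest
#' to `out_dir`. Outputs are byte-stable under a fixed config and seed.
#'
#' @param config a [run_config()].
#' @return invisible list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  tab <- config$property_table
  if (is.null(tab)) tab <- default_property_table()
  if (is.character(tab)) tab <- load_table(tab)
  params <- config$parameters %||% table_parameters(tab)
  pconf <- profiling_config(window_bp = config$window_bp)

  stage_msg("datasets", "building Datasets I, II and control")
  if (!is.null(config$simulate)) {
    n_j <- config$simulate$n_junction %||% 1000L
    n_c <- config$simulate$n_control %||% max(100L, n_j %/% 10L)
    ds1 <- generate_junction_dataset(
      synthetic_spec("dataset_I", n = n_j, seed = config$seed,
                     flank = config$flank), table = tab)$sequences
    ds2 <- generate_junction_dataset(
      synthetic_spec("dataset_II", n = n_j, seed = config$seed + 1L,
                     flank = config$flank), table = tab)$sequences
    ctrl <- generate_control_dataset(
      synthetic_spec("control", n = n_c, seed = config$seed + 2L,
                     flank = config$flank))
  } else {
    exons <- parse_protein_coding_exons(config$annotation)
    genome <- as_genome(config$genome)
    ds1 <- extract_boundary_dataset(genome, exons, flank = config$flank,
                                    kind = "dataset_I")
    ds2 <- extract_boundary_dataset(genome, exons, flank = config$flank,
                                    kind = "dataset_II")
    ctrl <- extract_control_dataset(genome, exons,
                                    window_length = 2L * config$flank + 1L,
                                    min_exon_length = 2L * config$flank + 601L)
  }
  datasets <- list(dataset_I = ds1, dataset_II = ds2, control = ctrl)
  for (nm in names(datasets)) {
    write_dataset(datasets[[nm]], out(paste0(nm, ".fa")),
                  bed = if (is.null(config$simulate)) out(paste0(nm, ".bed")))
  }
  stage_msg("datasets", "sizes: I=%d II=%d control=%d",
            nrow(ds1), nrow(ds2), nrow(ctrl))

  stage_msg("profiles", "encoding and smoothing %d parameter(s)", length(params))
  psets <- lapply(datasets, profile_dataset, table = tab,
                  parameters = params, config = pconf)
  averages <- lapply(psets, average_profiles)
  for (nm in names(averages)) {
    write_tsv(averages[[nm]], out(paste0("average_profile_", nm, ".tsv")))
  }
  joint <- lapply(averages, function(avg) {
    do.call(rbind, lapply(split(avg, avg$parameter), function(d) {
      d <- d[order(d$position), ]
      d$normalised <- minmax_normalize(d$mean)
      d[c("parameter", "position", "normalised")]
    }))
  })
  for (nm in names(joint)) {
    write_tsv(joint[[nm]], out(paste0("normalized_profile_", nm, ".tsv")))
  }

  stage_msg("detect", "junction-vs-control areas (k = %g)", config$k)
  reports <- lapply(psets[c("dataset_I", "dataset_II")], detection_report,
                    k = config$k, half_span = config$junction_half_span,
                    offset = config$control_offset)
  for (nm in names(reports)) {
    write_tsv(reports[[nm]]$areas, out(paste0("areas_", nm, ".tsv")))
    write_tsv(reports[[nm]]$summary, out(paste0("detection_", nm, ".tsv")))
  }

  stage_msg("consensus", "base frequencies and information content")
  freqs <- lapply(datasets[c("dataset_I", "dataset_II")],
                  position_frequencies,
                  range = c(-config$junction_half_span,
                            config$junction_half_span))
  consensus <- lapply(freqs, function(f) {
    list(freq = f, ic = information_content(f), string = consensus_string(f))
  })
  for (nm in names(consensus)) {
    write_tsv(consensus[[nm]]$freq, out(paste0("frequencies_", nm, ".tsv")))
    write_tsv(consensus[[nm]]$ic, out(paste0("information_content_", nm, ".tsv")))
  }
  writeLines(vapply(consensus, `[[`, "", "string"),
             out("consensus_strings.txt"))

  stage_msg("correlate", "position-specific correlations and grouping")
  baseline_hi <- min(-100L, min(psets$dataset_I$positions) + 40L)
  correlations <- list()
  groups <- list()
  for (nm in c("dataset_I", "dataset_II")) {
    cm <- pairwise_position_correlation(averages[[nm]])
    correlations[[nm]] <- cm
    heatmap_export(cm, out(paste0("correlation_", nm, ".tsv")),
                   plot = if (config$plots) out(paste0("correlation_", nm, ".png")))
    groups[[nm]] <- assign_groups(
      averages[[nm]],
      baseline_window = c(min(psets[[nm]]$positions), baseline_hi))
    write_tsv(groups[[nm]], out(paste0("groups_", nm, ".tsv")))
  }

  if (config$plots) {
    for (nm in names(averages)) {
      ggplot2::ggsave(out(paste0("profiles_", nm, ".png")),
                      plot_average_profiles(averages[[nm]]),
                      width = 12, height = 9, dpi = 150)
      ggplot2::ggsave(out(paste0("joint_", nm, ".png")),
                      plot_joint_profiles(averages[[nm]]),
                      width = 8, height = 5, dpi = 150)
    }
  }

  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  cfg_json <- jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE, digits = NA,
                               null = "null", force = TRUE)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(
    package = "splicescape",
    version = as.character(utils::packageVersion("splicescape")),
    seed = config$seed,
    config = cfg_for_hash,
    config_md5 = unname(tools::md5sum(tmp)),
    n_sequences = vapply(datasets, nrow, integer(1)),
    parameters = params)
  unlink(tmp)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)

  invisible(list(datasets = datasets, profiles = psets, averages = averages,
                 reports = reports, consensus = consensus,
                 correlations = correlations, groups = groups,
                 out_dir = config$out_dir))
}
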