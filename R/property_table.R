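#' Descriptors for the default parameter set
#'
#' The default set comprises 31 parameters: 9 backbone (Alpha, Beta, Gamma,
#' Delta, Epsilon, Zeta, Chi, Phase, Amplitude), 8 inter-base-pair (Shift,
#' Slide, Rise, Tilt, Roll, Twist, H-Rise, H-Twist), 6 intra-base-pair
#' (Shear, Stretch, Stagger, Buckle, Propel, Opening), 5 base-pair-axis
#' (X-Displacement, Y-Displacement, Inclination, Tip, Axis-Bend) and 3
#' energies (hydrogen-bond, stacking, solvation). Torsions, sugar phase and
#' the rotational helical/base parameters are flagged angular and averaged
#' circularly; translations, pucker amplitude and energies are linear.
#'
#' @return data.frame with columns `name`, `category`, `angular`, `units`.
#' @export
parameter_descriptors <- function() {
  d <- rbind(
    data.frame(name = c("Alpha", "Beta", "Gamma", "Delta", "Epsilon", "Zeta",
                        "Chi", "Phase", "Amplitude"),
               category = "backbone",
               angular = c(rep(TRUE, 8L), FALSE),
               units = "degrees"),
    data.frame(name = c("Shift", "Slide", "Rise", "Tilt", "Roll", "Twist",
                        "H-Rise", "H-Twist"),
               category = "inter-bp",
               angular = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE),
               units = c("Angstrom", "Angstrom", "Angstrom", "degrees",
                         "degrees", "degrees", "Angstrom", "degrees")),
    data.frame(name = c("Shear", "Stretch", "Stagger", "Buckle", "Propel",
                        "Opening"),
               category = "intra-bp",
               angular = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
               units = c("Angstrom", "Angstrom", "Angstrom", "degrees",
                         "degrees", "degrees")),
    data.frame(name = c("X-Displacement", "Y-Displacement", "Inclination",
                        "Tip", "Axis-Bend"),
               category = "bp-axis",
               angular = c(FALSE, FALSE, TRUE, TRUE, TRUE),
               units = c("Angstrom", "Angstrom", "degrees", "degrees",
                         "degrees")),
    data.frame(name = c("Hydrogen-Bond-Energy", "Stacking-Energy",
                        "Solvation-Energy"),
               category = "energy",
               angular = FALSE,
               units = "kcal/mol")
  )
  rownames(d) <- NULL
  d
}

#' Construct a dinucleotide property table
#'
#' A property table maps each parameter to a real value per canonical
#' dinucleotide step class (10 classes, see [canonical_steps()]). This is
#' the lookup used to turn a nucleotide sequence into numeric profiles.
#'
#' @param values numeric matrix or data.frame; one row per parameter (row
#'   names or a `parameter` column), columns named by the 10 canonical steps.
#' @param descriptors optional descriptor data.frame as returned by
#'   [parameter_descriptors()]; parameter names absent from it trigger a
#'   warning. `NULL` skips the check (useful for ad-hoc tables).
#' @param provenance character tag recording where the values came from.
#' @return An object of class `property_table`.
#' @export
property_table <- function(values, descriptors = NULL, provenance = "built") {
  if (is.data.frame(values)) {
    if ("parameter" %in% names(values)) {
      rn <- as.character(values$parameter)
      values <- values[setdiff(names(values), "parameter")]
      values <- as.matrix(values)
      rownames(values) <- rn
    } else {
      values <- as.matrix(values)
    }
  }
  steps <- canonical_steps()
  missing_cols <- setdiff(steps, colnames(values))
  if (length(missing_cols) > 0L) {
    ss_stop(sprintf("incomplete table: missing step column(s) %s",
                    paste(missing_cols, collapse = ", ")),
            "incomplete_table")
  }
  extra <- setdiff(colnames(values), steps)
  if (length(extra) > 0L) {
    ss_warn(sprintf("ignoring non-canonical column(s): %s",
                    paste(extra, collapse = ", ")), "extra_columns")
  }
  values <- values[, steps, drop = FALSE]
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    ss_stop("parameter names must be present and unique", "invalid_input")
  }
  if (!all(is.finite(values))) {
    bad <- rownames(values)[!apply(is.finite(values), 1L, all)]
    ss_stop(sprintf("incomplete table: non-finite value(s) for %s",
                    paste(bad, collapse = ", ")), "incomplete_table")
  }
  if (!is.null(descriptors)) {
    unknown <- setdiff(rownames(values), descriptors$name)
    if (length(unknown) > 0L) {
      ss_warn(sprintf("parameter(s) not in descriptor set: %s",
                      paste(unknown, collapse = ", ")), "unknown_parameter")
    }
  }
  structure(list(values = values, descriptors = descriptors,
                 provenance = provenance),
            class = "property_table")
}

#' @export
print.property_table <- function(x, ...) {
  cat(sprintf("<property_table> %d parameter(s) x %d step classes (%s)\n",
              nrow(x$values), ncol(x$values), x$provenance))
  print(utils::head(x$values, 6L))
  if (nrow(x$values) > 6L) cat(sprintf("... and %d more\n", nrow(x$values) - 6L))
  invisible(x)
}

#' Parameter names of a property table
#' @param table a `property_table`.
#' @return character vector.
#' @export
table_parameters <- function(table) {
  stopifnot(inherits(table, "property_table"))
  rownames(table$values)
}

#' Per-step values of one parameter
#' @param table a `property_table`.
#' @param parameter parameter name.
#' @return named numeric vector over the 10 canonical steps.
#' @export
step_values <- function(table, parameter) {
  stopifnot(inherits(table, "property_table"))
  if (!parameter %in% rownames(table$values)) {
    ss_stop(sprintf("parameter '%s' not in table", parameter), "unknown_parameter")
  }
  table$values[parameter, ]
}

# Angular flag lookup: FALSE when the table carries no descriptors.
is_angular <- function(table, parameter) {
  d <- table$descriptors
  if (is.null(d)) return(FALSE)
  i <- match(parameter, d$name)
  !is.na(i) && isTRUE(d$angular[i])
}

#' Build a property table from per-structure observations
#'
#' Observations (one measured value per dinucleotide occurrence in a set of
#' reference structures, read 5'->3') are pooled into reverse-complement
#' step classes via [canonical_step()] and averaged: arithmetically for
#' linear parameters, with [circular_mean()] for angular ones.
#'
#' @param obs data.frame with columns `structure_id`, `step`, `parameter`,
#'   `value` (angular values in degrees).
#' @param descriptors descriptor set controlling which parameters are kept
#'   and which are angular. Default [parameter_descriptors()].
#' @param sign_correct if `TRUE`, values of strand-asymmetric parameters
#'   (given by `asymmetric`) are negated for observations read as the
#'   reverse complement of their canonical label before pooling. Default
#'   `FALSE`: occurrences are pooled exactly as read.
#' @param asymmetric parameter names whose sign flips under a strand flip.
#' @return A `property_table` with provenance `"built"`.
#' @export
build_table <- function(obs, descriptors = parameter_descriptors(),
                        sign_correct = FALSE,
                        asymmetric = c("Tilt", "Shift", "Shear", "Buckle",
                                       "Tip", "Y-Displacement")) {
  req <- c("step", "parameter", "value")
  if (!all(req %in% names(obs))) {
    ss_stop("observations need columns step, parameter, value", "invalid_input")
  }
  cls <- canonical_step(obs$step)  # validates the alphabet
  params <- unique(as.character(obs$parameter))
  unknown <- setdiff(params, descriptors$name)
  if (length(unknown) > 0L) {
    ss_warn(sprintf("dropping observation parameter(s) not in descriptor set: %s",
                    paste(unknown, collapse = ", ")), "unknown_parameter")
    keep <- obs$parameter %in% descriptors$name
    obs <- obs[keep, , drop = FALSE]
    cls <- cls[keep]
    params <- intersect(params, descriptors$name)
  }
  if (length(params) == 0L) ss_stop("no usable observations", "invalid_input")
  steps <- canonical_steps()
  have <- unique(paste(obs$parameter, cls))
  need <- as.vector(outer(params, steps, paste))
  gaps <- setdiff(need, have)
  if (length(gaps) > 0L) {
    ss_stop(sprintf("incomplete observation coverage; missing (parameter, step): %s",
                    paste(gaps, collapse = "; ")), "incomplete_table")
  }
  val <- obs$value
  if (sign_correct) {
    flip <- obs$parameter %in% asymmetric & canonical_step(obs$step) != toupper(obs$step)
    val[flip] <- -val[flip]
  }
  ang <- setNames(descriptors$angular, descriptors$name)
  m <- matrix(NA_real_, nrow = length(params), ncol = length(steps),
              dimnames = list(params, steps))
  for (p in params) {
    sel_p <- obs$parameter == p
    for (s in steps) {
      v <- val[sel_p & cls == s]
      m[p, s] <- if (isTRUE(ang[[p]])) circular_mean(v) else mean(v)
    }
  }
  property_table(m, descriptors = descriptors, provenance = "built")
}

#' Read / write property tables as TSV
#'
#' Dialect: tab-separated, UTF-8, `.` decimal separator, `#` comment lines;
#' first column `parameter`, then ten columns headed by the canonical step
#' labels. Round-trips losslessly to 12 significant digits.
#'
#' @param path file path.
#' @param descriptors descriptor set used to warn on unknown parameter
#'   names; `NULL` disables the check.
#' @return `load_table()` returns a `property_table` with provenance set to
#'   the path; `write_table()` returns the path invisibly.
#' @export
load_table <- function(path, descriptors = parameter_descriptors()) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"parameter" %in% names(df)) {
    ss_stop("table file must have a 'parameter' column", "invalid_input")
  }
  missing_cols <- setdiff(canonical_steps(), names(df))
  if (length(missing_cols) > 0L) {
    ss_stop(sprintf("incomplete table: missing step column(s) %s",
                    paste(missing_cols, collapse = ", ")), "incomplete_table")
  }
  tab <- property_table(df, descriptors = descriptors, provenance = path)
  tab
}

#' @rdname load_table
#' @param table a `property_table`.
#' @export
write_table <- function(table, path) {
  stopifnot(inherits(table, "property_table"))
  v <- table$values
  fmt <- matrix(sprintf("%.12g", v), nrow = nrow(v), dimnames = dimnames(v))
  out <- data.frame(parameter = rownames(v), fmt, check.names = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# splicescape dinucleotide property table (TSV; '.' decimal)", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The shipped default property table
#'
#' Loads the package's built-in table of all 31 default parameters. Its
#' values are synthetic representative B-DNA figures (assembled to be in the
#' right range and with plausible step-to-step contrast for each parameter
#' class); they are a stand-in default so the pipeline runs out of the box,
#' not measurements from any particular crystal-structure set. Analyses
#' intended to support structural conclusions should supply a table built
#' from real observations via [build_table()] or [load_table()].
#'
#' @return A `property_table` of 31 parameters.
#' @export
default_property_table <- function() {
  path <- system.file("extdata", "property_table_synthetic_default.tsv",
                      package = "splicescape", mustWork = TRUE)
  load_table(path)
}
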