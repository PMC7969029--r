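#' Scale a series for group plotting
#'
#' Centring-and-range scaling used to overlay parameters of different
#' units on one axis when plotting the two junction-behaviour groups:
#' `(x - mean(x)) / (max(x) - min(x))`. The output always has mean 0.
#'
#' @param values numeric vector; must not be constant.
#' @return numeric vector of the same length.
#' @export
#' @examples
#' scale_for_grouping(c(0, 1, 2))  # -0.5, 0, 0.5
scale_for_grouping <- function(values) {
  stopifnot(is.numeric(values), length(values) > 0L)
  rng <- range(values, na.rm = TRUE)
  if (rng[2] == rng[1]) ss_stop("degenerate range (max == min)", "degenerate_range")
  (values - mean(values, na.rm = TRUE)) / (rng[2] - rng[1])
}

avg_profile_matrix <- function(avg, positions) {
  stopifnot(all(c("parameter", "position", "mean") %in% names(avg)))
  params <- unique(avg$parameter)
  m <- matrix(NA_real_, nrow = length(params), ncol = length(positions),
              dimnames = list(params, positions))
  sel <- avg$position %in% positions
  a <- avg[sel, , drop = FALSE]
  m[cbind(match(a$parameter, params), match(a$position, positions))] <- a$mean
  if (anyNA(m)) {
    bad <- positions[apply(is.na(m), 2L, any)]
    ss_stop(sprintf("average profiles do not cover position(s): %s",
                    paste(bad, collapse = ", ")), "coverage")
  }
  m
}

#' Position-specific inter-parameter correlation matrix
#'
#' Pearson correlation between every pair of parameters over their average
#' profile values within a position window (default the 11 integer
#' positions -35..-25, the upstream shoulder of the junction signal).
#' Parameters constant within the window yield `NA` (undefined), not 0.
#'
#' @param avg long average-profile data.frame from [average_profiles()]
#'   (`parameter`, `position`, `mean`).
#' @param window integer `c(from, to)` position window (default
#'   `c(-35, -25)`).
#' @return symmetric correlation matrix of class `correlation_matrix` with
#'   unit diagonal (where defined) and the window in
#'   `attr(, "window")`.
#' @export
pairwise_position_correlation <- function(avg, window = c(-35L, -25L)) {
  positions <- range_to_positions(window)
  m <- avg_profile_matrix(avg, positions)
  constant <- apply(m, 1L, function(x) stats::sd(x) == 0)
  cc <- suppressWarnings(stats::cor(t(m)))
  cc[constant, ] <- NA_real_
  cc[, constant] <- NA_real_
  d <- diag(cc)
  d[!constant] <- 1
  diag(cc) <- d
  structure(cc, window = positions, class = c("correlation_matrix", "matrix"))
}

#' Default parameters excluded from junction-behaviour grouping
#'
#' Five parameters whose profiles match neither the rising nor the falling
#' pattern near position -25 and are left out of the two groups.
#'
#' @return character vector of parameter names.
#' @export
grouping_excluded_parameters <- function() {
  c("Y-Displacement", "Opening", "Delta", "Stacking-Energy",
    "Solvation-Energy")
}

#' Assign parameters to junction-behaviour groups
#'
#' Each parameter's average profile is scored by its direction of change
#' near position -25: `score = mean(profile over junction_window) -
#' mean(profile over baseline_window)`. Positive scores join group I
#' (values rise approaching the junction), negative scores group II
#' (values fall). Parameters in `excluded` are labelled `excluded`
#' regardless, and near-zero scores are labelled `excluded` with a
#' borderline flag.
#'
#' @param avg long average-profile data.frame (`parameter`, `position`,
#'   `mean`).
#' @param junction_window window operationalising "near -25" (default
#'   `c(-30, -20)`).
#' @param baseline_window exon-side reference window (default
#'   `c(-188, -100)`).
#' @param excluded parameters forced to `excluded`
#'   (default [grouping_excluded_parameters()]).
#' @param tol absolute score below which a parameter is borderline.
#' @return data.frame `parameter`, `score`, `group`
#'   (`group_I`/`group_II`/`excluded`), `borderline`.
#' @export
assign_groups <- function(avg, junction_window = c(-30L, -20L),
                          baseline_window = c(-188L, -100L),
                          excluded = grouping_excluded_parameters(),
                          tol = 1e-8) {
  jm <- avg_profile_matrix(avg, range_to_positions(junction_window))
  bm <- avg_profile_matrix(avg, range_to_positions(baseline_window))
  params <- rownames(jm)
  score <- rowMeans(jm) - rowMeans(bm[params, , drop = FALSE])
  borderline <- abs(score) < tol
  group <- ifelse(score > 0, "group_I", "group_II")
  group[borderline] <- "excluded"
  group[params %in% excluded] <- "excluded"
  data.frame(parameter = params, score = unname(score), group = group,
             borderline = borderline, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Export a correlation matrix as TSV (and optionally a heat plot)
#'
#' The TSV is lossless (12 significant digits, `NA` for undefined
#' entries); the plot is a best-effort ggplot2 tile heatmap with missing
#' entries drawn in grey.
#'
#' @param mat a `correlation_matrix`.
#' @param tsv output TSV path.
#' @param plot optional output image path (format by extension).
#' @return invisible list of written paths.
#' @export
heatmap_export <- function(mat, tsv, plot = NULL) {
  m <- unclass(mat)
  fmt <- matrix(sprintf("%.12g", m), nrow = nrow(m), dimnames = dimnames(m))
  df <- data.frame(parameter = rownames(m), fmt, check.names = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(plot)) {
    long <- data.frame(row = rep(rownames(mat), times = ncol(mat)),
                       col = rep(colnames(mat), each = nrow(mat)),
                       r = as.vector(unclass(mat)))
    long$row <- factor(long$row, levels = rownames(mat))
    long$col <- factor(long$col, levels = colnames(mat))
    g <- ggplot2::ggplot(long, ggplot2::aes(x = col, y = row, fill = r)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                    high = "#B2182B", limits = c(-1, 1),
                                    na.value = "grey80", name = "r") +
      ggplot2::labs(x = NULL, y = NULL) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                         vjust = 0.5,
                                                         hjust = 1))
    ggplot2::ggsave(plot, g, width = 8, height = 7, dpi = 150)
  }
  invisible(list(tsv = tsv, plot = plot))
}

#' Read back a correlation matrix written by [heatmap_export()]
#' @param tsv path to the TSV.
#' @return a `correlation_matrix`.
#' @export
read_correlation_tsv <- function(tsv) {
  df <- utils::read.delim(tsv, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$parameter
  storage.mode(m) <- "double"
  structure(m, class = c("correlation_matrix", "matrix"))
}
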