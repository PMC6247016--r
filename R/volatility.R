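# Control-chart / spaghetti ("volatility") statistics and plot
# specifications for a longitudinal metric: global mean with warning limits
# at 2 SD and control limits at 3 SD, per-(group,state) aggregates, and
# per-subject trajectories.

#' Volatility (control-chart) statistics for a longitudinal metric
#'
#' Computes the global mean and sample standard deviation of the metric over
#' all usable samples, warning limits at the mean +/- 2 SD and control
#' limits at the mean +/- 3 SD (always computed across all samples, not per
#' group), per-(group,state) aggregates (mean, SD, n) for the group-mean
#' lines, per-subject series for the spaghetti lines, and per-sample outlier
#' flags for values beyond either band.
#'
#' @inheritParams first_differences
#' @param group_column optional categorical column used to aggregate samples
#'   into group averages per state; when absent a single aggregate series
#'   over all subjects is produced.
#' @return An object of class `volatility_stats` with elements
#'   `global_mean`, `global_sd`, `warning_limits`, `control_limits`,
#'   `aggregates`, `spaghetti`, `flags`, `metric`, `group_column`.
#' @export
volatility_stats <- function(metadata, metric, group_column = NULL) {
  df <- longitudinal_frame(metadata, metric = metric)
  if (nrow(df) < 2L) {
    stop("volatility statistics require at least 2 samples (SD undefined)")
  }
  if (!is.null(group_column)) {
    if (!group_column %in% names(metadata)) {
      stop("group column '", group_column, "' not found in metadata")
    }
    df$group <- as.character(metadata[df$sample_id, group_column])
  } else {
    df$group <- "all"
  }
  m <- mean(df$value)
  s <- stats::sd(df$value)
  agg <- do.call(rbind, lapply(split(df, list(df$group, df$state), drop = TRUE),
    function(g) {
      data.frame(group = g$group[1L], state = g$state[1L],
                 mean = mean(g$value),
                 sd = if (nrow(g) > 1L) stats::sd(g$value) else NA_real_,
                 sem = if (nrow(g) > 1L) stats::sd(g$value) / sqrt(nrow(g)) else NA_real_,
                 n = nrow(g), stringsAsFactors = FALSE)
    }))
  agg <- agg[order(agg$group, agg$state), , drop = FALSE]
  rownames(agg) <- NULL
  flags <- data.frame(sample_id = df$sample_id, value = df$value,
                      beyond_warning = abs(df$value - m) > 2 * s,
                      beyond_control = abs(df$value - m) > 3 * s,
                      stringsAsFactors = FALSE)
  spag <- df[order(df$subject, df$state),
             c("sample_id", "subject", "state", "value", "group")]
  rownames(spag) <- NULL
  structure(list(global_mean = m, global_sd = s,
                 warning_limits = c(lower = m - 2 * s, upper = m + 2 * s),
                 control_limits = c(lower = m - 3 * s, upper = m + 3 * s),
                 aggregates = agg, spaghetti = spag, flags = flags,
                 metric = metric, group_column = group_column),
            class = "volatility_stats")
}

#' @export
print.volatility_stats <- function(x, ...) {
  cat(sprintf("volatility_stats for '%s': mean %.4g, SD %.4g\n",
              x$metric, x$global_mean, x$global_sd))
  cat(sprintf("  warning limits (2 SD): [%.4g, %.4g]\n",
              x$warning_limits[["lower"]], x$warning_limits[["upper"]]))
  cat(sprintf("  control limits (3 SD): [%.4g, %.4g]\n",
              x$control_limits[["lower"]], x$control_limits[["upper"]]))
  cat(sprintf("  %d samples, %d beyond warning, %d beyond control\n",
              nrow(x$flags), sum(x$flags$beyond_warning),
              sum(x$flags$beyond_control)))
  invisible(x)
}

#' Declarative plot specification for a volatility chart
#'
#' Builds a JSON-serializable description of the chart: one mean-line layer
#' per group with error bars (+/- SD by default, SEM via
#' `options$error_bars = "sem"`), one faded spaghetti layer per subject,
#' and five horizontal rules — the global mean (solid), the two warning
#' limits (dotted), and the two control limits (dashed). The spec carries
#' the metric and grouping fields so a downstream interactive viewer can
#' re-bind them.
#'
#' @param stats a [volatility_stats] object.
#' @param options list of formatting options: `error_bars` (`"sd"` or
#'   `"sem"`), `title`.
#' @return A list of class `volatility_plot_spec`.
#' @export
volatility_plot_spec <- function(stats, options = list()) {
  stopifnot(inherits(stats, "volatility_stats"))
  error_bars <- if (identical(options$error_bars, "sem")) "sem" else "sd"
  mean_layers <- lapply(split(stats$aggregates, stats$aggregates$group),
    function(g) {
      list(type = "mean_line", group = g$group[1L],
           error_bars = error_bars,
           points = lapply(seq_len(nrow(g)), function(i) {
             list(state = g$state[i], mean = g$mean[i],
                  error = if (error_bars == "sd") g$sd[i] else g$sem[i],
                  n = g$n[i])
           }))
    })
  spaghetti_layers <- lapply(split(stats$spaghetti, stats$spaghetti$subject),
    function(s) {
      list(type = "spaghetti", subject = s$subject[1L], group = s$group[1L],
           points = lapply(seq_len(nrow(s)), function(i) {
             list(state = s$state[i], value = s$value[i],
                  sample_id = s$sample_id[i])
           }))
    })
  rules <- list(
    list(type = "rule", role = "mean", stroke = "solid",
         y = stats$global_mean),
    list(type = "rule", role = "warning_lower", stroke = "dotted",
         y = stats$warning_limits[["lower"]]),
    list(type = "rule", role = "warning_upper", stroke = "dotted",
         y = stats$warning_limits[["upper"]]),
    list(type = "rule", role = "control_lower", stroke = "dashed",
         y = stats$control_limits[["lower"]]),
    list(type = "rule", role = "control_upper", stroke = "dashed",
         y = stats$control_limits[["upper"]]))
  structure(list(chart = "volatility",
                 metric = stats$metric,
                 group_column = if (is.null(stats$group_column)) NA
                                else stats$group_column,
                 title = if (is.null(options$title)) stats$metric
                         else options$title,
                 mean_lines = unname(mean_layers),
                 spaghetti = unname(spaghetti_layers),
                 rules = rules),
            class = c("volatility_plot_spec", "list"))
}

#' Serialize a plot specification to JSON
#'
#' Deterministic output (fixed field order, 10 significant digits) so
#' identical inputs produce byte-identical files.
#'
#' @param spec a plot-spec list (e.g. from [volatility_plot_spec()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plot_spec <- function(spec, path) {
  json <- jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = I(10),
                           pretty = TRUE, na = "null")
  writeLines(json, path, sep = "\n")
  invisible(path)
}

#' Render a volatility chart
#'
#' Static figure matching the plot spec's encoding: thick group-mean lines
#' with error bars, faded per-subject spaghetti lines, and horizontal rules
#' for the global mean (solid), warning limits (dotted), and control limits
#' (dashed).
#'
#' @param stats a [volatility_stats] object.
#' @param error_bars `"sd"` (default) or `"sem"`.
#' @return A ggplot object.
#' @export
volatility_plot <- function(stats, error_bars = c("sd", "sem")) {
  stopifnot(inherits(stats, "volatility_stats"))
  error_bars <- match.arg(error_bars)
  agg <- stats$aggregates
  agg$err <- if (error_bars == "sd") agg$sd else agg$sem
  ggplot2::ggplot() +
    ggplot2::geom_line(data = stats$spaghetti,
                       ggplot2::aes(x = .data$state, y = .data$value,
                                    group = .data$subject, color = .data$group),
                       alpha = 0.25, linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = stats$global_mean, linetype = "solid") +
    ggplot2::geom_hline(yintercept = unname(stats$warning_limits),
                        linetype = "dotted") +
    ggplot2::geom_hline(yintercept = unname(stats$control_limits),
                        linetype = "dashed") +
    ggplot2::geom_errorbar(data = agg,
                           ggplot2::aes(x = .data$state,
                                        ymin = .data$mean - .data$err,
                                        ymax = .data$mean + .data$err,
                                        color = .data$group),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::geom_line(data = agg,
                       ggplot2::aes(x = .data$state, y = .data$mean,
                                    color = .data$group),
                       linewidth = 1) +
    ggplot2::labs(x = "state", y = stats$metric, color = stats$group_column) +
    ggplot2::theme_minimal()
}
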