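# Within-subject temporal transforms: first differences, first distances,
# baseline-referenced variants, and static-reference comparisons.

#' @keywords internal
#' Assemble the per-sample longitudinal frame (sample, subject, state),
#' dropping samples with missing state or subject with a warning and applying
#' the replicate policy for duplicated (subject, state) pairs.
longitudinal_frame <- function(metadata, metric = NULL,
                               replicate_policy = c("error", "drop", "mean")) {
  stopifnot(inherits(metadata, "sample_metadata"))
  replicate_policy <- match.arg(replicate_policy)
  subject_column <- attr(metadata, "subject_column")
  if (is.null(subject_column)) {
    stop("longitudinal operations require a designated subject column")
  }
  state_column <- attr(metadata, "state_column")
  df <- data.frame(sample_id = rownames(metadata),
                   subject = as.character(metadata[[subject_column]]),
                   state = metadata[[state_column]],
                   stringsAsFactors = FALSE)
  if (!is.null(metric)) {
    if (!metric %in% names(metadata)) stop("metric column '", metric, "' not found")
    if (!is.numeric(metadata[[metric]])) {
      stop("metric column '", metric, "' is categorical; a numeric metric is required")
    }
    df$value <- metadata[[metric]]
  }
  drop <- is.na(df$state) | is.na(df$subject) | df$subject == ""
  if (!is.null(metric)) drop <- drop | is.na(df$value)
  if (any(drop)) {
    warning(sum(drop), " sample(s) with missing state/subject/metric excluded: ",
            paste(utils::head(df$sample_id[drop], 5L), collapse = ", "),
            if (sum(drop) > 5L) ", ..." else "")
    df <- df[!drop, , drop = FALSE]
  }
  key <- paste(df$subject, df$state, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    if (replicate_policy == "error") {
      stop("replicate samples for the same subject and state (",
           length(dups), " replicated subject/state pairs); set replicate_policy ",
           "to 'drop' or 'mean' to proceed")
    } else if (replicate_policy == "drop") {
      df <- df[!key %in% dups, , drop = FALSE]
    } else {  # mean: average the metric, keep the first sample ID as key
      if (is.null(metric)) {
        stop("replicate_policy 'mean' is only defined for metric differences, ",
             "not distance lookups")
      }
      agg <- stats::aggregate(value ~ subject + state, data = df, FUN = mean)
      first <- df[!duplicated(key), c("sample_id", "subject", "state")]
      df <- merge(first, agg, by = c("subject", "state"), sort = FALSE)
      df <- df[, c("sample_id", "subject", "state", "value")]
    }
  }
  df[order(df$subject, df$state), , drop = FALSE]
}

difference_series <- function(df, mode, reference = NULL) {
  rownames(df) <- NULL
  structure(df, mode = mode, reference = reference,
            class = c("difference_series", "data.frame"))
}

#' @export
print.difference_series <- function(x, ...) {
  cat(sprintf("difference_series (%s): %d deltas over %d subjects\n",
              attr(x, "mode"), nrow(x), length(unique(x$subject))))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' First differences of a longitudinal metric
#'
#' For each subject, samples are ordered by ascending state and the first
#' difference at state `t` is `Y_t - Y_{t-1}` — the magnitude of change
#' between successive time points. Differences are taken at the fixed
#' intervals of the study's state grid (the sorted set of states observed
#' anywhere in the metadata): when a subject is missing the sample at `t`
#' or at the grid state immediately before it, no difference is emitted at
#' `t`. Each difference is keyed by the later sample's ID so the output can
#' be merged back into the metadata and fed to the mixed-model and
#' volatility tools.
#'
#' @param metadata a [sample_metadata] with designated state and subject
#'   columns.
#' @param metric name of the numeric metadata column to difference.
#' @param replicate_policy what to do when a subject has several samples at
#'   one state: `"error"` (default), `"drop"` them all, or `"mean"` the
#'   metric.
#' @param baseline optional state; when given, differences are taken from
#'   the subject's sample at this state instead of the preceding sample
#'   (see [from_baseline()]).
#' @return A `difference_series` data.frame with columns `sample_id`,
#'   `subject`, `state`, `value`.
#' @export
first_differences <- function(metadata, metric,
                              replicate_policy = c("error", "drop", "mean"),
                              baseline = NULL) {
  if (!is.null(baseline)) {
    return(from_baseline(metadata, metric = metric, baseline_state = baseline,
                         replicate_policy = replicate_policy))
  }
  df <- longitudinal_frame(metadata, metric = metric,
                           replicate_policy = replicate_policy)
  out <- successive_deltas(df, function(cur, prev) cur$value - prev$value)
  difference_series(out, mode = "successive",
                    reference = list(metric = metric))
}

# Per subject, deltas between adjacent states of the study's state grid
# (the sorted set of states observed anywhere in the metadata): the delta
# at state t exists only when the subject was also observed at the grid
# state immediately before t — a missing sample at t or t-1 means no delta
# at t. delta_fun receives the later and earlier one-row frames.
successive_deltas <- function(df, delta_fun) {
  grid <- sort(unique(df$state))
  pieces <- lapply(split(df, df$subject), function(sub) {
    if (nrow(sub) < 2L) {
      warning("subject '", sub$subject[1L],
              "' has fewer than 2 usable samples; no deltas emitted")
      return(NULL)
    }
    pos <- match(sub$state, grid)
    idx <- which(diff(pos) == 1L)  # pairs adjacent on the state grid
    if (!length(idx)) return(NULL)
    data.frame(sample_id = sub$sample_id[idx + 1L],
               subject = sub$subject[idx + 1L],
               state = sub$state[idx + 1L],
               value = vapply(idx, function(i) {
                 delta_fun(sub[i + 1L, ], sub[i, ])
               }, numeric(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(sample_id = character(), subject = character(),
                      state = numeric(), value = numeric())
  }
  out
}

#' First distances between a subject's successive samples
#'
#' Reads, for each subject and each pair of successive observed states, the
#' beta-diversity distance between the two samples from a precomputed
#' distance matrix. The same gap rule as [first_differences()] applies, and
#' all deltas are nonnegative. Samples absent from the distance matrix are
#' dropped with a warning.
#'
#' @param dm a [distance_matrix] covering the samples.
#' @inheritParams first_differences
#' @return A `difference_series` data.frame.
#' @export
first_distances <- function(dm, metadata,
                            replicate_policy = c("error", "drop"),
                            baseline = NULL) {
  stopifnot(inherits(dm, "distance_matrix"))
  replicate_policy <- match.arg(replicate_policy)
  if (!is.null(baseline)) {
    return(from_baseline(metadata, dm = dm, baseline_state = baseline,
                         replicate_policy = replicate_policy))
  }
  df <- longitudinal_frame(metadata, replicate_policy = replicate_policy)
  df <- restrict_to_dm(df, dm)
  usable <- table(df$subject)
  if (!any(usable >= 2L)) {
    stop("no subject has 2 or more samples present in the distance matrix")
  }
  out <- successive_deltas(df, function(cur, prev) {
    dm[cur$sample_id, prev$sample_id]
  })
  difference_series(out, mode = "successive", reference = list(distance = TRUE))
}

restrict_to_dm <- function(df, dm) {
  missing <- !df$sample_id %in% rownames(dm)
  if (any(missing)) {
    warning(sum(missing), " sample(s) absent from the distance matrix dropped: ",
            paste(utils::head(df$sample_id[missing], 5L), collapse = ", "),
            if (sum(missing) > 5L) ", ..." else "")
    df <- df[!missing, , drop = FALSE]
  }
  df
}

#' Differences or distances from a baseline state
#'
#' Computes, for each subject possessing a sample at `baseline_state`, the
#' change at every other observed state relative to that static point:
#' `Y_t - Y_baseline` in metric mode, or the distance between the sample at
#' `t` and the baseline sample in distance mode. No delta is emitted at the
#' baseline state itself; subjects lacking the baseline sample are excluded
#' with a warning. Deltas are keyed by the moving (non-baseline) sample's ID.
#'
#' @inheritParams first_distances
#' @param metric metric column name (metric mode); exactly one of `metric`
#'   and `dm` must be supplied.
#' @param baseline_state the state used as the static reference point.
#' @return A `difference_series` data.frame.
#' @export
from_baseline <- function(metadata, metric = NULL, dm = NULL, baseline_state,
                          replicate_policy = c("error", "drop", "mean")) {
  if (is.null(metric) == is.null(dm)) {
    stop("supply exactly one of 'metric' (differences) or 'dm' (distances)")
  }
  replicate_policy <- replicate_policy[1L]
  if (!is.null(dm)) {
    stopifnot(inherits(dm, "distance_matrix"))
    if (identical(replicate_policy, "mean")) {
      stop("replicate_policy 'mean' is only defined for metric differences")
    }
  }
  df <- longitudinal_frame(metadata, metric = metric,
                           replicate_policy = replicate_policy)
  if (!is.null(dm)) df <- restrict_to_dm(df, dm)
  if (!any(df$state == baseline_state)) {
    stop("baseline state ", baseline_state, " observed for no subject")
  }
  pieces <- lapply(split(df, df$subject), function(sub) {
    at_base <- sub$state == baseline_state
    if (!any(at_base)) {
      warning("subject '", sub$subject[1L], "' lacks a sample at baseline state ",
              baseline_state, "; excluded")
      return(NULL)
    }
    base <- sub[which(at_base)[1L], ]
    rest <- sub[!at_base, , drop = FALSE]
    if (!nrow(rest)) return(NULL)
    value <- if (is.null(dm)) rest$value - base$value
             else dm[rest$sample_id, base$sample_id]
    data.frame(sample_id = rest$sample_id, subject = rest$subject,
               state = rest$state, value = as.numeric(value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(sample_id = character(), subject = character(),
                      state = numeric(), value = numeric())
  }
  difference_series(out, mode = "baseline-state",
                    reference = list(baseline_state = baseline_state,
                                     metric = metric,
                                     distance = !is.null(dm)))
}

#' Distances from a static reference sample
#'
#' Tracks longitudinal change relative to a separate, nonlongitudinal
#' reference sample linked per subject (for example, each child's samples
#' against their mother's sample). `reference_column` must name a metadata
#' column giving the reference sample ID for each sample (constant within a
#' subject). Subjects whose reference is missing or absent from the distance
#' matrix are excluded with a warning; if all are excluded this is an error.
#'
#' @inheritParams first_distances
#' @param reference_column metadata column holding the reference sample ID.
#' @return A `difference_series` data.frame with one delta per observed
#'   state per retained subject.
#' @export
from_static_reference <- function(dm, metadata, reference_column,
                                  replicate_policy = c("error", "drop")) {
  stopifnot(inherits(dm, "distance_matrix"))
  replicate_policy <- replicate_policy[1L]
  if (!reference_column %in% names(metadata)) {
    stop("reference column '", reference_column, "' not found in metadata")
  }
  df <- longitudinal_frame(metadata, replicate_policy = replicate_policy)
  refs <- as.character(metadata[df$sample_id, reference_column])
  df$reference <- refs
  df <- restrict_to_dm(df, dm)
  pieces <- lapply(split(df, df$subject), function(sub) {
    ref <- unique(sub$reference[!is.na(sub$reference) & sub$reference != ""])
    if (length(ref) != 1L || !ref %in% rownames(dm)) {
      warning("subject '", sub$subject[1L], "' has ",
              if (!length(ref)) "no reference sample"
              else if (length(ref) > 1L) "conflicting reference samples"
              else paste0("reference '", ref, "' absent from the distance matrix"),
              "; excluded")
      return(NULL)
    }
    data.frame(sample_id = sub$sample_id, subject = sub$subject,
               state = sub$state,
               value = as.numeric(dm[sub$sample_id, ref]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    stop("every subject was excluded: no usable reference samples in '",
         reference_column, "'")
  }
  difference_series(out, mode = "static-sample",
                    reference = list(reference_column = reference_column))
}

#' Write a difference series as a per-sample TSV
#'
#' Two columns, `sample-id` and `value`, keyed by the later/current sample
#' so the result can be joined back onto sample metadata.
#'
#' @param x a `difference_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_difference_series <- function(x, path) {
  stopifnot(inherits(x, "difference_series"))
  rows <- paste(x$sample_id, vapply(x$value, format_number, character(1)),
                sep = "\t")
  writeLines(c("sample-id\tvalue", rows), path, sep = "\n")
  invisible(path)
}

#' Merge a difference series into sample metadata as a new column
#'
#' @param metadata a [sample_metadata].
#' @param series a `difference_series`.
#' @param column name for the new numeric column.
#' @return The metadata with an added numeric column (NA for samples without
#'   a delta).
#' @export
merge_series <- function(metadata, series, column) {
  stopifnot(inherits(metadata, "sample_metadata"),
            inherits(series, "difference_series"))
  vals <- rep(NA_real_, nrow(metadata))
  idx <- match(series$sample_id, rownames(metadata))
  vals[idx[!is.na(idx)]] <- series$value[!is.na(idx)]
  df <- as.data.frame(metadata)
  df[[column]] <- vals
  types <- attr(metadata, "column_types")
  types[[column]] <- "numeric"
  sample_metadata(df, state_column = attr(metadata, "state_column"),
                  subject_column = attr(metadata, "subject_column"),
                  column_types = types)
}
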