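# Pre/post style paired difference and distance testing between two states,
# within subjects and between groups. Nonparametric tests are the default;
# parametric equivalents are available via a flag.

paired_frame <- function(metadata, state1, state2, metric = NULL,
                         group_column = NULL,
                         replicate_policy = "error") {
  if (identical(state1, state2)) stop("state1 and state2 must differ")
  df <- longitudinal_frame(metadata, metric = metric,
                           replicate_policy = replicate_policy)
  a <- df[df$state == state1, , drop = FALSE]
  b <- df[df$state == state2, , drop = FALSE]
  common <- intersect(a$subject, b$subject)
  if (!length(common)) {
    stop("no subject observed at both state ", state1, " and state ", state2)
  }
  a <- a[match(common, a$subject), , drop = FALSE]
  b <- b[match(common, b$subject), , drop = FALSE]
  out <- data.frame(subject = common,
                    sample1 = a$sample_id, sample2 = b$sample_id,
                    stringsAsFactors = FALSE)
  if (!is.null(metric)) {
    out$value1 <- a$value
    out$value2 <- b$value
  }
  if (!is.null(group_column)) {
    if (!group_column %in% names(metadata)) {
      stop("group column '", group_column, "' not found in metadata")
    }
    g1 <- as.character(metadata[a$sample_id, group_column])
    g2 <- as.character(metadata[b$sample_id, group_column])
    if (any(!is.na(g1) & !is.na(g2) & g1 != g2)) {
      warning("group label differs between a subject's two samples; ",
              "using the state1 label")
    }
    out$group <- g1
  } else {
    out$group <- "all"
  }
  out
}

# One-sample location test of paired values against zero. Zero differences
# are dropped before the signed-rank test (Wilcoxon's original treatment).
one_sample_test <- function(values, parametric) {
  n <- length(values)
  if (n < 2L) {
    return(list(statistic = NA_real_, p = NA_real_, n = n, n_zero_dropped = 0L,
                method = NA_character_,
                note = "not applicable: fewer than 2 paired subjects"))
  }
  if (parametric) {
    if (stats::sd(values) == 0) {
      return(list(statistic = NA_real_, p = NA_real_, n = n, n_zero_dropped = 0L,
                  method = "one-sample t-test",
                  note = "not applicable: zero variance"))
    }
    ht <- stats::t.test(values, mu = 0)
    return(list(statistic = unname(ht$statistic), p = ht$p.value, n = n,
                n_zero_dropped = 0L, method = "one-sample t-test", note = NA_character_))
  }
  nonzero <- values[values != 0]
  dropped <- n - length(nonzero)
  if (length(nonzero) < 1L || length(unique(values)) == 1L && dropped == n) {
    return(list(statistic = NA_real_, p = NA_real_, n = n, n_zero_dropped = dropped,
                method = "Wilcoxon signed-rank",
                note = "not applicable: all differences zero"))
  }
  ht <- suppressWarnings(stats::wilcox.test(nonzero, mu = 0, exact = FALSE,
                                            correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value, n = n,
       n_zero_dropped = dropped, method = "Wilcoxon signed-rank",
       note = NA_character_)
}

# Omnibus + pairwise comparison of a value across groups, BH-corrected.
between_group_tests <- function(values, groups, parametric) {
  groups <- factor(groups)
  lv <- levels(droplevels(groups))
  if (length(lv) < 2L) return(NULL)
  if (length(unique(values)) == 1L) {
    # all values tied: every statistic sits at its null center
    overall <- data.frame(method = if (parametric) "one-way ANOVA"
                                   else "Kruskal-Wallis",
                          statistic = 0, p = 1)
    pw <- do.call(rbind, lapply(utils::combn(lv, 2L, simplify = FALSE),
      function(pr) data.frame(group1 = pr[1L], group2 = pr[2L],
                              statistic = NA_real_, p = 1,
                              note = "all values tied")))
    pw$p_adj <- 1
    return(list(overall = overall, pairwise = pw,
                method_pairwise = if (parametric) "pairwise t-test (BH)"
                                  else "pairwise Mann-Whitney U (BH)"))
  }
  if (parametric) {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1L]]
    overall <- data.frame(method = "one-way ANOVA",
                          statistic = an[["F value"]][1L],
                          p = an[["Pr(>F)"]][1L])
  } else {
    ht <- stats::kruskal.test(values, groups)
    overall <- data.frame(method = "Kruskal-Wallis",
                          statistic = unname(ht$statistic), p = ht$p.value)
  }
  pairs <- utils::combn(lv, 2L, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    x <- values[groups == pr[1L]]
    y <- values[groups == pr[2L]]
    if (length(x) < 2L || length(y) < 2L) {
      return(data.frame(group1 = pr[1L], group2 = pr[2L],
                        statistic = NA_real_, p = NA_real_,
                        note = "not applicable: fewer than 2 paired subjects"))
    }
    ht <- if (parametric) stats::t.test(x, y)
          else suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    data.frame(group1 = pr[1L], group2 = pr[2L],
               statistic = unname(ht$statistic), p = ht$p.value,
               note = NA_character_)
  }))
  pw$p_adj <- stats::p.adjust(pw$p, method = "BH")
  list(overall = overall,
       pairwise = pw,
       method_pairwise = if (parametric) "pairwise t-test (BH)"
                         else "pairwise Mann-Whitney U (BH)")
}

paired_result <- function(per_subject, within, between, kind) {
  structure(list(per_subject = per_subject, within_group = within,
                 between_group = between, kind = kind),
            class = "paired_result")
}

#' @export
print.paired_result <- function(x, ...) {
  cat(sprintf("paired_result (%s): %d paired subjects\n", x$kind,
              nrow(x$per_subject)))
  cat("\nWithin-group tests:\n")
  print.data.frame(x$within_group)
  if (!is.null(x$between_group)) {
    cat("\nBetween-group test (", x$between_group$overall$method, "):\n", sep = "")
    print.data.frame(x$between_group$overall)
    cat("\nPairwise (", x$between_group$method_pairwise, "):\n", sep = "")
    print.data.frame(x$between_group$pairwise)
  }
  invisible(x)
}

#' Paired differences between two states
#'
#' For each subject observed at both `state1` and `state2`, computes the
#' paired difference `Y_state2 - Y_state1`, tests within each group whether
#' the median difference departs from zero (Wilcoxon signed-rank by default,
#' one-sample t-test when `parametric = TRUE`), and, when a group column is
#' given, compares the differences between groups (Kruskal-Wallis overall
#' plus pairwise Mann-Whitney U by default; one-way ANOVA plus pairwise
#' t-tests when parametric), with Benjamini-Hochberg correction of the
#' pairwise P values. All tests are two-sided.
#'
#' @inheritParams first_differences
#' @param state1,state2 the two states to pair (must differ).
#' @param group_column optional categorical metadata column for group
#'   comparisons.
#' @param parametric use parametric equivalents of the default
#'   nonparametric tests.
#' @return A `paired_result` with elements `per_subject`, `within_group`
#'   and `between_group`.
#' @export
pairwise_differences <- function(metadata, metric, state1, state2,
                                 group_column = NULL, parametric = FALSE,
                                 replicate_policy = "error") {
  pf <- paired_frame(metadata, state1, state2, metric = metric,
                     group_column = group_column,
                     replicate_policy = replicate_policy)
  pf$value <- pf$value2 - pf$value1
  finish_paired(pf, group_column, parametric, kind = "differences",
                within = TRUE)
}

#' Paired distances between two states
#'
#' For each subject observed at both states, looks up the distance between
#' the subject's two samples in a precomputed distance matrix and compares
#' these within-pair distances between groups as in
#' [pairwise_differences()]. Distances carry no sign, so no within-group
#' zero-centered test is performed.
#'
#' @inheritParams pairwise_differences
#' @param dm a [distance_matrix] containing both samples of every pair.
#' @return A `paired_result`.
#' @export
pairwise_distances <- function(dm, metadata, state1, state2,
                               group_column = NULL, parametric = FALSE,
                               replicate_policy = "error") {
  stopifnot(inherits(dm, "distance_matrix"))
  pf <- paired_frame(metadata, state1, state2, group_column = group_column,
                     replicate_policy = replicate_policy)
  present <- pf$sample1 %in% rownames(dm) & pf$sample2 %in% rownames(dm)
  if (!all(present)) {
    warning(sum(!present), " pair(s) with samples absent from the distance ",
            "matrix excluded")
    pf <- pf[present, , drop = FALSE]
  }
  if (!nrow(pf)) stop("no subject pair fully present in the distance matrix")
  pf$value <- vapply(seq_len(nrow(pf)), function(i) {
    dm[pf$sample1[i], pf$sample2[i]]
  }, numeric(1))
  finish_paired(pf, group_column, parametric, kind = "distances",
                within = FALSE)
}

finish_paired <- function(pf, group_column, parametric, kind, within) {
  within_df <- if (within) {
    do.call(rbind, lapply(split(pf, pf$group), function(g) {
      res <- one_sample_test(g$value, parametric)
      data.frame(group = g$group[1L], n = res$n,
                 n_zero_dropped = res$n_zero_dropped, method = res$method,
                 statistic = res$statistic, p = res$p, note = res$note,
                 stringsAsFactors = FALSE)
    }))
  } else {
    do.call(rbind, lapply(split(pf, pf$group), function(g) {
      data.frame(group = g$group[1L], n = nrow(g),
                 mean = mean(g$value), median = stats::median(g$value),
                 stringsAsFactors = FALSE)
    }))
  }
  rownames(within_df) <- NULL
  between <- if (!is.null(group_column)) {
    between_group_tests(pf$value, pf$group, parametric)
  }
  paired_result(pf, within_df, between, kind)
}

#' Boxplot of paired values by group
#'
#' @param result a `paired_result`.
#' @return A ggplot object: per-group boxplots of the paired differences or
#'   within-pair distances, with jittered per-subject points.
#' @export
paired_plot <- function(result) {
  stopifnot(inherits(result, "paired_result"))
  df <- result$per_subject
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL,
                  y = if (result$kind == "differences") "paired difference"
                      else "within-pair distance") +
    ggplot2::theme_minimal()
}
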