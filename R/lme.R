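# Linear mixed-effects modeling of a longitudinal metric: fixed effects,
# random intercepts and (optionally) random slopes on time, grouped by
# subject. Coefficients are reported with Wald Z-scores and two-tailed P
# values against the standard normal.

#' Specify a linear mixed-effects model
#'
#' Describes the model `y_ij = X'_ij beta + Z_ij b_i + e_ij`, where `y_ij`
#' is the j-th measurement on subject i, `X_ij` the fixed-effect covariates
#' (group columns, declared interactions, and time), `b_i` the per-subject
#' random effects (intercept, optionally a slope on time, with multivariate
#' normal distribution), and `e_ij` independent Gaussian noise.
#'
#' @param response name of the numeric metric column to model.
#' @param fixed_effects character vector of covariate column names (group,
#'   sex, ...), in the order they should appear; the state column is
#'   appended automatically as the final fixed effect.
#' @param interactions character vector of interaction terms such as
#'   `"delivery:diet"`.
#' @param state_column name of the numeric time column (defaults to the
#'   metadata's designated state column at fit time).
#' @param include_random_slope add a per-subject random slope on the state
#'   column (random intercepts are always included).
#' @param formula_override explicit fixed-effects formula string, passed
#'   through verbatim in place of the canonical construction.
#' @param method `"REML"` (default) or `"ML"`.
#' @return An object of class `lme_spec`.
#' @export
lme_spec <- function(response, fixed_effects = character(),
                     interactions = character(), state_column = NULL,
                     include_random_slope = FALSE, formula_override = NULL,
                     method = c("REML", "ML")) {
  structure(list(response = response, fixed_effects = fixed_effects,
                 interactions = interactions, state_column = state_column,
                 include_random_slope = include_random_slope,
                 formula_override = formula_override,
                 method = match.arg(method)),
            class = "lme_spec")
}

#' Canonical fixed-effects formula for a model specification
#'
#' Deterministic construction so runs are reproducible: intercept,
#' categorical main effects in the user-given order, declared interactions,
#' then time. A `formula_override` passes through verbatim.
#'
#' @param spec an [lme_spec].
#' @param state_column the time column name (used when the spec leaves it
#'   unset).
#' @return The fixed-effects formula as a string.
#' @export
lme_formula <- function(spec, state_column = spec$state_column) {
  stopifnot(inherits(spec, "lme_spec"))
  if (!is.null(spec$formula_override)) return(spec$formula_override)
  if (is.null(state_column)) stop("no state column specified for the model")
  terms <- c(spec$fixed_effects, spec$interactions, state_column)
  paste(spec$response, "~", paste(terms, collapse = " + "))
}

#' Fit a linear mixed-effects model to longitudinal metadata
#'
#' Fits the model described by `spec` with subject as the grouping factor,
#' by restricted maximum likelihood by default. Categorical fixed effects
#' are treatment-coded against their lexicographically first level and
#' labeled `name [T.level]`; each coefficient is reported with its
#' estimate, standard error, Wald Z-score, and two-tailed P value from the
#' standard normal. Random-effect (co)variances and the residual variance
#' are reported as four explicit quantities. A singular or non-converged
#' fit is returned with `converged = FALSE` and a warning recommending
#' dropping the random slope, not an error.
#'
#' @param metadata a [sample_metadata] with designated state and subject
#'   columns.
#' @param spec an [lme_spec].
#' @return An object of class `lme_result` with elements `fixed_effects`
#'   (term, estimate, se, z, p), `random_effects` (intercept variance,
#'   slope variance, intercept-slope covariance), `residual_variance`,
#'   `n_subjects`, `n_observations`, `converged`, `formula`, and the
#'   underlying lme4 `model`.
#' @export
fit_lme <- function(metadata, spec) {
  stopifnot(inherits(metadata, "sample_metadata"), inherits(spec, "lme_spec"))
  subject_column <- attr(metadata, "subject_column")
  if (is.null(subject_column)) stop("metadata has no designated subject column")
  state_column <- if (is.null(spec$state_column)) attr(metadata, "state_column")
                  else spec$state_column
  fixed <- lme_formula(spec, state_column)

  used <- setdiff(all.vars(stats::as.formula(fixed)), spec$response)
  unknown <- setdiff(c(spec$response, used), names(metadata))
  if (length(unknown)) {
    stop("unknown column(s) in model specification: ",
         paste(unknown, collapse = ", "))
  }
  df <- as.data.frame(metadata)
  df$.subject <- as.character(metadata[[subject_column]])
  keep <- stats::complete.cases(df[, c(spec$response, used, ".subject")])
  df <- df[keep, , drop = FALSE]
  for (col in used) {
    if (!is.numeric(df[[col]])) df[[col]] <- factor(df[[col]])
  }
  y <- df[[spec$response]]
  if (!is.numeric(y)) stop("response '", spec$response, "' must be numeric")
  if (stats::var(y) == 0) stop("response '", spec$response, "' is constant")
  obs_per_subject <- table(df$.subject)
  if (sum(obs_per_subject >= 2L) < 2L) {
    stop("need at least 2 subjects with at least 2 observations each")
  }

  random <- if (spec$include_random_slope) {
    sprintf("(1 + %s | .subject)", state_column)
  } else "(1 | .subject)"
  full <- stats::as.formula(paste(fixed, "+", random))

  messages <- character()
  fit <- withCallingHandlers(
    lme4::lmer(full, data = df, REML = identical(spec$method, "REML"),
               control = lme4::lmerControl(calc.derivs = TRUE)),
    warning = function(w) {
      messages <<- c(messages, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      messages <<- c(messages, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  singular <- lme4::isSingular(fit, tol = 1e-4)
  converged <- !singular && !any(grepl("converge", messages, ignore.case = TRUE))
  if (!converged) {
    warning("mixed-model fit is singular or did not converge; estimates are ",
            "returned with converged = FALSE. Consider dropping the random ",
            "slope (include_random_slope = FALSE).")
  }

  co <- summary(fit)$coefficients
  z <- co[, "Estimate"] / co[, "Std. Error"]
  fe <- data.frame(term = relabel_terms(rownames(co), df, used),
                   estimate = unname(co[, "Estimate"]),
                   se = unname(co[, "Std. Error"]),
                   z = unname(z),
                   p = unname(2 * stats::pnorm(-abs(z))),
                   stringsAsFactors = FALSE)
  if (is.null(spec$formula_override)) {
    # present coefficients in the canonical order (main effects, declared
    # interactions, then time), not lme4's interaction-last ordering
    canon <- c("(Intercept)", spec$fixed_effects, spec$interactions,
               state_column)
    src <- source_terms(rownames(co), df, used)
    key <- match(vapply(strsplit(src, ":", fixed = TRUE),
                        function(p) paste(sort(p), collapse = ":"),
                        character(1)),
                 vapply(strsplit(canon, ":", fixed = TRUE),
                        function(p) paste(sort(p), collapse = ":"),
                        character(1)))
    fe <- fe[order(key, seq_len(nrow(fe))), , drop = FALSE]
    rownames(fe) <- NULL
  }

  vc <- lme4::VarCorr(fit)[[".subject"]]
  var_int <- unname(vc["(Intercept)", "(Intercept)"])
  var_slope <- cov_is <- NA_real_
  if (spec$include_random_slope) {
    var_slope <- unname(vc[state_column, state_column])
    cov_is <- unname(vc["(Intercept)", state_column])
  }
  structure(list(fixed_effects = fe,
                 random_effects = c(intercept_variance = var_int,
                                    slope_variance = var_slope,
                                    intercept_slope_covariance = cov_is),
                 residual_variance = stats::sigma(fit)^2,
                 n_subjects = length(obs_per_subject),
                 n_observations = nrow(df),
                 converged = converged,
                 formula = deparse1(full),
                 method = spec$method,
                 model = fit),
            class = "lme_result")
}

# The model term each coefficient belongs to ("deliveryvaginal:dietfd" ->
# "delivery:diet").
source_terms <- function(terms, data, used) {
  cats <- used[vapply(used, function(v) is.factor(data[[v]]), logical(1))]
  lookup <- list()
  for (v in cats) {
    for (lv in levels(data[[v]])[-1L]) lookup[[paste0(v, lv)]] <- v
  }
  vapply(terms, function(term) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1L]]
    parts <- vapply(parts, function(p) {
      if (!is.null(lookup[[p]])) lookup[[p]] else p
    }, character(1))
    paste(parts, collapse = ":")
  }, character(1), USE.NAMES = FALSE)
}

# Map lme4 coefficient names ("deliveryvaginal", "a:b") to the
# treatment-coded table labels ("delivery [T.vaginal]").
relabel_terms <- function(terms, data, used) {
  cats <- used[vapply(used, function(v) is.factor(data[[v]]), logical(1))]
  lookup <- list()
  for (v in cats) {
    for (lv in levels(data[[v]])[-1L]) {
      lookup[[paste0(v, lv)]] <- sprintf("%s [T.%s]", v, lv)
    }
  }
  vapply(terms, function(term) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1L]]
    parts <- vapply(parts, function(p) {
      if (!is.null(lookup[[p]])) lookup[[p]] else p
    }, character(1))
    paste(parts, collapse = ":")
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.lme_result <- function(x, digits = 3, ...) {
  cat("Linear mixed-effects model (", x$method, "): ", x$formula, "\n", sep = "")
  cat(sprintf("%d observations over %d subjects; converged: %s\n\n",
              x$n_observations, x$n_subjects, x$converged))
  fe <- x$fixed_effects
  fe$p <- ifelse(fe$p < 0.001, "<0.001", format(round(fe$p, 3)))
  tab <- data.frame(Variable = fe$term,
                    Estimate = round(fe$estimate, digits),
                    SE = round(fe$se, digits),
                    `Z-score` = round(fe$z, digits),
                    `P value` = fe$p, check.names = FALSE)
  cat("Fixed effects:\n")
  print.data.frame(tab, row.names = FALSE)
  cat("\nRandom effects:\n")
  re <- x$random_effects
  cat(sprintf("  Intercept (subject ID)      %s\n", round(re[["intercept_variance"]], digits)))
  if (!is.na(re[["slope_variance"]])) {
    cat(sprintf("  Slope (change per state)    %s\n", round(re[["slope_variance"]], digits)))
    cat(sprintf("  Covariance (intercept, time) %s\n", round(re[["intercept_slope_covariance"]], digits)))
  }
  cat(sprintf("  Residual variance           %s\n", round(x$residual_variance, digits)))
  invisible(x)
}

#' Coefficient table of a mixed-model fit
#'
#' Returns the fit as one data.frame in the reporting layout: fixed-effect
#' rows (Estimate, SE, Z-score, P value) followed by the random-effect
#' variance rows (intercept variance, slope variance, intercept-slope
#' covariance) and the residual variance.
#'
#' @param result an `lme_result`.
#' @return A data.frame with columns `section`, `term`, `estimate`, `se`,
#'   `z`, `p`.
#' @export
lme_table <- function(result) {
  stopifnot(inherits(result, "lme_result"))
  fe <- cbind(section = "Fixed effects", result$fixed_effects)
  re <- result$random_effects
  rand <- data.frame(section = "Random effects",
                     term = c("Intercept (subject ID)", "Slope (change per state)",
                              "Covariance (intercept, time)", "Residual variance"),
                     estimate = c(re[["intercept_variance"]], re[["slope_variance"]],
                                  re[["intercept_slope_covariance"]],
                                  result$residual_variance),
                     se = NA_real_, z = NA_real_, p = NA_real_,
                     stringsAsFactors = FALSE)
  rbind(fe, rand)
}

#' Diagnostic plots for a mixed-model fit
#'
#' @param result an `lme_result`.
#' @return A ggplot object: residuals against fitted values.
#' @export
lme_plot <- function(result) {
  stopifnot(inherits(result, "lme_result"))
  df <- data.frame(fitted = stats::fitted(result$model),
                   residual = stats::residuals(result$model))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$residual)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "fitted", y = "residual") +
    ggplot2::theme_minimal()
}
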