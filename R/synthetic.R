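# Synthetic longitudinal cohort generator: sample metadata with a metric
# drawn from the mixed-effects generative model, a feature table with
# planted time-trending features, and a matching distance matrix. Everything
# is reproducible from the design's seed.

#' Describe a longitudinal cohort design
#'
#' @param n_subjects number of subjects.
#' @param states numeric time grid (at least 2 states).
#' @param groups named list of group columns; each element is a named
#'   probability vector over that column's levels (e.g.
#'   `list(delivery = c(cesarean = 0.5, vaginal = 0.5))`).
#' @param dropout_probability per-(subject, state) probability that the
#'   sample is missing.
#' @param seed integer seed for all randomness.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_subjects, states,
                          groups = list(delivery = c(cesarean = 0.5,
                                                     vaginal = 0.5)),
                          dropout_probability = 0, seed) {
  stopifnot(n_subjects >= 2L, length(states) >= 2L,
            dropout_probability >= 0, dropout_probability <= 1)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  for (g in groups) {
    stopifnot(all(g >= 0), abs(sum(g) - 1) < 1e-8, !is.null(names(g)))
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 states = sort(as.numeric(states)), groups = groups,
                 dropout_probability = dropout_probability,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' An ECAM-like cohort design
#'
#' A documented preset emulating a small early-life cohort: 43 subjects
#' sampled monthly from birth to 24 months, two delivery-mode groups, two
#' diet groups, and moderate missingness.
#'
#' @param seed integer seed.
#' @param dropout_probability per-(subject, state) missingness.
#' @return A [cohort_design].
#' @export
ecam_like_design <- function(seed, dropout_probability = 0.15) {
  cohort_design(n_subjects = 43L, states = 0:24,
                groups = list(delivery = c(cesarean = 0.35, vaginal = 0.65),
                              diet = c(bd = 0.5, fd = 0.5)),
                dropout_probability = dropout_probability, seed = seed)
}

#' Specify the generative effects of a synthetic cohort
#'
#' The metric is generated from the mixed-effects model
#' `y_ij = b0 + group effects + (b1 + group slope effects + s_i) * t +
#' u_i + e_ij`, with per-subject random intercepts `u_i` and slopes `s_i`
#' and Gaussian residuals. The feature table carries `n_planted` features
#' whose mean abundance trends monotonically with state plus
#' time-independent noise features, generated either as truncated-Gaussian
#' abundances (`feature_model = "gaussian"`) or as Dirichlet-multinomial
#' counts around state-dependent mean compositions
#' (`feature_model = "dirichlet"`, mimicking microbiome compositionality).
#'
#' @param fixed_intercept population intercept.
#' @param fixed_slope population slope on state.
#' @param group_intercept_effects named list: group column -> named vector
#'   of intercept shifts for non-reference levels.
#' @param group_slope_effects named list: group column -> named vector of
#'   slope shifts for non-reference levels.
#' @param random_intercept_sd,random_slope_sd,residual_sd standard
#'   deviations of the random effects and residual (>= 0).
#' @param n_features,n_planted feature-table dimensions; `n_planted`
#'   features trend with state, the rest are noise.
#' @param planted_effect size of each planted feature's mean change over
#'   the full state range, in multiples of the feature noise SD.
#' @param feature_model `"gaussian"` or `"dirichlet"`.
#' @param feature_noise_sd per-feature noise SD (gaussian model).
#' @param sequencing_depth total counts per sample (dirichlet model).
#' @param distance distance used for the generated matrix: `"euclidean"`
#'   (gaussian default) or `"jaccard"` (dirichlet default).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(fixed_intercept = 0, fixed_slope = 0,
                        group_intercept_effects = list(),
                        group_slope_effects = list(),
                        random_intercept_sd = 1, random_slope_sd = 0,
                        residual_sd = 0.5,
                        n_features = 0L, n_planted = 0L, planted_effect = 3,
                        feature_model = c("gaussian", "dirichlet"),
                        feature_noise_sd = 1, sequencing_depth = 5000L,
                        distance = NULL) {
  feature_model <- match.arg(feature_model)
  stopifnot(random_intercept_sd >= 0, random_slope_sd >= 0, residual_sd >= 0,
            n_planted <= n_features)
  if (is.null(distance)) {
    distance <- if (feature_model == "dirichlet") "jaccard" else "euclidean"
  }
  structure(list(fixed_intercept = fixed_intercept, fixed_slope = fixed_slope,
                 group_intercept_effects = group_intercept_effects,
                 group_slope_effects = group_slope_effects,
                 random_intercept_sd = random_intercept_sd,
                 random_slope_sd = random_slope_sd, residual_sd = residual_sd,
                 n_features = as.integer(n_features),
                 n_planted = as.integer(n_planted),
                 planted_effect = planted_effect,
                 feature_model = feature_model,
                 feature_noise_sd = feature_noise_sd,
                 sequencing_depth = as.integer(sequencing_depth),
                 distance = match.arg(distance, c("euclidean", "jaccard"))),
            class = "effect_spec")
}

#' Simulate a longitudinal cohort
#'
#' Generates sample metadata (subject, state, group columns, sex, and a
#' continuous metric `y` from the mixed-effects generative model), a
#' feature table with planted trending features, and a distance matrix over
#' the samples, all reproducible from the design seed.
#'
#' @param design a [cohort_design].
#' @param effects an [effect_spec].
#' @return A list with elements `metadata` ([sample_metadata]), `table`
#'   ([feature_table] or NULL when `n_features` is 0), `dm`
#'   ([distance_matrix] or NULL), and `truth` (planted parameters, random
#'   effects, and planted feature IDs).
#' @export
simulate_cohort <- function(design, effects = effect_spec()) {
  stopifnot(inherits(design, "cohort_design"), inherits(effects, "effect_spec"))
  with_seed(design$seed, {
    ns <- design$n_subjects
    subjects <- sprintf("S%03d", seq_len(ns))
    group_levels <- lapply(design$groups, function(p) {
      sample(names(p), ns, replace = TRUE, prob = p)
    })
    sex <- sample(c("female", "male"), ns, replace = TRUE)
    u <- stats::rnorm(ns, 0, effects$random_intercept_sd)
    s <- stats::rnorm(ns, 0, effects$random_slope_sd)

    grid <- expand.grid(subject_idx = seq_len(ns), state = design$states,
                        KEEP.OUT.ATTRS = FALSE)
    keep <- stats::runif(nrow(grid)) >= design$dropout_probability
    grid <- grid[keep, , drop = FALSE]
    grid <- grid[order(grid$subject_idx, grid$state), , drop = FALSE]
    i <- grid$subject_idx
    t <- grid$state

    intercept <- rep(effects$fixed_intercept, nrow(grid))
    slope <- rep(effects$fixed_slope, nrow(grid))
    for (col in names(design$groups)) {
      lev <- group_levels[[col]][i]
      ie <- effects$group_intercept_effects[[col]]
      if (!is.null(ie)) {
        hit <- lev %in% names(ie)
        intercept[hit] <- intercept[hit] + ie[lev[hit]]
      }
      se <- effects$group_slope_effects[[col]]
      if (!is.null(se)) {
        hit <- lev %in% names(se)
        slope[hit] <- slope[hit] + se[lev[hit]]
      }
    }
    y <- intercept + u[i] + (slope + s[i]) * t +
      stats::rnorm(nrow(grid), 0, effects$residual_sd)

    ids <- sprintf("%s.%g", subjects[i], t)
    md <- data.frame(subject = subjects[i], month = t, sex = sex[i],
                     y = y, stringsAsFactors = FALSE, row.names = ids)
    for (col in names(design$groups)) md[[col]] <- group_levels[[col]][i]
    metadata <- sample_metadata(md, state_column = "month",
                                subject_column = "subject")

    table <- dm <- NULL
    planted <- character()
    if (effects$n_features > 0L) {
      p <- effects$n_features
      feats <- sprintf("F%04d", seq_len(p))
      planted <- utils::head(feats, effects$n_planted)
      t_scaled <- (t - min(design$states)) /
        max(1e-12, diff(range(design$states)))
      if (effects$feature_model == "gaussian") {
        base <- stats::runif(p, 8, 12)
        slope_f <- numeric(p)
        if (effects$n_planted > 0L) {
          sgn <- rep_len(c(1, -1), effects$n_planted)
          slope_f[seq_len(effects$n_planted)] <-
            sgn * effects$planted_effect * effects$feature_noise_sd
        }
        mu <- outer(t_scaled, slope_f) +
          matrix(base, nrow(grid), p, byrow = TRUE)
        vals <- pmax(mu + matrix(stats::rnorm(nrow(grid) * p, 0,
                                              effects$feature_noise_sd),
                                 nrow(grid), p), 0)
      } else {
        alpha0 <- stats::rlnorm(p, meanlog = 0, sdlog = 1)
        trend <- numeric(p)
        if (effects$n_planted > 0L) {
          sgn <- rep_len(c(1, -1), effects$n_planted)
          trend[seq_len(effects$n_planted)] <- sgn * effects$planted_effect
        }
        vals <- t(vapply(seq_len(nrow(grid)), function(r) {
          alpha <- alpha0 * exp(trend * t_scaled[r])
          g <- stats::rgamma(p, shape = alpha)
          stats::rmultinom(1L, effects$sequencing_depth, g / sum(g))[, 1L]
        }, numeric(p)))
      }
      dimnames(vals) <- list(ids, feats)
      table <- feature_table(vals)
      dm <- if (effects$distance == "jaccard") jaccard_distances(table)
            else {
              m <- as.matrix(stats::dist(unclass(table)))
              dimnames(m) <- list(ids, ids)
              distance_matrix(m)
            }
    }
    list(metadata = metadata, table = table, dm = dm,
         truth = list(random_intercepts = stats::setNames(u, subjects),
                      random_slopes = stats::setNames(s, subjects),
                      group_levels = group_levels,
                      planted_features = planted,
                      effects = effects))
  })
}
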