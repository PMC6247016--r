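# In-code fixture builders shared across test files.

# Quick metadata from vectors; sample IDs auto-generated unless given.
make_md <- function(subject, state, ..., ids = NULL,
                    state_column = "month", subject_column = "subject") {
  df <- data.frame(subject = subject, stringsAsFactors = FALSE, ...)
  df[[state_column]] <- state
  if (is.null(ids)) ids <- sprintf("samp%03d", seq_len(nrow(df)))
  rownames(df) <- ids
  sample_metadata(df, state_column = state_column,
                  subject_column = subject_column)
}

# Random cohort layout with missingness: one row per retained
# (subject, state), metric drawn iid normal.
random_panel <- function(n_subjects, states, miss = 0.3, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(subject = sprintf("S%03d", seq_len(n_subjects)),
                      state = states, stringsAsFactors = FALSE)
  grid <- grid[runif(nrow(grid)) >= miss, , drop = FALSE]
  # every subject keeps at least one sample
  grid <- grid[order(grid$subject, grid$state), , drop = FALSE]
  grid$value <- rnorm(nrow(grid))
  grid$id <- sprintf("%s.t%g", grid$subject, grid$state)
  grid
}

panel_md <- function(panel) {
  make_md(panel$subject, panel$state, value = panel$value, ids = panel$id)
}

# Random symmetric hollow distance matrix over the panel's samples.
random_dm <- function(ids, seed = 1) {
  set.seed(seed)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  v <- runif(n * (n - 1) / 2)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  distance_matrix(m)
}

make_table <- function(values, samples = NULL, features = NULL) {
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(nrow(values)))
  if (is.null(features)) features <- sprintf("f%d", seq_len(ncol(values)))
  dimnames(values) <- list(samples, features)
  feature_table(values)
}
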