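test_that("first differences subtract successive observations per subject", {
  md <- make_md(rep("A", 3), c(0, 1, 2), value = c(5, 7, 6))
  fd <- first_differences(md, "value")
  expect_equal(fd$state, c(1, 2))
  expect_equal(fd$value, c(2, -1))
  expect_equal(fd$sample_id, rownames(md)[2:3])  # keyed by the later sample

  const <- make_md(rep("A", 4), 0:3, value = rep(3, 4))
  expect_equal(first_differences(const, "value")$value, rep(0, 3))

  cat_md <- make_md(rep("A", 3), 0:2, value = c("x", "y", "z"))
  expect_error(first_differences(cat_md, "value"), "categorical")

  single <- make_md(c("A", "A", "B"), c(0, 1, 0), value = 1:3)
  expect_warning(fd <- first_differences(single, "value"), "fewer than 2")
  expect_false("B" %in% fd$subject)
})

test_that("replicate samples at one state follow the declared policy", {
  md <- make_md(c("A", "A", "A"), c(0, 0, 1), value = c(1, 3, 5))
  expect_error(first_differences(md, "value"), "replicate")
  dropped <- suppressWarnings(
    first_differences(md, "value", replicate_policy = "drop"))
  expect_equal(nrow(dropped), 0L)
  averaged <- first_differences(md, "value", replicate_policy = "mean")
  expect_equal(averaged$value, 3)  # 5 - mean(1, 3)
  dm <- random_dm(rownames(md))
  expect_error(first_distances(dm, md, replicate_policy = "mean"))
})

test_that("first distances look up successive pairs in the distance matrix", {
  md <- make_md(c("A", "A"), c(2, 5))
  dm <- distance_matrix(matrix(c(0, 0.42, 0.42, 0), 2,
                               dimnames = list(rownames(md), rownames(md))))
  fd <- first_distances(dm, md)
  expect_equal(fd$value, 0.42)
  expect_equal(fd$state, 5)

  zero <- distance_matrix(matrix(0, 2, 2,
                                 dimnames = list(rownames(md), rownames(md))))
  expect_equal(first_distances(zero, md)$value, 0)

  # no subject with two samples present in the matrix is a hard error
  part <- distance_matrix(matrix(0, 1, 1,
                                 dimnames = list(rownames(md)[1], rownames(md)[1])))
  expect_error(suppressWarnings(first_distances(part, md)), "no subject")
})

test_that("transforms match brute-force oracles on random cohorts with gaps", {
  panel <- random_panel(200, 0:9, miss = 0.35, seed = 11)
  md <- panel_md(panel)
  fd <- suppressWarnings(first_differences(md, "value"))
  expect_identical(sort_series(fd), sort_series(oracle_first_differences(panel)))

  dm <- random_dm(panel$id, seed = 12)
  fdist <- suppressWarnings(first_distances(dm, md))
  expect_identical(sort_series(fdist),
                   sort_series(oracle_first_distances(panel, dm)))
  expect_true(all(fdist$value >= 0))

  fb <- suppressWarnings(from_baseline(md, metric = "value", baseline_state = 0))
  expect_identical(sort_series(fb), sort_series(oracle_from_baseline(panel, 0)))
  fbd <- suppressWarnings(from_baseline(md, dm = dm, baseline_state = 0))
  expect_identical(sort_series(fbd),
                   sort_series(oracle_from_baseline(panel, 0, dm)))
  expect_false(any(fb$state == 0))  # no delta at the baseline state itself
})

test_that("baseline mode requires an observed baseline and drops lacking subjects", {
  md <- make_md(c("A", "A", "A", "B", "B"), c(0, 1, 2, 1, 2),
                value = c(5, 7, 6, 1, 4))
  fb <- suppressWarnings(from_baseline(md, metric = "value", baseline_state = 0))
  expect_equal(fb$value, c(2, 1))
  expect_false("B" %in% fb$subject)  # B lacks the baseline sample
  expect_error(from_baseline(md, metric = "value", baseline_state = 99),
               "observed for no subject")
})

test_that("static-reference distances track each subject against its linked sample", {
  ids <- c("c1.0", "c1.1", "c1.2", "mom1")
  md <- make_md(c("C1", "C1", "C1", "M1"), c(0, 1, 2, 0),
                mother = c("mom1", "mom1", "mom1", NA), ids = ids)
  m <- matrix(0, 4, 4, dimnames = list(ids, ids))
  m["c1.0", "mom1"] <- m["mom1", "c1.0"] <- 0.9
  m["c1.1", "mom1"] <- m["mom1", "c1.1"] <- 0.8
  m["c1.2", "mom1"] <- m["mom1", "c1.2"] <- 0.7
  m["c1.0", "c1.1"] <- m["c1.1", "c1.0"] <- 0.1
  dm <- distance_matrix(m)
  sr <- suppressWarnings(from_static_reference(dm, md, "mother"))
  got <- sr[sr$subject == "C1", ]
  expect_equal(got$value, c(0.9, 0.8, 0.7))

  # a subject with an empty reference is excluded with a warning
  expect_warning(from_static_reference(dm, md, "mother"), "M1")

  # random family structure against the oracle
  panel <- random_panel(40, 0:5, miss = 0.3, seed = 21)
  moms <- sprintf("mom%02d", seq_along(unique(panel$subject)))
  names(moms) <- unique(panel$subject)
  refs <- as.list(moms)
  refs[[3]] <- NA  # one family without a usable reference
  md2 <- make_md(panel$subject, panel$state,
                 mother = unname(unlist(refs)[panel$subject]), ids = panel$id)
  dm2 <- random_dm(c(panel$id, unname(moms[!is.na(unlist(refs))])), seed = 22)
  sr2 <- suppressWarnings(from_static_reference(dm2, md2, "mother"))
  expect_identical(sort_series(sr2),
                   sort_series(oracle_static_reference(panel, refs, dm2)))
})

test_that("difference-series identities hold on gap-free subjects", {
  set.seed(5)
  md <- make_md(rep(sprintf("S%d", 1:20), each = 6), rep(0:5, 20),
                value = rnorm(120))
  fd <- first_differences(md, "value")
  # telescoping: per-subject deltas sum to last - first
  for (s in sprintf("S%d", 1:5)) {
    vals <- md$value[md$subject == s][order(md$month[md$subject == s])]
    expect_equal(sum(fd$value[fd$subject == s]),
                 vals[length(vals)] - vals[1])
  }
  # sign symmetry under metric negation
  md_neg <- md
  md_neg$value <- -md_neg$value
  expect_equal(first_differences(md_neg, "value")$value, -fd$value)
  # baseline at the first state equals the cumulative sum of deltas
  fb <- from_baseline(md, metric = "value", baseline_state = 0)
  for (s in sprintf("S%d", 1:5)) {
    expect_equal(fb$value[fb$subject == s],
                 cumsum(fd$value[fd$subject == s]))
  }
  # no invented samples
  expect_true(all(fd$sample_id %in% rownames(md)))
})

test_that("difference series export and merge back into metadata", {
  md <- make_md(rep("A", 3), 0:2, value = c(1, 4, 9))
  fd <- first_differences(md, "value")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_difference_series(fd, path)
  lines <- readLines(path)
  expect_equal(lines[1], "sample-id\tvalue")
  expect_equal(length(lines), 3L)
  merged <- merge_series(md, fd, "delta")
  expect_equal(merged$delta, c(NA, 3, 5))
})
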