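make_trait_df <- function(values_by_trait, ids = NULL) {
  n <- length(values_by_trait[[1]])
  ids <- ids %||% sprintf("acc%02d", seq_len(n))
  df <- as.data.frame(stats::setNames(
    lapply(trait_names(), function(tr) values_by_trait[[tr]] %||% runif(n)),
    trait_names()))
  cbind(accession_id = ids, df)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("summarize_traits computes mean, population sd and CV%", {
  set.seed(47)
  df <- make_trait_df(list(count = c(1, 2, 3), height = c(5, 5, 5)))
  s <- summarize_traits(as_trait_matrix(df))
  row_count <- s[s$trait == "count", ]
  expect_equal(row_count$mean, 2)
  expect_equal(row_count$sd, sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(row_count$cv_percent, 100 * sqrt(2 / 3) / 2, tolerance = 1e-6)
  row_h <- s[s$trait == "height", ]
  expect_equal(c(row_h$sd, row_h$cv_percent), c(0, 0))
  # single accession: mean = value, sd = 0
  one <- summarize_traits(as_trait_matrix(make_trait_df(list(count = 7))))
  expect_equal(one[one$trait == "count", c("mean", "sd")],
               data.frame(mean = 7, sd = 0), ignore_attr = TRUE)
})

test_that("zscore_filter removes exactly the stated outlier one pass at a time", {
  set.seed(53)
  vals <- c(rep(10, 19), 110)
  df <- make_trait_df(list(count = vals))
  res <- zscore_filter(as_trait_matrix(df))
  expect_equal(nrow(res$removals[res$removals$trait == "count", ]), 1L)
  hit <- res$removals[res$removals$trait == "count", ]
  expect_equal(hit$value, 110)
  expect_equal(hit$z, 95 / sqrt(9500 / 20), tolerance = 1e-9) # ~4.36
  expect_equal(sum(is.na(res$filtered$values[, "count"])), 1L)

  # all 10s survive: their |z| ~ 0.23
  expect_true(all(res$filtered$values[1:19, "count"] == 10))
})

test_that("zscore_filter is guarded and monotone in the threshold", {
  set.seed(59)
  const <- make_trait_df(list(count = rep(4, 10)))
  res <- zscore_filter(as_trait_matrix(const))
  expect_equal(nrow(res$removals), 0L)

  # max |z| below the threshold: nothing removed
  x <- c(rep(0, 9), 3.9) # population z of the 3.9 is < 4 by construction
  z_max <- abs(3.9 - mean(x)) / sqrt(mean((x - mean(x))^2))
  stopifnot(z_max < 4)
  res2 <- zscore_filter(as_trait_matrix(make_trait_df(list(count = x))))
  expect_equal(nrow(res2$removals[res2$removals$trait == "count", ]), 0L)

  df <- make_trait_df(list(count = c(rnorm(30), 8, -9)))
  tm <- as_trait_matrix(df)
  n_rm <- vapply(c(1, 2, 3, 4, 6), function(z)
    nrow(zscore_filter(tm, stats_config(z_threshold = z))$removals),
    numeric(1))
  expect_true(all(diff(n_rm) <= 0))

  # one-pass semantics: survivors' |z| under the ORIGINAL mean/sd stay
  # below the threshold
  for (k in 1:20) {
    vals <- rnorm(25, 50, 10)^2
    tm2 <- as_trait_matrix(make_trait_df(list(count = vals)))
    res3 <- zscore_filter(tm2, stats_config(z_threshold = 2))
    mu <- mean(vals); s <- sqrt(mean((vals - mu)^2))
    surv <- res3$filtered$values[, "count"]
    surv <- surv[!is.na(surv)]
    expect_true(all(abs((surv - mu) / s) < 2))
  }
})

test_that("pearson_matrix is symmetric, unit-diagonal, pairwise-complete", {
  set.seed(61)
  n <- 20
  base <- rnorm(n)
  df <- make_trait_df(list(count = base, height = 2 * base + 3,
                           width = c(2, 1, 4, 3, rnorm(n - 4))))
  r <- pearson_matrix(as_trait_matrix(df))
  expect_equal(dim(r), c(24L, 24L))
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 24))
  expect_true(all(abs(r[!is.na(r)]) <= 1 + 1e-12))
  expect_equal(r["count", "height"], 1, tolerance = 1e-12)

  # hand-computed correlation on 4 points
  df4 <- make_trait_df(list(count = c(1, 2, 3, 4), height = c(2, 1, 4, 3)))
  r4 <- pearson_matrix(as_trait_matrix(df4))
  expect_equal(r4["count", "height"], 0.6, tolerance = 1e-12)

  # zero-variance trait and sparse pairs give missing cells
  df0 <- make_trait_df(list(count = rep(5, 4)))
  r0 <- pearson_matrix(as_trait_matrix(df0))
  expect_true(is.na(r0["count", "height"]))
  sparse <- make_trait_df(list(count = c(1, 2, NA, NA),
                               height = c(NA, NA, 1, 2)))
  rs <- pearson_matrix(as_trait_matrix(sparse))
  expect_true(is.na(rs["count", "height"]))
})

test_that("export_phenotypes writes Taxa-keyed CSV with NA at removed cells", {
  set.seed(67)
  df <- make_trait_df(list(count = c(rep(10, 19), 110)))
  tm <- as_trait_matrix(df)
  res <- zscore_filter(tm)
  path <- withr::local_tempfile(fileext = ".csv")
  export_phenotypes(res$filtered, path)
  txt <- readLines(path)
  expect_length(txt, 21L)
  expect_match(txt[1], "^Taxa,count,")
  expect_length(strsplit(txt[1], ",")[[1]], 25L)
  back <- utils::read.csv(path)
  expect_true(is.na(back$count[back$Taxa == "acc20"]))
  expect_equal(back$count[1:19], rep(10, 19))
  # round-trip of an unfiltered matrix is exact
  rt <- utils::read.csv({
    p2 <- withr::local_tempfile(fileext = ".csv"); export_phenotypes(tm, p2); p2
  })
  expect_equal(as.matrix(rt[, -1]), tm$values, ignore_attr = TRUE)
})

test_that("duplicate accession ids are rejected", {
  df <- make_trait_df(list(count = c(1, 2)), ids = c("a", "a"))
  expect_error(as_trait_matrix(df), "duplicate")
})
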