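test_that("read_survey loads and validates coded tables", {
  df <- data.frame(p1 = c(1, 2, 1), p2 = c(1, 1, 2),
                   contact = c(1, 4, 2), st1 = c(1, 5, 3),
                   st2 = c(5, 1, 2))
  tab <- toy_survey(df)
  expect_s3_class(tab, "survey_table")
  expect_equal(tab$n, 3L)
  expect_equal(ncol(tab$values), 5L)

  # out-of-range likert code names the cell
  bad <- df; bad$st1[2] <- 7
  expect_error(toy_survey(bad), "st1.*row 2.*7", ignore.case = TRUE)

  # missing codebook column
  expect_error(toy_survey(df[, -1]), "p1")
})

test_that("survey write -> read round-trips the synthetic generator output", {
  tab <- generate_survey_like(n = 60, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey(tab, path)
  back <- read_survey(path, tab$specs)
  expect_identical(back$values, tab$values)
  # and regeneration under the same seed is identical
  expect_identical(generate_survey_like(n = 60, seed = 5)$values, tab$values)
})

test_that("derive_outcome is an any-yes union and is monotone", {
  df <- data.frame(p1 = c(1, 1, 2, 1), p2 = c(1, 2, 2, NA),
                   contact = 1, st1 = 1, st2 = 1)
  tab <- toy_survey(df)
  out <- derive_outcome(tab, c("p1", "p2"))
  expect_equal(out, c(0L, 1L, 1L, NA_integer_))
  expect_error(derive_outcome(tab, character(0)), "at least one")

  # monotonicity: flipping any no to yes never flips 1 -> 0
  set.seed(3)
  for (r in 1:20) {
    v <- data.frame(p1 = sample(1:2, 6, TRUE), p2 = sample(1:2, 6, TRUE),
                    contact = 1, st1 = 1, st2 = 1)
    base <- derive_outcome(toy_survey(v), c("p1", "p2"))
    i <- sample(6, 1)
    v$p1[i] <- 2
    flipped <- derive_outcome(toy_survey(v), c("p1", "p2"))
    expect_true(all(flipped >= base))
  }
})

test_that("derive_outcome prevalence matches the closed-form union probability", {
  # independent items at 0.1 and 0.05 -> union prevalence 1 - 0.9*0.95 = 0.145
  set.seed(42)
  n <- 1000
  df <- data.frame(p1 = 1L + rbinom(n, 1, 0.10),
                   p2 = 1L + rbinom(n, 1, 0.05),
                   contact = 1, st1 = 1, st2 = 1)
  prev <- mean(derive_outcome(toy_survey(df), c("p1", "p2")))
  expect_lt(abs(prev - 0.145), 3 * sqrt(0.145 * 0.855 / n))
})

test_that("score_stereotypes reverse-codes and averages correctly", {
  df <- data.frame(p1 = 1, p2 = 1, contact = 1,
                   st1 = c(1, 1, 3), st2 = c(5, 1, NA))
  tab <- toy_survey(df)
  s <- score_stereotypes(tab, c("st1", "st2"))   # st2 reverse-coded via codebook
  expect_equal(s[1], 1)            # (1 + (6-5))/2
  expect_equal(s[2], 3)            # (1 + (6-1))/2
  expect_equal(s[3], 3)            # only st1 available
  # item order irrelevant; reverse-coding twice is identity
  expect_equal(score_stereotypes(tab, c("st2", "st1")), s)
  x <- c(1, 2, 3, 4, 5)
  expect_equal(6 - (6 - x), x)

  # direct-formula oracle on random items
  set.seed(9)
  df2 <- data.frame(p1 = 1, p2 = 1, contact = 1,
                    st1 = sample(1:5, 30, TRUE), st2 = sample(1:5, 30, TRUE))
  tab2 <- toy_survey(df2)
  expect_equal(score_stereotypes(tab2, c("st1", "st2")),
               (df2$st1 + (6 - df2$st2)) / 2)
})

test_that("cronbach_alpha matches the variance formula and its limits", {
  # two items with exactly zero sample covariance and equal variance -> 0
  a <- c(1, 1, 2, 2); b <- c(1, 2, 1, 2)
  expect_equal(cronbach_alpha(cbind(a, b)), 0)

  # k identical copies of one item -> 1
  z <- rnorm(10)
  expect_equal(cronbach_alpha(cbind(z, z, z)), 1)

  # 4x3 toy matrix vs independent covariance-matrix computation:
  # alpha = k/(k-1) * (1 - tr(C)/sum(C))
  m <- matrix(c(1, 2, 3, 4,
                2, 3, 2, 5,
                1, 3, 4, 4), ncol = 3)
  C <- cov(m)
  k <- ncol(m)
  expect_equal(cronbach_alpha(m), k / (k - 1) * (1 - sum(diag(C)) / sum(C)))
  expect_lte(cronbach_alpha(m), 1)

  # Spearman-Brown agreement for an exactly parallel (equal-variance)
  # two-item case
  set.seed(2)
  t_true <- rnorm(200)
  two <- scale(cbind(t_true + rnorm(200), t_true + rnorm(200)))
  r <- cor(two)[1, 2]
  expect_equal(cronbach_alpha(two), 2 * r / (1 + r), tolerance = 1e-10)

  expect_error(cronbach_alpha(cbind(rep(1, 5), rep(2, 5))), "constant")
})

test_that("binarize applies median splits and listwise deletion", {
  df <- data.frame(p1 = c(1, 1, 2, 1, 2), p2 = c(1, 2, 1, 1, 1),
                   contact = c(1, 1, 2, 3, 4), st1 = 1, st2 = 1)
  tab <- toy_survey(df)
  sv <- derive_outcome(tab, c("p1", "p2"))
  d <- binarize(tab, derived = list(sv = sv), quiet = TRUE)
  # ordinal (1,1,2,3,4): median 2 -> (0,0,0,1,1)
  expect_equal(unname(d$values[, "contact"]), c(0L, 0L, 0L, 1L, 1L))
  expect_equal(unname(d$values[, "sv"]), c(0L, 1L, 1L, 0L, 1L))
  expect_equal(unname(d$roles[c("contact", "sv")]), c("factor", "outcome"))

  # idempotent on already-binary data: rebinarizing the 0/1 sv column
  # through a binary spec leaves it unchanged
  expect_true(all(d$values %in% 0:1))

  # a respondent with missing analysis value is dropped and counted
  df2 <- df; df2$contact[2] <- NA
  tab2 <- toy_survey(df2)
  expect_message(d2 <- binarize(tab2, derived = list(sv = sv)),
                 "dropped 1")
  expect_equal(nrow(d2$values), 4L)

  # constant-after-split column is an estimation-blocking error
  df3 <- df; df3$contact <- 2
  expect_error(binarize(toy_survey(df3), derived = list(sv = sv),
                        quiet = TRUE), "contact")
})

test_that("binarized synthetic survey columns are non-degenerate", {
  tab <- generate_survey_like(n = 800, seed = 21)
  m <- default_survey_margins()
  sv_names <- names(m)[vapply(m, function(s) s$role == "outcome", logical(1))]
  items <- names(m)[vapply(m, function(s) s$role == "item", logical(1))]
  score <- score_stereotypes(tab, items)
  d <- binarize(tab, derived = list(stereotypes = score), quiet = TRUE)
  cm <- colMeans(d$values)
  expect_true(all(cm > 0 & cm < 1))
  expect_equal(sum(d$roles == "outcome"), 4L)
  expect_equal(sum(d$roles == "factor"), 11L)
})
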