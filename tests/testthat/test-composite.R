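make_scored <- function(vals, sample_id = "s1") {
  tibble::tibble(sample_id = sample_id,
                 pct_fps = vals, pct_present = vals, pct_discrepancy = vals,
                 pct_article = vals, pct_long = vals)
}

test_that("z-scoring gives mean 0, unit sample SD, and a zero-variance rule", {
  z <- zscore_categories(make_scored(c(0, 10)), group = NULL)
  expect_equal(z$z_fps, c(-1, 1) / sqrt(2))  # sample SD: z = -/+ 0.7071
  expect_equal(round(z$z_fps[1], 4), -0.7071)

  zc <- zscore_categories(make_scored(rep(4, 5)), group = NULL)
  expect_equal(zc$z_article, rep(0, 5))

  set.seed(1)
  zr <- zscore_categories(make_scored(runif(40)), group = NULL)
  expect_equal(mean(zr$z_long), 0)
  expect_equal(sd(zr$z_long), 1)
  expect_error(zscore_categories(make_scored(1), group = NULL), "fewer than 2")
})

test_that("z-scoring respects the per-sample population grouping", {
  d <- make_scored(c(1, 2, 3, 10, 20, 30),
                   sample_id = rep(c("a", "b"), each = 3))
  z <- zscore_categories(d, group = "sample_id")
  expect_equal(mean(z$z_fps[1:3]), 0)
  expect_equal(mean(z$z_fps[4:6]), 0)
  expect_equal(sd(z$z_fps[4:6]), 1)
})

test_that("composite reverse-codes fps/present/discrepancy and averages", {
  expect_equal(distancing_composite(c(1, 1, 1, -1, -1)), -1)
  expect_equal(distancing_composite(c(0, 0, 0, 0, 0)), 0)
  expect_equal(distancing_composite(c(-1, -1, -1, 1, 1)), 1)
})

test_that("composite is sign-equivariant and NA-propagating", {
  set.seed(2)
  z <- tibble::tibble(z_fps = rnorm(20), z_present = rnorm(20),
                      z_discrepancy = rnorm(20), z_article = rnorm(20),
                      z_long = rnorm(20))
  neg <- z
  neg[] <- lapply(neg, function(x) -x)
  expect_equal(distancing_composite(neg), -distancing_composite(z))
  z$z_long[3] <- NA
  expect_true(is.na(distancing_composite(z)[3]))
})

test_that("Cronbach's alpha matches closed forms and a covariance oracle", {
  x <- rnorm(50)
  expect_equal(cronbach_alpha(cbind(x, x, x))$alpha, 1)

  # two equal-variance items with exact sample correlation r: alpha = 2r/(1+r)
  set.seed(3)
  a <- as.numeric(scale(rnorm(200)))
  b <- as.numeric(scale(residuals(lm(rnorm(200) ~ a))))
  r <- 0.5
  y <- r * a + sqrt(1 - r^2) * b
  expect_equal(cronbach_alpha(cbind(a, y))$alpha, 2 * r / (1 + r),
               tolerance = 1e-10)
  expect_equal(round(2 * r / (1 + r), 4), 0.6667)

  # independent items: alpha near 0 at large n
  set.seed(4)
  ind <- matrix(rnorm(5 * 20000), ncol = 5)
  expect_lt(abs(cronbach_alpha(ind)$alpha), 0.05)

  # brute-force oracle from the covariance matrix on random 5-item matrices
  for (i in 1:5) {
    m <- matrix(rnorm(200), ncol = 5) %*% matrix(runif(25, -1, 1), 5)
    V <- cov(m)
    oracle <- 5 / 4 * (1 - sum(diag(V)) / sum(V))
    expect_equal(cronbach_alpha(m)$alpha, oracle, tolerance = 1e-10)
  }
  expect_error(cronbach_alpha(matrix(0, 10, 3)), "zero total variance")
})

test_that("aggregation computes the stated condition-mean differences", {
  d <- toy_scored()
  agg <- aggregate_participants(d, "study1")
  one <- d[d$participant_id == 1, ]
  cm <- tapply(one$abstractness, one$condition, mean)
  expect_equal(agg$delta_abstractness[agg$participant_id == 1],
               unname(cm["reappraise_negative"] - cm["look_negative"]))
  am <- tapply(one$affect, one$condition, mean)
  expect_equal(agg$reappraisal_success[agg$participant_id == 1],
               unname(am["look_negative"] - am["reappraise_negative"]))
  expect_equal(agg$emotional_reactivity[agg$participant_id == 1],
               unname(am["look_negative"] - am["look_neutral"]))
})

test_that("study 2 deltas are far minus close for language, close minus far for affect", {
  d <- toy_scored(conditions = c("close", "far"))
  d$domain <- "physical"
  agg <- aggregate_participants(d, "study2")
  one <- d[d$participant_id == 2, ]
  cm <- tapply(one$abstractness, one$condition, mean)
  am <- tapply(one$affect, one$condition, mean)
  expect_equal(agg$delta_abstractness[agg$participant_id == 2],
               unname(cm["far"] - cm["close"]))
  expect_equal(agg$delta_affect[agg$participant_id == 2],
               unname(am["close"] - am["far"]))
})

test_that("a participant missing a condition yields NA deltas with a warning", {
  d <- toy_scored()
  d <- d[!(d$participant_id == 3 & d$condition == "reappraise_negative"), ]
  expect_warning(agg <- aggregate_participants(d, "study1"), "missing")
  expect_true(is.na(agg$delta_abstractness[agg$participant_id == 3]))
  expect_false(anyNA(agg$delta_abstractness[agg$participant_id != 3]))
})

test_that("delta on condition means equals the mean of trialwise differences when balanced", {
  d <- toy_scored(n_participants = 6)
  agg <- aggregate_participants(d, "study1")
  trialwise <- sapply(1:6, function(p) {
    look <- d$abstractness[d$participant_id == p & d$condition == "look_negative"]
    reap <- d$abstractness[d$participant_id == p &
                             d$condition == "reappraise_negative"]
    mean(reap - look)
  })
  expect_equal(agg$delta_abstractness, trialwise)
})
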