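test_that("standardized regression recovers unit slope and the correlation identity", {
  d <- data.frame(x = rnorm(60))
  d$y <- d$x
  r <- suppressWarnings(standardized_regression(d, "y", "x"))
  expect_equal(r$beta, 1)
  expect_lt(r$p, 1e-12)

  set.seed(5)
  d2 <- data.frame(x = rnorm(100))
  d2$y <- 0.4 * d2$x + rnorm(100)
  r2 <- standardized_regression(d2, "y", "x")
  expect_equal(r2$beta, cor(d2$x, d2$y), tolerance = 1e-12)
  expect_true(r2$ci_low <= r2$beta && r2$beta <= r2$ci_high)
})

test_that("standardized regression is invariant to positive affine rescaling", {
  set.seed(6)
  d <- data.frame(x = rnorm(80), s = rep(c("a", "b"), 40))
  d$y <- 0.3 * d$x + rnorm(80)
  base <- standardized_regression(d, "y", "x", covariates = "s")
  d2 <- within(d, {x <- 3 * x + 7; y <- 0.5 * y - 2})
  resc <- standardized_regression(d2, "y", "x", covariates = "s")
  expect_equal(base$beta, resc$beta, tolerance = 1e-10)
  expect_equal(base$p, resc$p, tolerance = 1e-10)
})

test_that("a collinear design matrix fails naming the aliased column", {
  d <- data.frame(x = rnorm(30))
  d$x2 <- 2 * d$x
  d$y <- rnorm(30)
  expect_error(standardized_regression(d, "y", c("x", "x2")), "x2")
})

test_that("null predictors give CI-covered zero betas", {
  set.seed(7)
  cover <- replicate(200, {
    d <- data.frame(x = rnorm(50), y = rnorm(50))
    r <- standardized_regression(d, "y", "x")
    r$ci_low <= 0 && 0 <= r$ci_high
  })
  expect_gt(mean(cover), 0.90)
})

test_that("partial eta squared follows the F-df identity", {
  expect_equal(partial_eta_sq(0, 2, 100), 0)
  f <- c(1.3, 5.5, 40)
  eta <- partial_eta_sq(f, 2, 60)
  expect_equal(eta, f * 2 / (f * 2 + 60))
})

test_that("noncentral-F interval bounds invert the CDF at the stated tails", {
  ci <- eta_sq_ci(8.2, 3, 120)
  to_ncp <- function(eta) eta * (3 + 120 + 1) / (1 - eta)
  expect_equal(pf(8.2, 3, 120, ncp = to_ncp(ci[["high"]])), 0.05,
               tolerance = 1e-5)
  expect_equal(pf(8.2, 3, 120, ncp = to_ncp(ci[["low"]])), 0.95,
               tolerance = 1e-5)
  expect_equal(unname(eta_sq_ci(0, 2, 50)[["low"]]), 0)
  # below the central critical value the lower limit clips to 0
  expect_equal(unname(eta_sq_ci(1.0, 2, 200)[["low"]]), 0)
})

test_that("rm ANCOVA equals zero for identical conditions and t^2 for two", {
  d <- expand.grid(participant_id = 1:10, condition = c("a", "b", "c"))
  d$value <- rnorm(10)[d$participant_id]
  res <- rm_ancova(d, value = "value")
  expect_equal(res$f, 0)

  set.seed(8)
  d2 <- expand.grid(participant_id = 1:14, condition = c("a", "b"))
  d2$value <- rnorm(28) + 0.5 * (d2$condition == "b")
  res2 <- rm_ancova(d2, value = "value")
  wide <- matrix(d2$value, ncol = 2)
  tt <- t.test(wide[, 1], wide[, 2], paired = TRUE)
  expect_equal(res2$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res2$df2, unname(tt$parameter))
  # eta identity on the returned effect
  expect_equal(res2$eta_p_sq,
               res2$f * res2$df1 / (res2$f * res2$df1 + res2$df2))
})

test_that("rm ANCOVA matches a brute-force full-vs-reduced OLS oracle", {
  set.seed(9)
  for (i in 1:4) {
    n <- sample(8:12, 1)
    d <- expand.grid(participant_id = factor(1:n),
                     condition = factor(c("a", "b", "c")))
    d$value <- rnorm(nrow(d)) + as.numeric(d$condition) * 0.3
    res <- rm_ancova(d, value = "value")
    full <- lm(value ~ participant_id + condition, data = d)
    red <- lm(value ~ participant_id, data = d)
    oracle <- anova(red, full)
    expect_equal(res$f, oracle$F[2], tolerance = 1e-10)
    expect_equal(res$df1, oracle$Df[2])
    expect_equal(res$df2, oracle$Res.Df[2])
  }
})

test_that("mixed ANCOVA agrees with type III car::Anova on dummy-coded OLS", {
  skip_if_not_installed("car")
  set.seed(10)
  n <- 24
  d <- expand.grid(participant_id = factor(1:n),
                   distance = factor(c("close", "far")))
  dom <- factor(sample(c("physical", "social", "temporal"), n, replace = TRUE))
  samp <- factor(sample(c("s1", "s2"), n, replace = TRUE))
  d$domain <- dom[d$participant_id]
  d$sample_id <- samp[d$participant_id]
  d$value <- rnorm(nrow(d)) + 0.4 * (d$distance == "far") +
    0.3 * (d$distance == "far") * (d$domain == "physical")
  res <- mixed_ancova(d, covariate = "sample_id")

  # brute-force oracle: hand-built sum-to-zero columns, full vs reduced OLS
  zd <- ifelse(d$distance == "close", 1, -1)
  dm1 <- (d$domain == "physical") - (d$domain == "temporal")
  dm2 <- (d$domain == "social") - (d$domain == "temporal")
  full <- lm(d$value ~ d$participant_id + zd + I(zd * dm1) + I(zd * dm2))
  red_dist <- lm(d$value ~ d$participant_id + I(zd * dm1) + I(zd * dm2))
  red_int <- lm(d$value ~ d$participant_id + zd)
  o_dist <- anova(red_dist, full)
  o_int <- anova(red_int, full)
  expect_equal(res$f[res$effect == "distance"], o_dist$F[2], tolerance = 1e-8)
  expect_equal(res$df2[res$effect == "distance"], o_dist$Res.Df[2])
  expect_equal(res$f[res$effect == "distance:domain"], o_int$F[2],
               tolerance = 1e-8)

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  pm <- aggregate(value ~ participant_id + domain + sample_id, d, mean)
  between_fit <- lm(value ~ domain + sample_id, data = pm)
  cb <- car::Anova(between_fit, type = 3)
  expect_equal(res$f[res$effect == "domain"], cb["domain", "F value"],
               tolerance = 1e-8)
  expect_equal(res$df2[res$effect == "domain"], cb["Residuals", "Df"])
})

test_that("an injected far-shift in one domain produces a positive interaction F", {
  d <- expand.grid(participant_id = factor(1:18),
                   distance = factor(c("close", "far")))
  dom <- rep(c("physical", "social", "temporal"), each = 6)
  d$domain <- dom[as.integer(d$participant_id)]
  d$sample_id <- "s1"
  set.seed(11)
  d$value <- rnorm(nrow(d), sd = 0.2) +
    1.5 * (d$distance == "far" & d$domain == "physical")
  res <- mixed_ancova(d)
  expect_gt(res$f[res$effect == "distance:domain"], 0)
  expect_lt(res$p[res$effect == "distance:domain"], 0.05)
})

test_that("Morey within-subject intervals behave as specified", {
  d <- expand.grid(participant_id = 1:8, condition = c("a", "b"))
  d$value <- 3
  ci <- morey_within_ci(d, value = "value")
  expect_equal(ci$half_width, c(0, 0))

  # with two conditions the correction factor is sqrt(2)
  set.seed(12)
  d$value <- rnorm(16)
  ci2 <- morey_within_ci(d, value = "value")
  pm <- ave(d$value, d$participant_id)
  ynorm <- d$value - pm + mean(d$value)
  manual <- sapply(split(ynorm, d$condition), function(y) {
    qt(0.975, 7) * sd(y) / sqrt(8) * sqrt(2)
  })
  expect_equal(ci2$half_width, unname(manual))

  # large participant offsets: within-CI strictly narrower than naive CI
  set.seed(13)
  off <- rnorm(30, sd = 5)
  d3 <- expand.grid(participant_id = 1:30, condition = c("a", "b", "c"))
  d3$value <- off[d3$participant_id] + rnorm(90, sd = 0.3)
  ci3 <- morey_within_ci(d3, value = "value")
  naive <- sapply(split(d3$value, d3$condition), function(y) {
    qt(0.975, 29) * sd(y) / sqrt(30)
  })
  expect_true(all(ci3$half_width < naive))
  expect_error(morey_within_ci(d3[d3$condition == "a", ], value = "value"),
               "2 conditions")
})

test_that("reported rounding is half away from zero", {
  expect_equal(round_half_up(0.125), 0.13)
  expect_equal(round_half_up(-0.125), -0.13)
  expect_equal(round_half_up(2.8125, 4), 2.8125)
})
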