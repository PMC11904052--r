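test_that("the same config and seed reproduce the dataset exactly", {
  cfg <- study1_config(n_participants = 10, trials_per_condition = 3)
  a <- simulate_study1(cfg, seed = 21)
  b <- simulate_study1(cfg, seed = 21)
  expect_identical(a$trials, b$trials)
  expect_identical(a$truth$participants, b$truth$participants)
  c2 <- simulate_study1(cfg, seed = 22)
  expect_false(identical(a$trials$text, c2$trials$text))
})

test_that("scored output equals the by-construction trial profiles exactly", {
  for (s in c(31, 32)) {
    sim1 <- simulate_study1(study1_config(n_participants = 15,
                                          trials_per_condition = 3), seed = s)
    sc <- score_texts(sim1$trials$text)
    expect_equal(sc$abstractness, sim1$trial_profiles$abstractness)
    expect_equal(sc$pct_fps, sim1$trial_profiles$pct_fps)
    expect_equal(sc$pct_present, sim1$trial_profiles$pct_present)
    expect_equal(sc$n_classified, as.integer(sim1$trial_profiles$n_classified))

    sim2 <- simulate_study2(study2_config(n_participants = 15,
                                          trials_per_condition = 3), seed = s)
    sc2 <- score_texts(sim2$trials$text)
    expect_equal(sc2$abstractness, sim2$trial_profiles$abstractness)
    expect_equal(sc2$pct_long, sim2$trial_profiles$pct_long)
    expect_equal(sc2$pct_discrepancy, sim2$trial_profiles$pct_discrepancy)
  }
})

test_that("estimated emission rates converge to configured rates", {
  # ~10k trials with participant variation disabled so rates equal config
  cfg <- study1_config(n_participants = 56, trials_per_condition = 60,
                       propensity_spread = 0)
  cfg$rates$reappraise_negative <- cfg$rates$look_negative
  cfg$rates$look_neutral <- cfg$rates$look_negative
  sim <- simulate_study1(cfg, seed = 41)
  expect_gte(nrow(sim$trials), 10000)
  s <- score_texts(sim$trials$text)
  target <- cfg$rates$look_negative
  expect_lt(abs(mean(s$pct_fps) / 100 - target[["fps"]]), 0.01)
  expect_lt(abs(mean(s$pct_article) / 100 - target[["art"]]), 0.01)
  expect_lt(abs(mean(s$pct_discrepancy) / 100 - target[["disc"]]), 0.01)
  expect_lt(abs(mean(s$pct_present) / 100 - target[["pres"]]), 0.01)
})

test_that("full social-far suppression removes first-person pronouns", {
  cfg <- study2_config(n_participants = 12, trials_per_condition = 3,
                       fps_suppression = 1, propensity_spread = 0)
  sim <- simulate_study2(cfg, seed = 51)
  s <- score_texts(sim$trials$text)
  soc_far <- sim$trials$domain == "social" & sim$trials$condition == "far"
  expect_true(all(s$pct_fps[soc_far] == 0))
  expect_gt(mean(s$pct_fps[sim$trials$domain == "social" &
                             sim$trials$condition == "close"]), 0)
})

test_that("a tense-only temporal manipulation leaves abstractness flat", {
  cfg <- study2_config(n_participants = 120, trials_per_condition = 12)
  sim <- simulate_study2(cfg, seed = 61)
  s <- score_texts(sim$trials$text)
  tr <- dplyr::bind_cols(sim$trials[c("participant_id", "domain", "condition")],
                         s["abstractness"])
  cm <- tapply(tr$abstractness, list(tr$domain, tr$condition), mean,
               na.rm = TRUE)
  expect_lt(abs(cm["temporal", "far"] - cm["temporal", "close"]), 0.06)
  expect_gt(cm["physical", "far"] - cm["physical", "close"], 0.1)
  # temporal far trials shift to past tense even though abstractness is flat
  pres <- tapply(s$pct_present, list(sim$trials$domain, sim$trials$condition),
                 mean)
  expect_lt(pres["temporal", "far"], pres["temporal", "close"] / 2)
})

test_that("infeasible emission rates are rejected", {
  expect_error(study1_config(rates = list(
    look_negative = c(fps = .5, pron = .2, art = .2, disc = .1, pres = .2,
                      past = .1, adj = .1, noun = .1),
    reappraise_negative = c(fps = .1, pron = .1, art = .1, disc = .1,
                            pres = .1, past = .1, adj = .1, noun = .1),
    look_neutral = c(fps = .1, pron = .1, art = .1, disc = .1, pres = .1,
                     past = .1, adj = .1, noun = .1))),
    "exceed the word budget")
  expect_error(study1_config(lambda_dist = 0.9, lambda_abs = 0.9), "lambda")
})

test_that("matched passages score identically and differ in distancing", {
  s <- score_texts(passages$text)
  expect_equal(s$abstractness[1], s$abstractness[2])
  d <- cbind(passage = passages$passage, s, sample_id = "fixture")
  z <- zscore_categories(d, group = NULL)
  comp <- distancing_composite(z)
  expect_lt(comp[1], comp[2])  # low-distance passage scores lower
})
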