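test_that("single-category texts give 100 percent in that category", {
  p <- distancing_profile(annotate_text("the a an"))
  expect_equal(p$pct_article, 100)
  expect_equal(p$pct_fps + p$pct_present + p$pct_discrepancy + p$pct_long, 0)
  p2 <- distancing_profile(annotate_text("I me my"))
  expect_equal(p2$pct_fps, 100)
})

test_that("the low-distance passage has 7 of 44 first-person tokens", {
  p <- distancing_profile(annotate_text(
    passages$text[passages$passage == "low_distance"]))
  expect_equal(p$word_count, 44L)
  expect_equal(p$pct_fps, 100 * 7 / 44)
})

test_that("a token may count in several distancing categories", {
  # 9-letter discrepancy word: both discrepancy and long
  p <- distancing_profile(annotate_text("hopefully"))
  expect_equal(p$pct_discrepancy, 100)
  expect_equal(p$pct_long, 100)
})

test_that("empty text yields a flagged missing profile", {
  p <- distancing_profile(annotate_text(""))
  expect_true(p$missing)
  expect_true(is.na(p$pct_fps))
  s <- score_texts("")
  expect_false(s$qualifying)
  expect_true(is.na(s$abstractness))
})

test_that("abstractness is the weighted mean level with range [1, 5]", {
  expect_equal(abstractness_score(
    tibble::tibble(n1 = 3, n2 = 0, n3 = 0, n4 = 0, n5 = 0))$abstractness, 1)
  expect_equal(abstractness_score(
    tibble::tibble(n1 = 0, n2 = 0, n3 = 0, n4 = 0, n5 = 2))$abstractness, 5)
  out <- abstractness_score(
    tibble::tibble(n1 = 0, n2 = 0, n3 = 0, n4 = 0, n5 = 0))
  expect_true(is.na(out$abstractness))
  expect_false(out$qualifying)
})

test_that("abstractness stays in [1, 5] for random generated texts", {
  sim <- simulate_study1(study1_config(n_participants = 20,
                                       trials_per_condition = 3), seed = 7)
  s <- score_texts(sim$trials$text)
  q <- s$abstractness[s$qualifying]
  expect_true(all(q >= 1 & q <= 5))
})

test_that("percentages are scale-free under token duplication", {
  txt <- "I am scared of the huge spider and I want it to stop"
  p1 <- score_texts(txt)
  p2 <- score_texts(paste(txt, txt))
  cols <- c("pct_fps", "pct_present", "pct_discrepancy", "pct_article",
            "pct_long", "abstractness")
  expect_equal(p1[cols], p2[cols], tolerance = 1e-12)
})

test_that("scoring is deterministic and batch equals per-text scoring", {
  txts <- passages$text
  expect_identical(score_texts(txts), score_texts(txts))
  single <- lapply(txts, function(t) {
    tg <- annotate_text(t)
    cbind(distancing_profile(tg)[, -7], lcm_profile(tg),
          abstractness_score(lcm_profile(tg)))
  })
  batch <- score_texts(txts)
  expect_equal(batch$abstractness, vapply(single, function(x) x$abstractness, 0))
  expect_equal(batch$pct_fps, vapply(single, function(x) x$pct_fps, 0))
  expect_equal(batch$n_classified,
               vapply(single, function(x) x$n_classified, 0L))
})
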