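# Synthetic trial generator for the two study designs. Text is assembled
# from template word pools drawn from the packaged lexicons, so the
# distancing-category membership and LCM level of every emitted word is
# known by construction and the scorer can be tested exactly. Affect is a
# discretized latent normal (rounded, clipped to 1-7) with participant
# random effects and configurable linkage between a participant's realized
# language shift and their affect shift.

regular_past <- function(lemma) {
  out <- ifelse(endsWith(lemma, "e"), paste0(lemma, "d"),
         ifelse(grepl("[^aeiou]y$", lemma),
                paste0(substr(lemma, 1, nchar(lemma) - 1L), "ied"),
         ifelse(nchar(lemma) <= 4L & grepl("^[^aeiou]*[aeiou][bdgklmnprt]$", lemma),
                paste0(lemma, substr(lemma, nchar(lemma), nchar(lemma)), "ed"),
                paste0(lemma, "ed"))))
  out
}

regular_3sg <- function(lemma) {
  ifelse(grepl("(s|x|z|ch|sh|o)$", lemma), paste0(lemma, "es"),
  ifelse(grepl("[^aeiou]y$", lemma),
         paste0(substr(lemma, 1, nchar(lemma) - 1L), "ies"),
         paste0(lemma, "s")))
}

# word pools with known category membership; verbs carry their LCM level
# and both inflected forms the generator emits
build_pools <- function(lexicons = default_lexicons()) {
  irr <- lexicons$irregulars
  irr_past <- irr[irr$tense == "past" & irr$aux == "main", c("form", "lemma")]
  drop <- c("be", "have", "want", "need", "wish", "hope", "prefer", "lack",
            "hit", "shut", "hurt", "like")
  verb_tab <- do.call(rbind, lapply(list(c("dav", 1L), c("iav", 2L), c("sv", 3L)),
    function(cl) data.frame(lemma = as.character(lexicons[[cl[1]]]),
                            level = as.integer(cl[2]))))
  verb_tab <- verb_tab[!verb_tab$lemma %in% drop, ]
  m <- match(verb_tab$lemma, irr_past$lemma)
  verb_tab$past <- ifelse(is.na(m), regular_past(verb_tab$lemma), irr_past$form[m])
  verb_tab$pres <- regular_3sg(verb_tab$lemma)
  long <- function(x) nchar(x) >= 7L
  adj <- as.character(lexicons$adjectives)
  noun <- as.character(lexicons$nouns)
  list(
    verbs = verb_tab,
    fps = c("i", "i", "i", "me", "my"),
    pron = c("he", "she", "it", "they", "we", "them", "him", "her", "us", "you"),
    art = c("the", "the", "a", "a", "an"),
    disc = c("if", "rather", "hopefully", "ideally"),
    adj_short = adj[!long(adj)], adj_long = adj[long(adj)],
    noun_short = noun[!long(noun)], noun_long = noun[long(noun)],
    filler = c("and", "but", "or", "then", "there", "very", "quite", "still",
               "just", "too", "now", "soon", "often", "in", "on", "at",
               "with", "from", "over", "under", "near", "so", "not", "as")
  )
}

.rate_names <- c("fps", "pron", "art", "disc", "pres", "past", "adj", "noun")

#' Generator configuration for the within-subject reappraisal design
#'
#' Defaults mirror the reappraisal task: three within-subject conditions
#' (look negative, reappraise negative, look neutral), 20 trials per
#' condition, and a combined sample split into an original and a
#' replication half. Emission rates are expected per-word probabilities of
#' the distancing categories; `verb_mix` gives the DAV/IAV/SV class weights
#' and `long_rate` the share of long (7+ letter) variants among adjective
#' and noun draws, which together set the expected abstractness of each
#' condition (reappraise and neutral conditions emit more abstract
#' language). `lambda_dist` and `lambda_abs` couple a participant's
#' realized (z-scored) delta distancing / delta abstractness to their
#' reappraisal success on the affect scale.
#'
#' @param n_participants,trials_per_condition Design size.
#' @param rates Named list of per-condition emission-rate vectors.
#' @param verb_mix Named list of per-condition DAV/IAV/SV weights.
#' @param long_rate Named numeric vector per condition.
#' @param affect_base Latent condition means on the 1-7 scale.
#' @param participant_sd,trial_sd Random-effect and residual SDs of the
#'   latent affect.
#' @param success_mean,success_sd Mean and SD of reappraisal success
#'   (look-negative minus reappraise latent affect).
#' @param lambda_dist,lambda_abs Linkage coefficients in `[0, 1)` with
#'   `lambda_dist^2 + lambda_abs^2 < 1`.
#' @param propensity_spread Scale of participant variation in how strongly
#'   the reappraise condition shifts their emission rates.
#' @param words_range Min/max words per trial.
#' @return A config list for [simulate_study1()].
#' @export
study1_config <- function(n_participants = 217, trials_per_condition = 20,
                          rates = NULL, verb_mix = NULL, long_rate = NULL,
                          affect_base = c(look_negative = 4.8,
                                          reappraise_negative = 3.8,
                                          look_neutral = 1.8),
                          participant_sd = 0.8, trial_sd = 0.6,
                          success_mean = 1.0, success_sd = 0.9,
                          lambda_dist = 0.3, lambda_abs = 0.15,
                          propensity_spread = 0.6,
                          words_range = c(12L, 28L)) {
  if (is.null(rates)) {
    rates <- list(
      look_negative = c(fps = .12, pron = .03, art = .06, disc = .03,
                        pres = .14, past = .02, adj = .05, noun = .16),
      reappraise_negative = c(fps = .09, pron = .05, art = .07, disc = .04,
                              pres = .10, past = .05, adj = .055, noun = .17),
      look_neutral = c(fps = .10, pron = .04, art = .07, disc = .02,
                       pres = .13, past = .02, adj = .06, noun = .18))
  }
  if (is.null(verb_mix)) {
    verb_mix <- list(look_negative = c(dav = .35, iav = .40, sv = .25),
                     reappraise_negative = c(dav = .30, iav = .40, sv = .30),
                     look_neutral = c(dav = .30, iav = .40, sv = .30))
  }
  if (is.null(long_rate)) {
    long_rate <- c(look_negative = .35, reappraise_negative = .42,
                   look_neutral = .42)
  }
  cfg <- list(design = "study1", n_participants = n_participants,
              trials_per_condition = trials_per_condition, rates = rates,
              verb_mix = verb_mix, long_rate = long_rate,
              affect_base = affect_base, participant_sd = participant_sd,
              trial_sd = trial_sd, success_mean = success_mean,
              success_sd = success_sd, lambda_dist = lambda_dist,
              lambda_abs = lambda_abs, propensity_spread = propensity_spread,
              words_range = words_range)
  validate_config(cfg)
  cfg
}

#' Generator configuration for the distance-by-domain design
#'
#' Distance (close vs far) is within subject; domain (physical, social,
#' temporal) is between subjects. Far-condition manipulations follow the
#' cue structure: social-far suppresses first-person-singular emission by
#' `fps_suppression`, temporal-far moves present-tense emission to past
#' tense, and physical-far raises article, adjective, noun and long-word
#' emission. `lambda_abs` couples realized delta abstractness (far - close)
#' to the affect reduction (close - far).
#'
#' @inheritParams study1_config
#' @param rates_close Baseline emission rates shared by all close trials.
#' @param far_shift Named list of additive rate shifts for physical-far.
#' @param fps_suppression Fraction of fps emission removed on social-far
#'   trials (1 = full suppression).
#' @param affect_close Latent mean of close-trial affect.
#' @param reduction_mean,reduction_sd Affect reduction (close - far) mean
#'   and SD across participants.
#' @return A config list for [simulate_study2()].
#' @export
study2_config <- function(n_participants = 464, trials_per_condition = 20,
                          rates_close = c(fps = .11, pron = .04, art = .06,
                                          disc = .03, pres = .13, past = .02,
                                          adj = .05, noun = .16),
                          far_shift = c(fps = -.02, pron = 0, art = .03,
                                        disc = 0, pres = -.03, past = .03,
                                        adj = .02, noun = .04),
                          fps_suppression = 0.95,
                          verb_mix = c(dav = .35, iav = .40, sv = .25),
                          long_rate = c(close = .35, far = .50),
                          affect_close = 4.5, participant_sd = 0.8,
                          trial_sd = 0.6, reduction_mean = 0.5,
                          reduction_sd = 0.8, lambda_abs = 0.2,
                          propensity_spread = 0.6,
                          words_range = c(12L, 28L)) {
  cfg <- list(design = "study2", n_participants = n_participants,
              trials_per_condition = trials_per_condition,
              rates_close = rates_close, far_shift = far_shift,
              fps_suppression = fps_suppression, verb_mix = verb_mix,
              long_rate = long_rate, affect_close = affect_close,
              participant_sd = participant_sd, trial_sd = trial_sd,
              reduction_mean = reduction_mean, reduction_sd = reduction_sd,
              lambda_abs = lambda_abs, lambda_dist = 0,
              propensity_spread = propensity_spread,
              words_range = words_range)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  rate_sets <- if (cfg$design == "study1") cfg$rates else {
    list(close = cfg$rates_close,
         physical_far = cfg$rates_close + cfg$far_shift)
  }
  for (nm in names(rate_sets)) {
    r <- rate_sets[[nm]]
    if (!all(.rate_names %in% names(r))) {
      stop("emission rates for '", nm, "' must name ",
           paste(.rate_names, collapse = ", "))
    }
    if (any(r < 0) || any(r > 1)) stop("emission rates must lie in [0, 1]")
    if (sum(r) > 0.98) {
      stop("emission rates for '", nm, "' sum to ", round(sum(r), 3),
           "; exclusive slots exceed the word budget")
    }
  }
  if (cfg$trials_per_condition < 1L) stop("trials_per_condition must be >= 1")
  if (cfg$lambda_dist^2 + cfg$lambda_abs^2 >= 1) {
    stop("lambda_dist^2 + lambda_abs^2 must be < 1")
  }
  ab <- if (cfg$design == "study1") cfg$affect_base else cfg$affect_close
  if (any(ab < 1 | ab > 7)) stop("affect means must lie on the 1-7 scale")
  invisible(cfg)
}

# emit tokens for a set of trials given per-trial rate/verb-mix/long-rate
# matrices; returns the pasted texts plus realized per-trial profiles
emit_trials <- function(rate_mat, mix_mat, long_vec, words_range, pools) {
  n_trials <- nrow(rate_mat)
  n_words <- sample.int(words_range[2] - words_range[1] + 1L, n_trials,
                        replace = TRUE) + words_range[1] - 1L
  trial_of <- rep.int(seq_len(n_trials), n_words)
  n_tok <- length(trial_of)
  cum <- rate_mat
  for (j in 2:ncol(cum)) cum[, j] <- cum[, j] + cum[, j - 1]
  u <- stats::runif(n_tok)
  cum_tok <- cum[trial_of, , drop = FALSE]
  cat_idx <- rowSums(u > cum_tok) + 1L   # 9 = filler
  word <- character(n_tok)
  level <- integer(n_tok)
  is_present <- cat_idx == 5L
  is_past <- cat_idx == 6L

  pick <- function(pool, k) pool[sample.int(length(pool), k, replace = TRUE)]
  for (k in c(1L, 2L, 3L, 4L, 9L)) {
    idx <- which(cat_idx == k)
    pool <- switch(as.character(k), "1" = pools$fps, "2" = pools$pron,
                   "3" = pools$art, "4" = pools$disc, "9" = pools$filler)
    if (length(idx)) word[idx] <- pick(pool, length(idx))
  }
  vb <- which(cat_idx %in% c(5L, 6L))
  if (length(vb)) {
    mixc <- mix_mat[trial_of[vb], , drop = FALSE]
    u2 <- stats::runif(length(vb))
    cls <- 1L + (u2 > mixc[, 1]) + (u2 > mixc[, 1] + mixc[, 2])
    row <- integer(length(vb))
    for (cl in 1:3) {
      sel <- which(cls == cl)
      cand <- which(pools$verbs$level == cl)
      if (length(sel)) row[sel] <- cand[sample.int(length(cand), length(sel),
                                                   replace = TRUE)]
    }
    word[vb] <- ifelse(cat_idx[vb] == 5L, pools$verbs$pres[row],
                       pools$verbs$past[row])
    level[vb] <- pools$verbs$level[row]
  }
  for (k in c(7L, 8L)) {
    idx <- which(cat_idx == k)
    if (!length(idx)) next
    use_long <- stats::runif(length(idx)) < long_vec[trial_of[idx]]
    short_pool <- if (k == 7L) pools$adj_short else pools$noun_short
    long_pool <- if (k == 7L) pools$adj_long else pools$noun_long
    word[idx[use_long]] <- pick(long_pool, sum(use_long))
    word[idx[!use_long]] <- pick(short_pool, sum(!use_long))
    level[idx] <- if (k == 7L) 4L else 5L
  }

  cnt <- function(flag) tabulate_by(trial_of, flag, n_trials)
  wc <- as.numeric(n_words)
  lvl_cnt <- vapply(1:5, function(l) cnt(level == l), numeric(n_trials))
  n_classified <- rowSums(lvl_cnt)
  profile <- tibble::tibble(
    word_count = as.integer(wc),
    pct_fps = 100 * cnt(cat_idx == 1L) / wc,
    pct_present = 100 * cnt(is_present) / wc,
    pct_discrepancy = 100 * cnt(cat_idx == 4L) / wc,
    pct_article = 100 * cnt(cat_idx == 3L) / wc,
    pct_long = 100 * cnt(nchar(word) >= 7L) / wc,
    n1 = lvl_cnt[, 1], n2 = lvl_cnt[, 2], n3 = lvl_cnt[, 3],
    n4 = lvl_cnt[, 4], n5 = lvl_cnt[, 5],
    n_classified = n_classified,
    abstractness = ifelse(n_classified > 0,
                          as.numeric(lvl_cnt %*% (1:5)) / n_classified,
                          NA_real_),
    qualifying = n_classified >= 1L
  )
  texts <- vapply(split(word, trial_of), paste, character(1), collapse = " ")
  list(text = unname(texts), profile = profile)
}

clip_rates <- function(m) {
  m[] <- pmin(pmax(m, 0.002), 0.9)
  excess <- rowSums(m) > 0.95
  if (any(excess)) m[excess, ] <- m[excess, , drop = FALSE] * 0.95 / rowSums(m[excess, , drop = FALSE])
  m
}

discretize_affect <- function(latent) {
  pmin(pmax(round(latent), 1L), 7L)
}

link_noise <- function(z_dist, z_abs, lambda_dist, lambda_abs) {
  resid <- sqrt(max(0, 1 - lambda_dist^2 - lambda_abs^2))
  lambda_dist * z_dist + lambda_abs * z_abs +
    resid * stats::rnorm(length(z_abs))
}

zscore_vec <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

#' Simulate the within-subject reappraisal study
#'
#' Generates trial-level text and affect for three within-subject
#' conditions. Per-participant emission-rate shifts (scaled by a latent
#' propensity) create individual differences in delta distancing and delta
#' abstractness; affect in the reappraise condition is lowered by a
#' reappraisal-success term linked to the participant's realized language
#' shift through `lambda_dist`/`lambda_abs`.
#'
#' @param config A list from [study1_config()].
#' @param seed Integer seed; the same config and seed reproduce the dataset
#'   exactly.
#' @param lexicons Lexicon set used to build the word pools.
#' @return An object of class `lingdist_sim`: a list with `trials` (the
#'   trial table the pipeline consumes), `truth` (configured parameters,
#'   participant-level realized deltas and success terms) and
#'   `trial_profiles` (by-construction per-trial profiles, in the same form
#'   as [score_texts()] output).
#' @export
#' @examples
#' sim <- simulate_study1(study1_config(n_participants = 4,
#'                                      trials_per_condition = 2), seed = 1)
#' sim$trials
simulate_study1 <- function(config = study1_config(), seed = 1,
                            lexicons = default_lexicons()) {
  validate_config(config)
  set.seed(seed)
  pools <- build_pools(lexicons)
  np <- config$n_participants
  tpc <- config$trials_per_condition
  conds <- names(config$rates)
  u <- stats::rnorm(np)
  shift <- pmax(0, 1 + config$propensity_spread * u)

  grid <- expand.grid(trial = seq_len(tpc), condition = conds,
                      participant_id = seq_len(np),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base <- config$rates$look_negative
  cond_mat <- do.call(rbind, config$rates)[grid$condition, , drop = FALSE]
  base_mat <- matrix(base, nrow(grid), length(base), byrow = TRUE)
  rate_mat <- base_mat + (cond_mat - base_mat) * shift[grid$participant_id]
  rate_mat <- clip_rates(rate_mat)
  colnames(rate_mat) <- .rate_names

  mix_base <- config$verb_mix$look_negative
  mix_cond <- do.call(rbind, config$verb_mix)[grid$condition, , drop = FALSE]
  mix_mat <- matrix(mix_base, nrow(grid), 3, byrow = TRUE) +
    (mix_cond - matrix(mix_base, nrow(grid), 3, byrow = TRUE)) *
    shift[grid$participant_id]
  mix_mat <- pmax(mix_mat, 0.02)
  mix_mat <- mix_mat / rowSums(mix_mat)

  lr_base <- config$long_rate[["look_negative"]]
  long_vec <- pmin(pmax(lr_base + (config$long_rate[grid$condition] - lr_base) *
                          shift[grid$participant_id], 0.02), 0.95)

  emitted <- emit_trials(rate_mat, mix_mat, long_vec, config$words_range, pools)

  sample_id <- ifelse(seq_len(np) <= ceiling(np / 2), "original", "replication")
  trials <- tibble::tibble(
    participant_id = grid$participant_id,
    sample_id = sample_id[grid$participant_id],
    condition = grid$condition,
    trial = grid$trial,
    text = emitted$text
  )
  truth_trials <- dplyr::bind_cols(trials[c("participant_id", "sample_id",
                                            "condition")], emitted$profile)
  truth_trials$affect <- 0
  ztr <- zscore_categories(truth_trials, group = "sample_id")
  agg <- aggregate_participants(ztr, design = "study1")

  z_abs <- zscore_vec(agg$delta_abstractness)
  z_dist <- zscore_vec(agg$delta_distancing)
  success <- config$success_mean + config$success_sd *
    link_noise(z_dist, z_abs, config$lambda_dist, config$lambda_abs)
  b <- stats::rnorm(np, 0, config$participant_sd)

  mu <- config$affect_base[trials$condition] + b[trials$participant_id]
  reapp <- trials$condition == "reappraise_negative"
  mu[reapp] <- config$affect_base[["look_negative"]] +
    b[trials$participant_id[reapp]] -
    success[match(trials$participant_id[reapp], agg$participant_id)]
  latent <- mu + stats::rnorm(nrow(trials), 0, config$trial_sd)
  trials$affect <- discretize_affect(latent)

  truth <- list(
    config = config,
    participants = tibble::tibble(
      participant_id = agg$participant_id,
      propensity = u[agg$participant_id],
      delta_distancing = agg$delta_distancing,
      delta_abstractness = agg$delta_abstractness,
      success = success
    )
  )
  structure(list(trials = trials, truth = truth,
                 trial_profiles = emitted$profile),
            class = "lingdist_sim")
}

#' Simulate the distance-by-domain study
#'
#' @param config A list from [study2_config()].
#' @inheritParams simulate_study1
#' @return A `lingdist_sim` list; `trials` carries a `domain` column.
#' @export
simulate_study2 <- function(config = study2_config(), seed = 1,
                            lexicons = default_lexicons()) {
  validate_config(config)
  set.seed(seed)
  pools <- build_pools(lexicons)
  np <- config$n_participants
  tpc <- config$trials_per_condition
  domains <- c("physical", "social", "temporal")
  domain <- sample(rep_len(domains, np))
  u <- stats::rnorm(np)
  shift <- pmax(0, 1 + config$propensity_spread * u)

  grid <- expand.grid(trial = seq_len(tpc), distance = c("close", "far"),
                      participant_id = seq_len(np),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$domain <- domain[grid$participant_id]
  nr <- nrow(grid)
  base <- config$rates_close[.rate_names]
  rate_mat <- matrix(base, nr, length(base), byrow = TRUE)
  colnames(rate_mat) <- .rate_names
  far <- grid$distance == "far"
  sh <- shift[grid$participant_id]

  phys <- far & grid$domain == "physical"
  shift_mat <- matrix(config$far_shift[.rate_names], nr, length(base), byrow = TRUE)
  rate_mat[phys, ] <- rate_mat[phys, , drop = FALSE] +
    shift_mat[phys, , drop = FALSE] * sh[phys]

  soc <- far & grid$domain == "social"
  supp <- pmin(1, config$fps_suppression * sh[soc])
  removed <- rate_mat[soc, "fps"] * supp
  rate_mat[soc, "fps"] <- rate_mat[soc, "fps"] - removed
  rate_mat[soc, "pron"] <- rate_mat[soc, "pron"] + removed * 0.6
  rate_mat[soc, "noun"] <- rate_mat[soc, "noun"] + removed * 0.3
  rate_mat[soc, "adj"] <- rate_mat[soc, "adj"] + removed * 0.1

  temp <- far & grid$domain == "temporal"
  moved <- rate_mat[temp, "pres"] * pmin(1, 0.9 * sh[temp])
  rate_mat[temp, "pres"] <- rate_mat[temp, "pres"] - moved
  rate_mat[temp, "past"] <- rate_mat[temp, "past"] + moved
  rate_mat <- clip_rates(rate_mat)

  mix_mat <- matrix(config$verb_mix, nr, 3, byrow = TRUE)
  mix_mat <- mix_mat / rowSums(mix_mat)
  long_vec <- rep(config$long_rate[["close"]], nr)
  lr_delta <- config$long_rate[["far"]] - config$long_rate[["close"]]
  long_vec[phys] <- pmin(pmax(long_vec[phys] + lr_delta * sh[phys], 0.02), 0.95)

  emitted <- emit_trials(rate_mat, mix_mat, long_vec, config$words_range, pools)
  sample_id <- ifelse(seq_len(np) <= ceiling(np / 2), "original", "replication")
  trials <- tibble::tibble(
    participant_id = grid$participant_id,
    sample_id = sample_id[grid$participant_id],
    domain = grid$domain,
    condition = grid$distance,
    trial = grid$trial,
    text = emitted$text
  )
  truth_trials <- dplyr::bind_cols(trials[c("participant_id", "sample_id",
                                            "domain", "condition")],
                                   emitted$profile)
  truth_trials$affect <- 0
  ztr <- zscore_categories(truth_trials, group = "sample_id")
  agg <- aggregate_participants(ztr, design = "study2")

  z_abs <- zscore_vec(agg$delta_abstractness)
  z_dist <- zscore_vec(agg$delta_distancing)
  reduction <- config$reduction_mean + config$reduction_sd *
    link_noise(z_dist, z_abs, config$lambda_dist, config$lambda_abs)
  b <- stats::rnorm(np, 0, config$participant_sd)
  mu <- config$affect_close + b[trials$participant_id]
  is_far <- trials$condition == "far"
  mu[is_far] <- mu[is_far] -
    reduction[match(trials$participant_id[is_far], agg$participant_id)]
  trials$affect <- discretize_affect(mu + stats::rnorm(nrow(trials), 0,
                                                       config$trial_sd))
  truth <- list(
    config = config,
    participants = tibble::tibble(
      participant_id = agg$participant_id,
      domain = domain[agg$participant_id],
      propensity = u[agg$participant_id],
      delta_distancing = agg$delta_distancing,
      delta_abstractness = agg$delta_abstractness,
      reduction = reduction
    )
  )
  structure(list(trials = trials, truth = truth,
                 trial_profiles = emitted$profile),
            class = "lingdist_sim")
}

#' Matched validation passages
#'
#' Two fixture passages matched in content but differing radically in
#' linguistic distance: the low-distance version is written in first person
#' and present tense, the high-distance version in third person and past
#' tense. They are the canonical check that the distancing manipulation
#' leaves the abstractness score untouched: both score exactly 2.8125.
#'
#' @return A tibble with columns `passage` and `text`.
#' @export
#' @examples
#' score_texts(matched_passages()$text)$abstractness
matched_passages <- function() {
  tibble::tibble(
    passage = c("low_distance", "high_distance"),
    text = c(
      paste("I am writing about how I feel. I am scared and I hate that the",
            "spider is so huge. This is terrible and I want it to stop. Why",
            "is this happening to me? I never want to see a bug like this again."),
      paste("He was writing about how he felt. He was scared and he hated that",
            "the spider was so huge. This was terrible and he wanted it to stop.",
            "Why was this happening to him? He never wanted to see a bug like",
            "this again.")
    )
  )
}
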