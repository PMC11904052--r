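# Per-text scoring: the five distancing word categories and the LCM
# abstractness profile. A token may contribute to several distancing
# categories (a 7-letter discrepancy word counts in both), but LCM levels
# are mutually exclusive.

n_letters <- function(x) stringi::stri_count_regex(x, "[A-Za-z]")

category_flags <- function(tagged, lexicons, clitic_present = TRUE) {
  w <- tagged$lower
  present <- tagged$pos == "verb" & tagged$tense == "present"
  if (!clitic_present) {
    present <- present & !w %in% c("'m", "'re", "'s", "'ve")
  }
  tibble::tibble(
    fps = w %in% lexicons$fps,
    present = present,
    discrepancy = w %in% lexicons$discrepancy,
    article = tagged$pos == "article",
    long = tagged$is_word & n_letters(w) >= 7L
  )
}

#' Distancing word-category profile of an annotated text
#'
#' Computes the percentage of word tokens falling in each of the five
#' categories behind the linguistic distancing composite: first-person
#' singular pronouns, present-tense verbs, discrepancy words, articles, and
#' words with more than six letters (at least 7 alphabetic characters).
#'
#' @param tagged An annotated token tibble from [annotate_text()] or
#'   [tag_tokens()].
#' @param lexicons A lexicon set.
#' @param clitic_present Count verb clitics (`'m`, `'re`, `'s`, `'ve`) as
#'   present-tense verbs (default `TRUE`); the convention is configurable
#'   because dictionary-based tools differ on it.
#' @return A one-row tibble with `word_count`, `pct_fps`, `pct_present`,
#'   `pct_discrepancy`, `pct_article`, `pct_long`, and `missing` (`TRUE`
#'   with all percentages `NA` when the text has no word tokens).
#' @export
#' @examples
#' distancing_profile(annotate_text("I am writing about the accident."))
distancing_profile <- function(tagged, lexicons = default_lexicons(),
                               clitic_present = TRUE) {
  wc <- sum(tagged$is_word)
  if (wc == 0L) {
    return(tibble::tibble(word_count = 0L, pct_fps = NA_real_,
                          pct_present = NA_real_, pct_discrepancy = NA_real_,
                          pct_article = NA_real_, pct_long = NA_real_,
                          missing = TRUE))
  }
  fl <- category_flags(tagged, lexicons, clitic_present)
  tibble::tibble(
    word_count = wc,
    pct_fps = 100 * sum(fl$fps) / wc,
    pct_present = 100 * sum(fl$present) / wc,
    pct_discrepancy = 100 * sum(fl$discrepancy) / wc,
    pct_article = 100 * sum(fl$article) / wc,
    pct_long = 100 * sum(fl$long) / wc,
    missing = FALSE
  )
}

#' LCM abstraction-level profile of an annotated text
#'
#' Counts words at each abstraction level of the linguistic category model:
#' descriptive action verbs (1), interpretive action verbs (2), state verbs
#' (3), adjectives (4), nouns (5). Auxiliaries, pronouns, articles, adverbs
#' and other function words are unclassified.
#'
#' @inheritParams distancing_profile
#' @return A one-row tibble with counts `n1`..`n5` and `n_classified`.
#' @export
lcm_profile <- function(tagged, lexicons = default_lexicons()) {
  lvl <- tagged$lcm_level[!is.na(tagged$lcm_level)]
  counts <- tabulate(lvl, nbins = 5L)
  tibble::tibble(n1 = counts[1], n2 = counts[2], n3 = counts[3],
                 n4 = counts[4], n5 = counts[5],
                 n_classified = sum(counts))
}

#' Linguistic abstractness score from an LCM profile
#'
#' The score is the weighted mean abstraction level,
#' \eqn{(1 n_1 + 2 n_2 + 3 n_3 + 4 n_4 + 5 n_5) / (n_1 + \dots + n_5)},
#' ranging from 1 (all descriptive action verbs) to 5 (all nouns). A text
#' qualifies when at least `min_classified` words were classified;
#' non-qualifying texts score `NA`, never 0.
#'
#' @param profile A one-row tibble from [lcm_profile()] (or a named numeric
#'   vector with `n1`..`n5`).
#' @param min_classified Minimum classified words for a qualifying score
#'   (default 1).
#' @return A one-row tibble with `abstractness` and `qualifying`.
#' @export
#' @examples
#' abstractness_score(lcm_profile(annotate_text("The spider is huge.")))
abstractness_score <- function(profile, min_classified = 1L) {
  n <- unlist(profile[c("n1", "n2", "n3", "n4", "n5")])
  total <- sum(n)
  qualifying <- total >= min_classified && total > 0L
  value <- if (qualifying) sum(n * 1:5) / total else NA_real_
  tibble::tibble(abstractness = value, qualifying = qualifying)
}

#' Score a set of trial texts
#'
#' Batch path for the full text-scoring stage: tokenizes, annotates and
#' profiles every text in one vectorized pass. This is the per-trial scoring
#' table that the composite and aggregation stages consume.
#'
#' @param texts Character vector of trial texts.
#' @param lexicons A lexicon set.
#' @param min_classified Minimum classified words for a qualifying
#'   abstractness score.
#' @param clitic_present See [distancing_profile()].
#' @return A tibble with one row per text: `word_count`, the five category
#'   percentages, `n1`..`n5`, `n_classified`, `abstractness`, `qualifying`.
#' @export
#' @examples
#' score_texts(c("I am scared of the spider.", "He admired the mountain."))
score_texts <- function(texts, lexicons = default_lexicons(),
                        min_classified = 1L, clitic_present = TRUE) {
  stopifnot(is.character(texts))
  ndoc <- length(texts)
  toks <- tokenize_batch(texts)
  tagged <- tag_tokens(toks, lexicons)
  doc <- tagged$doc
  wc <- tabulate_by(doc, tagged$is_word, ndoc)
  fl <- category_flags(tagged, lexicons, clitic_present)
  pct <- function(flag) ifelse(wc > 0, 100 * tabulate_by(doc, flag, ndoc) / wc, NA_real_)
  lvl_count <- function(k) {
    tabulate_by(doc, !is.na(tagged$lcm_level) & tagged$lcm_level == k, ndoc)
  }
  n1 <- lvl_count(1L); n2 <- lvl_count(2L); n3 <- lvl_count(3L)
  n4 <- lvl_count(4L); n5 <- lvl_count(5L)
  n_classified <- n1 + n2 + n3 + n4 + n5
  qualifying <- n_classified >= max(min_classified, 1L)
  abstractness <- ifelse(qualifying,
                         (n1 + 2 * n2 + 3 * n3 + 4 * n4 + 5 * n5) / n_classified,
                         NA_real_)
  tibble::tibble(
    word_count = wc,
    pct_fps = pct(fl$fps), pct_present = pct(fl$present),
    pct_discrepancy = pct(fl$discrepancy), pct_article = pct(fl$article),
    pct_long = pct(fl$long),
    n1 = n1, n2 = n2, n3 = n3, n4 = n4, n5 = n5,
    n_classified = n_classified,
    abstractness = abstractness, qualifying = qualifying
  )
}

# rowsum-based grouped counts for a logical vector, including empty docs
tabulate_by <- function(doc, flag, ndoc) {
  out <- numeric(ndoc)
  if (length(doc)) {
    s <- rowsum(as.numeric(flag), doc, reorder = FALSE)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}
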