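# Rule-based POS/lemma/tense annotation. The tagger is deterministic and
# lexicon-driven: closed-class words come from packaged lists, verbs are
# recognised through an irregular-form table plus suffix rules keyed to the
# LCM verb lexicons, and unknown open-class words default to noun (the most
# abstract class). Context rules distinguish auxiliary from copular "be"
# and resolve tense, which is what the distancing and abstractness measures
# need: auxiliaries are excluded from LCM counting while copular "be" is a
# state verb, and present-tense detection covers clitics and gerunds under
# a present auxiliary.

strip_ing <- function(w, verb_lemmas) {
  stem <- substr(w, 1, nchar(w) - 3L)
  cand_e <- paste0(stem, "e")
  undouble <- substr(stem, 1, nchar(stem) - 1L)
  dbl <- nchar(stem) > 2L &
    substr(stem, nchar(stem), nchar(stem)) == substr(stem, nchar(stem) - 1L, nchar(stem) - 1L)
  out <- stem
  out[cand_e %in% verb_lemmas & !(stem %in% verb_lemmas)] <-
    cand_e[cand_e %in% verb_lemmas & !(stem %in% verb_lemmas)]
  pick_undouble <- dbl & !(stem %in% verb_lemmas) & (undouble %in% verb_lemmas)
  out[pick_undouble] <- undouble[pick_undouble]
  out
}

strip_ed <- function(w, verb_lemmas) {
  # try -ed, then -d (hate -> hated), then undoubling (stopped -> stop),
  # then -ied -> y (carried -> carry)
  stem_ed <- substr(w, 1, nchar(w) - 2L)
  stem_d <- substr(w, 1, nchar(w) - 1L)
  undouble <- substr(stem_ed, 1, nchar(stem_ed) - 1L)
  y_form <- ifelse(endsWith(stem_ed, "i"),
                   paste0(substr(stem_ed, 1, nchar(stem_ed) - 1L), "y"), NA_character_)
  out <- stem_ed
  hit <- stem_ed %in% verb_lemmas
  use_d <- !hit & stem_d %in% verb_lemmas
  out[use_d] <- stem_d[use_d]
  hit <- hit | use_d
  use_u <- !hit & undouble %in% verb_lemmas &
    substr(stem_ed, nchar(stem_ed), nchar(stem_ed)) ==
      substr(stem_ed, nchar(stem_ed) - 1L, nchar(stem_ed) - 1L)
  out[use_u] <- undouble[use_u]
  hit <- hit | use_u
  use_y <- !hit & !is.na(y_form) & y_form %in% verb_lemmas
  out[use_y] <- y_form[use_y]
  out
}

strip_s <- function(w, lemmas) {
  # 3rd-person singular present: walks, watches, carries
  stem_s <- substr(w, 1, nchar(w) - 1L)
  stem_es <- substr(w, 1, nchar(w) - 2L)
  ies <- endsWith(w, "ies")
  y_form <- paste0(substr(w, 1, nchar(w) - 3L), "y")
  out <- rep(NA_character_, length(w))
  out[stem_s %in% lemmas] <- stem_s[stem_s %in% lemmas]
  # -es attaches only after sibilants and o (kisses, watches, goes)
  need <- is.na(out) & grepl("(s|x|z|ch|sh|o)es$", w) & stem_es %in% lemmas
  out[need] <- stem_es[need]
  need <- is.na(out) & ies & y_form %in% lemmas
  out[need] <- y_form[need]
  out
}

#' Annotate a token table with POS, lemma, tense and LCM level
#'
#' @param tokens A tibble from [tokenize_text()] or the internal batch
#'   tokenizer; must contain `lower` and `is_word` (a `doc` column is added
#'   if absent).
#' @param lexicons A lexicon set from [load_lexicons()].
#' @return The input tibble with columns `pos` (noun, verb, adjective,
#'   adverb, pronoun, article, other), `lemma`, `tense` (present, past,
#'   other, na), `is_aux`, and `lcm_level` (1-5, or `NA` for unclassified
#'   tokens).
#' @export
#' @examples
#' tag_tokens(tokenize_text("He was writing"))[, c("lower", "pos", "lemma", "tense")]
tag_tokens <- function(tokens, lexicons = default_lexicons()) {
  n <- nrow(tokens)
  if (!n) {
    return(dplyr::mutate(tokens, pos = character(), lemma = character(),
                         tense = character(), is_aux = logical(),
                         lcm_level = integer()))
  }
  if (!"doc" %in% names(tokens)) tokens$doc <- 1L
  w <- tokens$lower
  is_word <- tokens$is_word

  pos <- rep("other", n)
  lemma <- w
  tense <- rep("na", n)
  is_aux <- rep(FALSE, n)
  form <- rep("", n)   # base, s, ed, ing, participle, finite
  done <- !is_word
  pos[!is_word] <- "other"

  claim <- function(idx) { done[idx] <<- TRUE }

  # ---- irregular verb forms (incl. be/have/do and verb clitics) ----
  irr <- lexicons$irregulars
  hit <- match(w, irr$form)
  take <- !done & !is.na(hit)
  pos[take] <- "verb"
  lemma[take] <- irr$lemma[hit[take]]
  itense <- irr$tense[hit[take]]
  tense[take] <- ifelse(itense %in% c("present", "past"), itense, "other")
  form[take] <- ifelse(itense == "gerund", "ing",
                ifelse(itense == "participle", "participle",
                ifelse(itense == "base", "base", "finite")))
  is_aux[take] <- irr$aux[hit[take]] == "aux"
  aux_auto <- rep(FALSE, n)
  aux_auto[take] <- irr$aux[hit[take]] == "auto"
  claim(take)

  # ---- modals (always auxiliary, tense "other") ----
  modal_map <- c("ca" = "can", "wo" = "will", "'ll" = "will", "'d" = "would")
  is_modal <- !done & (w %in% lexicons$modals | w %in% names(modal_map))
  pos[is_modal] <- "verb"
  lemma[is_modal] <- ifelse(w[is_modal] %in% names(modal_map),
                            modal_map[w[is_modal]], w[is_modal])
  tense[is_modal] <- "other"
  is_aux[is_modal] <- TRUE
  claim(is_modal)

  # ---- closed classes ----
  cls <- list(pronoun = c(lexicons$fps, lexicons$pronouns),
              article = lexicons$articles,
              adverb = lexicons$adverbs)
  for (p in names(cls)) {
    take <- !done & w %in% cls[[p]]
    pos[take] <- p
    claim(take)
  }
  other_closed <- c(lexicons$determiners, lexicons$prepositions,
                    lexicons$conjunctions, lexicons$interjections)
  take <- !done & w %in% other_closed
  pos[take] <- "other"
  claim(take)

  # ---- open-class lexicon matches ----
  take <- !done & w %in% lexicons$adjectives
  pos[take] <- "adjective"
  claim(take)

  nouns <- lexicons$nouns
  plural <- strip_s(w, nouns)
  take <- !done & (w %in% nouns | !is.na(plural))
  pos[take] <- "noun"
  lemma[take] <- ifelse(w[take] %in% nouns, w[take], plural[take])
  claim(take)

  # ---- regular verb forms derived from the LCM lexicons ----
  vl <- lexicons$verb_lemmas
  take <- !done & w %in% vl
  pos[take] <- "verb"; form[take] <- "base"
  claim(take)

  s3 <- strip_s(w, vl)
  take <- !done & !is.na(s3) & endsWith(w, "s")
  pos[take] <- "verb"; lemma[take] <- s3[take]; form[take] <- "s"
  claim(take)

  has_ed <- !done & nchar(w) > 3L & endsWith(w, "ed")
  ed_lemma <- strip_ed(w, vl)
  take <- has_ed & ed_lemma %in% vl
  pos[take] <- "verb"; lemma[take] <- ed_lemma[take]; form[take] <- "ed"
  claim(take)

  has_ing <- !done & nchar(w) > 4L & endsWith(w, "ing")
  ing_lemma <- strip_ing(w, vl)
  take <- has_ing & ing_lemma %in% vl
  pos[take] <- "verb"; lemma[take] <- ing_lemma[take]; form[take] <- "ing"
  claim(take)

  # ---- heuristics for words outside every lexicon ----
  take <- !done & nchar(w) > 3L & endsWith(w, "ly")
  pos[take] <- "adverb"
  claim(take)

  take <- !done & nchar(w) > 4L & endsWith(w, "ing")
  pos[take] <- "verb"; lemma[take] <- strip_ing(w, vl)[take]; form[take] <- "ing"
  claim(take)

  take <- !done & nchar(w) > 3L & endsWith(w, "ed")
  pos[take] <- "verb"; lemma[take] <- strip_ed(w, vl)[take]; form[take] <- "ed"
  claim(take)

  take <- !done
  pos[take] <- "noun"
  claim(take)

  # ---- context pass: doc-boundary-masked shifts ----
  doc <- tokens$doc
  lead_k <- function(x, k, fill) {
    if (k >= length(x)) return(rep(fill, length(x)))
    out <- c(x[-seq_len(k)], rep(fill, k))
    out[doc != c(doc[-seq_len(k)], rep(-1L, k))] <- fill
    out
  }
  lag_k <- function(x, k, fill) {
    nn <- length(x)
    if (k >= nn) return(rep(fill, nn))
    out <- c(rep(fill, k), x[seq_len(nn - k)])
    out[doc != c(rep(-1L, k), doc[seq_len(nn - k)])] <- fill
    out
  }

  ing_part <- form %in% c("ing", "participle")
  edish <- form %in% c("ed", "participle")
  pastish <- edish | (pos == "verb" & tense == "past" & !w %in% c("was", "were", "had", "did"))

  # be/have with context-dependent auxiliary status
  near_ing <- lead_k(ing_part, 1, FALSE) | lead_k(ing_part, 2, FALSE) | lead_k(ing_part, 3, FALSE)
  near_ed <- lead_k(edish, 1, FALSE) | lead_k(edish, 2, FALSE) | lead_k(edish, 3, FALSE)
  near_past <- lead_k(pastish, 1, FALSE) | lead_k(pastish, 2, FALSE) | lead_k(pastish, 3, FALSE)
  be_aux <- aux_auto & lemma == "be" & (near_ing | near_ed)
  have_aux <- aux_auto & lemma == "have" & near_past
  is_aux[be_aux | have_aux] <- TRUE

  # tense of governed gerunds/participles: inherit from the nearest
  # preceding be/have auxiliary in a 3-token window
  aux_be <- is_aux & lemma == "be"
  aux_have <- is_aux & lemma == "have"
  aux_any <- aux_be | aux_have
  gov_tense <- rep(NA_character_, n)
  for (k in 1:3) {
    cand_aux <- lag_k(aux_any, k, FALSE)
    cand_tense <- lag_k(ifelse(aux_have, "past", tense), k, NA_character_)
    fill <- is.na(gov_tense) & cand_aux
    gov_tense[fill] <- cand_tense[fill]
  }
  governed <- (form %in% c("ing", "participle", "ed")) & !is.na(gov_tense)
  tense[governed] <- gov_tense[governed]
  tense[form == "ing" & !governed] <- "other"
  tense[form == "ed" & !governed & pos == "verb"] <- "past"
  tense[form == "participle" & !governed] <- "past"

  # finite base/-s forms: present, unless in an infinitive or modal scope
  finite <- pos == "verb" & form %in% c("base", "s")
  prev1 <- lag_k(w, 1, "")
  modal_prev <- lag_k(is_modal | w == "to", 1, FALSE) | lag_k(is_modal, 2, FALSE)
  tense[finite] <- "present"
  tense[finite & (prev1 == "to" | modal_prev)] <- "other"
  tense[pos == "verb" & tense == "na"] <- "other"
  tense[pos != "verb"] <- "na"

  # ---- LCM abstraction level ----
  lcm <- rep(NA_integer_, n)
  main_verb <- pos == "verb" & !is_aux
  lcm[main_verb] <- verb_level(lemma[main_verb], lexicons)
  lcm[pos == "adjective"] <- 4L
  lcm[pos == "noun"] <- 5L

  tokens$pos <- pos
  tokens$lemma <- lemma
  tokens$tense <- tense
  tokens$is_aux <- is_aux
  tokens$lcm_level <- lcm
  tokens
}

#' Tokenize and annotate one text
#'
#' Convenience wrapper: [tokenize_text()] followed by [tag_tokens()].
#'
#' @inheritParams tokenize_text
#' @inheritParams tag_tokens
#' @return An annotated token tibble.
#' @export
annotate_text <- function(text, lexicons = default_lexicons()) {
  tok <- tokenize_text(text)
  wc <- attr(tok, "word_count")
  out <- tag_tokens(tok, lexicons)
  attr(out, "word_count") <- wc
  out
}
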