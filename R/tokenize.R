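# Word-level tokenization. Contracted forms are split into host + clitic
# ("I'm" -> "I", "'m"; "don't" -> "do", "n't") so that pronoun and verb
# clitics can be matched against the lexicons independently.

.token_regex <- "[A-Za-z]+(?:'[A-Za-z]+)*|[0-9]+|[^A-Za-z0-9\\s]"
.clitic_regex <- "^([a-z]+)(n't|'m|'re|'ve|'ll|'d|'s)$"

#' Tokenize one text into a token sequence
#'
#' Splits a string into word and punctuation tokens with character spans.
#' Clitics are separated from their hosts and the word count includes only
#' tokens containing at least one letter.
#'
#' @param text A single string (possibly empty).
#' @return A tibble with columns `token`, `lower`, `start`, `end`, `is_word`
#'   and an attribute `word_count`.
#' @export
#' @examples
#' tok <- tokenize_text("I'm scared.")
#' attr(tok, "word_count")  # 3
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- stringi::stri_replace_all_fixed(text, "’", "'")
  loc <- stringi::stri_locate_all_regex(text, .token_regex, omit_no_match = TRUE)[[1]]
  if (!nrow(loc)) {
    out <- tibble::tibble(token = character(), lower = character(),
                          start = integer(), end = integer(), is_word = logical())
    attr(out, "word_count") <- 0L
    return(out)
  }
  token <- stringi::stri_sub(text, loc[, 1], loc[, 2])
  lower <- stringi::stri_trans_tolower(token)
  m <- stringi::stri_match_first_regex(lower, .clitic_regex)
  has_split <- !is.na(m[, 1])
  reps <- 1L + has_split
  idx <- rep.int(seq_along(lower), reps)
  part <- sequence(reps)
  tok_out <- token[idx]
  low_out <- lower[idx]
  start <- loc[idx, 1]
  end <- loc[idx, 2]
  sp <- has_split[idx]
  host_len <- nchar(m[idx, 2])
  # host keeps the leading characters, clitic the trailing ones
  first <- part == 1L
  tok_out[sp & first] <- substr(token[idx], 1, host_len)[sp & first]
  low_out[sp & first] <- m[idx, 2][sp & first]
  end[sp & first] <- (start + host_len - 1L)[sp & first]
  tok_out[sp & !first] <- m[idx, 3][sp & !first]
  low_out[sp & !first] <- m[idx, 3][sp & !first]
  start[sp & !first] <- (start + host_len)[sp & !first]
  is_word <- stringi::stri_detect_regex(low_out, "[a-z]")
  out <- tibble::tibble(token = tok_out, lower = low_out,
                        start = as.integer(start), end = as.integer(end),
                        is_word = is_word)
  attr(out, "word_count") <- sum(is_word)
  out
}

#' Tokenize a vector of texts (batch path)
#'
#' @param texts Character vector.
#' @return A tibble with columns `doc` (index into `texts`), `lower`,
#'   `is_word`.
#' @keywords internal
tokenize_batch <- function(texts) {
  texts <- stringi::stri_replace_all_fixed(texts, "’", "'")
  toks <- stringi::stri_extract_all_regex(texts, .token_regex, omit_no_match = TRUE)
  n <- lengths(toks)
  doc <- rep.int(seq_along(texts), n)
  lower <- stringi::stri_trans_tolower(unlist(toks, use.names = FALSE))
  if (!length(lower)) {
    return(tibble::tibble(doc = integer(), lower = character(), is_word = logical()))
  }
  m <- stringi::stri_match_first_regex(lower, .clitic_regex)
  has_split <- !is.na(m[, 1])
  reps <- 1L + has_split
  idx <- rep.int(seq_along(lower), reps)
  part <- sequence(reps)
  out <- lower[idx]
  sp <- has_split[idx]
  first <- part == 1L
  out[sp & first] <- m[idx, 2][sp & first]
  out[sp & !first] <- m[idx, 3][sp & !first]
  tibble::tibble(doc = doc[idx],
                 lower = out,
                 is_word = stringi::stri_detect_regex(out, "[a-z]"))
}
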