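#' Load a single lexicon file
#'
#' Lexicon files are plain text with a header line of the form
#' `# category: <name> | match: <surface|lemma>` followed by one lowercase
#' entry per line.
#'
#' @param path Path to a lexicon file.
#' @return A character vector of entries with attributes `category` and
#'   `match_mode`.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines) || !grepl("^#", lines[[1]])) {
    stop("lexicon file ", path, " lacks a '# category: ... | match: ...' header")
  }
  header <- lines[[1]]
  category <- sub("^#\\s*category:\\s*([^|]+?)\\s*\\|.*$", "\\1", header)
  match_mode <- sub("^.*match:\\s*(\\S+).*$", "\\1", header)
  entries <- trimws(lines[-1])
  entries <- entries[nzchar(entries) & !grepl("^#", entries)]
  if (any(entries != tolower(entries))) {
    stop("lexicon ", category, " contains non-lowercase entries")
  }
  structure(unique(entries), category = category, match_mode = match_mode)
}

#' Load a full lexicon set from a directory
#'
#' Reads every category lexicon the scorer needs (distancing word categories,
#' LCM verb classes, closed-class function words) plus the irregular-verb
#' table. The packaged set under `inst/extdata/lexicons` is the default used
#' throughout the package.
#'
#' @param dir Directory containing the lexicon files. Defaults to the
#'   packaged lexicons.
#' @return A named list of class `lingdist_lexicons`.
#' @export
#' @examples
#' lex <- load_lexicons()
#' head(lex$sv)
load_lexicons <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- system.file("extdata", "lexicons", package = "lingdist")
  }
  stopifnot(dir.exists(dir))
  file_of <- function(name) file.path(dir, paste0(name, ".txt"))
  lex <- list(
    fps          = read_lexicon(file_of("fps")),
    articles     = read_lexicon(file_of("articles")),
    discrepancy  = read_lexicon(file_of("discrepancy")),
    pronouns     = read_lexicon(file_of("pronouns_other")),
    determiners  = read_lexicon(file_of("determiners")),
    adverbs      = read_lexicon(file_of("adverbs")),
    prepositions = read_lexicon(file_of("prepositions")),
    conjunctions = read_lexicon(file_of("conjunctions")),
    modals       = read_lexicon(file_of("modals")),
    interjections = read_lexicon(file_of("interjections")),
    dav          = read_lexicon(file_of("dav")),
    iav          = read_lexicon(file_of("iav")),
    sv           = read_lexicon(file_of("sv")),
    adjectives   = read_lexicon(file_of("adjectives")),
    nouns        = read_lexicon(file_of("nouns"))
  )
  # LCM classes are mutually exclusive by construction; fail loudly if an
  # entry drifts into two of them.
  lcm_all <- c(lex$dav, lex$iav, lex$sv)
  if (anyDuplicated(lcm_all)) {
    stop("LCM verb lists overlap: ", paste(unique(lcm_all[duplicated(lcm_all)]), collapse = ", "))
  }
  irr <- utils::read.delim(file.path(dir, "irregular_verbs.tsv"),
                           stringsAsFactors = FALSE)
  stopifnot(all(c("form", "lemma", "tense", "aux") %in% names(irr)))
  lex$irregulars <- irr
  lex$verb_lemmas <- sort(unique(c(lex$dav, lex$iav, lex$sv)))
  class(lex) <- "lingdist_lexicons"
  lex
}

.lingdist_env <- new.env(parent = emptyenv())

#' Packaged default lexicon set (cached)
#' @return A `lingdist_lexicons` list.
#' @export
default_lexicons <- function() {
  if (is.null(.lingdist_env$lexicons)) {
    .lingdist_env$lexicons <- load_lexicons()
  }
  .lingdist_env$lexicons
}

#' LCM abstraction level of a verb lemma
#'
#' Descriptive action verbs are level 1, interpretive action verbs level 2,
#' state verbs level 3. Verbs absent from all three lists fall to the
#' documented default of level 2 (the middle action class).
#'
#' @param lemma Character vector of lowercase verb lemmas.
#' @param lexicons A lexicon set.
#' @return Integer vector of levels.
#' @keywords internal
verb_level <- function(lemma, lexicons = default_lexicons()) {
  lvl <- rep(2L, length(lemma))
  lvl[lemma %in% lexicons$dav] <- 1L
  lvl[lemma %in% lexicons$sv] <- 3L
  lvl[lemma %in% lexicons$iav] <- 2L
  lvl
}
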