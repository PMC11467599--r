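#' Default English stopword list
#'
#' A standard English stopword list frozen in the package so preprocessing
#' is reproducible. One lowercase term per line; covers determiners,
#' pronouns, auxiliaries and common particles (including informal
#' contractions with their apostrophes stripped, e.g. "dont", "im", since
#' symbol stripping removes apostrophes before tokenisation).
#'
#' @param path Optional path to an alternative stopword file (one term per
#'   line, `#` comments allowed).
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "convomine",
                        mustWork = TRUE)
  }
  words <- readLines(path, encoding = "UTF-8", warn = FALSE)
  words <- trimws(words)
  unique(words[nzchar(words) & !startsWith(words, "#")])
}

# Emoji/pictograph blocks named for removal: Emoticons; Miscellaneous
# Symbols and Pictographs; Transport and Map Symbols; Supplemental Symbols
# and Pictographs; plus the legacy Miscellaneous Symbols and Dingbats
# blocks and variation selectors that ride along with emoji.
emoji_block_regex <- paste0(
  "(*UTF)[",
  "\\x{1F300}-\\x{1F5FF}",  # Misc Symbols and Pictographs
  "\\x{1F600}-\\x{1F64F}",  # Emoticons
  "\\x{1F680}-\\x{1F6FF}",  # Transport and Map Symbols
  "\\x{1F900}-\\x{1F9FF}",  # Supplemental Symbols and Pictographs
  "\\x{2600}-\\x{26FF}",    # Miscellaneous Symbols
  "\\x{2700}-\\x{27BF}",    # Dingbats
  "\\x{FE00}-\\x{FE0F}",    # Variation Selectors
  "\\x{200D}",              # Zero-width joiner (emoji sequences)
  "]"
)

#' Strip emoji, symbols and punctuation from raw text
#'
#' Deletes every character in the configured emoji/pictograph Unicode
#' blocks, all Unicode punctuation, and all remaining symbol characters.
#' Letters, digits and whitespace are preserved unchanged; removed
#' characters are deleted outright (not replaced by spaces), so the result
#' is never longer than the input.
#'
#' @param text Character vector of raw strings.
#' @return Character vector of the same length, symbol-free.
#' @examples
#' strip_symbols("ouch!!! \U0001F525 burnt")
#' @export
strip_symbols <- function(text) {
  text[is.na(text)] <- ""
  out <- gsub(emoji_block_regex, "", enc2utf8(text), perl = TRUE)
  gsub("(*UTF)[\\p{P}\\p{S}]", "", out, perl = TRUE)
}

# Irregular lemma lookup. Small and frozen: inflections of common verbs,
# irregular plurals, and domain words whose regular-suffix analysis would
# misfire (calories -> calorie, not "calory").
irregular_lemmas <- c(
  was = "be", were = "be", is = "be", are = "be", am = "be", been = "be",
  being = "be", has = "have", had = "have", having = "have",
  does = "do", did = "do", done = "do", doing = "do",
  went = "go", gone = "go", goes = "go", got = "get", gotten = "get",
  said = "say", says = "say", made = "make", making = "make",
  took = "take", taken = "take", gave = "give", given = "give",
  came = "come", coming = "come", using = "use", used = "use",
  left = "leave", felt = "feel", kept = "keep", put = "put", ran = "run",
  running = "run", saw = "see", seen = "see", told = "tell",
  thought = "think", found = "find", held = "hold", lost = "lose",
  burnt = "burn", sunburnt = "sunburn", scalding = "scald",
  children = "child", feet = "foot", teeth = "tooth", men = "man",
  women = "woman", mice = "mouse", people = "person",
  calories = "calorie", movies = "movie", cookies = "cookie",
  nappies = "nappy", species = "species", series = "series"
)

vowels <- c("a", "e", "i", "o", "u")

ends_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3L) return(FALSE)
  ch <- strsplit(w, "")[[1]]
  c3 <- ch[n - 2L]; c2 <- ch[n - 1L]; c1 <- ch[n]
  !(c3 %in% vowels) && (c2 %in% vowels) &&
    !(c1 %in% c(vowels, "w", "x", "y"))
}

undouble <- function(w) {
  n <- nchar(w)
  if (n >= 2L) {
    last <- substr(w, n, n)
    if (substr(w, n - 1L, n - 1L) == last &&
        last %in% c("b", "d", "g", "m", "n", "p", "r", "t")) {
      return(substr(w, 1L, n - 1L))
    }
  }
  w
}

lemma_one <- function(w) {
  hit <- irregular_lemmas[w]
  if (!is.na(hit)) return(unname(hit))
  n <- nchar(w)
  # participle/gerund suffixes first
  if (n > 5L && endsWith(w, "ied")) return(paste0(substr(w, 1L, n - 3L), "y"))
  if (n > 4L && endsWith(w, "ed") && !endsWith(w, "eed")) {
    stem <- substr(w, 1L, n - 2L)
    stem2 <- undouble(stem)
    if (nchar(stem2) < nchar(stem)) return(stem2)
    if (ends_cvc(stem)) return(paste0(stem, "e"))
    return(stem)
  }
  if (n > 5L && endsWith(w, "ing")) {
    stem <- substr(w, 1L, n - 3L)
    stem2 <- undouble(stem)
    if (nchar(stem2) < nchar(stem)) return(stem2)
    if (ends_cvc(stem)) return(paste0(stem, "e"))
    return(stem)
  }
  # noun plurals
  if (n > 4L && endsWith(w, "ies")) return(paste0(substr(w, 1L, n - 3L), "y"))
  if (n > 4L && grepl("(ss|x|z|ch|sh)es$", w)) return(substr(w, 1L, n - 2L))
  if (n > 4L && endsWith(w, "oes")) return(substr(w, 1L, n - 2L))
  if (n > 3L && endsWith(w, "s") && !endsWith(w, "ss") &&
      !endsWith(w, "us") && !endsWith(w, "is")) {
    return(substr(w, 1L, n - 1L))
  }
  w
}

#' Lemmatize lowercase tokens
#'
#' A deterministic rule-based English lemmatizer: an irregular-form lookup
#' table backed by suffix rules for plurals (-s/-es/-ies/-oes), past forms
#' (-ed/-ied with consonant undoubling and silent-e restoration) and
#' gerunds (-ing). It is intentionally lightweight — informal social-media
#' text defeats heavyweight taggers too — and is frozen so that token
#' output never changes between runs.
#'
#' @param tokens Character vector of lowercase tokens.
#' @return Character vector of lemmas, same length.
#' @examples
#' lemmatize(c("burns", "treated", "scalded", "calories"))
#' @export
lemmatize <- function(tokens) {
  if (length(tokens) == 0L) return(character())
  vapply(tokens, function(w) {
    # iterate to a fixed point ("meetings" -> "meeting" -> "meet") so that
    # lemmatizing a lemma is always the identity
    for (i in 1:4) {
      nxt <- lemma_one(w)
      if (identical(nxt, w)) break
      w <- nxt
    }
    w
  }, character(1), USE.NAMES = FALSE)
}

#' Normalize raw text to a stopword-free lemma token list
#'
#' Applies, in order: symbol/emoji/punctuation stripping, lowercasing,
#' whitespace tokenisation, stopword removal, lemmatisation, and a second
#' stopword pass (a lemma can land on a stopword, e.g. "was" -> "be").
#' The composition is idempotent: running it on its own re-joined output
#' returns the same tokens.
#'
#' @param text A single raw string.
#' @param stopwords Character vector of stopwords ([default_stopwords()]).
#' @param keep_numbers Keep purely numeric tokens (default `TRUE`; "20
#'   minutes" is topically meaningful in first-aid text).
#' @return Character vector of lemma tokens in original text order (empty
#'   for empty or all-stopword input).
#' @examples
#' tokenize_lemmatize("The burns were treated")
#' @export
tokenize_lemmatize <- function(text, stopwords = default_stopwords(),
                               keep_numbers = TRUE) {
  if (is.null(text) || length(text) == 0L || is.na(text)) return(character())
  clean <- tolower(strip_symbols(text))
  tokens <- strsplit(trimws(clean), "[[:space:]]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (!keep_numbers) tokens <- tokens[!grepl("^[0-9]+$", tokens)]
  tokens <- tokens[!(tokens %in% stopwords)]
  tokens <- lemmatize(tokens)
  tokens[!(tokens %in% stopwords)]
}

#' Preprocess a corpus of raw texts
#'
#' Vectorised convenience over [tokenize_lemmatize()].
#'
#' @param texts Character vector of raw strings.
#' @inheritParams tokenize_lemmatize
#' @return List of token vectors, one per input text.
#' @export
preprocess_corpus <- function(texts, stopwords = default_stopwords(),
                              keep_numbers = TRUE) {
  lapply(texts, tokenize_lemmatize, stopwords = stopwords,
         keep_numbers = keep_numbers)
}
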