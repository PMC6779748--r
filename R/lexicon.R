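# LIWC-style category lexicon and psycholinguistic text features.
#
# A lexicon maps category names to word lists whose entries are lowercase
# literals or prefix patterns ending in '*' (the classic dictionary-lookup
# mechanism: closed-class word lists, no POS tagging). Category usage is
# reported as the proportion of a period's tokens matching the category.

#' Tokenize social-media text
#'
#' Lowercases, drops URLs and @-handles, then extracts maximal runs of
#' letters, digits and apostrophes; punctuation and emoji fall away.
#'
#' @param text Character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize <- function(text) {
  tokenize_many(text)[[1]]
}

# vectorized tokenizer: list of token vectors, one per input string
tokenize_many <- function(texts) {
  x <- tolower(as.character(texts))
  x <- gsub("(https?://|www\\.)[^[:space:]]+", " ", x)
  x <- gsub("@[[:alnum:]_]+", " ", x)
  m <- gregexpr("[a-z0-9']+", x)
  out <- regmatches(x, m)
  lapply(out, function(t) if (length(t) == 1 && t[1] == "") character(0) else t)
}

#' Load a category lexicon
#'
#' Plain-text dic-like format: one category per line,
#' `name: entry, entry, ...`; `#` starts a comment; `*` is allowed only at the
#' end of an entry (prefix pattern). Duplicate entries within a category are
#' deduplicated; an empty category or a malformed line is a parse error naming
#' the line.
#'
#' @param path Lexicon file.
#' @return A `lexicon` object (list with element `categories`).
#' @export
load_lexicon <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cats <- list()
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[ln])
    if (!nzchar(trimws(raw))) next
    m <- regmatches(raw, regexec("^\\s*([^:]+?)\\s*:(.*)$", raw))[[1]]
    if (length(m) != 3)
      stop(sprintf("malformed lexicon line %d: %s", ln, trimws(lines[ln])))
    name <- m[2]
    entries <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
    entries <- tolower(entries[nzchar(entries)])
    if (length(entries) == 0)
      stop(sprintf("empty category '%s' on line %d", name, ln))
    bad <- grepl("\\*.", entries)
    if (any(bad))
      stop(sprintf("'*' must be entry-final (line %d: %s)", ln, entries[bad][1]))
    if (name %in% names(cats))
      stop(sprintf("duplicate category '%s' on line %d", name, ln))
    cats[[name]] <- unique(entries)
  }
  if (length(cats) == 0) stop("no categories in ", path)
  structure(list(categories = cats), class = "lexicon")
}

#' Built-in mini-lexicon
#'
#' Loads the small open lexicon shipped with the package (36 categories
#' covering the screened psycholinguistic features, including pronoun, tense
#' and function-word classes). A user-supplied full dictionary in the same
#' format can be used instead via [load_lexicon()].
#'
#' @return A `lexicon`.
#' @export
default_lexicon <- function() {
  load_lexicon(system.file("extdata", "mini_lexicon.dic",
                           package = "relapsewatch", mustWork = TRUE))
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon> %d categories, %d entries\n",
              length(x$categories), sum(lengths(x$categories))))
  invisible(x)
}

# logical matrix: unique tokens x categories (token matches a literal entry
# or the stem of a '*' entry as prefix)
category_matrix <- function(utok, lexicon) {
  cats <- lexicon$categories
  M <- matrix(FALSE, length(utok), length(cats),
              dimnames = list(NULL, names(cats)))
  for (j in seq_along(cats)) {
    entries <- cats[[j]]
    wild <- endsWith(entries, "*")
    hit <- utok %in% entries[!wild]
    for (stem in sub("\\*$", "", entries[wild])) {
      hit <- hit | startsWith(utok, stem)
    }
    M[, j] <- hit
  }
  M
}

#' Category proportions of a token list
#'
#' A token matches a category if it equals one of its literal entries or
#' begins with the stem of a `*` entry; a token may match several categories.
#' Each proportion is (matching tokens) / (total tokens); all proportions are
#' 0 for an empty token list.
#'
#' @param tokens Character vector of tokens.
#' @param lexicon A `lexicon`.
#' @return Named numeric vector over all lexicon categories, values in [0,1].
#' @export
category_proportions <- function(tokens, lexicon) {
  cats <- names(lexicon$categories)
  if (length(tokens) == 0)
    return(stats::setNames(numeric(length(cats)), cats))
  ut <- unique(tokens)
  M <- category_matrix(ut, lexicon)
  cnt <- as.vector(table(factor(tokens, levels = ut)))
  stats::setNames(as.vector(crossprod(M, cnt)) / length(tokens), cats)
}

# heuristic syllable count: vowel-group runs, minus a silent final 'e'
count_syllables <- function(words) {
  w <- gsub("[^a-z]", "", tolower(words))
  groups <- vapply(gregexpr("[aeiouy]+", w),
                   function(m) sum(m > 0), 0L)
  silent <- grepl("[^aeiouy]e$", w) & !grepl("le$", w) & groups > 1
  syl <- groups - silent
  syl[nchar(w) > 0] <- pmax(syl[nchar(w) > 0], 1L)
  syl
}

#' Structural language features of a period
#'
#' Texts of a period are pooled, then three measures are computed:
#' readability as Flesch Reading Ease (206.835 - 1.015 words/sentence -
#' 84.6 syllables/word, with a vowel-group syllable heuristic; 0 when there
#' are no tokens), repeatability as 1 - distinct/total tokens (0 when at most
#' one token), and the mean number of characters per token (0 when empty).
#'
#' @param texts Character vector: the texts of one period's events.
#' @return Named numeric: `readability`, `repeatability`, `mean_word_length`.
#' @export
structural_features <- function(texts) {
  pooled <- paste(texts, collapse = " ")
  tokens <- tokenize(pooled)
  n <- length(tokens)
  if (n == 0)
    return(c(readability = 0, repeatability = 0, mean_word_length = 0))
  segs <- strsplit(pooled, "[.!?]+")[[1]]
  n_sent <- sum(vapply(tokenize_many(segs), length, 0L) > 0)
  if (n_sent == 0) n_sent <- 1L
  syl <- sum(count_syllables(tokens))
  readability <- 206.835 - 1.015 * (n / n_sent) - 84.6 * (syl / n)
  d <- length(unique(tokens))
  repeatability <- if (n <= 1) 0 else 1 - d / n
  c(readability = readability,
    repeatability = repeatability,
    mean_word_length = mean(nchar(tokens)))
}

#' Unigram vocabulary and usage features
#'
#' `build_vocabulary` picks the `k` most frequent unigrams of a training
#' corpus (ties broken lexicographically); it must only ever see
#' training-split texts so no test information leaks into the feature space.
#' `unigram_features` reports, per vocabulary word, its share of a token
#' list; out-of-vocabulary mass is ignored.
#'
#' @param texts Character vector of training texts.
#' @param k Vocabulary size (>= 1).
#' @return `build_vocabulary`: character vector of at most `k` words.
#' @export
build_vocabulary <- function(texts, k) {
  if (k < 1) stop("vocabulary size k must be >= 1")
  tokens <- unlist(tokenize_many(texts), use.names = FALSE)
  if (length(tokens) == 0) return(character(0))
  tab <- table(tokens)
  ord <- order(-as.vector(tab), names(tab))
  utils::head(names(tab)[ord], k)
}

#' @rdname build_vocabulary
#' @param tokens Character vector of one period's tokens.
#' @param vocabulary Vocabulary from [build_vocabulary()].
#' @return `unigram_features`: named numeric vector (`unigram__<word>`).
#' @export
unigram_features <- function(tokens, vocabulary) {
  nms <- paste0("unigram__", vocabulary)
  if (length(tokens) == 0 || length(vocabulary) == 0)
    return(stats::setNames(numeric(length(vocabulary)), nms))
  cnt <- table(factor(tokens, levels = vocabulary))
  stats::setNames(as.vector(cnt) / length(tokens), nms)
}
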