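#' Preprocessing configuration
#'
#' Controls the text-cleaning pipeline that turns noisy tweet text into token
#' lists for topic modelling. The fixed stage order is: HTML strip, URL and
#' mention removal, lowercasing, hashtag-mark stripping, punctuation removal,
#' whitespace tokenization, elongation squeezing, lexical normalization,
#' stopword removal, optional stemming.
#'
#' @param stopwords character vector of stopwords (default: bundled standard
#'   English list, one word per line in
#'   `system.file("extdata/stopwords_en.txt", package = "trendsent")`).
#' @param norm_lexicon named character vector mapping lexical variants to
#'   canonical forms (`"tmrw"` to `"tomorrow"` and the like); multi-word
#'   canonical forms expand to several tokens. Default: bundled two-column
#'   TSV. Keys must be lowercase and no key may map to itself; the mapping is
#'   applied at most once per token (no chaining).
#' @param squeeze squeeze elongated forms (3+ repeated characters collapse to
#'   2, so `"goooood"` becomes `"good"`) before lexicon lookup.
#' @param stem apply a light regular-suffix stripper (`-ing`, `-ed`, plural
#'   `-s`) after all other stages. Default `FALSE`: topic word lists are more
#'   readable unstemmed.
#' @param remove_stopwords set `FALSE` to keep stopwords.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(stopwords = default_stopwords(),
                              norm_lexicon = default_norm_lexicon(),
                              squeeze = TRUE,
                              stem = FALSE,
                              remove_stopwords = TRUE) {
  stopwords <- tolower(as.character(stopwords))
  if (remove_stopwords && length(stopwords) == 0) {
    stop("stopword removal enabled but the stopword list is empty")
  }
  if (length(norm_lexicon)) {
    if (is.null(names(norm_lexicon)) || any(!nzchar(names(norm_lexicon)))) {
      stop("`norm_lexicon` must be a named character vector")
    }
    if (any(names(norm_lexicon) != tolower(names(norm_lexicon)))) {
      stop("normalization lexicon keys must be lowercase")
    }
    if (any(names(norm_lexicon) == norm_lexicon)) {
      stop("normalization lexicon must not map a token to itself")
    }
  }
  structure(list(stopwords = stopwords, norm_lexicon = norm_lexicon,
                 squeeze = isTRUE(squeeze), stem = isTRUE(stem),
                 remove_stopwords = isTRUE(remove_stopwords)),
            class = "preprocess_config")
}

.asset_cache <- new.env(parent = emptyenv())

#' Bundled default English stopword list
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function() {
  if (is.null(.asset_cache$stopwords)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "trendsent")
    .asset_cache$stopwords <- readLines(path, encoding = "UTF-8")
  }
  .asset_cache$stopwords
}

#' Bundled default lexical-normalization dictionary
#' @return Named character vector: variant token -> canonical form.
#' @export
default_norm_lexicon <- function() {
  if (is.null(.asset_cache$norm_lexicon)) {
    path <- system.file("extdata", "norm_lexicon.tsv", package = "trendsent")
    tab <- read.delim(path, header = FALSE, sep = "\t", quote = "",
                      comment.char = "#", stringsAsFactors = FALSE,
                      encoding = "UTF-8")
    .asset_cache$norm_lexicon <- setNames(tab[[2]], tab[[1]])
  }
  .asset_cache$norm_lexicon
}

#' Read a normalization lexicon from a two-column TSV file
#'
#' @param path TSV file with columns variant, canonical.
#' @return Named character vector suitable for [preprocess_config()].
#' @export
read_norm_lexicon <- function(path) {
  if (!file.exists(path)) stop("normalization lexicon file not found: ", path)
  tab <- read.delim(path, header = FALSE, sep = "\t", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE,
                    encoding = "UTF-8")
  setNames(tab[[2]], tab[[1]])
}

#' Clean raw tweet text
#'
#' Removes HTML tags and entities, URLs and user mentions; strips the `#`
#' from hashtags (the hashtag word itself is kept); lowercases; replaces
#' remaining punctuation with spaces and collapses whitespace. The result may
#' be empty. Cleaning is idempotent.
#'
#' @param x character vector of raw texts.
#' @param cfg a [preprocess_config()] (reserved; cleaning has no options).
#' @return Character vector of cleaned texts.
#' @examples
#' clean_text("Press briefing LIVE https://t.co/xyz #news")
#' @export
clean_text <- function(x, cfg = preprocess_config()) {
  x <- as.character(x)
  x <- gsub("<[^>]*>", " ", x, perl = TRUE)              # HTML tags
  x <- gsub("&[a-zA-Z]+;|&#[0-9]+;", " ", x, perl = TRUE) # HTML entities
  x <- gsub("(https?://|www\\.)\\S+", " ", x, perl = TRUE) # URLs
  x <- gsub("(^|\\s)@\\S+", " ", x, perl = TRUE)          # user mentions
  x <- tolower(x)
  x <- gsub("#", " ", x, fixed = TRUE)                    # keep hashtag word
  x <- gsub("[^\\p{L}\\p{N}\\s]", " ", x, perl = TRUE)    # punctuation
  x <- gsub("\\s+", " ", x, perl = TRUE)
  trimws(x)
}

squeeze_elongation <- function(tokens) {
  gsub("(\\p{L})\\1{2,}", "\\1\\1", tokens, perl = TRUE)
}

light_stem <- function(tokens) {
  out <- sub("(\\p{L}{4,})ing$", "\\1", tokens, perl = TRUE)
  out <- sub("(\\p{L}{3,})ed$", "\\1", out, perl = TRUE)
  out <- sub("(\\p{L}{2,}[^su])s$", "\\1", out, perl = TRUE)
  out
}

#' Tokenize and normalize cleaned text
#'
#' Whitespace tokenization of [clean_text()] output, followed by elongation
#' squeezing (3+ character repeats collapse to 2, then lexicon lookup, so
#' `"comeee"` ends up as `"come"`), lexical-variant substitution (multi-word
#' canonical forms expand), stopword removal and optional light stemming.
#'
#' @param x character vector of cleaned texts.
#' @param cfg a [preprocess_config()].
#' @return A list of character token vectors, one element per input text.
#' @examples
#' tokenize_normalize(clean_text("comeee tmrw"))
#' @export
tokenize_normalize <- function(x, cfg = preprocess_config()) {
  lex <- cfg$norm_lexicon
  lapply(strsplit(as.character(x), "\\s+"), function(tok) {
    tok <- tok[nzchar(tok)]
    if (cfg$squeeze) tok <- squeeze_elongation(tok)
    if (length(lex)) {
      hit <- match(tok, names(lex))
      repl <- ifelse(is.na(hit), tok, lex[hit])
      tok <- unlist(strsplit(repl, " ", fixed = TRUE), use.names = FALSE)
    }
    if (cfg$remove_stopwords) tok <- tok[!(tok %in% cfg$stopwords)]
    if (cfg$stem) tok <- light_stem(tok)
    tok
  })
}

#' Preprocess a tweet stream
#'
#' Adds a `tokens` list-column to the stream: the cleaned, normalized,
#' stopword-free token list of every tweet, ready for topic modelling.
#' Sentiment scoring operates on this same processed stream (see
#' [score_stream()]).
#'
#' @param stream a `tweet_stream`.
#' @param cfg a [preprocess_config()].
#' @param overwrite allow replacing an existing `tokens` annotation.
#' @return The stream with a `tokens` column.
#' @export
preprocess_stream <- function(stream, cfg = preprocess_config(),
                              overwrite = FALSE) {
  stopifnot(inherits(stream, "tweet_stream"))
  check_annotation(stream, "tokens", overwrite)
  stream$tokens <- tokenize_normalize(clean_text(stream$text, cfg), cfg)
  stream
}
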