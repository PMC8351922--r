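# Lexicon-and-rule sentiment engine of the VADER family (valence-aware
# dictionary with heuristics for boosters, negation, capitalisation,
# punctuation emphasis and contrastive "but"). Implemented here because no
# sentiment package ships with the environment; the bundled lexicon is a
# curated subset of the published MIT-licensed ratings.

# Rule constants of the reference algorithm.
B_INCR <- 0.293
B_DECR <- -0.293
C_INCR <- 0.733   # ALL-CAPS emphasis
N_SCALAR <- -0.74 # negation flip-and-damp
ALPHA_NORM <- 15  # compound normalization: s / sqrt(s^2 + alpha)

NEGATE <- c(
  "aint", "arent", "cannot", "cant", "couldnt", "darent", "didnt", "doesnt",
  "ain't", "aren't", "can't", "couldn't", "daren't", "didn't", "doesn't",
  "dont", "hadnt", "hasnt", "havent", "isnt", "mightnt", "mustnt", "neither",
  "don't", "hadn't", "hasn't", "haven't", "isn't", "mightn't", "mustn't",
  "neednt", "needn't", "never", "none", "nope", "nor", "not", "nothing",
  "nowhere", "oughtnt", "shant", "shouldnt", "uhuh", "wasnt", "werent",
  "oughtn't", "shan't", "shouldn't", "uh-uh", "wasn't", "weren't", "without",
  "wont", "wouldnt", "won't", "wouldn't", "rarely", "seldom", "despite"
)

BOOSTER_DICT <- c(
  "absolutely" = B_INCR, "amazingly" = B_INCR, "awfully" = B_INCR,
  "completely" = B_INCR, "considerable" = B_INCR, "considerably" = B_INCR,
  "decidedly" = B_INCR, "deeply" = B_INCR, "effing" = B_INCR,
  "enormous" = B_INCR, "enormously" = B_INCR, "entirely" = B_INCR,
  "especially" = B_INCR, "exceptional" = B_INCR, "exceptionally" = B_INCR,
  "extreme" = B_INCR, "extremely" = B_INCR, "fabulously" = B_INCR,
  "flipping" = B_INCR, "flippin" = B_INCR, "frackin" = B_INCR,
  "fracking" = B_INCR, "fricking" = B_INCR, "frickin" = B_INCR,
  "frigging" = B_INCR, "friggin" = B_INCR, "fully" = B_INCR,
  "fucking" = B_INCR, "fuckin" = B_INCR, "greatly" = B_INCR,
  "hella" = B_INCR, "highly" = B_INCR, "hugely" = B_INCR,
  "incredible" = B_INCR, "incredibly" = B_INCR, "intensely" = B_INCR,
  "major" = B_INCR, "majorly" = B_INCR, "more" = B_INCR, "most" = B_INCR,
  "purely" = B_INCR, "quite" = B_INCR, "really" = B_INCR,
  "remarkably" = B_INCR, "so" = B_INCR, "substantially" = B_INCR,
  "thoroughly" = B_INCR, "total" = B_INCR, "totally" = B_INCR,
  "tremendous" = B_INCR, "tremendously" = B_INCR, "uber" = B_INCR,
  "unbelievably" = B_INCR, "unusually" = B_INCR, "utter" = B_INCR,
  "utterly" = B_INCR, "very" = B_INCR,
  "almost" = B_DECR, "barely" = B_DECR, "hardly" = B_DECR,
  "just enough" = B_DECR, "kind of" = B_DECR, "kinda" = B_DECR,
  "kindof" = B_DECR, "kind-of" = B_DECR, "less" = B_DECR, "little" = B_DECR,
  "marginal" = B_DECR, "marginally" = B_DECR, "occasional" = B_DECR,
  "occasionally" = B_DECR, "partly" = B_DECR, "scarce" = B_DECR,
  "scarcely" = B_DECR, "slight" = B_DECR, "slightly" = B_DECR,
  "somewhat" = B_DECR, "sort of" = B_DECR, "sorta" = B_DECR,
  "sortof" = B_DECR, "sort-of" = B_DECR
)

SPECIAL_CASE_IDIOMS <- c(
  "the shit" = 3, "the bomb" = 3, "bad ass" = 1.5, "badass" = 1.5,
  "bus stop" = 0.0, "yeah right" = -2, "kiss of death" = -1.5,
  "to die for" = 3, "beating heart" = 3.1, "broken heart" = -2.9
)

#' Bundled valence lexicon
#'
#' Loads (and caches) the valence lexicon shipped with the package: a curated
#' subset of the published VADER ratings, one `word<TAB>valence` pair per
#' line, mean valence on the -4..4 scale. Because it is a subset, texts whose
#' sentiment-bearing words fall outside it score closer to neutral than under
#' the full published lexicon.
#'
#' @param path optional path to an alternative lexicon TSV.
#' @return Named numeric vector of word valences.
#' @export
vader_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.asset_cache$vader_lexicon)) {
      p <- system.file("extdata", "valence_lexicon.tsv", package = "trendsent")
      tab <- read.delim(p, header = FALSE, sep = "\t", quote = "",
                        comment.char = "#", stringsAsFactors = FALSE,
                        encoding = "UTF-8")
      .asset_cache$vader_lexicon <- setNames(as.numeric(tab[[2]]), tab[[1]])
    }
    return(.asset_cache$vader_lexicon)
  }
  tab <- read.delim(path, header = FALSE, sep = "\t", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE,
                    encoding = "UTF-8")
  setNames(as.numeric(tab[[2]]), tab[[1]])
}

# --- tokenization helpers ---------------------------------------------------

# ASCII punctuation, as the reference tokenizer strips it.
.PUNC_RE <- "^[!-/:-@\\[-`{-~]+|[!-/:-@\\[-`{-~]+$"

vader_tokens <- function(text) {
  raw <- strsplit(text, "\\s+")[[1]]
  raw <- raw[nzchar(raw)]
  stripped <- gsub(.PUNC_RE, "", raw, perl = TRUE)
  # pure-punctuation tokens (emoticons) are kept verbatim
  ifelse(nzchar(stripped), stripped, raw)
}

is_upper_token <- function(tok) {
  grepl("[A-Z]", tok) & !grepl("[a-z]", tok)
}

# TRUE when some but not all tokens are ALL-CAPS (emphasis is informative
# only in mixed-case text).
allcap_differential <- function(tokens) {
  cased <- tokens[grepl("[A-Za-z]", tokens)]
  n_up <- sum(is_upper_token(cased))
  n_up > 0 && n_up < length(cased)
}

negated <- function(words) {
  any(tolower(words) %in% NEGATE) || any(grepl("n't", tolower(words), fixed = TRUE))
}

# Booster/dampener contribution of `word` preceding a valenced item.
scalar_inc_dec <- function(word, valence, is_cap_diff) {
  wl <- tolower(word)
  if (!(wl %in% names(BOOSTER_DICT))) return(0)
  scalar <- unname(BOOSTER_DICT[[wl]])
  if (valence < 0) scalar <- -scalar
  if (is_upper_token(word) && is_cap_diff) {
    scalar <- scalar + if (valence > 0) C_INCR else -C_INCR
  }
  scalar
}

# --- rule checks ------------------------------------------------------------

negation_check <- function(valence, wl, start_i, i) {
  # indices are 1-based; start_i in 0:2 is the distance being examined
  if (start_i == 0) {
    if (negated(wl[i - 1])) valence <- valence * N_SCALAR
  } else if (start_i == 1) {
    if (wl[i - 2] == "never" && wl[i - 1] %in% c("so", "this")) {
      valence <- valence * 1.25
    } else if (wl[i - 2] == "without" && wl[i - 1] == "doubt") {
      # "without doubt" is not a negation
    } else if (negated(wl[i - 2])) {
      valence <- valence * N_SCALAR
    }
  } else if (start_i == 2) {
    if (wl[i - 3] == "never" &&
        (wl[i - 2] %in% c("so", "this") || wl[i - 1] %in% c("so", "this"))) {
      valence <- valence * 1.25
    } else if (wl[i - 3] == "without" &&
               (wl[i - 2] == "doubt" || wl[i - 1] == "doubt")) {
      # not a negation
    } else if (negated(wl[i - 3])) {
      valence <- valence * N_SCALAR
    }
  }
  valence
}

special_idioms_check <- function(valence, wl, i) {
  n <- length(wl)
  seqs <- c(
    paste(wl[i - 1], wl[i]),
    paste(wl[i - 2], wl[i - 1], wl[i]),
    paste(wl[i - 2], wl[i - 1]),
    paste(wl[i - 3], wl[i - 2], wl[i - 1]),
    paste(wl[i - 3], wl[i - 2])
  )
  for (s in seqs) {
    if (s %in% names(SPECIAL_CASE_IDIOMS)) {
      valence <- unname(SPECIAL_CASE_IDIOMS[[s]])
      break
    }
  }
  if (n > i) {
    s <- paste(wl[i], wl[i + 1])
    if (s %in% names(SPECIAL_CASE_IDIOMS)) valence <- unname(SPECIAL_CASE_IDIOMS[[s]])
  }
  if (n > i + 1) {
    s <- paste(wl[i], wl[i + 1], wl[i + 2])
    if (s %in% names(SPECIAL_CASE_IDIOMS)) valence <- unname(SPECIAL_CASE_IDIOMS[[s]])
  }
  for (s in c(paste(wl[i - 3], wl[i - 2]), paste(wl[i - 2], wl[i - 1]))) {
    if (s %in% names(BOOSTER_DICT)) valence <- valence + unname(BOOSTER_DICT[[s]])
  }
  valence
}

least_check <- function(valence, wl, i, lexicon) {
  if (i > 2 && !(wl[i - 1] %in% names(lexicon)) && wl[i - 1] == "least") {
    if (!(wl[i - 2] %in% c("at", "very"))) valence <- valence * N_SCALAR
  } else if (i > 1 && !(wl[i - 1] %in% names(lexicon)) && wl[i - 1] == "least") {
    valence <- valence * N_SCALAR
  }
  valence
}

but_check <- function(wl, sentiments) {
  bi <- match("but", wl)
  if (!is.na(bi)) {
    before <- seq_along(sentiments) < bi
    after <- seq_along(sentiments) > bi
    sentiments[before] <- sentiments[before] * 0.5
    sentiments[after] <- sentiments[after] * 1.5
  }
  sentiments
}

punctuation_emphasis <- function(text) {
  ep <- min(lengths(regmatches(text, gregexpr("!", text, fixed = TRUE))), 4) * 0.292
  qm_count <- lengths(regmatches(text, gregexpr("?", text, fixed = TRUE)))
  qm <- if (qm_count > 1) {
    if (qm_count <= 3) qm_count * 0.18 else 0.96
  } else 0
  ep + qm
}

# Valence of token i after all context rules.
token_valence <- function(tokens, wl, i, is_cap_diff, lexicon) {
  item_l <- wl[i]
  if (!(item_l %in% names(lexicon))) return(0)
  valence <- unname(lexicon[[item_l]])
  n <- length(wl)
  # "no" before a lexicon word acts as a negator, not as a lexicon item
  if (item_l == "no" && i < n && wl[i + 1] %in% names(lexicon)) {
    valence <- 0
  }
  if ((i > 1 && wl[i - 1] == "no") ||
      (i > 2 && wl[i - 2] == "no") ||
      (i > 3 && wl[i - 3] == "no" && wl[i - 1] %in% c("or", "nor"))) {
    valence <- unname(lexicon[[item_l]]) * N_SCALAR
  }
  if (is_upper_token(tokens[i]) && is_cap_diff) {
    valence <- valence + if (valence > 0) C_INCR else -C_INCR
  }
  for (start_i in 0:2) {
    j <- i - (start_i + 1)
    if (j >= 1 && !(wl[j] %in% names(lexicon))) {
      s <- scalar_inc_dec(tokens[j], valence, is_cap_diff)
      if (start_i == 1 && s != 0) s <- s * 0.95
      if (start_i == 2 && s != 0) s <- s * 0.9
      valence <- valence + s
      valence <- negation_check(valence, wl, start_i, i)
      if (start_i == 2) valence <- special_idioms_check(valence, wl, i)
    }
  }
  least_check(valence, wl, i, lexicon)
}

vader_normalize <- function(s) {
  out <- s / sqrt(s * s + ALPHA_NORM)
  pmin(pmax(out, -1), 1)
}

score_one <- function(text, lexicon) {
  if (is.na(text) || !nzchar(trimws(text))) {
    # all-neutral convention for empty input
    return(c(pos = 0, neg = 0, neu = 1, compound = 0))
  }
  tokens <- vader_tokens(text)
  if (length(tokens) == 0) return(c(pos = 0, neg = 0, neu = 1, compound = 0))
  wl <- tolower(tokens)
  is_cap_diff <- allcap_differential(tokens)
  n <- length(tokens)
  sentiments <- numeric(n)
  for (i in seq_len(n)) {
    if (wl[i] %in% names(BOOSTER_DICT) ||
        (i < n && wl[i] == "kind" && wl[i + 1] == "of")) {
      sentiments[i] <- 0
    } else {
      sentiments[i] <- token_valence(tokens, wl, i, is_cap_diff, lexicon)
    }
  }
  sentiments <- but_check(wl, sentiments)
  s_total <- sum(sentiments)
  punct <- punctuation_emphasis(text)
  if (s_total > 0) s_total <- s_total + punct
  if (s_total < 0) s_total <- s_total - punct
  compound <- vader_normalize(s_total)
  pos_sum <- sum(sentiments[sentiments > 0] + 1)
  neg_sum <- sum(sentiments[sentiments < 0] - 1)
  neu_count <- sum(sentiments == 0)
  if (pos_sum > abs(neg_sum)) pos_sum <- pos_sum + punct
  if (pos_sum < abs(neg_sum)) neg_sum <- neg_sum - punct
  total <- pos_sum + abs(neg_sum) + neu_count
  if (total > 0) {
    pos <- abs(pos_sum / total)
    neg <- abs(neg_sum / total)
    neu <- abs(neu_count / total)
  } else {
    pos <- 0; neg <- 0; neu <- 0
  }
  c(pos = round(pos, 3), neg = round(neg, 3), neu = round(neu, 3),
    compound = round(compound, 4))
}

#' Rule-based sentiment scores for texts
#'
#' Scores each text with the valence lexicon plus the reference rule set:
#' degree boosters and dampeners (with distance damping), negation (including
#' "no", "n't" forms, "never so/this" intensification and the "at least" /
#' "without doubt" exceptions), ALL-CAPS emphasis in mixed-case text,
#' exclamation/question-mark emphasis, contrastive "but" reweighting, and a
#' handful of idioms. The raw valence sum is normalized to the compound score
#' \eqn{\varrho = s / \sqrt{s^2 + 15}}, bounded in \eqn{[-1, 1]}; `pos`,
#' `neg`, `neu` are the proportions of the text's tokens in each category
#' (summing to 1 within rounding).
#'
#' Empty or all-whitespace input scores `pos = neg = 0, neu = 1, compound = 0`
#' by convention.
#'
#' @param text character vector of texts (raw or preprocessed).
#' @param lexicon named numeric valence vector; default [vader_lexicon()].
#' @return A data frame with columns `pos`, `neg`, `neu`, `compound`, one row
#'   per text. Proportions are rounded to 3 decimals, the compound to 4, as
#'   in the reference implementation.
#' @examples
#' vader_scores(c("this is great", "this is not great", "the table stands"))
#' @export
vader_scores <- function(text, lexicon = vader_lexicon()) {
  text <- as.character(text)
  out <- t(vapply(text, score_one, numeric(4), lexicon = lexicon,
                  USE.NAMES = FALSE))
  colnames(out) <- c("pos", "neg", "neu", "compound")
  as.data.frame(out)
}

#' Classify a compound sentiment score
#'
#' Threshold classification with inclusive boundaries: positive when
#' \eqn{\varrho \ge 0.05}, negative when \eqn{\varrho \le -0.05}, neutral in
#' the open interval between.
#'
#' @param compound numeric vector of compound scores in \eqn{[-1, 1]}.
#' @param threshold positive cutoff (the negative cutoff is its mirror).
#' @return Factor with levels `negative`, `neutral`, `positive`.
#' @export
classify_sentiment <- function(compound, threshold = 0.05) {
  stopifnot(is.numeric(compound), threshold > 0)
  out <- ifelse(compound >= threshold, "positive",
                ifelse(compound <= -threshold, "negative", "neutral"))
  factor(out, levels = c("negative", "neutral", "positive"))
}
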