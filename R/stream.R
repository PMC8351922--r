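#' Construct a tweet stream
#'
#' A tweet stream is a data frame with one row per tweet, sorted by timestamp,
#' carrying the raw record plus (optionally) annotation columns filled in by
#' later pipeline stages: `tokens` (list column, from [preprocess_stream()]),
#' `topic` (integer, from [assign_topics()]) and sentiment columns
#' (`pos`, `neg`, `neu`, `compound`, `label`, from [score_stream()]).
#'
#' Invariants enforced here: tweet ids are unique, texts are non-empty,
#' timestamps are UTC instants, rows are sorted non-decreasing by timestamp.
#' The stream's span `[t_first, t_last]` is kept as an attribute.
#'
#' @param tweet_id character vector of unique tweet ids.
#' @param user_id character vector of user ids.
#' @param timestamp `POSIXct` vector (converted to UTC).
#' @param text character vector of raw tweet texts (non-empty).
#' @return An object of class `tweet_stream` (a data frame).
#' @export
tweet_stream <- function(tweet_id, user_id, timestamp, text) {
  tweet_id <- as.character(tweet_id)
  user_id <- as.character(user_id)
  text <- as.character(text)
  if (!inherits(timestamp, "POSIXct")) {
    stop("`timestamp` must be POSIXct")
  }
  attr(timestamp, "tzone") <- "UTC"
  n <- length(tweet_id)
  if (length(user_id) != n || length(timestamp) != n || length(text) != n) {
    stop("all fields must have the same length")
  }
  if (anyDuplicated(tweet_id)) {
    stop("tweet ids must be unique within a stream")
  }
  if (n > 0 && any(!nzchar(text) | is.na(text))) {
    stop("tweet texts must be non-empty")
  }
  if (any(is.na(timestamp))) {
    stop("timestamps must not be NA")
  }
  df <- data.frame(
    tweet_id = tweet_id, user_id = user_id,
    timestamp = timestamp, text = text,
    stringsAsFactors = FALSE
  )
  df <- df[order(df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("tweet_stream", "data.frame")
  attr(df, "span") <- if (n > 0) range(df$timestamp) else NULL
  attr(df, "skipped") <- 0L
  df
}

#' Span of a tweet stream
#'
#' @param x a `tweet_stream`.
#' @return A length-2 `POSIXct` vector `[t_first, t_last]`, or `NULL` for an
#'   empty stream (the "span undefined" degenerate case).
#' @export
stream_span <- function(x) {
  stopifnot(inherits(x, "tweet_stream"))
  attr(x, "span")
}

#' @export
print.tweet_stream <- function(x, ...) {
  cat(sprintf(
    "Tweet stream: %d tweets, %d users\n",
    nrow(x), length(unique(x$user_id))
  ))
  sp <- attr(x, "span")
  if (!is.null(sp)) {
    cat(sprintf("  span: %s -- %s (UTC)\n", format(sp[1]), format(sp[2])))
  } else {
    cat("  span: undefined (empty stream)\n")
  }
  sk <- attr(x, "skipped")
  if (!is.null(sk) && sk > 0) cat(sprintf("  skipped on read: %d\n", sk))
  ann <- intersect(c("tokens", "topic", "compound", "label"), names(x))
  if (length(ann)) cat("  annotations:", paste(ann, collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.tweet_stream` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("tweet_id", "timestamp") %in% names(out))) {
    class(out) <- c("tweet_stream", "data.frame")
    attr(out, "span") <- attr(x, "span")
    attr(out, "skipped") <- attr(x, "skipped")
  } else if (is.data.frame(out)) {
    class(out) <- "data.frame"
  }
  out
}

# Parse ISO-8601-ish timestamps to POSIXct UTC; NA where unparseable.
parse_iso8601 <- function(x) {
  x <- as.character(x)
  x <- sub("Z$", "", x)
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC", tryFormats = c(
    "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d"
  ), optional = TRUE)
  out
}

#' Read a tweet stream from a JSON Lines file
#'
#' One JSON object per line, UTF-8. Field names are configurable through
#' `field_map`; the defaults match common Twitter export layouts. Malformed
#' lines (unparseable JSON, missing fields, unparseable timestamps, empty
#' text) are skipped with a warning; the number skipped is kept in the
#' `skipped` attribute of the result.
#'
#' @param path path to a JSONL file.
#' @param field_map named character vector mapping the roles `id`, `user`,
#'   `time`, `text` to the JSON keys that carry them.
#' @return A [tweet_stream()], sorted by timestamp. An empty file yields an
#'   empty stream with `NULL` span.
#' @export
read_tweet_stream <- function(path,
                              field_map = c(id = "id", user = "user_id",
                                            time = "created_at", text = "text")) {
  if (!file.exists(path)) stop("cannot read stream: file not found: ", path)
  stopifnot(all(c("id", "user", "time", "text") %in% names(field_map)))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  skipped <- 0L
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]), error = function(e) NULL)
    ok <- is.list(rec) && all(field_map %in% names(rec))
    if (ok) {
      ts <- parse_iso8601(rec[[field_map[["time"]]]])
      txt <- as.character(rec[[field_map[["text"]]]])
      if (!is.na(ts) && length(txt) == 1 && !is.na(txt) && nzchar(txt)) {
        recs[[i]] <- data.frame(
          tweet_id = as.character(rec[[field_map[["id"]]]]),
          user_id = as.character(rec[[field_map[["user"]]]]),
          timestamp = ts, text = txt, stringsAsFactors = FALSE
        )
      } else {
        ok <- FALSE
      }
    }
    if (!ok) skipped <- skipped + 1L
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (skipped > 0) {
    warning(sprintf("skipped %d malformed line(s) in %s", skipped, path))
  }
  if (length(recs) == 0) {
    out <- tweet_stream(character(), character(),
                        as.POSIXct(character(), tz = "UTC"), character())
  } else {
    df <- do.call(rbind, recs)
    out <- tweet_stream(df$tweet_id, df$user_id, df$timestamp, df$text)
  }
  attr(out, "skipped") <- skipped
  out
}

#' Write a tweet stream as JSON Lines
#'
#' Inverse of [read_tweet_stream()]: raw fields round-trip bit-identically.
#' Annotation columns are not serialized.
#'
#' @param x a `tweet_stream`.
#' @param path output file path.
#' @param field_map as in [read_tweet_stream()].
#' @return `path`, invisibly.
#' @export
write_tweet_stream <- function(x, path,
                               field_map = c(id = "id", user = "user_id",
                                             time = "created_at", text = "text")) {
  stopifnot(inherits(x, "tweet_stream"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    rec <- list()
    rec[[field_map[["id"]]]] <- x$tweet_id[i]
    rec[[field_map[["user"]]]] <- x$user_id[i]
    rec[[field_map[["time"]]]] <- format(x$timestamp[i], "%Y-%m-%dT%H:%M:%SZ",
                                         tz = "UTC")
    rec[[field_map[["text"]]]] <- x$text[i]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con, useBytes = TRUE)
  }
  invisible(path)
}

# Guard against silently overwriting an annotation column already present.
check_annotation <- function(x, col, overwrite) {
  if (col %in% names(x) && !overwrite) {
    stop(sprintf(
      "stream already carries a `%s` annotation; pass overwrite = TRUE to replace it",
      col
    ))
  }
  invisible(TRUE)
}
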