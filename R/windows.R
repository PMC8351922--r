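#' Sliding-window configuration
#'
#' Defines the overlapping-window partition of a stream's span: windows have
#' fixed length `len` and consecutive windows are shifted by `shift`
#' (`0 < shift <= len`, so overlap is allowed but gaps are not). Durations can
#' be given as seconds or as strings like `"3d"`, `"12h"`, `"30m"`, `"45s"`.
#'
#' @param len window length (duration).
#' @param shift shift between consecutive window starts (duration).
#' @param origin optional `POSIXct` anchor for the first window start; default
#'   is the span start of the stream being partitioned.
#' @return An object of class `window_config`.
#' @examples
#' window_config("3d", "1d")
#' @export
window_config <- function(len, shift, origin = NULL) {
  len <- parse_duration(len)
  shift <- parse_duration(shift)
  if (!is.finite(len) || len <= 0) stop("window length must be > 0")
  if (!is.finite(shift) || shift <= 0 || shift > len) {
    stop("window shift must satisfy 0 < shift <= len (overlap allowed, gaps not)")
  }
  if (!is.null(origin)) {
    stopifnot(inherits(origin, "POSIXct"))
    attr(origin, "tzone") <- "UTC"
  }
  structure(list(len = len, shift = shift, origin = origin),
            class = "window_config")
}

#' @export
print.window_config <- function(x, ...) {
  cat(sprintf("Window config: len = %s, shift = %s%s\n",
              format_duration(x$len), format_duration(x$shift),
              if (is.null(x$origin)) "" else paste0(", origin = ", format(x$origin))))
  invisible(x)
}

parse_duration <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (inherits(x, "difftime")) return(as.numeric(x, units = "secs"))
  if (is.character(x) && length(x) == 1) {
    m <- regmatches(x, regexec("^([0-9.]+)([dhms])$", x))[[1]]
    if (length(m) == 3) {
      mult <- c(d = 86400, h = 3600, m = 60, s = 1)[[m[3]]]
      return(as.numeric(m[2]) * mult)
    }
  }
  stop("cannot parse duration: ", deparse(x))
}

format_duration <- function(secs) {
  if (secs %% 86400 == 0) return(sprintf("%gd", secs / 86400))
  if (secs %% 3600 == 0) return(sprintf("%gh", secs / 3600))
  if (secs %% 60 == 0) return(sprintf("%gm", secs / 60))
  sprintf("%gs", secs)
}

#' Partition a stream's span into (overlapping) time windows
#'
#' Window m starts at `origin + (m-1) * shift` and covers the half-open
#' interval `[start, start + len)`. Starts are emitted while the window fits
#' entirely within the span; if the retained windows do not reach the span
#' end, one final (overrunning) window is appended so that the union of
#' windows covers the span. With `shift == len` the windows are disjoint; with
#' `shift < len` consecutive windows overlap by `len - shift`.
#'
#' @param x a `tweet_stream`, or a length-2 `POSIXct` giving the span
#'   directly.
#' @param cfg a [window_config()].
#' @param span_end optional explicit span end; by default the stream span end
#'   (exclusive end = last timestamp). For calendar-date spans, pass the
#'   instant one unit past the last covered moment.
#' @return A data frame of class `time_windows` with columns `index`, `start`,
#'   `end`.
#' @examples
#' sp <- as.POSIXct(c("2020-03-23", "2020-04-01"), tz = "UTC")
#' time_windows(sp, window_config("3d", "1d"))  # 7 windows
#' @export
time_windows <- function(x, cfg, span_end = NULL) {
  stopifnot(inherits(cfg, "window_config"))
  if (inherits(x, "tweet_stream")) {
    sp <- stream_span(x)
    if (is.null(sp)) stop("empty stream: span undefined; pass the span explicitly")
  } else if (inherits(x, "POSIXct") && length(x) == 2) {
    sp <- x
  } else {
    stop("`x` must be a tweet_stream or a length-2 POSIXct span")
  }
  attr(sp, "tzone") <- "UTC"
  if (!is.null(span_end)) sp[2] <- span_end
  if (sp[2] < sp[1]) stop("span end precedes span start")
  origin <- if (is.null(cfg$origin)) sp[1] else cfg$origin
  span_secs <- as.numeric(difftime(sp[2], origin, units = "secs"))
  # all starts s with s + len <= span end
  n_fit <- if (span_secs < cfg$len) 0L else floor((span_secs - cfg$len) / cfg$shift) + 1
  starts <- origin + cfg$shift * seq_len(max(n_fit, 0)) - cfg$shift
  covered <- if (n_fit > 0) as.numeric(difftime(starts[n_fit] + cfg$len, origin,
                                                units = "secs")) else 0
  if (covered < span_secs) {
    # one overrunning window so the union still covers the span
    starts <- c(starts, origin + cfg$shift * n_fit)
  }
  out <- data.frame(
    index = seq_along(starts),
    start = as.POSIXct(starts, tz = "UTC"),
    end = as.POSIXct(starts, tz = "UTC") + cfg$len
  )
  class(out) <- c("time_windows", "data.frame")
  attr(out, "config") <- cfg
  out
}

#' @export
print.time_windows <- function(x, ...) {
  cat(sprintf("%d time window(s), half-open [start, end):\n", nrow(x)))
  print.data.frame(x)
  invisible(x)
}

#' Tweets falling in one time window
#'
#' Membership is half-open: a tweet belongs to window m iff
#' `start_m <= t < end_m`. With overlapping windows a tweet can belong to
#' several windows. Original stream order is preserved.
#'
#' @param stream a `tweet_stream`.
#' @param window one row of a [time_windows()] frame (or a list with `start`
#'   and `end`).
#' @return The sub-stream of tweets in the window.
#' @export
tweets_in_window <- function(stream, window) {
  stopifnot(inherits(stream, "tweet_stream"))
  keep <- stream$timestamp >= window$start & stream$timestamp < window$end
  stream[keep, , drop = FALSE]
}

#' Per-window tweet counts
#'
#' @param stream a `tweet_stream`.
#' @param windows a [time_windows()] frame.
#' @return The `windows` frame with an added `n_tweets` column.
#' @export
window_counts <- function(stream, windows) {
  windows$n_tweets <- vapply(
    seq_len(nrow(windows)),
    function(i) nrow(tweets_in_window(stream, windows[i, ])),
    integer(1)
  )
  windows
}
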