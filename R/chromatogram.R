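#' Construct a chromatogram trace object
#'
#' A `sanger_trace` is a data frame with one row per position and columns
#' `pos` (contiguous 1-based index), `A`, `C`, `G`, `T` (non-negative
#' channel intensities), `call` (called base, always the argmax channel with
#' ties broken in A < C < G < T order) and `strand`.
#'
#' @param df Data frame with the columns above (`call` is recomputed and
#'   checked).
#' @return The validated `sanger_trace`.
#' @export
as_sanger_trace <- function(df) {
  need <- c("pos", "A", "C", "G", "T", "call", "strand")
  if (!all(need %in% names(df))) {
    stop("trace needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[, need]
  if (!identical(as.integer(df$pos), seq_len(nrow(df)))) {
    stop("trace positions must be contiguous from 1", call. = FALSE)
  }
  m <- as.matrix(df[, c("A", "C", "G", "T")])
  if (any(m < 0)) stop("negative channel intensity", call. = FALSE)
  argmax <- c("A", "C", "G", "T")[apply(m, 1L, which.max)]
  bad <- which(toupper(df$call) != argmax)
  if (length(bad)) {
    stop("called base is not the argmax channel at position ", bad[1L],
         call. = FALSE)
  }
  if (length(unique(df$strand)) != 1L ||
      !df$strand[1L] %in% c("forward", "reverse")) {
    stop("strand must be a single value, 'forward' or 'reverse'",
         call. = FALSE)
  }
  df$pos <- as.integer(df$pos)
  df$call <- toupper(df$call)
  class(df) <- c("sanger_trace", "data.frame")
  df
}

#' Called-base sequence of a trace
#'
#' @param trace A `sanger_trace`.
#' @return Single character string.
#' @export
trace_sequence <- function(trace) paste(trace$call, collapse = "")

#' Peak intensity triplet at a query site
#'
#' Holds the three intensities entering the S- and N-value statistics:
#' `i1` the main peak at the site, `i2` the secondary peak at the site, and
#' `i0` the average noise intensity over a window around the site.
#'
#' @param i0,i1,i2 Non-negative intensities with `i1 >= i2`.
#' @param site Optional 1-based site index.
#' @param window Optional inclusive window range used for `i0`.
#' @return An object of class `peak_triplet`.
#' @examples
#' s_value(peak_triplet(i0 = 110, i1 = 850, i2 = 150))  # 0.15
#' @export
peak_triplet <- function(i0, i1, i2, site = NA_integer_, window = NULL) {
  if (i0 < 0 || i1 < 0 || i2 < 0) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  if (i2 > i1) stop("i1 must be the larger of the two site peaks",
                    call. = FALSE)
  structure(list(i0 = i0, i1 = i1, i2 = i2, site = site, window = window),
            class = "peak_triplet")
}

#' Extract the peak triplet at a site
#'
#' `i1` and `i2` are the largest and second-largest channel intensities at
#' the query site.  `i0` is the mean, over the window positions excluding
#' the site itself, of each position's second-largest channel: the main peak
#' at a neighbouring position is true signal, so its runner-up channel is
#' the natural noise analogue of `i2`.  Window endpoints are arguments so
#' other conventions remain one call away.
#'
#' @param trace A `sanger_trace`.
#' @param site 1-based query position.
#' @param window Length-2 inclusive range; defaults to `site + c(-5, 5)`,
#'   matching a noise window of the 117th-127th positions for site 122.
#' @return A [peak_triplet()].
#' @export
extract_peaks <- function(trace, site, window = site + c(-5L, 5L)) {
  stopifnot(inherits(trace, "sanger_trace"))
  L <- nrow(trace)
  window <- as.integer(window)
  if (length(window) != 2L || window[1L] > window[2L]) {
    stop("window must be an increasing length-2 range", call. = FALSE)
  }
  if (site < window[1L] || site > window[2L]) {
    stop("window must contain the query site", call. = FALSE)
  }
  if (window[1L] < 1L || window[2L] > L) {
    stop("window extends beyond the trace", call. = FALSE)
  }
  noise_pos <- setdiff(window[1L]:window[2L], site)
  if (length(noise_pos) < 3L) {
    stop("fewer than 3 noise positions after excluding the site; ",
         "widen the window", call. = FALSE)
  }
  m <- as.matrix(trace[, c("A", "C", "G", "T")])
  at_site <- sort(m[site, ], decreasing = TRUE)
  second <- apply(m[noise_pos, , drop = FALSE], 1L,
                  function(x) sort(x, decreasing = TRUE)[2L])
  peak_triplet(i0 = mean(second), i1 = at_site[[1L]], i2 = at_site[[2L]],
               site = as.integer(site), window = window)
}

#' Secondary-peak ratio (S-value)
#'
#' `S = I2 / (I1 + I2)`: the fraction of site signal carried by the
#' secondary peak; the proxy for the minor-template fraction.
#'
#' @param p A [peak_triplet()].
#' @return Fraction in [0, 0.5].
#' @export
s_value <- function(p) {
  stopifnot(inherits(p, "peak_triplet"))
  if (p$i1 + p$i2 <= 0) stop("empty signal: i1 + i2 = 0", call. = FALSE)
  p$i2 / (p$i1 + p$i2)
}

#' Background-noise ratio (N-value)
#'
#' `N = I0 / (I0 + I1)`: the noise floor expressed on the same scale as the
#' S-value, so the two are directly comparable in the variance analysis.
#'
#' @param p A [peak_triplet()].
#' @return Fraction in [0, 1].
#' @export
n_value <- function(p) {
  stopifnot(inherits(p, "peak_triplet"))
  if (p$i0 + p$i1 <= 0) stop("empty signal: i0 + i1 = 0", call. = FALSE)
  p$i0 / (p$i0 + p$i1)
}

## per-position secondary ratio second/(top+second) for a whole trace
.per_position_s <- function(trace) {
  m <- as.matrix(trace[, c("A", "C", "G", "T")])
  apply(m, 1L, function(x) {
    s <- sort(x, decreasing = TRUE)
    if (s[1L] + s[2L] <= 0) 0 else s[2L] / (s[1L] + s[2L])
  })
}

#' Write a trace to the tabular trace dialect
#'
#' One row per position, TSV with header `pos A C G T call strand`.
#'
#' @param trace A `sanger_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sanger_trace"))
  utils::write.table(trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a trace from the tabular trace dialect
#'
#' Validates the file row by row: negative intensities, non-contiguous
#' indices, or malformed rows raise an error naming the offending line
#' (line 1 is the header).
#'
#' @param path File written by [write_trace()].
#' @return A `sanger_trace`.
#' @export
read_trace <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  need <- c("pos", "A", "C", "G", "T", "call", "strand")
  if (!all(need %in% names(df))) {
    stop("malformed trace file (line 1): expected header '",
         paste(need, collapse = " "), "'", call. = FALSE)
  }
  for (col in c("A", "C", "G", "T")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0)
    if (length(bad)) {
      stop("negative or non-numeric ", col, " intensity (line ",
           bad[1L] + 1L, ")", call. = FALSE)
    }
  }
  bad <- which(as.integer(df$pos) != seq_len(nrow(df)))
  if (length(bad)) {
    stop("non-contiguous position index (line ", bad[1L] + 1L, ")",
         call. = FALSE)
  }
  as_sanger_trace(df)
}
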