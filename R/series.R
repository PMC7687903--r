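#' Count time series
#'
#' Container for a regularly spaced series of non-negative integer event
#' counts, e.g. weekly case reports or daily posts on a topic. Spacing is
#' implicit: the series carries an integer time origin and index arithmetic
#' only, no timestamps.
#'
#' Fractional values are rejected rather than rounded: a count arriving as
#' 3.5 almost always signals an upstream error (pre-normalised rates, joined
#' columns), and silent coercion would mask it. Integer-valued doubles
#' (e.g. the literal `3`) are accepted.
#'
#' @param values numeric vector of non-negative integer counts, length >= 1.
#' @param start_index integer time origin of the first observation.
#' @param label free-text label carried through sampling and windowing.
#' @return An object of class `count_series`.
#' @examples
#' x <- count_series(c(3, 0, 7), label = "toy")
#' length(x)
#' @export
count_series <- function(values, start_index = 1L, label = "") {
  if (length(values) < 1L) {
    stop("a count series needs at least one value", call. = FALSE)
  }
  if (!is.numeric(values) || anyNA(values)) {
    stop("counts must be numeric and free of missing values", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(values != trunc(values))) {
    stop("counts must be integer-valued; fractional counts are rejected, not rounded",
         call. = FALSE)
  }
  structure(
    list(values = as.double(values),
         start_index = as.integer(start_index)[1L],
         label = as.character(label)[1L]),
    class = "count_series"
  )
}

#' Real-valued time series (external signal)
#'
#' Container for a regularly spaced real-valued series, used for external
#' signals S that may carry information about a ground-truth count process
#' (search-trend proxies, prices, temperatures).
#'
#' @param values numeric vector, length >= 1, no missing values.
#' @param label free-text label.
#' @return An object of class `real_series`.
#' @export
real_series <- function(values, label = "") {
  if (length(values) < 1L) {
    stop("a real series needs at least one value", call. = FALSE)
  }
  if (!is.numeric(values) || anyNA(values)) {
    stop("values must be numeric and free of missing values", call. = FALSE)
  }
  structure(
    list(values = as.double(values), label = as.character(label)[1L]),
    class = "real_series"
  )
}

#' @export
length.count_series <- function(x) length(x$values)

#' @export
length.real_series <- function(x) length(x$values)

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("<count_series> %s: T=%d, mean=%.3f, var=%.3f\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$values), mean(x$values), stats::var(x$values)))
  invisible(x)
}

#' @export
print.real_series <- function(x, ...) {
  cat(sprintf("<real_series> %s: T=%d, mean=%.3f, sd=%.3f\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$values), mean(x$values), stats::sd(x$values)))
  invisible(x)
}

# Accept a series object or a bare numeric vector; return the values.
series_values <- function(x) {
  if (inherits(x, "count_series") || inherits(x, "real_series")) {
    return(x$values)
  }
  if (is.numeric(x)) {
    return(as.double(x))
  }
  stop("expected a count_series, real_series or numeric vector", call. = FALSE)
}

#' Read / write count series as CSV
#'
#' The on-disk format is a two-column UTF-8 CSV with header `t,count`
#' (`t,value` for real series): one row per interval, comma delimited.
#'
#' @param path file path.
#' @param label label attached to the returned series (defaults to the
#'   file name).
#' @return `read_count_series` returns a `count_series`;
#'   `read_real_series` a `real_series`; the writers return the path,
#'   invisibly.
#' @export
read_count_series <- function(path, label = basename(path)) {
  df <- utils::read.csv(path, header = TRUE)
  if (!all(c("t", "count") %in% names(df))) {
    stop("expected columns 't' and 'count' in ", path, call. = FALSE)
  }
  df <- df[order(df$t), , drop = FALSE]
  count_series(df$count, start_index = as.integer(df$t[1L]), label = label)
}

#' @rdname read_count_series
#' @param x the series to write.
#' @export
write_count_series <- function(x, path) {
  stopifnot(inherits(x, "count_series"))
  t <- seq.int(x$start_index, length.out = length(x$values))
  utils::write.csv(data.frame(t = t, count = as.integer(x$values)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_count_series
#' @export
read_real_series <- function(path, label = basename(path)) {
  df <- utils::read.csv(path, header = TRUE)
  if (!all(c("t", "value") %in% names(df))) {
    stop("expected columns 't' and 'value' in ", path, call. = FALSE)
  }
  df <- df[order(df$t), , drop = FALSE]
  real_series(df$value, label = label)
}

#' @rdname read_count_series
#' @export
write_real_series <- function(x, path) {
  stopifnot(inherits(x, "real_series"))
  utils::write.csv(data.frame(t = seq_along(x$values), value = x$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
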