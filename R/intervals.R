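#' Genomic interval
#'
#' A single stranded interval on a named sequence. Coordinates are stored
#' 0-based half-open throughout the package; GFF3/BED I/O converts at the
#' boundary.
#'
#' @param seq_id Sequence (chromosome/scaffold) name, nonempty.
#' @param start,end 0-based half-open bounds, `0 <= start < end`.
#' @param strand One of `"+"`, `"-"`, `"*"`.
#' @return An object of class `genomic_interval`.
#' @examples
#' gi <- genomic_interval("Ra02", 100, 200)
#' interval_length(gi)
#' @export
genomic_interval <- function(seq_id, start, end, strand = "*") {
  if (!is.character(seq_id) || length(seq_id) != 1L || !nzchar(seq_id))
    stop("seq_id must be a nonempty string")
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || start >= end)
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  if (!strand %in% c("+", "-", "*"))
    stop("strand must be one of '+', '-', '*'")
  structure(list(seq_id = seq_id, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:[%s, %s) %s>\n", x$seq_id,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              x$strand))
  invisible(x)
}

#' Interval length under a coordinate convention
#'
#' Lengths differ by one between the internal 0-based half-open convention
#' (`end - start`) and the 1-based fully-closed convention used in printed
#' coordinate ranges (`end - start + 1`).
#'
#' @param a A [genomic_interval], or a numeric vector `c(start, end)`.
#' @param convention `"internal"` (half-open) or `"one_based_inclusive"`.
#' @return Length in base pairs.
#' @examples
#' interval_length(c(25901374, 37085204), "one_based_inclusive")  # 11183831
#' @export
interval_length <- function(a, convention = c("internal", "one_based_inclusive")) {
  convention <- match.arg(convention)
  if (inherits(a, "genomic_interval")) {
    w <- a$end - a$start
  } else {
    a <- as.numeric(a)
    if (length(a) != 2L || anyNA(a)) stop("expected a genomic_interval or c(start, end)")
    w <- a[2L] - a[1L]
  }
  if (convention == "one_based_inclusive") w <- w + 1
  if (w <= 0) stop("interval has non-positive length")
  w
}

## shared low-level validator for (start, end) interval matrices
check_interval_matrix <- function(m, what = "interval") {
  if (!is.matrix(m) || ncol(m) != 2L)
    stop(what, " set must be a two-column (start, end) matrix")
  storage.mode(m) <- "double"
  if (nrow(m) == 0L) return(m)
  if (anyNA(m) || any(m[, 1L] < 0) || any(m[, 2L] <= m[, 1L]))
    stop(what, "s must satisfy 0 <= start < end")
  m
}
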