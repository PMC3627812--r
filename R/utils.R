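#' Size of a 1-based inclusive interval
#'
#' All serialized coordinates in this package are 1-based and inclusive, so an
#' interval's size is `end - start + 1`.
#'
#' @param start,end Integer vectors of interval bounds (1-based, inclusive).
#' @return Integer vector of interval sizes.
#' @examples
#' interval_size(1073741, 1074185)  # 445
#' @export
interval_size <- function(start, end) {
  stopifnot(all(end >= start))
  as.integer(end - start + 1)
}

#' Nearest-integer percentage
#'
#' @param n Numerator (count).
#' @param total Denominator (count); `total = 0` reports 0.
#' @return Integer percent, rounded to the nearest whole percent.
#' @examples
#' percent_of(92, 140)  # 66
#' @export
percent_of <- function(n, total) {
  if (length(total) == 1L) total <- rep(total, length(n))
  out <- ifelse(total > 0, round(100 * n / total), 0)
  as.integer(out)
}

# Random DNA of a given GC fraction; returns a single character string.
random_dna <- function(n, gc = 0.5) {
  if (n == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Reverse complement of a plain character string.
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Integer sampling that behaves for length-1 vectors too.
sample_one <- function(x) x[sample.int(length(x), 1L)]

# Stop with a formatted message, no call.
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
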