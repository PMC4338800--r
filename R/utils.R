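`%||%` <- function(x, y) if (is.null(x)) y else x

#' Merge sorted column indices into maximal 1-based inclusive ranges
#'
#' @param cols integer vector of (1-based) column indices, any order,
#'   no duplicates.
#' @return two-column integer matrix with columns `start`, `end`; zero rows
#'   for empty input. Ranges are ascending and maximally merged.
#' @examples
#' merge_ranges(c(2, 3, 4, 8, 10, 11))
#' @export
merge_ranges <- function(cols) {
  cols <- sort(unique(as.integer(cols)))
  if (length(cols) == 0L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  breaks <- which(diff(cols) > 1L)
  starts <- cols[c(1L, breaks + 1L)]
  ends <- cols[c(breaks, length(cols))]
  cbind(start = starts, end = ends)
}

# expand a start/end range matrix back to a sorted index vector
.expand_ranges <- function(ranges) {
  if (nrow(ranges) == 0L) return(integer(0))
  sort(unique(unlist(lapply(seq_len(nrow(ranges)), function(i) {
    seq.int(ranges[i, 1L], ranges[i, 2L])
  }))))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# split a string into single characters
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# sample from a vector even when it has length 1 (avoids sample()'s
# scalar-expansion behaviour)
.resample <- function(x, size = 1L, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.AMBIG <- c("B", "X", "Z")
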