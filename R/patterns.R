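#' Attribute-mastery patterns
#'
#' An attribute pattern (knowledge state) is a length-`K` binary vector, one
#' bit per attribute, 1 meaning mastered. The canonical class index treats
#' attribute 1 as the most significant bit, so for `K = 4` the pattern
#' `(0,0,0,0)` has index 0, `(0,0,0,1)` index 1, `(1,0,0,0)` index 8 and
#' `(1,1,1,1)` index 15; printed tuples sort like binary numbers.
#'
#' @param k Number of attributes (positive integer).
#' @return `attribute_patterns()` returns a `2^k` by `k` 0/1 matrix whose
#'   rows are the patterns in canonical index order (row `i` is index
#'   `i - 1`).
#' @examples
#' attribute_patterns(2)
#' pattern_index(c(1, 0, 0, 1))  # 9
#' pattern_label(c(1, 0, 0, 1))  # "(1,0,0,1)"
#' @export
attribute_patterns <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1, k == round(k))
  idx <- 0:(2^k - 1)
  m <- matrix(unlist(lapply(idx, index_to_bits, k)), ncol = k, byrow = TRUE)
  rownames(m) <- apply(m, 1L, pattern_label)
  m
}

#' @rdname attribute_patterns
#' @param bits A binary vector (a single pattern).
#' @return `pattern_index()` returns the canonical 0-based class index.
#' @export
pattern_index <- function(bits) {
  bits <- check_bits(bits)
  k <- length(bits)
  sum(bits * 2^((k - 1):0))
}

index_to_bits <- function(index, k) {
  as.integer(intToBits(index))[k:1]
}

#' @rdname attribute_patterns
#' @return `pattern_label()` renders a pattern as e.g. `"(1,0,0,1)"`.
#' @export
pattern_label <- function(bits) {
  bits <- check_bits(bits)
  paste0("(", paste(bits, collapse = ","), ")")
}

#' @rdname attribute_patterns
#' @param label A string like `"(1,0,0,1)"`; bare digit strings (`"1001"`)
#'   are accepted too.
#' @return `parse_pattern()` returns the integer bit vector.
#' @export
parse_pattern <- function(label) {
  digits <- gsub("[^01]", "", label)
  if (nchar(digits) == 0L) {
    stop("cannot parse attribute pattern from ", sQuote(label))
  }
  as.integer(strsplit(digits, "")[[1L]])
}

check_bits <- function(bits) {
  if (is.character(bits) && length(bits) == 1L) bits <- parse_pattern(bits)
  bits <- as.integer(bits)
  if (length(bits) < 1L || anyNA(bits) || !all(bits %in% c(0L, 1L))) {
    stop("an attribute pattern must be a non-empty 0/1 vector")
  }
  bits
}
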