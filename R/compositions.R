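#' Binary compositions of compartments and vesicles
#'
#' Compartments and vesicles are both identified by a length-`N` binary row
#' vector recording which molecular label types (coats, SNAREs, GTPases,
#' lipids, cargo) are present. Vectors are ordered by the standard binary
#' convention: the leftmost element is the most significant bit, so for
#' `N = 3` the index 5 corresponds to the vector `[1 0 1]`. Index 0 (the
#' empty composition) denotes a fully vesiculated compartment and is never
#' stored as a member of a cell state.
#'
#' @param index integer composition index in `[0, 2^N - 1]`.
#' @param N number of molecular label types.
#' @return `index_to_bits` returns an integer 0/1 vector of length `N`;
#'   `bits_to_index` returns the corresponding integer index.
#' @examples
#' index_to_bits(5, 3)        # [1 0 1]
#' bits_to_index(c(1, 0, 1))  # 5
#' @export
index_to_bits <- function(index, N) {
  index <- as.integer(index)
  N <- as.integer(N)
  if (length(index) != 1L || is.na(index) || index < 0L || index > 2^N - 1L) {
    stop("composition index must be a single integer in [0, 2^N - 1]")
  }
  bitwAnd(bitwShiftR(index, (N - 1L):0L), 1L)
}

#' @param bits integer 0/1 vector, most significant bit first.
#' @rdname index_to_bits
#' @export
bits_to_index <- function(bits) {
  bits <- as.integer(bits)
  if (any(is.na(bits) | (bits != 0L & bits != 1L))) {
    stop("bits must be a vector of 0s and 1s")
  }
  n <- length(bits)
  as.integer(sum(bits * 2^((n - 1L):0L)))
}

#' All non-zero compositions as a bit matrix
#'
#' Row `i` holds the bits of composition index `i` (most significant bit in
#' column 1). Used internally to vectorize the Boolean update over whole
#' cell states.
#'
#' @param N number of molecular label types.
#' @return a `(2^N - 1) x N` integer 0/1 matrix.
#' @export
composition_bits <- function(N) {
  N <- as.integer(N)
  stopifnot(N >= 1L)
  C <- 2L^N - 1L
  m <- matrix(0L, C, N)
  for (b in seq_len(N)) {
    m[, b] <- bitwAnd(bitwShiftR(seq_len(C), N - b), 1L)
  }
  m
}

#' Number of labels carried by each composition index
#' @keywords internal
#' @noRd
popcount <- function(idx, N) {
  out <- integer(length(idx))
  for (b in 0:(N - 1L)) out <- out + bitwAnd(bitwShiftR(as.integer(idx), b), 1L)
  out
}

#' Format a composition index as a bit string such as "101"
#' @param index composition index (vectorized).
#' @param N number of label types.
#' @return character vector of bit strings.
#' @export
format_composition <- function(index, N) {
  vapply(
    as.integer(index),
    function(i) paste0(index_to_bits(i, N), collapse = ""),
    character(1)
  )
}
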