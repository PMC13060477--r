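# Basis-index conventions and small internal utilities.
#
# One convention everywhere: bitstring position k (0-based, left to right in
# gene_order) maps to qubit k; the basis index of bitstring s is
# sum_k s_k * 2^(d-1-k) (big-endian, qubit 0 is the most significant bit).
# R vectors are 1-based, so amplitude slot (index + 1) holds basis state
# `index`.

#' Convert basis indices to bitstrings
#'
#' @param idx integer vector of 0-based basis indices.
#' @param d register width (number of qubits).
#' @return character vector of `d`-character bitstrings, big-endian (qubit 0
#'   leftmost).
#' @examples
#' index_to_bits(0:3, 2)
#' @export
index_to_bits <- function(idx, d) {
  stopifnot(d >= 1, all(idx >= 0), all(idx < 2^d))
  vapply(idx, function(i) {
    bits <- integer(d)
    for (k in seq_len(d)) {
      bits[k] <- bitwAnd(bitwShiftR(as.integer(i), d - k), 1L)
    }
    paste(bits, collapse = "")
  }, character(1))
}

#' Convert bitstrings to basis indices
#'
#' @param s character vector of bitstrings (all the same width).
#' @return integer vector of 0-based basis indices under the big-endian
#'   convention (leftmost character is qubit 0, the most significant bit).
#' @examples
#' bits_to_index(c("00", "01", "10", "11"))
#' @export
bits_to_index <- function(s) {
  stopifnot(is.character(s), length(s) > 0)
  d <- unique(nchar(s))
  if (length(d) != 1) stop("bitstrings must all have the same width")
  if (!all(grepl("^[01]+$", s))) stop("bitstrings must contain only 0 and 1")
  vapply(strsplit(s, ""), function(b) {
    sum(as.integer(b) * 2^(rev(seq_along(b)) - 1))
  }, numeric(1)) |> as.integer()
}

# Bit of qubit k (0-based) in 0-based indices `idx`, width d.
qubit_bit <- function(idx, k, d) {
  bitwAnd(bitwShiftR(as.integer(idx), d - 1L - as.integer(k)), 1L)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}
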