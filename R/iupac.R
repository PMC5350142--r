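# Degenerate-nucleotide algebra: every IUPAC code is a 4-bit mask over
# A=1, C=2, G=4, T=8; two codes are compatible iff their masks intersect.

IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

# mask -> code (index = mask value 1..15)
IUPAC_CODE <- names(IUPAC_MASK)[order(IUPAC_MASK)]

# mask -> base-wise complement mask (A<->T swaps bits 1/8, C<->G swaps 2/4)
COMP_MASK <- vapply(1:15, function(m) {
  as.integer(
    bitwAnd(m, 1L) * 8L + bitwAnd(m, 8L) %/% 8L +
      bitwAnd(m, 2L) * 2L + bitwAnd(m, 4L) %/% 2L
  )
}, integer(1))

POPCOUNT4 <- vapply(1:15, function(m) {
  sum(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L)
}, integer(1))

# Convert a sequence string to its integer mask vector, with a position-aware
# error for anything outside the IUPAC alphabet.
iupac_masks <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  m <- unname(IUPAC_MASK[chars])
  if (anyNA(m)) {
    bad <- which(is.na(m))[1]
    stop("invalid nucleotide character '", chars[bad], "' at position ", bad,
         " (allowed: ", paste(names(IUPAC_MASK), collapse = ""), ")",
         call. = FALSE)
  }
  m
}

#' Bases denoted by an IUPAC nucleotide code
#'
#' @param code Single IUPAC character.
#' @return Character vector of concrete bases (subset of A, C, G, T).
#' @examples
#' iupac_bases("R")
#' @export
iupac_bases <- function(code) {
  m <- iupac_masks(code)
  if (length(m) != 1L) stop("'code' must be a single character", call. = FALSE)
  c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L]
}

#' Degeneracy of an IUPAC primer sequence
#'
#' The number of concrete A/C/G/T oligonucleotides a degenerate sequence
#' stands for: the product over positions of the size of each position's
#' base set.
#'
#' @param seq IUPAC nucleotide string.
#' @return Positive integer.
#' @examples
#' iupac_degeneracy("ACGT")                  # 1
#' iupac_degeneracy("CATCGCAATCGCACRATGATY") # 4
#' @export
iupac_degeneracy <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  prod(POPCOUNT4[iupac_masks(seq)])
}

#' Expand a degenerate sequence into its concrete variants
#'
#' @param seq IUPAC nucleotide string.
#' @param cap Refuse to expand beyond this many variants.
#' @return Character vector of all concrete expansions, lexicographically
#'   ordered.
#' @examples
#' iupac_expand("AR")
#' @export
iupac_expand <- function(seq, cap = 1024L) {
  d <- iupac_degeneracy(seq)
  if (d > cap) {
    stop("degeneracy ", d, " exceeds expansion cap ", cap, call. = FALSE)
  }
  sets <- lapply(iupac_masks(seq), function(m) {
    c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L]
  })
  Reduce(function(acc, bases) as.vector(t(outer(acc, bases, paste0))),
         sets, accumulate = FALSE, init = "")
}

#' Do two IUPAC codes admit a common base?
#'
#' Vectorised over both arguments. A primer position is considered to pair
#' with a template position iff the two base sets intersect.
#'
#' @param a,b IUPAC nucleotide strings of equal length (or length 1).
#' @return Logical vector.
#' @examples
#' iupac_match("R", "A")  # TRUE
#' iupac_match("R", "C")  # FALSE
#' @export
iupac_match <- function(a, b) {
  ma <- iupac_masks(paste(a, collapse = ""))
  mb <- iupac_masks(paste(b, collapse = ""))
  bitwAnd(ma, mb) > 0L
}

#' Minimal IUPAC code covering a base set
#'
#' @param bases Character vector, non-empty subset of A, C, G, T.
#' @return Single IUPAC character whose base set equals the input.
#' @examples
#' consensus_code(c("A", "G"))  # "R"
#' @export
consensus_code <- function(bases) {
  bases <- unique(toupper(bases))
  if (length(bases) == 0L) stop("empty base set", call. = FALSE)
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("bases must be a subset of A, C, G, T", call. = FALSE)
  }
  m <- sum(IUPAC_MASK[bases])
  IUPAC_CODE[m]
}

reverse_complement <- function(seq) {
  m <- rev(COMP_MASK[iupac_masks(seq)])
  paste(IUPAC_CODE[m], collapse = "")
}
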