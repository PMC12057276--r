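#' Canonical hash of identifiers
#'
#' Deterministic, platform-independent ordering key used for every tie-break
#' in the pipeline: labeling equally sized clusters, ordering the rows and
#' columns of the Lin-clustering matrix, selecting candidate k-mers, and the
#' final pseudo-randomization tier of representative selection.
#'
#' The key is the first 8 bytes of the SHA-256 digest of the UTF-8 encoded
#' identifier, returned as a 16-character lowercase hex string. Comparing
#' these strings lexicographically is equivalent to comparing the 8-byte
#' prefixes as big-endian unsigned integers.
#'
#' @param x character vector of identifiers.
#' @return character vector of 16-character hex keys, same length as `x`.
#' @examples
#' canonical_hash(c("gA", "gB"))
#' @export
canonical_hash <- function(x) {
  if (!is.character(x)) x <- as.character(x)
  hash_prefix_cpp(enc2utf8(x))
}

#' Order identifiers by canonical hash
#'
#' @param x character vector.
#' @return integer permutation ordering `x` by ascending [canonical_hash()].
#' @keywords internal
hash_order <- function(x) order(canonical_hash(x), method = "radix")
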