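#' Dice similarity between two EGGs
#'
#' With A and B the sets of (family, label) pairs at non-missing positions
#' of the two Lin-combinations, the Dice index is `2 * |A n B| / (|A| + |B|)`.
#' A family missing in one EGG contributes only to the other EGG's set, so
#' absence is never counted as agreement.
#'
#' @param a,b named integer vectors of labels (names are family ids, `NA`
#'   marks a missing family), e.g. rows of an `egg_set$labels` matrix.
#' @return the Dice index, in `[0, 1]`.
#' @examples
#' dice(c(uL1 = 3L, uL3 = 2L), c(uL1 = 3L, uL3 = 3L, uL4 = 3L))  # 2/5
#' @export
dice <- function(a, b) {
  ta <- egg_label_tokens(a)
  tb <- egg_label_tokens(b)
  if (length(ta) == 0L || length(tb) == 0L)
    stop("Dice index undefined: EGG with no non-missing label")
  2 * length(intersect(ta, tb)) / (length(ta) + length(tb))
}

#' Dice similarity matrix of a set of EGGs
#'
#' Computes all pairwise Dice indices for the EGGs of one (pre-connected)
#' component. To avoid materialising all pairs naively, the matrix is
#' computed per column block: a sparse EGG x (family, label) one-hot
#' indicator is built once, shared-label counts for a block of EGGs are the
#' product of the indicator with the block's transpose, and denominators
#' come from per-EGG non-missing counts. The result is numerically identical
#' to calling [dice()] on every pair.
#'
#' @param eggs an `egg_set`.
#' @param egg_ids integer ids of the EGGs to include (default all).
#' @param block_size number of EGG columns per block (no effect on values).
#' @return a symmetric numeric matrix with unit diagonal; dimnames are the
#'   egg ids as characters.
#' @export
similarity_matrix <- function(eggs, egg_ids = NULL, block_size = 1024L) {
  stopifnot(inherits(eggs, "egg_set"), block_size >= 1L)
  if (is.null(egg_ids)) egg_ids <- seq_len(nrow(eggs$labels))
  n <- length(egg_ids)
  stopifnot(n >= 1L)
  tokens <- lapply(egg_ids, function(i) egg_label_tokens(eggs$labels[i, ]))
  sizes <- lengths(tokens)
  if (any(sizes == 0L))
    stop("Dice index undefined: EGG with no non-missing label")
  vocab <- unique(unlist(tokens, use.names = FALSE))
  onehot <- Matrix::sparseMatrix(
    i = rep(seq_len(n), sizes),
    j = match(unlist(tokens, use.names = FALSE), vocab),
    x = 1, dims = c(n, length(vocab)))
  sim <- matrix(0, n, n)
  for (start in seq(1L, n, by = block_size)) {
    cols <- start:min(start + block_size - 1L, n)
    shared <- as.matrix(onehot %*% Matrix::t(onehot[cols, , drop = FALSE]))
    sim[, cols] <- 2 * shared / outer(sizes, sizes[cols], `+`)
  }
  dimnames(sim) <- list(as.character(egg_ids), as.character(egg_ids))
  sim
}
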