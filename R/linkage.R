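#' Complete-linkage dendrogram of EGGs
#'
#' Agglomerates the EGGs of one component by repeatedly merging the pair of
#' current clusters with the highest complete-link similarity (the minimum
#' pairwise Dice index across the two clusters). Ties are broken by the
#' smallest pair of canonical EGG indices (each cluster represented by its
#' smallest member). Every merge is recorded down to similarity 0, so one
#' dendrogram serves every threshold.
#'
#' @param sim symmetric Dice matrix from [similarity_matrix()].
#' @return an object of class `mps_dendrogram`: `leaves` (integer egg ids),
#'   `merge` (hclust-style (n-1) x 2 matrix, negative entries are leaves),
#'   `similarity` (complete-link similarity at each merge, non-increasing).
#' @export
build_dendrogram <- function(sim) {
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim))
  leaves <- as.integer(rownames(sim))
  n <- nrow(sim)
  if (n == 1L)
    return(structure(list(leaves = leaves,
                          merge = matrix(integer(0), 0, 2),
                          similarity = numeric(0)),
                     class = "mps_dendrogram"))
  S <- sim
  diag(S) <- -Inf
  code <- -seq_len(n)            # hclust encoding: -leaf or +merge step
  minmember <- leaves            # smallest egg id in each active cluster
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    sub <- S[act, act, drop = FALSE]
    best <- max(sub)
    idx <- which(sub == best, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    a <- act[idx[, 1]]; b <- act[idx[, 2]]
    lo <- pmin(minmember[a], minmember[b])
    hi <- pmax(minmember[a], minmember[b])
    pick <- order(lo, hi, method = "radix")[1]
    i <- a[pick]; j <- b[pick]
    if (minmember[j] < minmember[i]) { tmp <- i; i <- j; j <- tmp }
    merge[step, ] <- c(code[i], code[j])
    height[step] <- best
    S[i, ] <- pmin(S[i, ], S[j, ])
    S[, i] <- S[i, ]
    S[i, i] <- -Inf
    active[j] <- FALSE
    S[j, ] <- -Inf
    S[, j] <- -Inf
    code[i] <- step
    minmember[i] <- min(minmember[i], minmember[j])
  }
  structure(list(leaves = leaves, merge = merge, similarity = height),
            class = "mps_dendrogram")
}

#' Cut a dendrogram at a minimum similarity
#'
#' Applies every merge whose complete-link similarity is at least `delta`
#' (boundary inclusive): the resulting clusters satisfy the complete-link
#' guarantee that every pair of member EGGs has Dice `>= delta`. `delta = 1`
#' returns the EGGs unchanged, equivalent to bypassing this clustering.
#'
#' @param dend an `mps_dendrogram`.
#' @param delta minimum similarity threshold, in `[0, 1]`.
#' @return list of integer vectors of egg ids, ordered by smallest member.
#' @export
cut_dendrogram <- function(dend, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) ||
      delta < 0 || delta > 1)
    stop("delta must be a single value in [0, 1]")
  n <- length(dend$leaves)
  memb <- seq_len(n)
  k <- sum(dend$similarity >= delta)
  if (k > 0L) {
    cluster_of_step <- integer(k)
    for (step in seq_len(k)) {
      pick <- function(code) {
        if (code < 0L) memb[-code] else cluster_of_step[code]
      }
      ca <- pick(dend$merge[step, 1]); cb <- pick(dend$merge[step, 2])
      memb[memb == cb] <- ca
      cluster_of_step[step] <- ca
    }
  }
  groups <- unname(split(dend$leaves, memb))
  groups <- lapply(groups, as.integer)
  groups[order(vapply(groups, min, integer(1)))]
}

#' Cut dendrograms at several thresholds
#'
#' Dendrograms are built once per component and cut once per distinct
#' threshold, identical to independent runs at each value.
#'
#' @param dends list of `mps_dendrogram`, one per component.
#' @param deltas numeric vector of thresholds in `[0, 1]` (duplicates are
#'   removed).
#' @return named list (one element per distinct delta, names formatted with
#'   `formatC(format = "g")`) of cluster lists; each cluster is an integer
#'   vector of egg ids, clusters ordered by smallest member across all
#'   components.
#' @export
multi_delta_cut <- function(dends, deltas) {
  if (length(deltas) == 0L) stop("at least one delta value is required")
  if (any(!is.finite(deltas) | deltas < 0 | deltas > 1))
    stop("delta values must lie in [0, 1]")
  deltas <- unique(deltas)
  out <- lapply(deltas, function(d) {
    clusters <- unlist(lapply(dends, cut_dendrogram, delta = d),
                       recursive = FALSE)
    clusters[order(vapply(clusters, min, integer(1)))]
  })
  stats::setNames(out, formatC(deltas, format = "g"))
}
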