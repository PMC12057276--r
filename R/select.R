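#' Select the representative genome of one MPS-cluster
#'
#' Applies the four-tier priority cascade, filtering the cluster's genomes
#' tier by tier until one survivor remains:
#' 1. highest user-defined priority score (absent genomes score 0);
#' 2. highest number of non-missing protein families (completeness);
#' 3. highest centrality: the sum, over every other genome g' of the
#'    cluster, of the Dice index between the two genomes' EGGs (genomes
#'    sharing an EGG contribute 1 to each other);
#' 4. lowest canonical hash of the genome id (pseudo-randomization).
#'
#' @param cluster_eggs integer egg ids of the cluster.
#' @param eggs the `egg_set`.
#' @param sim Dice matrix of the component containing the cluster (dimnames
#'   are egg ids).
#' @param priorities a `priority_table` or `NULL`.
#' @return the selected genome id (length-1 character).
#' @export
select_representative <- function(cluster_eggs, eggs, sim,
                                  priorities = NULL) {
  stopifnot(length(cluster_eggs) >= 1L)
  genome <- unlist(eggs$genomes[cluster_eggs], use.names = FALSE)
  egg_of <- rep(cluster_eggs, eggs$sizes[cluster_eggs])
  # tier 1: user priority
  sc <- priority_score(priorities, genome)
  keep <- sc == max(sc)
  genome <- genome[keep]; egg_of <- egg_of[keep]
  if (length(genome) > 1L) {
    # tier 2: protein-family completeness
    nfam <- rowSums(!is.na(eggs$labels))[as.character(egg_of)]
    keep <- nfam == max(nfam)
    genome <- genome[keep]; egg_of <- egg_of[keep]
  }
  if (length(genome) > 1L) {
    # tier 3: centrality within the cluster
    all_eggs <- rep(cluster_eggs, eggs$sizes[cluster_eggs])
    cent <- vapply(seq_along(genome), function(i) {
      e <- egg_of[i]
      pair_sim <- ifelse(all_eggs == e, 1,
                         sim[as.character(e), as.character(all_eggs)])
      sum(pair_sim) - 1  # exclude the genome itself
    }, numeric(1))
    keep <- abs(cent - max(cent)) < 1e-12
    genome <- genome[keep]
  }
  if (length(genome) > 1L) {
    # tier 4: canonical hash
    h <- canonical_hash(genome)
    if (anyDuplicated(h))
      stop("canonical hash collision among genome ids: ",
           paste(genome[duplicated(h) | duplicated(h, fromLast = TRUE)],
                 collapse = ", "))
    genome <- genome[order(h, method = "radix")][1]
  }
  genome
}

#' Map every genome to its MPS-representative
#'
#' @param clusters list of integer egg-id vectors (one per MPS-cluster,
#'   as returned by [cut_dendrogram()] / [multi_delta_cut()]).
#' @param representatives character vector, one genome per cluster.
#' @param eggs the `egg_set`.
#' @return a data.frame with columns `genome_id`, `representative_id`,
#'   `mps_cluster_id`, `egg_id`, one row per genome, in canonical genome
#'   order.
#' @export
build_mapping <- function(clusters, representatives, eggs) {
  stopifnot(length(clusters) == length(representatives))
  rows <- lapply(seq_along(clusters), function(ci) {
    egg_ids <- clusters[[ci]]
    data.frame(genome_id = unlist(eggs$genomes[egg_ids], use.names = FALSE),
               representative_id = unname(representatives[ci]),
               mps_cluster_id = ci,
               egg_id = rep(egg_ids, eggs$sizes[egg_ids]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  canonical <- names(eggs$genome2egg)
  out[match(canonical, out$genome_id), , drop = FALSE] |>
    `rownames<-`(NULL)
}
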