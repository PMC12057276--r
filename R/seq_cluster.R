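#' Clustering parameters for Lin-cluster construction
#'
#' Defaults follow the tool's published settings: `evalue = 1e-5`,
#' `coverage_mode = 0` (coverage must hold for both sequences),
#' `min_cov = 0.8`, `min_seq_id = 0.6`. The k-mer prefilter selects, per
#' sequence, the `kmers_per_seq` distinct k-mers with the lowest canonical
#' hash; candidate pairs share at least one selected k-mer. E-values use the
#' Karlin-Altschul form `K * m * n * exp(-lambda * S)` with the standard
#' gapped BLOSUM62 constants.
#'
#' @param evalue maximum alignment e-value.
#' @param min_cov minimum alignment coverage fraction, in `[0, 1]`.
#' @param min_seq_id minimum fractional sequence identity, in `[0, 1]`.
#' @param coverage_mode integer code; 0 requires coverage on both sequences.
#' @param kmer_size k-mer length for the prefilter.
#' @param kmers_per_seq number of lowest-hash k-mers kept per sequence.
#' @param gap_open,gap_extend affine gap penalties for the local alignment.
#' @param lambda,K Karlin-Altschul constants for the e-value.
#' @return a list of class `cluster_params`.
#' @export
cluster_params <- function(evalue = 1e-5, min_cov = 0.8, min_seq_id = 0.6,
                           coverage_mode = 0L, kmer_size = 5L,
                           kmers_per_seq = 20L, gap_open = 11,
                           gap_extend = 1, lambda = 0.267, K = 0.041) {
  stopifnot(evalue > 0, min_cov >= 0, min_cov <= 1,
            min_seq_id >= 0, min_seq_id <= 1,
            kmer_size >= 1, kmers_per_seq >= 1)
  coverage_mode <- as.integer(coverage_mode)
  if (!coverage_mode %in% 0L)
    stop("only coverage_mode = 0 (both sequences) is supported")
  structure(list(evalue = evalue, min_cov = min_cov,
                 min_seq_id = min_seq_id, coverage_mode = coverage_mode,
                 kmer_size = as.integer(kmer_size),
                 kmers_per_seq = as.integer(kmers_per_seq),
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "cluster_params")
}

seq_kmers <- function(residues, k) {
  n <- nchar(residues)
  if (n < k) return(residues)
  unique(substring(residues, seq_len(n - k + 1), k:n))
}

#' Candidate sequence pairs from the k-mer prefilter
#'
#' Each sequence contributes its `kmers_per_seq` distinct k-mers with the
#' lowest canonical hash (all of them if it has fewer); two sequences become
#' a candidate pair when they share at least one selected k-mer. Sequences
#' shorter than `kmer_size` contribute their whole string as a single token.
#'
#' @param family a `protein_family`.
#' @param params a `cluster_params` object.
#' @return a two-column character matrix of genome-id pairs (each unordered
#'   pair once, columns sorted so `[,1] < [,2]`); zero rows when no pair.
#' @export
candidate_pairs <- function(family, params = cluster_params()) {
  rec <- family$records
  if (nrow(rec) < 2L)
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("a", "b"))))
  km_list <- lapply(rec$residues, seq_kmers, k = params$kmer_size)
  all_km <- unique(unlist(km_list, use.names = FALSE))
  km_hash <- stats::setNames(canonical_hash(all_km), all_km)
  sel <- lapply(km_list, function(km) {
    km[order(km_hash[km], method = "radix")][
      seq_len(min(params$kmers_per_seq, length(km)))]
  })
  token <- unlist(sel, use.names = FALSE)
  owner <- rep(rec$genome_id, lengths(sel))
  pairs <- unlist(lapply(split(owner, token), function(g) {
    g <- unique(g)
    if (length(g) < 2L) return(NULL)
    g <- sort(g)
    utils::combn(g, 2L)
  }), use.names = FALSE)
  if (is.null(pairs) || length(pairs) == 0L)
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("a", "b"))))
  m <- matrix(pairs, ncol = 2, byrow = TRUE, dimnames = list(NULL, c("a", "b")))
  unique(m)
}

#' Verify a candidate pair by local alignment
#'
#' Scores one Smith-Waterman alignment (BLOSUM62, affine gaps) and applies
#' the acceptance rule: `evalue <= max`, `identity >= min_seq_id`, and, in
#' coverage mode 0, coverage of both sequences `>= min_cov`. Identity is the
#' number of identical aligned positions divided by the number of alignment
#' columns; coverage of a sequence is its aligned span divided by its length;
#' the e-value is `K * m * n * exp(-lambda * S)` with `m` the query length
#' and `n` the total residue count of the family.
#'
#' @param a,b amino-acid strings (or single-row `protein_family` records).
#' @param params a `cluster_params` object.
#' @param family_residue_total total number of residues in the family,
#'   the search-space size for the e-value.
#' @return a list: `accepted`, `identity`, `coverage_a`, `coverage_b`,
#'   `evalue`, `score`.
#' @export
verify_pair <- function(a, b, params = cluster_params(),
                        family_residue_total = nchar(a) + nchar(b)) {
  stopifnot(nzchar(a), nzchar(b))
  st <- align_stats(a, b, params, family_residue_total)
  lapply(st, `[[`, 1L)
}

# Vectorised alignment of many queries against one subject.
align_stats <- function(queries, subject, params, family_residue_total) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(queries), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  ncols <- Biostrings::nchar(aln)
  identity <- Biostrings::nmatch(aln) / ncols
  p <- Biostrings::pattern(aln)
  s <- Biostrings::subject(aln)
  cov_a <- (BiocGenerics::end(p) - BiocGenerics::start(p) + 1) / nchar(queries)
  cov_b <- (BiocGenerics::end(s) - BiocGenerics::start(s) + 1) / nchar(subject)
  sc <- Biostrings::score(aln)
  ev <- params$K * nchar(queries) * family_residue_total *
    exp(-params$lambda * sc)
  accepted <- ev <= params$evalue & identity >= params$min_seq_id &
    cov_a >= params$min_cov & cov_b >= params$min_cov
  list(accepted = accepted, identity = identity,
       coverage_a = cov_a, coverage_b = cov_b, evalue = ev, score = sc)
}

# Verify all candidate pairs of a family; returns the accepted subset.
verify_candidates <- function(family, pairs, params) {
  if (nrow(pairs) == 0L) return(pairs)
  rec <- family$records
  res <- stats::setNames(rec$residues, rec$genome_id)
  total <- sum(nchar(rec$residues))
  keep <- logical(nrow(pairs))
  for (b in unique(pairs[, 2])) {
    idx <- which(pairs[, 2] == b)
    st <- align_stats(unname(res[pairs[idx, 1]]), res[[b]], params, total)
    keep[idx] <- st$accepted
  }
  pairs[keep, , drop = FALSE]
}

#' Greedy set-cover clustering of a verified-pair graph
#'
#' Repeatedly picks the unassigned vertex with the most unassigned accepted
#' neighbours as a centroid (ties broken by ascending canonical hash of the
#' vertex id) and forms a cluster of the centroid plus its unassigned
#' neighbours. Isolated vertices end up as singleton clusters.
#'
#' @param vertices character vector of sequence/genome ids.
#' @param edges two-column character matrix of accepted pairs.
#' @return a list of character vectors, one per cluster (unlabeled
#'   partition).
#' @export
greedy_set_cover <- function(vertices, edges) {
  stopifnot(all(edges %in% vertices))
  adj <- stats::setNames(vector("list", length(vertices)), vertices)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      if (a == b) next
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    adj <- lapply(adj, unique)
  }
  hkey <- stats::setNames(canonical_hash(vertices), vertices)
  unassigned <- stats::setNames(rep(TRUE, length(vertices)), vertices)
  clusters <- list()
  while (any(unassigned)) {
    cand <- names(unassigned)[unassigned]
    deg <- vapply(cand, function(v) sum(unassigned[adj[[v]]]), integer(1))
    pick <- cand[order(-deg, hkey[cand], method = "radix")][1]
    members <- c(pick, adj[[pick]][unassigned[adj[[pick]]]])
    unassigned[members] <- FALSE
    clusters[[length(clusters) + 1L]] <- unname(members)
  }
  clusters
}

#' Label a partition by decreasing cluster size
#'
#' Clusters are labeled 1..C from largest to smallest; equal-size ties are
#' broken by ascending canonical hash of each cluster's lexicographically
#' smallest member, so labels are invariant under permutation of the input.
#'
#' @param partition list of character vectors (cluster members).
#' @param family_id family identifier stored in the result.
#' @return an object of class `lin_clustering`: `family_id`, `assignment`
#'   (named integer vector genome -> label), `cluster_sizes` (named by
#'   label, non-increasing).
#' @export
label_by_size <- function(partition, family_id) {
  stopifnot(length(partition) >= 1L)
  members <- unlist(partition, use.names = FALSE)
  if (anyDuplicated(members))
    stop("not a partition: duplicated member(s) in family ", family_id)
  sizes <- lengths(partition)
  anchor <- vapply(partition, function(g) sort(g)[1], character(1))
  ord <- order(-sizes, canonical_hash(anchor), method = "radix")
  assignment <- integer(0)
  for (i in seq_along(ord)) {
    g <- partition[[ord[i]]]
    assignment[g] <- i
  }
  structure(list(family_id = family_id,
                 assignment = assignment[sort(names(assignment))],
                 cluster_sizes = stats::setNames(sizes[ord],
                                                 seq_along(ord))),
            class = "lin_clustering")
}

#' Cluster one protein family into labeled Lin-clusters
#'
#' Runs the full built-in clusterer: k-mer candidate pairs, local-alignment
#' verification, greedy set cover, size labeling. This is a simplified
#' single-round clusterer in the spirit of Linclust; real Linclust/MMseqs2
#' output can be substituted through [external_cluster_adapter()].
#'
#' @inheritParams candidate_pairs
#' @return a `lin_clustering` object.
#' @export
lin_cluster_family <- function(family, params = cluster_params()) {
  pairs <- candidate_pairs(family, params)
  accepted <- verify_candidates(family, pairs, params)
  partition <- greedy_set_cover(family$records$genome_id, accepted)
  label_by_size(partition, family$family_id)
}

#' Import an external clustering of a family
#'
#' Parses a two-column TSV in the native cluster format of MMseqs2-style
#' tools (`representative_seq_id<TAB>member_seq_id`, one row per member,
#' representatives listed as their own member) and applies the standard size
#' labeling, bypassing the built-in clusterer.
#'
#' @param family the `protein_family` the clustering refers to.
#' @param tsv_path path to the cluster TSV.
#' @return a `lin_clustering` object.
#' @export
external_cluster_adapter <- function(family, tsv_path) {
  df <- utils::read.delim(tsv_path, header = FALSE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("cluster TSV must have two columns (rep, member)")
  rep_id <- df[[1]]; member <- df[[2]]
  rec <- family$records
  unknown <- setdiff(c(rep_id, member), rec$seq_id)
  if (length(unknown))
    stop("unknown seq_id in cluster TSV: ", paste(unknown, collapse = ", "))
  if (anyDuplicated(member))
    stop("member referenced twice in cluster TSV: ",
         paste(unique(member[duplicated(member)]), collapse = ", "))
  missing <- setdiff(rec$seq_id, member)
  if (length(missing))
    stop("sequences absent from cluster TSV: ",
         paste(missing, collapse = ", "))
  seq2genome <- stats::setNames(rec$genome_id, rec$seq_id)
  partition <- unname(split(unname(seq2genome[member]), rep_id))
  label_by_size(partition, family$family_id)
}
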