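AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa <- function(len) paste(sample(AA20, len, replace = TRUE),
                                 collapse = "")

# Substitute round((1 - identity) * L) distinct positions with a different
# residue, so the pre-alignment identity to `seq` is exactly the target.
mutate_to_identity <- function(seq, identity) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  k <- round((1 - identity) * length(chars))
  if (k > 0) {
    pos <- sample(length(chars), k)
    chars[pos] <- vapply(chars[pos], function(old)
      sample(setdiff(AA20, old), 1), character(1))
  }
  paste(chars, collapse = "")
}

#' The ten-genome worked-example label matrix
#'
#' A 10-genome x 4-family Lin-clustering matrix (families uL1..uL4, genomes
#' gA..gJ) with a fully known downstream structure: 7 EGGs, two
#' pre-connected components at `min_nb_linclusters = 2` (7 and 3 genomes),
#' a Dice index of 2/5 between the EGGs of gI and gJ, and five MPS-clusters
#' at `delta = 0.5`. uL2 is missing in gB, gC, gI and gJ; uL4 is missing in
#' gI. Every family has exactly 3 Lin-clusters. The equal-size label
#' tie-breaks (uL2: gD's cluster before gH's; uL4: the gA/gD cluster
#' labeled 2) coincide with the canonical-hash tie-break used by
#' [label_by_size()].
#'
#' @return integer matrix, rows gA..gJ, columns uL1..uL4, `NA` = missing.
#' @export
fixture_label_matrix <- function() {
  m <- matrix(c(
    1L,  1L, 1L, 2L,   # gA
    2L,  NA, 1L, 1L,   # gB
    2L,  NA, 1L, 1L,   # gC
    2L,  2L, 2L, 2L,   # gD
    1L,  1L, 1L, 1L,   # gE
    1L,  1L, 1L, 1L,   # gF
    1L,  1L, 1L, 1L,   # gG
    3L,  3L, 2L, 3L,   # gH
    3L,  NA, 2L, NA,   # gI
    3L,  NA, 3L, 3L),  # gJ
    nrow = 10, byrow = TRUE,
    dimnames = list(paste0("g", LETTERS[1:10]),
                    paste0("uL", 1:4)))
  m
}

fixture_partitions <- function() {
  list(
    uL1 = list(c("gA", "gE", "gF", "gG"), c("gB", "gC", "gD"),
               c("gH", "gI", "gJ")),
    uL2 = list(c("gA", "gE", "gF", "gG"), "gD", "gH"),
    uL3 = list(c("gA", "gB", "gC", "gE", "gF", "gG"),
               c("gD", "gH", "gI"), "gJ"),
    uL4 = list(c("gB", "gC", "gE", "gF", "gG"), c("gA", "gD"),
               c("gH", "gJ")))
}

#' Sequence-level worked-example fixture
#'
#' Generates four protein families (uL1..uL4, ten genomes gA..gJ, sequences
#' of length `len`) whose default-parameter Lin-clustering reproduces
#' [fixture_label_matrix()] exactly. Each Lin-cluster descends from an
#' independent random ancestor; members carry ~2.5% substitutions
#' (pairwise within-cluster identity ~0.95), while unrelated ancestors have
#' background identity (~0.05-0.2 after local alignment). The generator
#' re-clusters its own output and fails loudly if the label matrix does not
#' match, so a successful return is self-certified.
#'
#' @param seed RNG seed; the output is a deterministic function of it.
#' @param len ancestor sequence length.
#' @param params `cluster_params` used for the self-check.
#' @return named list of four `protein_family` objects.
#' @export
fixture_families <- function(seed = 42L, len = 150L,
                             params = cluster_params()) {
  fams <- with_local_seed(seed, {
    lapply(names(fixture_partitions()), function(fam) {
      part <- fixture_partitions()[[fam]]
      genome <- character(0); residues <- character(0)
      for (members in part) {
        anc <- random_aa(len)
        for (g in members) {
          genome <- c(genome, g)
          residues <- c(residues, mutate_to_identity(anc, 0.975))
        }
      }
      ord <- order(genome)
      protein_family(fam, paste(genome[ord], fam, sep = "_"),
                     genome[ord], residues[ord])
    })
  })
  names(fams) <- names(fixture_partitions())
  got <- build_label_matrix(lapply(fams, lin_cluster_family, params = params))
  want <- fixture_label_matrix()
  got <- got[rownames(want), colnames(want)]
  if (!identical(got, want))
    stop("fixture self-check failed: clustering the generated sequences ",
         "does not reproduce the worked-example label matrix; ",
         "try another seed")
  fams
}

#' Simulate protein families with known group structure
#'
#' Generates `n_groups * genomes_per_group` genomes over `n_families`
#' single-copy families. Each family has one random root sequence; group
#' ancestors are derived from the root so that between-group pairwise
#' identity is approximately `between_identity`, and group members from
#' their ancestor so that within-group pairwise identity is approximately
#' `within_identity` (members at identity sqrt(target) to the common
#' ancestor). Substitution-only mutation keeps alignment coverage near 1.
#' Optionally, (genome, family) cells are dropped at `missing_rate`, never
#' emptying a genome's whole row.
#'
#' @param n_groups number of ground-truth groups.
#' @param genomes_per_group genomes per group.
#' @param n_families number of protein families.
#' @param within_identity target within-group pairwise identity.
#' @param between_identity approximate between-group pairwise identity.
#' @param missing_rate probability that a (genome, family) sequence is
#'   absent.
#' @param len sequence length.
#' @param seed RNG seed; output is a deterministic function of the spec.
#' @return a list with `families` (named list of `protein_family`) and
#'   `truth` (data.frame `genome_id`, `group`).
#' @export
simulate_families <- function(n_groups = 3L, genomes_per_group = 5L,
                              n_families = 4L, within_identity = 0.9,
                              between_identity = 0.3, missing_rate = 0,
                              len = 150L, seed = 1L) {
  stopifnot(within_identity >= 0, within_identity <= 1,
            between_identity >= 0, between_identity <= 1,
            missing_rate >= 0, missing_rate < 1,
            n_groups >= 1, genomes_per_group >= 1, n_families >= 1)
  genome_id <- paste0("grp", rep(seq_len(n_groups), each = genomes_per_group),
                      "_g", rep(seq_len(genomes_per_group), n_groups))
  group <- rep(seq_len(n_groups), each = genomes_per_group)
  with_local_seed(seed, {
    keep <- matrix(TRUE, length(genome_id), n_families)
    if (missing_rate > 0) {
      keep[] <- stats::runif(length(keep)) >= missing_rate
      empty <- rowSums(keep) == 0L
      keep[empty, 1L] <- TRUE  # a genome must keep at least one family
    }
    families <- lapply(seq_len(n_families), function(f) {
      fam_id <- sprintf("fam%02d", f)
      root <- random_aa(len)
      res <- character(length(genome_id))
      for (g in seq_len(n_groups)) {
        anc <- mutate_to_identity(root, sqrt(between_identity))
        idx <- which(group == g)
        res[idx] <- vapply(idx, function(i)
          mutate_to_identity(anc, sqrt(within_identity)), character(1))
      }
      k <- keep[, f]
      protein_family(fam_id,
                     paste(genome_id[k], fam_id, sep = "_"),
                     genome_id[k], res[k])
    })
    names(families) <- vapply(families, `[[`, character(1), "family_id")
    list(families = families,
         truth = data.frame(genome_id = genome_id, group = group,
                            stringsAsFactors = FALSE))
  })
}
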