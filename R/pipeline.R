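#' Run the full representative-genome sampling pipeline
#'
#' Executes, in order: per-family Lin-clustering (or the supplied external
#' clusterings), label-matrix assembly and canonical ordering, collapse into
#' EGGs, optional pre-connection, per-component Dice similarity matrices,
#' complete-linkage dendrograms, one cut per distinct threshold, and
#' representative selection. The clustering stages up to the similarity
#' matrix run once however many thresholds are requested. One structured
#' log line per stage records counts.
#'
#' @param families named list of `protein_family` objects.
#' @param params `cluster_params` for the built-in clusterer.
#' @param deltas thresholds to cut at; default is the standard ladder
#'   `c(1, 0.9, ..., 0.1, 0.05)`.
#' @param preconnect logical; run the optional pre-connection step.
#' @param min_nb_linclusters pre-connection sharing threshold.
#' @param priorities a `priority_table` or `NULL`.
#' @param clusterings optional list of precomputed `lin_clustering` objects
#'   (e.g. from [external_cluster_adapter()]); bypasses the built-in
#'   clusterer.
#' @param out_dir if non-`NULL`, [write_outputs()] is called on the result.
#' @param quiet suppress stage logs.
#' @return an object of class `mps_run`; see Details.
#' @details The returned list carries every intermediate: `clusterings`,
#'   `label_matrix` (canonical), `eggs`, `components`, `similarities` (one
#'   Dice matrix per component), `dendrograms`, and `results`, a list with
#'   one element per distinct delta holding `delta`, `clusters` (egg-id
#'   vectors), `representatives` (data.frame `mps_cluster_id`,
#'   `representative_id`, `n_genomes`) and `mapping` (data.frame
#'   `genome_id`, `representative_id`, `mps_cluster_id`, `egg_id`).
#' @export
mps_run <- function(families = NULL, params = cluster_params(),
                    deltas = c(1, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3,
                               0.2, 0.1, 0.05),
                    preconnect = FALSE, min_nb_linclusters = 2L,
                    priorities = NULL, clusterings = NULL,
                    out_dir = NULL, quiet = FALSE) {
  if (length(families) == 0L && is.null(clusterings))
    stop("empty dataset: no protein families")
  if (length(deltas) == 0L) stop("at least one delta value is required")
  t0 <- proc.time()[["elapsed"]]
  tick <- function() round(proc.time()[["elapsed"]] - t0, 2)

  if (is.null(clusterings)) {
    clusterings <- lapply(families, lin_cluster_family, params = params)
  }
  n_seq <- if (length(families))
    sum(vapply(families, function(f) nrow(f$records), integer(1)))
  else NA_integer_
  stage_log(quiet, "lin_cluster", n_families = length(clusterings),
            n_sequences = n_seq,
            n_lin_clusters = sum(vapply(clusterings, function(cl)
              length(cl$cluster_sizes), integer(1))),
            elapsed = tick())

  m <- canonical_order(build_label_matrix(clusterings))
  eggs <- collapse_to_eggs(m)
  stage_log(quiet, "egg_builder", n_genomes = nrow(m),
            n_eggs = nrow(eggs$labels), elapsed = tick())

  components <- if (preconnect) {
    build_components(eggs, min_nb_linclusters)
  } else {
    bypass_components(eggs)
  }
  stage_log(quiet, "preconnect", enabled = preconnect,
            n_components = length(components$components), elapsed = tick())

  similarities <- lapply(components$components, function(ids)
    similarity_matrix(eggs, ids))
  stage_log(quiet, "similarity",
            n_pairs = sum(vapply(similarities, function(s)
              nrow(s) * (nrow(s) - 1) / 2, numeric(1))),
            elapsed = tick())

  dendrograms <- lapply(similarities, build_dendrogram)
  cuts <- multi_delta_cut(dendrograms, deltas)
  stage_log(quiet, "linkage", n_deltas = length(cuts), elapsed = tick())

  results <- lapply(names(cuts), function(tag) {
    clusters <- cuts[[tag]]
    reps <- unname(vapply(clusters, function(egg_ids) {
      comp <- components$egg2component[egg_ids[1]]
      select_representative(egg_ids, eggs, similarities[[comp]], priorities)
    }, character(1)))
    representatives <- data.frame(
      mps_cluster_id = seq_along(clusters),
      representative_id = reps,
      n_genomes = vapply(clusters, function(ids)
        sum(eggs$sizes[ids]), integer(1)),
      stringsAsFactors = FALSE)
    list(delta = as.numeric(tag), clusters = clusters,
         representatives = representatives,
         mapping = build_mapping(clusters, reps, eggs))
  })
  names(results) <- names(cuts)
  stage_log(quiet, "select",
            n_clusters = paste(vapply(results, function(r)
              nrow(r$representatives), integer(1)), collapse = ","),
            elapsed = tick())

  run <- structure(
    list(params = params, deltas = as.numeric(names(cuts)),
         preconnect = preconnect,
         min_nb_linclusters = as.integer(min_nb_linclusters),
         clusterings = clusterings, label_matrix = m, eggs = eggs,
         components = components, similarities = similarities,
         dendrograms = dendrograms, results = results),
    class = "mps_run")
  if (!is.null(out_dir)) write_outputs(run, out_dir)
  run
}

#' @export
print.mps_run <- function(x, ...) {
  cat("<mps_run>", nrow(x$label_matrix), "genomes,",
      ncol(x$label_matrix), "families,", nrow(x$eggs$labels), "EGGs,",
      length(x$components$components), "component(s)\n")
  for (r in x$results)
    cat(sprintf("  delta=%-5s %d MPS-clusters\n", formatC(r$delta, format = "g"),
                nrow(r$representatives)))
  invisible(x)
}

#' Taxonomic diversity and redundancy of a sample
#'
#' For each rank (phylum, class, order, family, genus, species), reports the
#' proportion of the input's taxa that are retained among the
#' representatives, and the taxonomic redundancy: the mean number of sampled
#' genomes per retained taxon. Blank or absent assignments are excluded from
#' that rank's denominator; genomes missing from the taxonomy table are
#' treated as unassigned at every rank, with a warning.
#'
#' @param mapping a per-delta mapping data.frame from [mps_run()] (columns
#'   `genome_id`, `representative_id`).
#' @param taxonomy data.frame with column `genome_id` and one column per
#'   rank; empty strings or `NA` mark unassigned ranks.
#' @param ranks rank columns to evaluate (defaults to those present among
#'   the six standard ranks).
#' @return data.frame `rank`, `n_taxa_input`, `n_taxa_sample`,
#'   `proportion_retained`, `mean_genomes_per_taxon`.
#' @export
taxonomic_report <- function(mapping, taxonomy,
                             ranks = intersect(c("phylum", "class", "order",
                                                 "family", "genus",
                                                 "species"),
                                               names(taxonomy))) {
  stopifnot(length(ranks) >= 1L, "genome_id" %in% names(taxonomy))
  sample_ids <- unique(mapping$representative_id)
  input_ids <- unique(mapping$genome_id)
  absent <- setdiff(input_ids, taxonomy$genome_id)
  if (length(absent))
    warning(length(absent),
            " genome(s) absent from the taxonomy table, treated as ",
            "unassigned")
  if (length(intersect(input_ids, taxonomy$genome_id)) == 0L)
    stop("taxonomy covers no genome of the run")
  tx <- taxonomy[match(input_ids, taxonomy$genome_id), , drop = FALSE]
  rows <- lapply(ranks, function(rk) {
    val <- as.character(tx[[rk]])
    val[is.na(val) | !nzchar(val)] <- NA
    assigned <- !is.na(val)
    taxa_input <- unique(val[assigned])
    in_sample <- assigned & input_ids %in% sample_ids
    taxa_sample <- unique(val[in_sample])
    data.frame(rank = rk,
               n_taxa_input = length(taxa_input),
               n_taxa_sample = length(taxa_sample),
               proportion_retained = if (length(taxa_input))
                 length(taxa_sample) / length(taxa_input) else NA_real_,
               mean_genomes_per_taxon = if (length(taxa_sample))
                 sum(in_sample) / length(taxa_sample) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-tip phylogenetic diversity of a sample
#'
#' Prunes the tree to the sampled tips and returns the total branch length
#' divided by the number of retained tips.
#'
#' @param tree an `ape::phylo` object or a path to a Newick file with
#'   branch lengths.
#' @param tips character vector of sampled tip labels; tips absent from the
#'   tree are ignored (an error is raised if none overlap).
#' @return a single number: tree length per tip after pruning.
#' @export
phylo_diversity <- function(tree, tips) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  keep <- intersect(tips, tree$tip.label)
  if (length(keep) == 0L)
    stop("no sampled tip is present in the tree")
  pruned <- if (length(keep) == length(tree$tip.label)) tree
            else ape::keep.tip(tree, keep)
  sum(pruned$edge.length) / length(pruned$tip.label)
}

#' Read a run configuration from YAML
#'
#' Keys mirror the command-line flags of the `mps-sampling` script:
#' `families` (paths or glob), `deltas`, `evalue`, `min_cov`, `min_seq_id`,
#' `coverage_mode`, `kmer_size`, `kmers_per_seq`, `preconnect`,
#' `min_nb_linclusters`, `priority_table`, `taxonomy`, `tree`, `out`.
#'
#' @param path YAML file path.
#' @return a named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  if (!is.null(cfg$deltas)) cfg$deltas <- as.numeric(unlist(cfg$deltas))
  cfg
}
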