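# Independent reference implementations used as oracles. They deliberately
# avoid the package's code paths (set arithmetic instead of one-hot
# products, direct graph simulation instead of the package's greedy loop).

# Dice index computed position by position, without token sets.
dice_ref <- function(a, b) {
  fams <- union(names(a), names(b))
  a <- a[fams]; b <- b[fams]
  na <- sum(!is.na(a)); nb <- sum(!is.na(b))
  shared <- sum(!is.na(a) & !is.na(b) & a == b)
  2 * shared / (na + nb)
}

# All-pairs Dice by double loop.
sim_ref <- function(eggs, egg_ids = seq_len(nrow(eggs$labels))) {
  n <- length(egg_ids)
  out <- matrix(0, n, n,
                dimnames = list(as.character(egg_ids),
                                as.character(egg_ids)))
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- dice_ref(eggs$labels[egg_ids[i], ],
                          eggs$labels[egg_ids[j], ])
  out
}

# Step-by-step greedy set cover simulation (independent bookkeeping).
greedy_ref <- function(vertices, edges) {
  nb <- lapply(stats::setNames(vertices, vertices), function(v) {
    unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
  })
  h <- stats::setNames(mpsampler::canonical_hash(vertices), vertices)
  left <- vertices
  clusters <- list()
  while (length(left)) {
    deg <- vapply(left, function(v) length(intersect(nb[[v]], left)),
                  integer(1))
    best <- left[deg == max(deg)]
    centroid <- best[order(h[best])][1]
    cl <- union(centroid, intersect(nb[[centroid]], left))
    clusters[[length(clusters) + 1L]] <- cl
    left <- setdiff(left, cl)
  }
  clusters
}

# Partition helpers: order-independent canonical form.
partition_key <- function(clusters) {
  sort(vapply(clusters, function(x)
    paste(sort(as.character(x)), collapse = ","), character(1)))
}

# Random label matrix -> egg_set, for property tests.
random_egg_set <- function(n_genomes, n_families, n_labels = 3L,
                           missing_rate = 0.15) {
  m <- matrix(sample.int(n_labels, n_genomes * n_families, replace = TRUE),
              nrow = n_genomes,
              dimnames = list(sprintf("g%03d", seq_len(n_genomes)),
                              sprintf("f%02d", seq_len(n_families))))
  m[matrix(stats::runif(length(m)) < missing_rate, nrow = n_genomes)] <- NA
  # every genome needs one label, every family at least one
  for (i in which(rowSums(!is.na(m)) == 0L)) m[i, 1L] <- 1L
  storage.mode(m) <- "integer"
  collapse_to_eggs(canonical_order(m))
}

# Lin-clusterings built from the worked-example partitions (label level).
fixture_clusterings <- function() {
  parts <- list(
    uL1 = list(c("gA", "gE", "gF", "gG"), c("gB", "gC", "gD"),
               c("gH", "gI", "gJ")),
    uL2 = list(c("gA", "gE", "gF", "gG"), "gD", "gH"),
    uL3 = list(c("gA", "gB", "gC", "gE", "gF", "gG"),
               c("gD", "gH", "gI"), "gJ"),
    uL4 = list(c("gB", "gC", "gE", "gF", "gG"), c("gA", "gD"),
               c("gH", "gJ")))
  lapply(names(parts), function(f) label_by_size(parts[[f]], f))
}

# Label-level worked-example run through the public pipeline.
fixture_run <- function(deltas = c(1, 0.5), ...) {
  mps_run(clusterings = fixture_clusterings(), deltas = deltas,
          quiet = TRUE, ...)
}

# Genome sets of the clusters of one per-delta result.
cluster_genomes <- function(run, delta) {
  res <- run$results[[formatC(delta, format = "g")]]
  lapply(res$clusters, function(ids)
    sort(unlist(run$eggs$genomes[ids], use.names = FALSE)))
}

write_fasta <- function(path, ids, seqs) {
  writeLines(paste0(">", ids, "\n", seqs), path)
}
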