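fixture_eggs <- function() {
  collapse_to_eggs(canonical_order(build_label_matrix(fixture_clusterings())))
}

test_that("the dendrogram merges the worked-example component as published", {
  eggs <- fixture_eggs()
  pc <- build_components(eggs, 2L)
  sim1 <- similarity_matrix(eggs, pc$components[[1]])
  d <- build_dendrogram(sim1)
  # first merge joins the gE/gF/gG EGG with the gA EGG at similarity 0.75
  expect_equal(d$similarity[1], 0.75)
  first <- abs(d$merge[1, ])
  first_genomes <- sort(unlist(eggs$genomes[d$leaves[first]],
                               use.names = FALSE))
  expect_equal(first_genomes, c("gA", "gE", "gF", "gG"))
  expect_false(is.unsorted(-d$similarity))

  # two EGGs with Dice 0: single merge at 0
  m <- matrix(c(1L, 2L), 2, 1, dimnames = list(c("a", "b"), "f1"))
  e2 <- collapse_to_eggs(canonical_order(m))
  d2 <- build_dendrogram(similarity_matrix(e2))
  expect_equal(d2$similarity, 0)

  d1 <- build_dendrogram(similarity_matrix(e2, 1L))
  expect_equal(nrow(d1$merge), 0L)
})

test_that("cutting reproduces the five worked-example clusters", {
  run <- fixture_run(deltas = c(1, 0.5, 0))
  g05 <- cluster_genomes(run, 0.5)
  expect_equal(partition_key(g05), partition_key(list(
    c("gA", "gE", "gF", "gG"), c("gH", "gI"), c("gB", "gC"),
    "gD", "gJ")))
  # delta = 1 bypasses the clustering: one cluster per EGG
  g1 <- cluster_genomes(run, 1)
  expect_equal(length(g1), 7L)
  expect_equal(partition_key(g1),
               partition_key(lapply(run$eggs$genomes, sort)))
  # delta = 0 merges each processed component entirely (no pre-connection)
  expect_equal(length(cluster_genomes(run, 0)), 1L)

  expect_error(cut_dendrogram(run$dendrograms[[1]], 1.2), "\\[0, 1\\]")
  expect_error(cut_dendrogram(run$dendrograms[[1]], -0.1), "\\[0, 1\\]")
})

test_that("multi-threshold cuts equal independent runs and deduplicate", {
  run <- fixture_run(deltas = c(1, 0.5, 0.5, 1))
  expect_equal(names(run$results), c("1", "0.5"))
  expect_equal(vapply(run$results, function(r) length(r$clusters),
                      integer(1)),
               c("1" = 7L, "0.5" = 5L))
  solo <- fixture_run(deltas = 0.5)
  expect_equal(partition_key(cluster_genomes(solo, 0.5)),
               partition_key(cluster_genomes(run, 0.5)))
  expect_error(multi_delta_cut(run$dendrograms, numeric(0)),
               "at least one delta")
})

test_that("every cluster satisfies the complete-link guarantee", {
  set.seed(61)
  for (rep in 1:6) {
    eggs <- random_egg_set(n_genomes = sample(10:25, 1),
                           n_families = sample(3:6, 1))
    sim <- similarity_matrix(eggs)
    d <- build_dendrogram(sim)
    for (delta in c(0.9, 0.6, 0.3, 0.05)) {
      clusters <- cut_dendrogram(d, delta)
      for (cl in clusters) {
        if (length(cl) > 1) {
          sub <- sim[as.character(cl), as.character(cl)]
          expect_gte(min(sub), delta)
        }
      }
      # all EGGs present exactly once
      expect_setequal(unlist(clusters), d$leaves)
    }
    # monotonicity: cluster count non-increasing as delta decreases
    counts <- vapply(c(1, 0.8, 0.6, 0.4, 0.2, 0),
                     function(dd) length(cut_dendrogram(d, dd)), integer(1))
    expect_false(is.unsorted(rev(counts)))
  }
})

test_that("cuts agree with hclust complete linkage when similarities are distinct", {
  set.seed(73)
  for (rep in 1:6) {
    n <- sample(5:10, 1)
    # random symmetric similarity with all-distinct off-diagonal values
    vals <- sample(seq(0.01, 0.99, by = 0.01), n * (n - 1) / 2)
    sim <- matrix(0, n, n, dimnames = list(as.character(1:n),
                                           as.character(1:n)))
    sim[upper.tri(sim)] <- vals
    sim <- sim + t(sim)
    diag(sim) <- 1
    d <- build_dendrogram(sim)
    hc <- stats::hclust(stats::as.dist(1 - sim), method = "complete")
    for (delta in c(0.85, 0.55, 0.25)) {
      ours <- cut_dendrogram(d, delta)
      ref <- stats::cutree(hc, h = 1 - delta)
      ref_clusters <- unname(split(as.integer(names(ref)), ref))
      expect_equal(partition_key(ours), partition_key(ref_clusters))
    }
  }
})
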