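test_that("the priority cascade picks the worked-example representatives", {
  run <- fixture_run(deltas = 0.5)
  res <- run$results[["0.5"]]
  reps <- res$representatives
  expect_equal(nrow(reps), 5L)
  by_cluster <- lapply(res$clusters, function(ids)
    sort(unlist(run$eggs$genomes[ids], use.names = FALSE)))
  for (i in seq_len(nrow(reps)))
    expect_true(reps$representative_id[i] %in% by_cluster[[i]])

  # singleton cluster {gD} is forced
  i_d <- which(vapply(by_cluster, function(g) identical(g, "gD"),
                      logical(1)))
  expect_equal(reps$representative_id[i_d], "gD")

  # 4-genome cluster: tier 2 ties (all complete), tier 3 prefers the
  # 3-genome EGG (centrality 2.75 vs 2.25), so gA never wins
  i_4 <- which(vapply(by_cluster, length, integer(1)) == 4L)
  expect_true(reps$representative_id[i_4] %in% c("gE", "gF", "gG"))

  # {gH, gI}: gH has 4 families, gI only 2 -> completeness tier decides
  i_hi <- which(vapply(by_cluster, function(g)
    identical(g, c("gH", "gI")), logical(1)))
  expect_equal(reps$representative_id[i_hi], "gH")
})

test_that("a user priority score dominates every other tier", {
  pt <- priority_table("gA", 10)
  run <- fixture_run(deltas = 0.5, priorities = pt)
  reps <- run$results[["0.5"]]$representatives
  expect_true("gA" %in% reps$representative_id)
  # gA represents its own 4-genome cluster
  expect_equal(reps$representative_id[reps$n_genomes == 4L], "gA")
})

test_that("raising the winner's priority never dethrones it", {
  run <- fixture_run(deltas = 0.5)
  base <- run$results[["0.5"]]$representatives
  for (g in base$representative_id) {
    boosted <- fixture_run(deltas = 0.5,
                           priorities = priority_table(g, 5))
    got <- boosted$results[["0.5"]]$representatives
    expect_true(g %in% got$representative_id)
  }
})

test_that("the mapping is total and representatives map to themselves", {
  run <- fixture_run(deltas = c(1, 0.5))
  for (res in run$results) {
    map <- res$mapping
    expect_setequal(map$genome_id, paste0("g", LETTERS[1:10]))
    expect_equal(anyDuplicated(map$genome_id), 0L)
    reps <- res$representatives$representative_id
    self <- map$representative_id[match(reps, map$genome_id)]
    expect_equal(self, reps)
    # no genome maps outside its cluster
    for (i in seq_len(nrow(map))) {
      cl <- map$mps_cluster_id[i]
      expect_equal(map$representative_id[i],
                   res$representatives$representative_id[cl])
    }
  }
  # all-distinct EGGs at delta 1: identity mapping
  m <- matrix(c(1L, 2L, 3L), 3, 1,
              dimnames = list(c("a", "b", "c"), "f1"))
  cl <- list(structure(list(family_id = "f1",
                            assignment = c(a = 1L, b = 2L, c = 3L),
                            cluster_sizes = c(`1` = 1L, `2` = 1L,
                                              `3` = 1L)),
                       class = "lin_clustering"))
  run1 <- mps_run(clusterings = cl, deltas = 1, quiet = TRUE)
  map1 <- run1$results[["1"]]$mapping
  expect_equal(map1$representative_id, map1$genome_id)

  expect_error(select_representative(integer(0), run$eggs,
                                     run$similarities[[1]]),
               "length")
})

test_that("selection is deterministic and input-order invariant", {
  cls <- fixture_clusterings()
  a <- mps_run(clusterings = cls, deltas = 0.5, quiet = TRUE)
  b <- mps_run(clusterings = rev(cls), deltas = 0.5, quiet = TRUE)
  expect_identical(a$results[["0.5"]]$representatives,
                   b$results[["0.5"]]$representatives)
  expect_identical(a$results[["0.5"]]$mapping, b$results[["0.5"]]$mapping)
})
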