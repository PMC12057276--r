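test_that("k-mer prefilter finds identical pairs and skips unrelated ones", {
  set.seed(7)
  s <- paste(sample(c("M", "K", "V", "L", "W"), 50, replace = TRUE),
             collapse = "")
  fam <- protein_family("f", c("s1_a", "s2_a"), c("s1", "s2"), c(s, s))
  expect_equal(nrow(candidate_pairs(fam)), 1L)

  fam2 <- protein_family("f", c("a_x", "b_x"), c("a", "b"),
                         c(strrep("A", 60), strrep("G", 60)))
  expect_equal(nrow(candidate_pairs(fam2)), 0L)

  fam3 <- protein_family("f", "a_x", "a", strrep("M", 30))
  expect_equal(nrow(candidate_pairs(fam3)), 0L)

  # sequences shorter than the k-mer size contribute their whole string
  fam4 <- protein_family("f", c("a_x", "b_x"), c("a", "b"), c("MKV", "MKV"))
  expect_equal(nrow(candidate_pairs(fam4)), 1L)
})

test_that("alignment verification applies identity, coverage and e-value", {
  set.seed(11)
  a <- paste(sample(mpsampler:::AA20, 100, replace = TRUE), collapse = "")
  st <- verify_pair(a, a, family_residue_total = 1000)
  expect_equal(st$identity, 1)
  expect_equal(st$coverage_a, 1)
  expect_equal(st$coverage_b, 1)
  expect_lt(st$evalue, 1e-5)
  expect_true(st$accepted)

  # half-length fragment: coverage of the long sequence ~0.5 < 0.8
  b <- substr(a, 1, 50)
  st2 <- verify_pair(a, b, family_residue_total = 1000)
  expect_lt(st2$coverage_a, 0.8)
  expect_false(st2$accepted)

  # 50% mismatches: direct position count gives identity 0.5; the local
  # alignment cannot reach the 0.6 identity threshold
  chars <- strsplit(a, "")[[1]]
  idx <- seq(1, 100, by = 2)
  chars[idx] <- vapply(chars[idx], function(x)
    sample(setdiff(mpsampler:::AA20, x), 1), character(1))
  c50 <- paste(chars, collapse = "")
  direct_identity <- mean(strsplit(a, "")[[1]] == chars)
  expect_equal(direct_identity, 0.5)
  st3 <- verify_pair(a, c50, family_residue_total = 1000)
  expect_lt(st3$identity, 0.6)
  expect_false(st3$accepted)
})

test_that("greedy set cover matches an independent simulation", {
  # star: hub picked first, one cluster
  star <- matrix(c("v1", "v2", "v1", "v3", "v1", "v4"),
                 ncol = 2, byrow = TRUE)
  got <- greedy_set_cover(paste0("v", 1:4), star)
  expect_equal(partition_key(got), partition_key(list(paste0("v", 1:4))))

  # no edges: all singletons
  none <- greedy_set_cover(c("a", "b", "c"),
                           matrix(character(0), ncol = 2))
  expect_equal(lengths(none), c(1L, 1L, 1L))

  # path a-b-c: b has highest degree, single cluster
  path <- matrix(c("a", "b", "b", "c"), ncol = 2, byrow = TRUE)
  got <- greedy_set_cover(c("a", "b", "c"), path)
  expect_equal(partition_key(got), partition_key(list(c("a", "b", "c"))))

  # oracle equivalence on random graphs with <= 8 vertices
  set.seed(202)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    verts <- paste0("n", seq_len(n))
    all_pairs <- t(combn(verts, 2))
    pick <- runif(nrow(all_pairs)) < 0.35
    edges <- all_pairs[pick, , drop = FALSE]
    expect_equal(partition_key(greedy_set_cover(verts, edges)),
                 partition_key(greedy_ref(verts, edges)))
  }
})

test_that("size labeling is deterministic and order-invariant", {
  part <- list(c("gA", "gE", "gF", "gG"), c("gB", "gC", "gD"),
               c("gH", "gI", "gJ"))
  cl <- label_by_size(part, "uL1")
  expect_equal(unname(cl$assignment[c("gA", "gB", "gH")]), c(1L, 2L, 3L))
  expect_equal(unname(cl$cluster_sizes), c(4L, 3L, 3L))

  expect_equal(label_by_size(list("gZ"), "x")$assignment, c(gZ = 1L))

  # permuting clusters and members changes nothing
  perm <- lapply(rev(part), rev)
  expect_identical(label_by_size(perm, "uL1")$assignment, cl$assignment)

  # equal-size singletons: fixed by hash, stable across calls
  a <- label_by_size(list("gD", "gH"), "uL2")$assignment
  b <- label_by_size(list("gH", "gD"), "uL2")$assignment
  expect_identical(a, b)
})

test_that("clustering a family yields a partition regardless of input order", {
  sim <- simulate_families(n_groups = 2, genomes_per_group = 3,
                           n_families = 1, seed = 5)
  fam <- sim$families[[1]]
  cl <- lin_cluster_family(fam)
  expect_setequal(names(cl$assignment), fam$records$genome_id)
  expect_false(is.unsorted(-cl$cluster_sizes))
  # permuted record order
  ord <- sample(nrow(fam$records))
  fam_perm <- protein_family(fam$family_id, fam$records$seq_id[ord],
                             fam$records$genome_id[ord],
                             fam$records$residues[ord])
  expect_identical(lin_cluster_family(fam_perm)$assignment, cl$assignment)
})

test_that("external cluster TSVs are parsed and labeled like built-in output", {
  fam <- protein_family("uL1",
                        paste0(paste0("g", LETTERS[1:10]), "_uL1"),
                        paste0("g", LETTERS[1:10]),
                        rep(strrep("MKVLAWTHIS", 12), 10))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  # singletons: every sequence its own representative
  writeLines(paste(fam$records$seq_id, fam$records$seq_id, sep = "\t"), tsv)
  cl <- external_cluster_adapter(fam, tsv)
  expect_equal(length(cl$cluster_sizes), 10L)

  # everything in one cluster
  writeLines(paste(fam$records$seq_id[1], fam$records$seq_id, sep = "\t"),
             tsv)
  cl1 <- external_cluster_adapter(fam, tsv)
  expect_equal(unname(cl1$cluster_sizes), 10L)
  expect_true(all(cl1$assignment == 1L))

  # the worked-example uL1 partition labels identically to label_by_size
  part <- list(c("gA", "gE", "gF", "gG"), c("gB", "gC", "gD"),
               c("gH", "gI", "gJ"))
  reps <- vapply(part, `[`, character(1), 1)
  lines <- unlist(lapply(seq_along(part), function(i)
    paste(paste0(reps[i], "_uL1"), paste0(part[[i]], "_uL1"), sep = "\t")))
  writeLines(lines, tsv)
  expect_identical(external_cluster_adapter(fam, tsv)$assignment,
                   label_by_size(part, "uL1")$assignment)

  writeLines(c("gA_uL1\tgB_uL1", lines), tsv)
  expect_error(external_cluster_adapter(fam, tsv), "twice")
  writeLines(paste0("gZ_uL1\t", fam$records$seq_id), tsv)
  expect_error(external_cluster_adapter(fam, tsv), "unknown seq_id")
})
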