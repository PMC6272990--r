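test_that("NJ recovers a hand-built additive 4-taxon tree exactly", {
  # generating tree ((A:1,B:2):0.5,(C:3,D:4):0.5)
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d)
  ref <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  expect_true(same_topology(tr, ref))
  expect_equal(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]], d,
               tolerance = 1e-9)
})

test_that("three taxa get the closed-form trifurcation", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(tr$Nnode, 1)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[c("a", "b", "c")], c(a = 0.5, b = 1.5, c = 2.5))
})

test_that("ties are broken deterministically by lowest index pair", {
  d <- matrix(2, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  t1 <- nj_tree(d)
  t2 <- nj_tree(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  # the first join must be the pair (1, 2) = (A, B)
  parts <- ape::prop.part(t1)
  cherries <- Filter(function(p) length(p) == 2, parts)
  expect_true(any(vapply(cherries, function(p)
    setequal(t1$tip.label[p], c("A", "B")), TRUE)))
})

test_that("NJ is exact on every 4- and 5-leaf additive topology", {
  set.seed(51)
  for (n in 4:5) {
    for (topo in phangorn::allTrees(n, rooted = FALSE)) {
      topo$tip.label <- paste0("t", seq_len(n))
      topo$edge.length <- runif(nrow(topo$edge), 0.1, 2)
      d <- ape::cophenetic.phylo(topo)[topo$tip.label, topo$tip.label]
      tr <- nj_tree(d)
      expect_true(same_topology(tr, topo))
      expect_equal(ape::cophenetic.phylo(tr)[topo$tip.label, topo$tip.label],
                   d, tolerance = 1e-8)
    }
  }
})

test_that("topology agrees with an independent NJ implementation", {
  set.seed(52)
  bm <- random_bm(12, 40)
  d <- dissimilarity_matrix(bm)
  expect_true(same_topology(nj_tree(d), ape::nj(as.dist(d))))
})

test_that("non-symmetric input is rejected", {
  d <- matrix(runif(16), 4)
  expect_error(nj_tree(d), "symmetric")
})

test_that("Newick writing round-trips and keeps supports", {
  tr <- ape::read.tree(text = "((A:1,B:2)87:1,C:3,D:4);")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- ape::read.tree(f)
  expect_true(same_topology(back, tr))
  expect_setequal(back$tip.label, tr$tip.label)
  expect_true("87" %in% back$node.label)
  expect_match(readLines(f), "87")
})

test_that("bootstrap supports are seeded, bounded and sane", {
  sim <- simulate_band_matrix(sim_config(n_pops = 2, samples_per_pop = 5,
                                         primers = c(SSR = 4),
                                         divergence = 0.3, seed = 61,
                                         study_labels = FALSE))
  # a single replicate can only give 0 or 100
  t1 <- bootstrap_support(sim$matrix, n_reps = 1, seed = 1)
  sup <- as.integer(t1$node.label[t1$node.label != ""])
  expect_true(all(sup %in% c(0L, 100L)))
  # identical seed, identical supports
  t2 <- bootstrap_support(sim$matrix, n_reps = 25, seed = 9)
  t3 <- bootstrap_support(sim$matrix, n_reps = 25, seed = 9)
  expect_identical(t2$node.label, t3$node.label)
  expect_true(all(as.integer(t2$node.label[-1]) >= 0 &
                    as.integer(t2$node.label[-1]) <= 100))
})

test_that("duplicating every band leaves the Dice NJ tree unchanged", {
  set.seed(62)
  bm <- random_bm(8, 15)
  v2 <- cbind(bm$values, bm$values)
  colnames(v2) <- sprintf("b%03d", seq_len(ncol(v2)))
  bm2 <- tiny_bm(v2)
  expect_equal(dissimilarity_matrix(bm2), dissimilarity_matrix(bm))
  expect_true(same_topology(nj_tree(dissimilarity_matrix(bm2)),
                            nj_tree(dissimilarity_matrix(bm))))
})
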