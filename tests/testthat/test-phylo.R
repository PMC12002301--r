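test_that("distance corrections follow their closed forms", {
  msa <- alignment(c("a", "b", "c"),
                   c("AAAAAAAAAA", "AAAAAAAAAC", "CCCCCCCCCC"))
  Dp <- distance_matrix(msa, "p")
  expect_equal(Dp["a", "b"], 0.1)
  expect_equal(diag(Dp), c(a = 0, b = 0, c = 0))
  expect_true(isSymmetric(Dp))
  # saturation (a-c, b-c pairs) is capped with a warning
  expect_warning(Dk <- distance_matrix(msa, "kimura_protein"), "capped")
  expect_equal(Dk["a", "b"], -log(1 - 0.1 - 0.2 * 0.01), tolerance = 1e-12)
  expect_equal(Dk["a", "b"], 0.10758, tolerance = 1e-4)
  expect_equal(Dk["a", "c"], -log(1 - 0.85 - 0.2 * 0.85^2), tolerance = 1e-12)
  # pairwise gap deletion; zero overlap errors
  msa2 <- alignment(c("a", "b", "c"), c("AA--", "--CC", "AACC"))
  expect_error(distance_matrix(msa2, "p"), "overlap")
})

test_that("neighbor joining solves the additive 4-taxon worked example exactly", {
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A","B"] <- 3; D["A","C"] <- 5; D["A","D"] <- 6
  D["B","C"] <- 6; D["B","D"] <- 7; D["C","D"] <- 7
  D <- D + t(D)
  tr <- nj_tree(D)
  # split AB|CD, path lengths reproduce the matrix exactly
  pd <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(unname(pd), unname(D), tolerance = 1e-12)
  expect_equal(rf_dist(tr, ape::read.tree(text = "((A,B),(C,D));")), 0)
  # tip branch lengths
  el <- setNames(tr$edge.length[tr$edge[, 2] <= 4],
                 tr$tip.label[tr$edge[tr$edge[, 2] <= 4, 2]])
  expect_equal(el[c("A", "B", "C", "D")], c(A = 1, B = 2, C = 3, D = 4))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|3")
})

test_that("NJ recovers the generating topology for random additive matrices", {
  set.seed(21)
  for (r in 1:30) {
    n <- sample(4:8, 1)
    gen <- random_additive_tree(n)
    D <- ape::cophenetic.phylo(gen)
    rec <- nj_tree(D)
    expect_equal(rf_dist(rec, gen), 0)
    # and against the independent NJ implementation
    expect_equal(rf_dist(rec, ape::nj(D)), 0)
  }
})

test_that("NJ and UPGMA agree on ultrametric matrices", {
  set.seed(4)
  for (r in 1:10) {
    gen <- ape::rcoal(6)   # ultrametric
    D <- ape::cophenetic.phylo(gen)
    nj <- nj_tree(D)
    up <- ape::as.phylo(stats::hclust(stats::as.dist(D), "average"))
    expect_equal(rf_dist(nj, up), 0)
  }
})

test_that("bootstrap support is high for a clean two-clade alignment", {
  set.seed(2)
  base1 <- random_peptide(200); base2 <- random_peptide(200)
  jitter <- function(s, k) {
    aa <- strsplit(s, "")[[1]]
    idx <- sample(length(aa), k)
    aa[idx] <- vapply(idx, function(i) random_peptide(1), "")
    paste(aa, collapse = "")
  }
  msa <- alignment(c("a1", "a2", "a3", "b1", "b2", "b3"),
                   c(jitter(base1, 8), jitter(base1, 8), jitter(base1, 8),
                     jitter(base2, 8), jitter(base2, 8), jitter(base2, 8)))
  bs <- bootstrap_support(msa, n_reps = 100, seed = 17, return_trees = TRUE)
  supp <- split_support(bs$trees, c("a1", "a2", "a3"))
  expect_gte(supp, 0.95)
  # determinism
  bs2 <- bootstrap_support(msa, n_reps = 100, seed = 17)
  expect_equal(bs$support, bs2$support)
  # single replicate gives 0/1 supports
  bs1 <- bootstrap_support(msa, n_reps = 1, seed = 3)
  expect_true(all(bs1$support[!is.na(bs1$support)] %in% c(0, 1)))
})

test_that("bipartition supports are invariant under leaf order permutation", {
  recs <- make_ortholog_set(3)$records
  msa <- progressive_msa(recs)
  bs1 <- bootstrap_support(msa, n_reps = 30, seed = 5, return_trees = TRUE)
  perm <- sample(length(msa$ids))
  msa2 <- alignment(msa$ids[perm], msa$rows[perm])
  bs2 <- bootstrap_support(msa2, n_reps = 30, seed = 5, return_trees = TRUE)
  s1 <- split_support(bs1$trees, c("echA1", "echA2", "echA3"))
  s2 <- split_support(bs2$trees, c("echA1", "echA2", "echA3"))
  expect_equal(s1, s2)
})

test_that("clade membership test on hand-built trees", {
  tr <- ape::read.tree(text = "(((q:1,(r1:1,r2:1):1):1,(c1:1,c2:1):1):1,out:3);")
  res <- is_in_clade_with(tr, "q", c("r1", "r2"), "out")
  expect_true(res$in_clade)
  expect_setequal(res$clade_leaves, c("q", "r1", "r2"))
  # query sister to the contrast clade
  tr2 <- ape::read.tree(text = "(((r1:1,r2:1):1,(q:1,(c1:1,c2:1):1):1):1,out:3);")
  expect_false(is_in_clade_with(tr2, "q", c("r1", "r2"), "out")$in_clade)
  # reference = all non-outgroup leaves is vacuously true
  expect_true(is_in_clade_with(tr2, "q", c("r1", "r2", "c1", "c2"),
                               "out")$in_clade)
  expect_error(is_in_clade_with(tr, "out", "r1", "out"), "outgroup")
})

test_that("newick round-trip preserves topology, lengths and supports", {
  recs <- make_ortholog_set(7)$records
  msa <- progressive_msa(recs)
  bs <- bootstrap_support(msa, n_reps = 20, seed = 1)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(bs$tree, f)
  back <- read_newick(f)
  expect_equal(rf_dist(back, bs$tree), 0)
  expect_equal(sort(back$edge.length), sort(bs$tree$edge.length),
               tolerance = 1e-9)
  expect_setequal(back$node.label, bs$tree$node.label)
})
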