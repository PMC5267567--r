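test_that("Newick reading validates and round-trips", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(length(tr$tip.label) + tr$Nnode, 5L)

  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  expect_equal(sum(back$edge.length), sum(tr$edge.length))
  expect_identical(ape::write.tree(back), ape::write.tree(tr))

  expect_error(read_newick(text = "(A,B);"), "no branch lengths")
  expect_warning(tr2 <- read_newick(text = "(A,B);", default_length = 1),
                 "assigning default")
  expect_equal(tr2$edge.length, c(1, 1))
  expect_error(read_newick(text = "((A:1,A:1):1,C:2);"), "duplicate")
})

test_that("polytomy resolution is seeded, binary, and length-preserving", {
  tri <- read_newick(text = "(A:1,B:1,C:1);")
  res <- resolve_polytomies(tri, seed = 1)
  expect_true(ape::is.binary(res))
  expect_equal(sum(res$edge.length), sum(tri$edge.length))
  # tip-to-root path lengths unchanged (zero-length insertions)
  expect_equal(diag(ape::vcv(res))[tri$tip.label],
               diag(ape::vcv(tri))[tri$tip.label])
  # deterministic per seed
  expect_identical(ape::write.tree(resolve_polytomies(tri, seed = 7)),
                   ape::write.tree(resolve_polytomies(tri, seed = 7)))
  # binary trees are a fixed point
  bin <- read_newick(text = "((A:1,B:1):1,C:2);")
  expect_identical(ape::write.tree(resolve_polytomies(bin, seed = 3)),
                   ape::write.tree(bin))

  # a single trichotomy has 3 resolutions; each drawn ~uniformly.
  # Identify the resolution by which pair of tips shares a non-root
  # parent (inserted edges have length 0, so path lengths can't tell).
  cherry_of <- function(tree) {
    ntip <- length(tree$tip.label)
    parents <- tree$edge[match(seq_len(ntip), tree$edge[, 2]), 1]
    shared <- parents[duplicated(parents) | duplicated(parents,
                                                       fromLast = TRUE)]
    deepest <- max(shared)  # non-root parent has the larger node number
    paste(sort(tree$tip.label[which(parents == deepest)]), collapse = "")
  }
  picks <- vapply(1:600, function(s)
    cherry_of(resolve_polytomies(tri, seed = s)), character(1))
  counts <- table(picks)
  expect_equal(length(counts), 3L)
  expect_true(all(abs(counts - 200) < 5 * sqrt(600 * (1 / 3) * (2 / 3))))
})

test_that("pruning preserves pairwise path lengths and reports mismatches", {
  tr <- read_newick(text = "(((A:1,B:2):1,(C:1,D:1):2):1,E:5);")
  full_d <- ape::cophenetic.phylo(tr)
  pr <- prune_to_taxa(tr, c("A", "C", "E", "Zed"))
  expect_equal(sort(pr$tree$tip.label), c("A", "C", "E"))
  expect_equal(pr$in_data_only, "Zed")
  expect_setequal(pr$in_tree_only, c("B", "D"))
  pruned_d <- ape::cophenetic.phylo(pr$tree)
  expect_equal(pruned_d[c("A", "C", "E"), c("A", "C", "E")],
               full_d[c("A", "C", "E"), c("A", "C", "E")])

  # identity prune and name normalization (case, space vs underscore)
  pr2 <- prune_to_taxa(tr, c("a", "B", "C ", "D", "E"))
  expect_equal(length(pr2$tree$tip.label), 5L)
  expect_error(prune_to_taxa(tr, c("A", "B")), "insufficient overlap")
})

test_that("independent contrasts match the hand-executed oracle", {
  # two tips: single contrast (3 - 1)/sqrt(2)
  tr2 <- read_newick(text = "(A:1,B:1);")
  c2 <- pic_contrasts(tr2, c(A = 3, B = 1))
  expect_equal(abs(unname(c2$contrasts)), sqrt(2))

  # three tips, hand-executed pruning: AB ancestor value 2, its edge
  # extends to 1 + 1/2, contrasts {(1-3)/sqrt(2), (2-6)/sqrt(3.5)}
  tr3 <- read_newick(text = "((A:1,B:1):1,C:2);")
  c3 <- pic_contrasts(tr3, c(A = 1, B = 3, C = 6))
  expect_equal(sort(abs(unname(c3$contrasts))),
               sort(c(2 / sqrt(2), 4 / sqrt(3.5))))
  expect_setequal(c3$node_variances, c(2, 3.5))

  # constant trait: all contrasts zero
  expect_equal(unname(pic_contrasts(tr3, c(A = 5, B = 5, C = 5))$contrasts),
               c(0, 0))

  # n - 1 contrasts, invariant to tip-value ordering
  tr <- ape::rtree(25)
  x <- stats::setNames(rnorm(25), tr$tip.label)
  cs <- pic_contrasts(tr, x)
  expect_length(cs$contrasts, 24L)
  expect_equal(pic_contrasts(tr, rev(x))$contrasts, cs$contrasts)

  expect_error(pic_contrasts(tr, x[-1]), "missing tip value")
  zz <- read_newick(text = "((A:0,B:0):1,C:2);")
  expect_error(pic_contrasts(zz, c(A = 1, B = 2, C = 3)),
               "zero working length")
})

test_that("contrasts agree with the ape reference on random trees", {
  set.seed(21)
  for (i in 1:10) {
    tr <- ape::rtree(sample(5:60, 1))
    x <- stats::setNames(rnorm(length(tr$tip.label)), tr$tip.label)
    expect_equal(sort(abs(unname(pic_contrasts(tr, x)$contrasts))),
                 sort(abs(unname(ape::pic(x, tr)))),
                 tolerance = 1e-10)
  }
})

test_that("Brownian contrasts are standardized to the simulation rate", {
  tr <- simulate_tree(80, 1, seed = 15)
  set.seed(16)
  msq <- replicate(60, {
    x <- ape::rTraitCont(tr, sigma = 0.7)
    mean(pic_contrasts(tr, x)$contrasts^2)
  })
  expect_equal(mean(msq), 0.7^2, tolerance = 0.05)
})

test_that("Blomberg's K is 1 on an equal-branch star and affine-invariant", {
  star <- read_newick(text = "(A:2,B:2,C:2,D:2,E:2,F:2);")
  set.seed(3)
  x <- stats::setNames(rnorm(6), star$tip.label)
  expect_equal(blomberg_k(star, x), 1)

  tr <- ape::rtree(30)
  y <- stats::setNames(rnorm(30), tr$tip.label)
  k <- blomberg_k(tr, y)
  expect_equal(blomberg_k(tr, 3.2 * y + 11), k)
  expect_gte(k, 0)

  # shuffling destroys signal on a deep balanced tree
  deep <- read_newick(text = balanced_tree_text())
  sig <- stats::setNames(c(0, 0, 0, 0, 10, 10, 10, 10) +
                           rnorm(8, 0, 0.1), deep$tip.label)
  set.seed(10)
  k_shuf <- replicate(50, {
    blomberg_k(deep, stats::setNames(sample(sig), deep$tip.label))
  })
  expect_gt(blomberg_k(deep, sig), mean(k_shuf))
})

test_that("K agrees with the picante reference implementation", {
  skip_if_not_installed("picante")
  set.seed(6)
  for (i in 1:5) {
    tr <- ape::rtree(40)
    x <- stats::setNames(rnorm(40), tr$tip.label)
    expect_equal(blomberg_k(tr, x),
                 as.numeric(picante::Kcalc(x[tr$tip.label], tr,
                                           checkdata = FALSE)),
                 tolerance = 1e-8)
  }
})

test_that("permutation test of signal is calibrated and detects structure", {
  # planted clade structure on a balanced tree: strong signal
  deep <- read_newick(text = balanced_tree_text())
  big <- simulate_tree(32, 1, seed = 91)
  set.seed(92)
  trait <- ape::rTraitCont(big, sigma = 1)
  res <- k_significance(big, trait, n_permutations = 999, seed = 17)
  expect_lte(res$p_value, 0.01)
  expect_gt(res$p_value, 0)

  # n_permutations = 1: p is (1 + 0)/2 or (1 + 1)/2
  r1 <- k_significance(deep, stats::setNames(rnorm(8), deep$tip.label),
                       n_permutations = 1, seed = 2)
  expect_true(r1$p_value %in% c(0.5, 1))

  # i.i.d. traits: rejection rate ~ alpha
  set.seed(93)
  rej <- replicate(200, {
    x <- stats::setNames(rnorm(32), big$tip.label)
    k_significance(big, x, n_permutations = 99,
                   seed = sample.int(1e6, 1))$p_value <= 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.05)
})
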