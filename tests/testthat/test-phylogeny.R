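test_that("p-distance and Poisson correction follow the closed forms", {
  expect_equal(pairwise_distance(c(a = "ACDE", b = "ACDE"))["a", "b"], 0)
  expect_equal(pairwise_distance(c(a = "AAAA", b = "AAAT"))["a", "b"], 0.25)
  expect_equal(
    pairwise_distance(c(a = "AAAA", b = "AAAT"),
                      model = "poisson-corrected")["a", "b"],
    -log(0.75))

  # pairwise vs complete deletion
  msa <- c(a = "AC-E", b = "ACDE", c = "TCDE")
  D <- pairwise_distance(msa)                       # pairwise-deletion
  expect_equal(D["a", "b"], 0)                      # 3 comparable, 0 diffs
  expect_equal(D["a", "c"], 1 / 3)
  Dc <- pairwise_distance(msa, gap_policy = "complete-deletion")
  expect_equal(Dc["a", "c"], 1 / 3)                 # col 1 of 3 kept differs

  expect_error(pairwise_distance(c(a = "A---", b = "-CDE")),
               "zero comparable.*a / b")
  expect_error(pairwise_distance(c(a = "AAAA", b = "CCCC"),
                                 model = "poisson-corrected"),
               "a / b")
})

test_that("three-taxon neighbor joining solves the closed form", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("neighbor joining reconstructs random additive trees exactly", {
  skip_if_not_installed("phangorn")
  set.seed(606)
  for (i in 1:100) {
    case <- random_additive_case(sample(6:10, 1L))
    out <- neighbor_joining(case$D)
    expect_equal(phangorn::RF.dist(ape::unroot(case$tree), out), 0)
    labs <- rownames(case$D)
    expect_lt(max(abs(stats::cophenetic(out)[labs, labs] - case$D)), 1e-9)
  }
})

test_that("neighbor joining agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(19)
  for (i in 1:10) {
    msa <- evolve_alignment(ape::rtree(7), 300, seed = 500 + i)
    D <- pairwise_distance(msa, model = "poisson-corrected")
    expect_equal(phangorn::RF.dist(neighbor_joining(D),
                                   ape::unroot(ape::nj(as.dist(D)))), 0)
  }
})

test_that("ties resolve deterministically and negative branches are clamped", {
  # equidistant 4-taxon star: any resolution is legitimate, but the
  # documented (row, column) tie rule must make it reproducible
  D <- matrix(1, 4, 4) - diag(4)
  dimnames(D) <- list(letters[1:4], letters[1:4])
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$edge.length >= 0))

  # a matrix engineered to produce a negative NJ branch
  D2 <- matrix(c(0, 1, 5, 5,
                 1, 0, 4, 6,
                 5, 4, 0, 2,
                 5, 6, 2, 0), 4,
               dimnames = list(letters[1:4], letters[1:4]))
  t3 <- neighbor_joining(D2)
  expect_true(all(t3$edge.length >= 0))
})

test_that("bootstrap supports behave at the degenerate ends", {
  msa <- evolve_alignment(
    ape::read.tree(text = "((A:0.1,B:0.1):0.5,(C:0.1,D:0.1):0.5,(E:0.1,F:0.1):0.5);"),
    500, seed = 21)
  one <- bootstrap_consensus(msa, n_reps = 1, seed = 3)
  sup <- suppressWarnings(as.numeric(one$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))

  # duplicate identical taxa: the zero-distance pair is always joined
  msa2 <- evolve_alignment(
    ape::read.tree(text = "((A:0.2,B:0.2):0.3,(C:0.2,D:0.2):0.3,E:0.4);"),
    400, seed = 9)
  msa2 <- c(msa2, A_copy = unname(msa2[["A"]]))
  bt <- bootstrap_consensus(msa2, n_reps = 50, seed = 4)
  expect_true(are_sister(bt, "A", "A_copy"))
  parent <- bt$edge[bt$edge[, 2] == match("A", bt$tip.label), 1]
  cherry_support <- bt$node.label[parent - length(bt$tip.label)]
  expect_equal(as.numeric(cherry_support), 100)
})

test_that("high supports emerge for every true bipartition on long internal branches", {
  true_tree <- ape::read.tree(
    text = "((A:0.1,B:0.1):0.5,(C:0.1,D:0.1):0.5,(E:0.1,F:0.1):0.5);")
  msa <- evolve_alignment(true_tree, 2000, seed = 31)
  bt <- bootstrap_consensus(msa, n_reps = 200, seed = 13,
                            model = "poisson-corrected")
  for (pair in list(c("A", "B"), c("C", "D"), c("E", "F"))) {
    expect_true(are_sister(bt, pair[1], pair[2]))
  }
  sup <- as.numeric(bt$node.label[bt$node.label != ""])
  expect_true(all(sup >= 90))
})

test_that("bipartition supports are invariant to leaf-label permutation", {
  true_tree <- ape::read.tree(
    text = "((A:0.1,B:0.1):0.4,(C:0.1,D:0.1):0.4,(E:0.1,F:0.1):0.4);")
  msa <- evolve_alignment(true_tree, 800, seed = 41)
  perm <- rev(seq_along(msa))
  s1 <- bootstrap_consensus(msa, n_reps = 60, seed = 8)
  s2 <- bootstrap_consensus(msa[perm], n_reps = 60, seed = 8)
  key <- function(tr) {
    lab <- sort(stats::setNames(tr$node.label,
                                vapply(seq_len(tr$Nnode), function(i) {
                                  tips <- ape::extract.clade(tr,
                                    length(tr$tip.label) + i)$tip.label
                                  paste(sort(tips), collapse = "|")
                                }, "")))
    lab[names(lab) != ""]
  }
  # same split set; supports computed from the same resampling seed
  expect_setequal(names(key(s1)), names(key(s2)))
})

test_that("sister-pair queries follow the cherry definition", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_true(are_sister(tr, "A", "B"))
  expect_false(are_sister(tr, "A", "C"))
  expect_error(are_sister(tr, "A", "Z"), "Z")

  # degenerate 3-taxon unrooted tree: every pair is a cherry
  tr3 <- ape::read.tree(text = "(A,B,C);")
  expect_true(are_sister(tr3, "A", "C"))

  tr5 <- ape::read.tree(text = "(((A,B),C),(D,E));")
  expect_false(are_sister(tr5, "A", "C"))
  expect_true(are_sister(tr5, "D", "E"))
})

test_that("duplicated-domain and recruited-domain scenarios separate on the tree", {
  # duplication: the two domain copies of one lineage diverge after
  # speciation and stay sisters; recruitment: the second copy originates
  # outside the lineage and does not pair with the first
  dup_tree <- ape::read.tree(
    text = "((sp1_A:0.05,sp1_B:0.05):0.45,(sp2:0.25,sp3:0.25):0.25,out:0.5);")
  msa <- evolve_alignment(dup_tree, 1500, seed = 55)
  nj_dup <- neighbor_joining(pairwise_distance(msa,
                                               model = "poisson-corrected"))
  expect_true(are_sister(nj_dup, "sp1_A", "sp1_B"))

  rec_tree <- ape::read.tree(
    text = "((sp1_A:0.1,sp2:0.1):0.4,(sp1_B:0.1,sp3:0.1):0.4,out:0.5);")
  msa2 <- evolve_alignment(rec_tree, 1500, seed = 56)
  nj_rec <- neighbor_joining(pairwise_distance(msa2,
                                               model = "poisson-corrected"))
  expect_false(are_sister(nj_rec, "sp1_A", "sp1_B"))
  expect_true(are_sister(nj_rec, "sp1_A", "sp2"))
})

test_that("distances from evolved alignments converge to the path lengths", {
  tree <- ape::read.tree(
    text = "((A:0.15,B:0.2):0.3,(C:0.25,D:0.1):0.2,E:0.4);")
  true_D <- stats::cophenetic(tree)
  mae <- function(L, seed) {
    msa <- evolve_alignment(tree, L, seed = seed)
    D <- pairwise_distance(msa, model = "poisson-corrected")
    labs <- rownames(true_D)
    mean(abs(D[labs, labs] - true_D))
  }
  expect_lt(mae(10000, 71), mae(100, 71))
})
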