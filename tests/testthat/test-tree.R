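dist_from_tree <- function(tree) {
  D <- ape::cophenetic.phylo(tree)
  D[tree$tip.label, tree$tip.label]
}

rand_bltree <- function(n_tips, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tips, rooted = FALSE,
                   tip.label = sprintf("t%02d", seq_len(n_tips)))
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.05, 1)
  tr
}

test_that("three-taxon tree solves the unique branch-length system", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- bionj_tree(D)
  # pendant edge lengths: a = (dAB + dAC - dBC)/2 etc.
  tip_edge <- function(tree, tip) {
    tree$edge.length[tree$edge[, 2] == match(tip, tree$tip.label)]
  }
  expect_equal(tip_edge(tr, "A"), 1, tolerance = 1e-12)
  expect_equal(tip_edge(tr, "B"), 1, tolerance = 1e-12)
  expect_equal(tip_edge(tr, "C"), 3, tolerance = 1e-12)
})

test_that("additive matrices are recovered exactly (tree metric identity)", {
  for (seed in 1:25) {
    n <- sample(5:10, 1)
    tr0 <- rand_bltree(n, seed)
    D <- dist_from_tree(tr0)
    tr <- bionj_tree(D)
    expect_equal(dist_from_tree(tr)[rownames(D), colnames(D)], D,
                 tolerance = 1e-9)
  }
})

test_that("two clear ultrametric clusters are separated by the analytic branch", {
  # two 3-leaf clusters: within-cluster distance 0.2, between 1.0
  labs <- c("a1", "a2", "a3", "b1", "b2", "b3")
  D <- matrix(1, 6, 6, dimnames = list(labs, labs))
  D[1:3, 1:3] <- 0.2; D[4:6, 4:6] <- 0.2; diag(D) <- 0
  tr <- bionj_tree(D)
  len <- internal_branch_length(tr, list(labs[1:3], labs[4:6]))
  # leaf depth within a cluster = 0.1; cluster joins at 0.1 + x where
  # 2*(0.1 + x) ... path between clusters: 0.1 + x + 0.8-ish; the unique
  # additive solution has the separating branch = 1.0 - 2*0.1 - 2*x with
  # cluster-internal node depths 0.1: total between = 0.2 + internal = 1.0
  expect_equal(len, 0.8, tolerance = 1e-9)
})

test_that("two-sample trees split the distance across the pendant edges", {
  D <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(to_newick(bionj_tree(D)), "(A:0.2,B:0.2);")
})

test_that("matrix validation rejects broken input", {
  D <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("A", "B"),
                                                   c("A", "B")))
  expect_error(bionj_tree(D), "not symmetric")
  D2 <- matrix(c(0, -1, -1, 0), 2, 2, dimnames = list(c("A", "B"),
                                                      c("A", "B")))
  expect_error(bionj_tree(D2), "negative")
  expect_error(bionj_tree(matrix(0, 1, 1, dimnames = list("A", "A"))),
               ">=2")
})

test_that("newick serialization: branch-length flag and negative clamping", {
  tr <- rand_bltree(6, 99)
  nwk <- to_newick(tr)
  expect_match(nwk, ";$")
  reread <- ape::read.tree(text = nwk)
  expect_equal(dist_from_tree(reread)[tr$tip.label, tr$tip.label],
               dist_from_tree(tr), tolerance = 1e-6)

  topo <- to_newick(tr, with_branch_lengths = FALSE)
  expect_false(grepl(":", topo, fixed = TRUE))
  expect_true(all(ape::read.tree(text = topo)$tip.label %in% tr$tip.label))

  tr$edge.length[1] <- -0.05
  clamped <- ape::read.tree(text = to_newick(tr))
  expect_true(all(clamped$edge.length >= 0))
  raw <- ape::read.tree(text = to_newick(tr, clamp_negative = FALSE))
  expect_lt(min(raw$edge.length), 0)
})

test_that("internal_branch_length finds exactly the induced bipartition", {
  tr0 <- rand_bltree(8, 123)
  # pick a genuine internal edge's bipartition
  post <- ape::reorder.phylo(tr0, "postorder")
  ntip <- length(tr0$tip.label)
  internal <- which(tr0$edge[, 2] > ntip)
  e <- internal[1]
  clade <- ape::extract.clade(tr0, tr0$edge[e, 2])$tip.label
  len <- internal_branch_length(tr0, list(clade,
                                          setdiff(tr0$tip.label, clade)))
  expect_equal(len, tr0$edge.length[e], tolerance = 1e-12)

  # a partition no edge induces (if both sides >= 2 and mixed)
  labs <- tr0$tip.label
  mixed <- list(c(clade[1], setdiff(labs, clade)[1]),
                setdiff(labs, c(clade[1], setdiff(labs, clade)[1])))
  if (!setequal(mixed[[1]], clade)) {
    expect_true(is.na(internal_branch_length(tr0, mixed)) ||
                  is.numeric(internal_branch_length(tr0, mixed)))
  }

  expect_error(internal_branch_length(tr0, list(labs[1], labs[-1])),
               ">=2 tips")
  expect_error(internal_branch_length(tr0, list(labs[1:3], labs[3:8])),
               "overlap")
  expect_error(internal_branch_length(tr0, list(labs[1:3], labs[4:7])),
               "cover")
})

test_that("agglomeration topology matches the reference implementation", {
  # ape's bionj is an independent implementation (the original C code);
  # topologies must agree everywhere, branch lengths exactly on additive
  # input (ape's float arithmetic and negative-length clamping differ on
  # non-additive matrices)
  for (rep in 1:10) {
    set.seed(800 + rep)
    n <- sample(4:9, 1)
    M <- matrix(stats::runif(n * n, 0.2, 1), n, n)
    M <- (M + t(M)) / 2; diag(M) <- 0
    dimnames(M) <- list(sprintf("s%d", 1:n), sprintf("s%d", 1:n))
    t1 <- bionj_tree(M)
    t2 <- ape::bionj(M)
    expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
                 ignore_attr = TRUE)
  }
  tr0 <- rand_bltree(8, 801)
  D <- dist_from_tree(tr0)
  expect_equal(sort(bionj_tree(D)$edge.length),
               sort(ape::bionj(D)$edge.length), tolerance = 1e-5)
})

test_that("label permutation yields an isomorphic tree", {
  tr0 <- rand_bltree(7, 7)
  D <- dist_from_tree(tr0)
  perm <- sample(rownames(D))
  D2 <- D[perm, perm]
  t1 <- bionj_tree(D)
  t2 <- bionj_tree(D2)
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
  expect_equal(dist_from_tree(t2)[rownames(D), colnames(D)],
               dist_from_tree(t1)[rownames(D), colnames(D)],
               tolerance = 1e-9)
})
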