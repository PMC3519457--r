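# independent oracles: each formula evaluated through a different algebraic
# route than the implementation uses
oracle_shot <- function(pc) 1 - sqrt(mean(c((pc$c_ij / pc$c_i)^2,
                                            (pc$c_ij / pc$c_j)^2)))
oracle_minimum <- function(pc) 1 - pc$c_ij / min(pc$c_i, pc$c_j)
oracle_reads <- function(pc) 1 - sqrt(mean(c((pc$r_ij / pc$r_i)^2,
                                             (pc$r_ji / pc$r_j)^2)))
oracle_wootters <- function(p, q) {
  bc <- drop(crossprod(sqrt(p), sqrt(q)))
  2 / pi * acos(min(max(bc, 0), 1))
}

test_that("hand-computed distance examples reproduce exactly", {
  pc <- pc_from_counts(4, 9, 3)
  expect_equal(dist_shot(pc), 1 - 3 * sqrt((16 + 81) / (2 * 16 * 81)),
               tolerance = 1e-15)
  expect_equal(dist_shot(pc), oracle_shot(pc), tolerance = 1e-12)
  expect_equal(dist_minimum(pc), 0.25, tolerance = 1e-15)

  expect_equal(dist_wootters(c(0.5, 0.5, 0), c(0.5, 0, 0.5)), 2 / 3,
               tolerance = 1e-12)

  pc2 <- pc_from_counts(10, 10, 5, r_i = 100, r_j = 200,
                        r_ij = 50, r_ji = 80)
  expect_equal(dist_reads(pc2), 1 - sqrt((0.25^2 / 0.25 + 0.16) / 2),
               tolerance = 1e-12)
  expect_equal(dist_reads(pc2), 1 - sqrt((0.25 + 0.16) / 2),
               tolerance = 1e-15)
})

test_that("degenerate sharing hits the documented extremes", {
  full <- pc_from_counts(5, 5, 5, r_i = 50, r_j = 50, r_ij = 50, r_ji = 50)
  expect_equal(dist_shot(full), 0)
  expect_equal(dist_minimum(full), 0)
  expect_equal(dist_reads(full), 0)

  none <- pc_from_counts(7, 3, 0, r_ij = 0, r_ji = 0)
  expect_equal(dist_shot(none), 1)
  expect_equal(dist_minimum(none), 1)
  expect_equal(dist_reads(none), 1)

  nested <- pc_from_counts(9, 4, 4)  # c_ij = min
  expect_equal(dist_minimum(nested), 0)

  p <- rand_prob_vec(6)
  expect_equal(dist_wootters(p, p), 0, tolerance = 1e-12)
  expect_equal(dist_wootters(c(1, 0, 0), c(0, 0.4, 0.6)), 1,
               tolerance = 1e-12)
})

test_that("formulas match the independent oracles on 1000 random instances", {
  set.seed(20)
  for (rep in 1:1000) {
    pc <- rand_pc()
    expect_equal(dist_shot(pc), oracle_shot(pc), tolerance = 1e-12)
    expect_equal(dist_minimum(pc), oracle_minimum(pc), tolerance = 1e-12)
    expect_equal(dist_reads(pc), oracle_reads(pc), tolerance = 1e-12)
    p <- rand_prob_vec(12); q <- rand_prob_vec(12)
    expect_equal(dist_wootters(p, q), oracle_wootters(p, q),
                 tolerance = 1e-12)
  }
})

test_that("shot distance dominates minimum distance (RMS <= min ratio)", {
  set.seed(21)
  for (rep in 1:1000) {
    pc <- rand_pc()
    ds <- dist_shot(pc); dm <- dist_minimum(pc)
    expect_gte(ds, dm - 1e-12)
    if (pc$c_i != pc$c_j && pc$c_ij > 0) expect_gt(ds, dm)
  }
})

test_that("all four distances live in [0,1] and vanish only as documented", {
  set.seed(22)
  for (rep in 1:300) {
    pc <- rand_pc()
    for (d in c(dist_shot(pc), dist_minimum(pc), dist_reads(pc))) {
      expect_gte(d, 0); expect_lte(d, 1)
    }
    if (pc$c_ij == 0) {
      expect_equal(dist_shot(pc), 1)
      expect_equal(dist_reads(pc), 1)
    }
    p <- rand_prob_vec(8); q <- rand_prob_vec(8)
    dw <- dist_wootters(p, q)
    expect_gte(dw, 0); expect_lte(dw, 1)
  }
})

test_that("wootters is a metric: symmetry and triangle inequality", {
  set.seed(23)
  for (rep in 1:1000) {
    n <- sample(3:15, 1)
    p <- rand_prob_vec(n); q <- rand_prob_vec(n); r <- rand_prob_vec(n)
    expect_equal(dist_wootters(p, q), dist_wootters(q, p),
                 tolerance = 1e-12)
    expect_lte(dist_wootters(p, r),
               dist_wootters(p, q) + dist_wootters(q, r) + 1e-9)
  }
})

test_that("wootters input validation and the radians option", {
  expect_error(dist_wootters(c(0.5, 0.5), c(1, 0, 0)), "length")
  expect_error(dist_wootters(c(0.7, 0.7), c(0.5, 0.5)), "sum to 1")
  p <- rand_prob_vec(5); q <- rand_prob_vec(5)
  expect_equal(dist_wootters(p, q, scale = "radians"),
               dist_wootters(p, q) * pi / 2, tolerance = 1e-12)
})

test_that("distance_matrix applies the pair operation cell by cell", {
  prof <- rand_profile(60, 4, seed = 55)
  P <- abundance_vectors(prof)
  for (f in c("shot", "minimum", "wootters", "reads")) {
    D <- distance_matrix(prof, f)
    expect_equal(D, t(D))
    expect_equal(unname(diag(D)), rep(0, 4))
    for (i in 1:3) for (j in (i + 1):4) {
      expected <- if (f == "wootters") {
        dist_wootters(P[, i], P[, j])
      } else {
        pc <- pairwise_counts(prof, i, j)
        switch(f, shot = dist_shot(pc), minimum = dist_minimum(pc),
               reads = dist_reads(pc))
      }
      expect_equal(D[i, j], expected)
    }
  }
  expect_error(distance_matrix(prof, "nope"))
})

test_that("identical samples sharing private contigs are at distance zero", {
  R <- matrix(c(3L, 1L, 0L,
                3L, 1L, 0L,
                0L, 0L, 5L), 3, 3,
              dimnames = list(c("c1", "c2", "c3"), c("s1", "s2", "s3")))
  prof <- profile_from_matrix(R)
  for (f in c("shot", "minimum", "wootters", "reads")) {
    expect_equal(distance_matrix(prof, f)["s1", "s2"], 0,
                 tolerance = 1e-12)
  }
})

test_that("distance matrices serialize as TSV and PHYLIP", {
  prof <- rand_profile(30, 3, seed = 88)
  D <- distance_matrix(prof, "wootters")
  tsv <- tempfile(); phy <- tempfile()
  write_distance_matrix(D, tsv, "tsv")
  tab <- read.delim(tsv, row.names = 1)
  expect_equal(as.matrix(tab), unclass(D)[, , drop = FALSE],
               ignore_attr = TRUE, tolerance = 1e-9)
  write_distance_matrix(D, phy, "phylip")
  lines <- readLines(phy)
  expect_equal(as.integer(trimws(lines[1])), 3L)
  expect_length(lines, 4)
})
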