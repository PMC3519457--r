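test_that("genome pools are bit-reproducible and honor their parameters", {
  p1 <- make_genome_pool(3, c(5000, 5000), c(0.45, 0.55), seed = 8)
  p2 <- make_genome_pool(3, c(5000, 5000), c(0.45, 0.55), seed = 8)
  expect_identical(p1$genomes, p2$genomes)
  expect_equal(unname(nchar(p1$genomes)), rep(5000L, 3))

  hi <- make_genome_pool(4, c(50000, 50000), c(0.60, 0.65), seed = 9)
  expect_true(all(hi$gc >= 0.58 & hi$gc <= 0.67))  # range +- 0.02

  rng <- make_genome_pool(5, c(2000, 4000), c(0.4, 0.6), seed = 10)
  expect_true(all(nchar(rng$genomes) >= 2000 & nchar(rng$genomes) <= 4000))

  expect_error(make_genome_pool(0, seed = 1), "n_genomes")
  expect_error(make_genome_pool(2, c(500, 400), seed = 1), "length_range")
  expect_error(make_genome_pool(2, gc_range = c(0, 1.2), seed = 1),
               "gc_range")
})

test_that("divergent pools share exact k-mers; independent pools do not", {
  div <- make_genome_pool(2, c(20000, 20000), c(0.4, 0.5), seed = 11,
                          divergence = 0.02)
  indep <- make_genome_pool(2, c(20000, 20000), c(0.4, 0.5), seed = 12)
  kmers <- function(s, k = 21) {
    substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
  }
  shared_div <- length(intersect(kmers(div$genomes[1]),
                                 kmers(div$genomes[2])))
  shared_ind <- length(intersect(kmers(indep$genomes[1]),
                                 kmers(indep$genomes[2])))
  # expectation ~ (1 - 0.02)^(2*21) ~ 0.43 of positions
  expect_gt(shared_div, 0.3 * 20000)
  expect_equal(shared_ind, 0)
})

test_that("markov pools carry a reproducible dinucleotide signature", {
  p <- make_genome_pool(2, c(50000, 50000), c(0.45, 0.55), seed = 13,
                        dinuc_bias = 0.4)
  prof1 <- dinuc_profile(p$genomes[1])
  prof2 <- dinuc_profile(p$genomes[2])
  expect_gt(max(abs(prof1$rho - 1)), 0.05)       # a real signature
  expect_lt(dist_dinuc(prof1, prof2), 0.05)      # shared within the pool
})

test_that("community specs validate and normalize abundances", {
  cs <- community_spec("s", c("g1", "g2", "g3"), abundance = "logarithmic",
                       decay = 0.5, n_reads = 10)
  expect_equal(cs$abundance, c(4, 2, 1) / 7)
  expect_equal(sum(community_spec("s", letters[1:5])$abundance), 1)
  expect_error(community_spec("s", character(0)), ">=1")
  expect_error(community_spec("s", "g", n_reads = 0), "positive")
  expect_error(community_spec("s", "g", noise_fraction = 1.5), "noise")
  expect_error(community_spec("s", c("g1", "g2"), abundance = c(1, 2, 3)),
               "length")
})

test_that("error-free reads are exact substrings at their recorded locus", {
  pool <- make_genome_pool(2, c(10000, 10000), c(0.4, 0.5), seed = 14)
  rs <- sample_reads(community_spec("s1", names(pool$genomes),
                                    n_reads = 50),
                     pool, seed = 15, error_rate = 0)
  for (i in seq_len(nrow(rs$reads))) {
    r <- rs$reads[i, ]
    ref <- substr(pool$genomes[[r$genome]], r$start,
                  r$start + r$length - 1)
    obs <- rs$sequences[[r$id]]
    if (r$strand == "-") {
      ref <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(ref)))
    }
    expect_identical(obs, ref)
  }
  expect_true(all(rs$reads$n_sub + rs$reads$n_ins + rs$reads$n_del == 0))
})

test_that("error and contamination rates match their binomial targets", {
  pool <- make_genome_pool(2, c(30000, 30000), c(0.4, 0.5), seed = 16)
  noise <- make_genome_pool(3, c(30000, 30000), c(0.45, 0.5), seed = 17,
                            prefix = "n")
  rs <- sample_reads(community_spec("s1", names(pool$genomes),
                                    n_reads = 10000, noise_fraction = 0.3),
                     pool, seed = 18, noise_pool = noise)
  events <- sum(rs$reads$n_sub + rs$reads$n_ins + rs$reads$n_del)
  rate <- events / sum(rs$reads$length)
  # nominal 2% inflated a little by homopolymer runs
  expect_gt(rate, 0.015); expect_lt(rate, 0.035)
  expect_gt(sum(rs$reads$n_sub) / events, 0.75)   # ~85% substitutions

  n_noise <- sum(startsWith(rs$reads$genome, "n"))
  expect_gte(n_noise, 2800); expect_lte(n_noise, 3200)
})

test_that("read lengths follow the truncated normal model", {
  pool <- make_genome_pool(1, c(50000, 50000), c(0.45, 0.5), seed = 19)
  rs <- sample_reads(community_spec("s1", names(pool$genomes),
                                    n_reads = 3000),
                     pool, seed = 20, error_rate = 0)
  expect_true(all(rs$reads$length >= 50))
  expect_equal(mean(rs$reads$length), 450, tolerance = 0.02)
  expect_equal(sd(rs$reads$length), 100, tolerance = 0.1)
})

test_that("toy assembler joins shared-genome samples and not disjoint ones", {
  pool <- make_genome_pool(1, c(15000, 15000), c(0.45, 0.5), seed = 21)
  rs <- lapply(1:2, function(s) {
    sample_reads(community_spec(paste0("s", s), names(pool$genomes),
                                n_reads = 200),
                 pool, seed = 21 + s, error_rate = 0)
  })
  asm <- toy_cross_assemble(rs)
  prof <- build_profile(readsets_inventory(rs), asm$membership)
  expect_gt(pairwise_counts(prof, "s1", "s2")$c_ij, 0)

  other <- make_genome_pool(1, c(15000, 15000), c(0.45, 0.5), seed = 30,
                            prefix = "z")
  rs2 <- list(rs[[1]],
              sample_reads(community_spec("s2", names(other$genomes),
                                          n_reads = 200),
                           other, seed = 31, error_rate = 0))
  asm2 <- toy_cross_assemble(rs2)
  prof2 <- build_profile(readsets_inventory(rs2), asm2$membership)
  expect_equal(pairwise_counts(prof2, "s1", "s2")$c_ij, 0L)
})

test_that("toy-assembly ground truth matches the membership exactly", {
  fx <- small_fixture(seed = 33, n_samples = 2, n_reads = 200)
  tr <- fx$asm$truth
  prof <- build_profile(fx$inventory, fx$asm$membership)
  counts <- tapply(tr$n_reads, list(tr$contig_id, tr$sample), sum,
                   default = 0L)
  expect_equal(unname(prof$R[rownames(counts), colnames(counts)]),
               unname(counts))
  expect_setequal(c(unlist(fx$asm$membership$reads_by_contig),
                    fx$asm$singletons),
                  unlist(lapply(fx$readsets, function(r) r$reads$id)))
})

test_that("assembler parameter validation", {
  fx <- small_fixture(seed = 34, n_samples = 2, n_reads = 30)
  expect_error(toy_cross_assemble(list()), "no read sets")
  expect_error(toy_cross_assemble(fx$readsets, k = 10), "k must")
  expect_error(toy_cross_assemble(fx$readsets, min_shared = 0),
               "min_shared")
})

test_that("overlap experiment: monotone overlap series with fixed endpoints", {
  fix <- experiment_overlap(n_steps = 5, species_per_sample = 3, seed = 35,
                            genome_length = 5000, n_reads_per_sample = 40)
  expect_length(fix$readsets, 5)
  expect_equal(fix$overlap, c(1, 2/3, 1/3, 0))
  expect_true(all(diff(fix$overlap) < 0))
  expect_error(experiment_overlap(n_steps = 8, species_per_sample = 3,
                                  seed = 1), "too many steps")
  # step 1 shares the reference's exact species set
  m0 <- fix$readsets[[1]]$spec$members
  m1 <- fix$readsets[[2]]$spec$members
  expect_setequal(m0, m1)
})

test_that("abundance experiment: identical within pairs, permuted across", {
  fix <- experiment_abundance(n_pairs = 3, n_species = 6, seed = 36,
                              genome_length = 5000,
                              n_reads_per_sample = 40)
  expect_length(fix$readsets, 6)
  for (p in 1:3) {
    a <- fix$readsets[[2 * p - 1]]$spec
    b <- fix$readsets[[2 * p]]$spec
    expect_identical(a$abundance, b$abundance)
    expect_identical(a$members, b$members)
  }
  ab1 <- sort(fix$readsets[[1]]$spec$abundance)
  for (p in 2:3) {
    expect_equal(sort(fix$readsets[[2 * p]]$spec$abundance), ab1,
                 tolerance = 1e-12)
    expect_false(identical(fix$readsets[[2 * p]]$spec$abundance,
                           fix$readsets[[1]]$spec$abundance))
  }
})

test_that("noise experiment: contamination endpoints are exact", {
  fix <- experiment_noise(noise_levels = c(0, 1), seed = 37,
                          species_per_sample = 2,
                          genome_length = 5000, contaminant_length = 5000,
                          n_reads_per_sample = 30)
  rs0 <- fix$readsets_by_level[[1]]
  expect_true(all(vapply(rs0, function(r) {
    !any(startsWith(r$reads$genome, "pro"))
  }, NA)))
  rs1 <- fix$readsets_by_level[[2]]
  expect_true(all(vapply(rs1, function(r) {
    all(startsWith(r$reads$genome, "pro"))
  }, NA)))
  expect_length(rs0, 9)
  expect_error(experiment_noise(noise_levels = c(0, 2), seed = 1),
               "noise_levels")
})

test_that("readsets convert to a sequence-bearing inventory", {
  fx <- small_fixture(seed = 38, n_samples = 2, n_reads = 25)
  inv <- fx$inventory
  expect_s3_class(inv, "read_inventory")
  expect_equal(lengths(inv$reads_by_sample), c(s1 = 25L, s2 = 25L))
  expect_false(any(vapply(inv$sequences_by_sample, is.null, NA)))
})
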