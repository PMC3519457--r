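#' Species-overlap experiment fixture
#'
#' Builds a series of simulated samples with decreasing species overlap
#' against a fixed reference.  The reference (step 0) and step 1 contain the
#' same low-GC community; from step 2 on, one additional member is replaced
#' by a genome from a separate high-GC pool, until (with the defaults: 10
#' species, 12 steps) the final step shares no species with the reference.
#' Each step is meant to be cross-assembled pairwise with step 0, mirroring
#' how a distance-versus-overlap response curve is measured.
#'
#' @param n_steps Total number of samples including the reference (>= 3; at
#'   most `species_per_sample + 2`).
#' @param species_per_sample Community size of every sample.
#' @param seed Integer seed (drives pools, replacement order and reads).
#' @param genome_length Genome length in nt (all genomes equal length).
#' @param n_reads_per_sample Reads drawn per sample.
#' @param error_rate Per-base sequencing error rate.
#' @return An object of class `overlap_experiment`: list with `readsets`
#'   (named, `ov00` first), `overlap` (true species-overlap fraction of each
#'   non-reference step with the reference) and the pools/parameters.
#' @export
experiment_overlap <- function(n_steps = 12, species_per_sample = 10,
                               seed = 1, genome_length = 20000,
                               n_reads_per_sample = 2000,
                               error_rate = 0.02) {
  if (n_steps < 3) stop("n_steps must be >= 3")
  if (n_steps - 2 > species_per_sample) {
    stop("too many steps: can replace at most species_per_sample = ",
         species_per_sample, " members (need n_steps <= ",
         species_per_sample + 2, ")")
  }
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_steps + 3L)
  pool_lo <- make_genome_pool(species_per_sample,
                              c(genome_length, genome_length),
                              gc_range = c(0.28, 0.38), seed = seeds[1],
                              dinuc_bias = 0.4, prefix = "fir")
  pool_hi <- make_genome_pool(species_per_sample,
                              c(genome_length, genome_length),
                              gc_range = c(0.58, 0.68), seed = seeds[2],
                              dinuc_bias = 0.4, prefix = "pro")
  set.seed(seeds[3])
  replace_order <- sample.int(species_per_sample)

  labels <- sprintf("ov%02d", seq_len(n_steps) - 1L)
  readsets <- vector("list", n_steps)
  overlap <- numeric(n_steps - 1L)
  for (t in seq_len(n_steps)) {
    replaced <- max(0L, t - 2L)
    members <- names(pool_lo$genomes)
    swap <- replace_order[seq_len(replaced)]
    members[swap] <- names(pool_hi$genomes)[swap]
    spec <- community_spec(labels[t], members, abundance = "uniform",
                           n_reads = n_reads_per_sample)
    # both pools supply genomes; pass the union as the sampling pool
    joint <- structure(list(genomes = c(pool_lo$genomes, pool_hi$genomes)),
                       class = "genome_pool")
    readsets[[t]] <- sample_reads(spec, joint, seed = seeds[3L + t],
                                  error_rate = error_rate)
    if (t >= 2L) {
      overlap[t - 1L] <- (species_per_sample - replaced) / species_per_sample
    }
  }
  names(readsets) <- labels
  structure(list(readsets = readsets, overlap = overlap,
                 pool_low_gc = pool_lo, pool_high_gc = pool_hi,
                 params = list(n_steps = n_steps,
                               species_per_sample = species_per_sample,
                               seed = seed, genome_length = genome_length,
                               n_reads_per_sample = n_reads_per_sample,
                               error_rate = error_rate)),
            class = "overlap_experiment")
}

#' Run the overlap experiment: pairwise cross-assembly with the reference
#'
#' Cross-assembles every step with the reference sample, builds the profile
#' and evaluates all four cross-assembly distances plus the dinucleotide
#' baseline for each pair.
#'
#' @param fix An `overlap_experiment` fixture.
#' @param k,min_shared Toy-assembler parameters (see
#'   [toy_cross_assemble()]).
#' @return Data frame with one row per non-reference step: `step`,
#'   `overlap`, and columns `shot`, `minimum`, `wootters`, `reads`, `dinuc`.
#' @export
run_overlap_experiment <- function(fix, k = 21, min_shared = 2) {
  stopifnot(inherits(fix, "overlap_experiment"))
  ref <- fix$readsets[[1]]
  steps <- seq_along(fix$readsets)[-1]
  out <- data.frame(step = steps - 1L, overlap = fix$overlap,
                    shot = NA_real_, minimum = NA_real_,
                    wootters = NA_real_, reads = NA_real_,
                    dinuc = NA_real_)
  for (r in seq_along(steps)) {
    rs <- fix$readsets[[steps[r]]]
    asm <- toy_cross_assemble(list(ref, rs), k = k, min_shared = min_shared)
    inv <- readsets_inventory(list(ref, rs))
    prof <- build_profile(inv, asm$membership)
    for (f in c("shot", "minimum", "wootters", "reads")) {
      out[[f]][r] <- distance_matrix(prof, f)[1, 2]
    }
    out$dinuc[r] <- dinuc_distance_matrix(inv)[1, 2]
  }
  out
}

#' Abundance-permutation experiment fixture
#'
#' Generates pairs of samples over a single shared species set with
#' logarithmically decaying abundances: the two members of a pair use the
#' identical species-to-abundance assignment (but independent reads), while
#' different pairs use different random permutations of the same abundance
#' profile.  A correct method should recover each pair as sisters in the
#' cladogram of the joint cross-assembly.
#'
#' @param n_pairs Number of sample pairs (>= 2).
#' @param n_species Shared community size.
#' @param seed Integer seed.
#' @param genome_length Genome length in nt.
#' @param n_reads_per_sample Reads per sample (kept low so per-sample genome
#'   coverage spans sparse to moderate and assemblies fragment, which is
#'   what gives the presence/absence formulas their signal).
#' @param decay Rank-decay of the logarithmic abundance profile.
#' @param error_rate Per-base sequencing error rate.
#' @return An object of class `abundance_experiment`: list with `readsets`
#'   (labels `ab01`, `ab02`, ...), `pairs` (list of label pairs),
#'   `permutations`, the pool and parameters.
#' @export
experiment_abundance <- function(n_pairs = 4, n_species = 10, seed = 1,
                                 genome_length = 400000,
                                 n_reads_per_sample = 1500, decay = 0.65,
                                 error_rate = 0.02) {
  if (n_pairs < 2) stop("n_pairs must be >= 2")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 2L * n_pairs + 2L)
  # narrow GC band keeps the genomes exchangeable: strongly AT-rich genomes
  # carry many homopolymer runs, whose inflated error rate makes them
  # assemble systematically worse than the rest of the pool
  pool <- make_genome_pool(n_species, c(genome_length, genome_length),
                           gc_range = c(0.38, 0.48), seed = seeds[1],
                           prefix = "fir")
  base <- decay^(seq_len(n_species) - 1)
  base <- base / sum(base)
  # pairs get deliberately distinct, jointly balanced abundance
  # assignments: a greedy balanced design keeps every genome's total
  # abundance across all samples (and hence its joint coverage and contig
  # granularity) nearly equal, while no two pairs concentrate their mass on
  # the same genomes.  Randomly drawn permutations can collide in the top
  # ranks and skew joint coverage, which nests sparse samples inside dense
  # ones and corrupts the presence/absence distances.
  perms <- balanced_rank_assignments(base, n_pairs)

  labels <- sprintf("ab%02d", seq_len(2L * n_pairs))
  readsets <- vector("list", 2L * n_pairs)
  pairs <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    ab <- base[perms[[p]]]   # abundance assigned to members in pool order
    for (m in 1:2) {
      s <- 2L * (p - 1L) + m
      spec <- community_spec(labels[s], names(pool$genomes), abundance = ab,
                             n_reads = n_reads_per_sample)
      readsets[[s]] <- sample_reads(spec, pool, seed = seeds[2L + s],
                                    error_rate = error_rate)
    }
    pairs[[p]] <- labels[c(2L * p - 1L, 2L * p)]
  }
  names(readsets) <- labels
  structure(list(readsets = readsets, pairs = pairs, permutations = perms,
                 pool = pool,
                 params = list(n_pairs = n_pairs, n_species = n_species,
                               seed = seed, genome_length = genome_length,
                               n_reads_per_sample = n_reads_per_sample,
                               decay = decay, error_rate = error_rate)),
            class = "abundance_experiment")
}

# one rank assignment (permutation of 1..n ranks over genomes) per pair,
# chosen by longest-processing-time greedy so the per-genome abundance
# totals across pairs are nearly equal; deterministic
balanced_rank_assignments <- function(abund, n_pairs) {
  n <- length(abund)
  sig <- matrix(0L, n_pairs, n)
  partial <- rep(0, n)
  items <- expand.grid(p = seq_len(n_pairs), r = seq_len(n))
  items <- items[order(abund[items$r], decreasing = TRUE), ]
  for (it in seq_len(nrow(items))) {
    p <- items$p[it]; r <- items$r[it]
    cand <- which(sig[p, ] == 0L)
    g <- cand[which.min(partial[cand])]
    sig[p, g] <- r
    partial[g] <- partial[g] + abund[r]
  }
  lapply(seq_len(n_pairs), function(p) sig[p, ])
}

#' Run the abundance experiment: joint cross-assembly and sister recovery
#'
#' Cross-assembles all samples together, computes the distance matrix for
#' each requested formula, builds the BioNJ cladogram and checks which true
#' pairs appear as sisters (i.e. an internal edge induces the bipartition
#' pair-versus-rest).
#'
#' @param fix An `abundance_experiment` fixture.
#' @param formulas Distance formulas to evaluate.
#' @param k,min_shared Toy-assembler parameters.
#' @return List with `sisters` (logical matrix, formula x pair), `trees`,
#'   `distances` and the `profile`.
#' @export
run_abundance_experiment <- function(fix,
                                     formulas = c("shot", "minimum",
                                                  "wootters", "reads"),
                                     k = 21, min_shared = 2) {
  stopifnot(inherits(fix, "abundance_experiment"))
  asm <- toy_cross_assemble(fix$readsets, k = k, min_shared = min_shared)
  inv <- readsets_inventory(fix$readsets)
  prof <- build_profile(inv, asm$membership)
  labels <- inv$samples
  trees <- distances <- list()
  sisters <- matrix(NA, length(formulas), length(fix$pairs),
                    dimnames = list(formulas,
                                    vapply(fix$pairs, paste, "",
                                           collapse = "+")))
  for (f in formulas) {
    D <- distance_matrix(prof, f)
    tr <- bionj_tree(D)
    distances[[f]] <- D
    trees[[f]] <- tr
    for (p in seq_along(fix$pairs)) {
      pair <- fix$pairs[[p]]
      len <- internal_branch_length(tr, list(pair, setdiff(labels, pair)))
      sisters[f, p] <- !is.na(len)
    }
  }
  list(sisters = sisters, trees = trees, distances = distances,
       profile = prof)
}

#' Noise-contamination experiment fixture
#'
#' Two groups of samples -- three drawn from a high-GC pool and six from a
#' low-GC pool, every sample containing *different* species of its pool --
#' are contaminated with an increasing fraction of reads from a shared
#' third contaminant pool.  Within-group relatedness comes from pool-level
#' homology (genomes of one pool diverge from a common ancestor), so the
#' cross-assembly can link different species of the same group.  As the
#' contamination fraction grows, the internal branch separating the two
#' groups in the cladogram shrinks and eventually disappears.
#'
#' @param noise_levels Contamination fractions in \[0, 1\].
#' @param seed Integer seed.
#' @param species_per_sample Species per sample.
#' @param n_group_a,n_group_b Samples in the high-GC and low-GC groups.
#' @param genome_length Length of each pool's ancestor (and hence of every
#'   pool member) in nt.  Sized so each sample covers its pool's sequence
#'   space sparsely (~0.3x) while the group jointly reaches ~1-2x: the
#'   fragmented-assembly regime in which presence/absence signals carry
#'   information.
#' @param contaminant_length,n_contaminant Size and number of the
#'   independent contaminant genomes shared by all samples.
#' @param n_reads_per_sample Reads per sample.
#' @param divergence Within-pool per-site divergence from the pool ancestor.
#' @param error_rate Per-base sequencing error rate.
#' @return An object of class `noise_experiment`: list with
#'   `readsets_by_level` (one list of 9 read sets per level), `group_a` and
#'   `group_b` (sample labels), pools and parameters.
#' @export
experiment_noise <- function(noise_levels = c(0, 0.25, 0.5, 0.75, 1),
                             seed = 1, species_per_sample = 4,
                             n_group_a = 3, n_group_b = 6,
                             genome_length = 800000,
                             contaminant_length = 100000,
                             n_contaminant = 10,
                             n_reads_per_sample = 700,
                             divergence = 0.02, error_rate = 0.02) {
  if (any(noise_levels < 0 | noise_levels > 1)) {
    stop("noise_levels must lie in [0, 1]")
  }
  n_samples <- n_group_a + n_group_b
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max,
                      3L + length(noise_levels) * n_samples)
  pool_a <- make_genome_pool(n_group_a * species_per_sample,
                             c(genome_length, genome_length),
                             gc_range = c(0.58, 0.68), seed = seeds[1],
                             divergence = divergence, dinuc_bias = 0.4,
                             prefix = "act")
  pool_b <- make_genome_pool(n_group_b * species_per_sample,
                             c(genome_length, genome_length),
                             gc_range = c(0.28, 0.38), seed = seeds[2],
                             divergence = divergence, dinuc_bias = 0.4,
                             prefix = "fir")
  pool_c <- make_genome_pool(n_contaminant,
                             c(contaminant_length, contaminant_length),
                             gc_range = c(0.44, 0.52), seed = seeds[3],
                             dinuc_bias = 0.4, prefix = "pro")
  group_a <- sprintf("act%d", seq_len(n_group_a))
  group_b <- sprintf("fir%d", seq_len(n_group_b))
  labels <- c(group_a, group_b)
  members_of <- c(
    lapply(seq_len(n_group_a), function(s) {
      names(pool_a$genomes)[(s - 1L) * species_per_sample +
                              seq_len(species_per_sample)]
    }),
    lapply(seq_len(n_group_b), function(s) {
      names(pool_b$genomes)[(s - 1L) * species_per_sample +
                              seq_len(species_per_sample)]
    }))
  pool_of <- c(rep(list(pool_a), n_group_a), rep(list(pool_b), n_group_b))

  readsets_by_level <- vector("list", length(noise_levels))
  si <- 3L
  for (l in seq_along(noise_levels)) {
    rs <- vector("list", n_samples)
    for (s in seq_len(n_samples)) {
      si <- si + 1L
      spec <- community_spec(labels[s], members_of[[s]],
                             abundance = "uniform",
                             n_reads = n_reads_per_sample,
                             noise_fraction = noise_levels[l])
      rs[[s]] <- sample_reads(spec, pool_of[[s]], seed = seeds[si],
                              noise_pool = pool_c, error_rate = error_rate)
    }
    names(rs) <- labels
    readsets_by_level[[l]] <- rs
  }
  names(readsets_by_level) <- sprintf("noise%03.0f", 100 * noise_levels)
  structure(list(readsets_by_level = readsets_by_level,
                 noise_levels = noise_levels,
                 group_a = group_a, group_b = group_b,
                 pool_a = pool_a, pool_b = pool_b, pool_c = pool_c,
                 params = list(seed = seed,
                               species_per_sample = species_per_sample,
                               genome_length = genome_length,
                               n_reads_per_sample = n_reads_per_sample,
                               divergence = divergence,
                               error_rate = error_rate)),
            class = "noise_experiment")
}

#' Run the noise experiment: separating-branch length versus contamination
#'
#' For every noise level, cross-assembles the nine samples jointly, builds
#' the distance matrix and BioNJ cladogram per formula, and measures the
#' length of the internal branch inducing the group-A-versus-group-B
#' bipartition (`NA` when the cladogram no longer separates the groups).
#'
#' @param fix A `noise_experiment` fixture.
#' @param formulas Distance formulas to evaluate.
#' @param k,min_shared Toy-assembler parameters.
#' @return Data frame with columns `noise`, `formula`, `branch_length`.
#' @export
run_noise_experiment <- function(fix,
                                 formulas = c("shot", "minimum",
                                              "wootters", "reads"),
                                 k = 21, min_shared = 2) {
  stopifnot(inherits(fix, "noise_experiment"))
  out <- expand.grid(noise = fix$noise_levels, formula = formulas,
                     stringsAsFactors = FALSE)
  out$branch_length <- NA_real_
  part <- list(fix$group_a, fix$group_b)
  for (l in seq_along(fix$noise_levels)) {
    rs <- fix$readsets_by_level[[l]]
    asm <- toy_cross_assemble(rs, k = k, min_shared = min_shared)
    inv <- readsets_inventory(rs)
    prof <- build_profile(inv, asm$membership)
    for (f in formulas) {
      tr <- bionj_tree(distance_matrix(prof, f))
      len <- internal_branch_length(tr, part)
      out$branch_length[out$noise == fix$noise_levels[l] &
                          out$formula == f] <- len
    }
  }
  out
}
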