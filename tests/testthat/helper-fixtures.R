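# fixture builders shared across test files; everything is generated in code

# cross_profile straight from a count matrix (contigs x samples)
profile_from_matrix <- function(R, singletons = NULL) {
  samples <- colnames(R)
  if (is.null(singletons)) {
    singletons <- stats::setNames(rep(list(character(0)), length(samples)),
                                  samples)
  }
  structure(list(samples = samples, contig_ids = rownames(R),
                 R = R, singletons = singletons),
            class = "cross_profile")
}

rand_profile <- function(n_contigs, n_samples, seed,
                         lambda = 1.2, min_reads = 1) {
  set.seed(seed)
  repeat {
    R <- matrix(rpois(n_contigs * n_samples, lambda), n_contigs, n_samples)
    R <- R[rowSums(R) >= min_reads, , drop = FALSE]
    if (nrow(R) >= 2 && all(colSums(R) > 0)) break
  }
  dimnames(R) <- list(sprintf("c%03d", seq_len(nrow(R))),
                      sprintf("s%d", seq_len(n_samples)))
  profile_from_matrix(R)
}

# pairwise_counts object from raw numbers (documented plain-list structure)
pc_from_counts <- function(c_i, c_j, c_ij, r_i = 10 * c_i, r_j = 10 * c_j,
                           r_ij = c_ij, r_ji = c_ij) {
  structure(list(i = "i", j = "j", c_i = c_i, c_j = c_j, c_ij = c_ij,
                 r_i = r_i, r_j = r_j, r_ij = r_ij, r_ji = r_ji),
            class = "pairwise_counts")
}

rand_pc <- function() {
  c_i <- sample(1:500, 1); c_j <- sample(1:500, 1)
  c_ij <- sample(0:min(c_i, c_j), 1)
  r_i <- c_i + sample(0:2000, 1); r_j <- c_j + sample(0:2000, 1)
  r_ij <- if (c_ij == 0) 0 else sample(c_ij:r_i, 1)
  r_ji <- if (c_ij == 0) 0 else sample(c_ij:r_j, 1)
  pc_from_counts(c_i, c_j, c_ij, r_i, r_j, r_ij, r_ji)
}

rand_prob_vec <- function(n) {
  x <- rexp(n)
  x / sum(x)
}

write_tmp_fasta <- function(records, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

write_tmp_fastq <- function(records, path = tempfile(fileext = ".fastq")) {
  writeLines(unlist(lapply(names(records), function(id) {
    s <- records[[id]]
    c(paste0("@", id), s, "+", strrep("I", nchar(s)))
  })), path)
  path
}

# a small end-to-end synthetic fixture: pool, reads, toy assembly
small_fixture <- function(seed = 5, n_samples = 3, n_reads = 300,
                          n_genomes = 4, genome_length = 20000) {
  pool <- make_genome_pool(n_genomes, c(genome_length, genome_length),
                           c(0.4, 0.5), seed = seed)
  rs <- lapply(seq_len(n_samples), function(s) {
    sample_reads(community_spec(paste0("s", s), names(pool$genomes),
                                n_reads = n_reads),
                 pool, seed = seed + s)
  })
  asm <- toy_cross_assemble(rs)
  list(pool = pool, readsets = rs, asm = asm,
       inventory = readsets_inventory(rs))
}
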