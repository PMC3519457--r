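#' Generate a pool of synthetic genomes
#'
#' Creates desk-scale genomes (default tens of kilobases) with controlled GC
#' content, standing in for the genome pools a community simulation draws
#' from.  Two usage modes:
#'
#' * `divergence = NULL` (default): each genome is an independent iid
#'   sequence with its own GC content drawn from `gc_range`.  Genomes share
#'   no k-mers beyond chance, so two pools with disjoint GC ranges mimic
#'   phyla that are distinguishable both by signature (GC / dinucleotides)
#'   and by sequence content (e.g. high-GC vs low-GC gram-positives).
#' * `divergence = x` in (0, 1): all genomes of the pool are derived from a
#'   single ancestor by per-site random substitution at rate `x`.  Members
#'   of such a pool share exact k-mers in proportion to `(1-x)^(2k)` -- this
#'   emulates within-phylum homology, which is what lets a cross-assembly
#'   link *different* species of the same clade.
#'
#' @param n_genomes Number of genomes (>= 1).
#' @param length_range Integer interval of genome lengths in nt (>= 1000).
#' @param gc_range Interval of GC content in (0, 1).
#' @param seed Integer seed; generation is bit-reproducible given
#'   `(seed, parameters)`.
#' @param divergence Per-site substitution rate from a common pool ancestor,
#'   or `NULL` for independent genomes.
#' @param dinuc_bias Standard deviation of a pool-wide log-scale
#'   perturbation of the dinucleotide transition probabilities.  With the
#'   default 0 genomes are iid and carry no dinucleotide signature
#'   (`rho* ~ 1` everywhere); with a positive value the pool's genomes are
#'   first-order Markov chains sharing one random signature, emulating the
#'   clade-specific dinucleotide biases of real genomes that the
#'   odds-ratio baseline distance detects.
#' @param prefix Genome identifier prefix.
#' @return An object of class `genome_pool`: list with `genomes` (named
#'   character vector), `gc` (realized GC per genome) and the generating
#'   parameters.
#' @export
make_genome_pool <- function(n_genomes, length_range = c(20000, 100000),
                             gc_range = c(0.3, 0.7), seed = 1,
                             divergence = NULL, dinuc_bias = 0,
                             prefix = "g") {
  if (n_genomes < 1) stop("n_genomes must be >= 1")
  if (length(length_range) != 2 || any(length_range < 1000) ||
      length_range[1] > length_range[2]) {
    stop("invalid length_range (need lo <= hi, both >= 1000 nt)")
  }
  if (length(gc_range) != 2 || any(gc_range <= 0) || any(gc_range >= 1) ||
      gc_range[1] > gc_range[2]) {
    stop("invalid gc_range (need 0 < lo <= hi < 1)")
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  gc_probs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  ids <- sprintf("%s%02d", prefix, seq_len(n_genomes))

  # one dinucleotide signature per pool: log-scale perturbation of the
  # transition probabilities away from the iid (signature-free) chain
  bias <- if (dinuc_bias > 0) {
    matrix(exp(stats::rnorm(16L, 0, dinuc_bias)), 4L, 4L,
           dimnames = list(bases, bases))
  } else NULL
  draw_seq <- function(len, gc) {
    p0 <- gc_probs(gc)
    if (is.null(bias)) {
      sample(bases, len, replace = TRUE, prob = p0)
    } else {
      trans <- sweep(bias, 2L, p0, "*")
      trans <- trans / rowSums(trans)
      markov_chars(len, p0, trans)
    }
  }

  # seq() not 1:hi -- and guard the scalar case, where sample(x, n) would
  # sample from 1:x instead of from x itself
  draw_lens <- function(k) {
    if (length_range[1] == length_range[2]) rep(length_range[1], k)
    else sample(seq(length_range[1], length_range[2]), k, replace = TRUE)
  }
  if (is.null(divergence)) {
    lens <- draw_lens(n_genomes)
    gc <- stats::runif(n_genomes, gc_range[1], gc_range[2])
    genomes <- vapply(seq_len(n_genomes), function(g) {
      paste(draw_seq(lens[g], gc[g]), collapse = "")
    }, "")
  } else {
    if (divergence <= 0 || divergence >= 1) stop("divergence must be in (0,1)")
    len <- draw_lens(1L)
    gc <- stats::runif(1L, gc_range[1], gc_range[2])
    anc <- draw_seq(len, gc)
    genomes <- vapply(seq_len(n_genomes), function(g) {
      x <- anc
      hit <- which(stats::runif(len) < divergence)
      if (length(hit)) {
        x[hit] <- sample(bases, length(hit), replace = TRUE,
                         prob = gc_probs(gc))
      }
      paste(x, collapse = "")
    }, "")
    lens <- rep(len, n_genomes)
    gc <- rep(gc, n_genomes)
  }
  names(genomes) <- ids
  realized_gc <- vapply(genomes, function(s) {
    b <- Biostrings::letterFrequency(Biostrings::DNAString(s), c("G", "C"))
    sum(b) / nchar(s)
  }, 0)
  structure(list(genomes = genomes, gc = realized_gc, lengths = lens,
                 seed = seed, divergence = divergence,
                 dinuc_bias = dinuc_bias),
            class = "genome_pool")
}

# first-order Markov sequence: initial distribution p0, transition matrix
# trans (rows = current base); returns a character vector of bases
markov_chars <- function(len, p0, trans) {
  bases <- colnames(trans)
  cum <- t(apply(trans, 1L, cumsum))
  x <- integer(len)
  u <- stats::runif(len)
  x[1L] <- sample.int(4L, 1L, prob = p0)
  for (i in 2:len) {
    x[i] <- findInterval(u[i], cum[x[i - 1L], ]) + 1L
  }
  bases[x]
}

#' Describe a simulated community
#'
#' Fixes the composition of one simulated metagenome: which genomes it
#' contains, their relative abundances, how many reads to draw, and what
#' fraction of the reads is contamination from a separate genome pool.
#'
#' @param label Sample label.
#' @param members Genome identifiers from a [make_genome_pool()] pool.
#' @param abundance `"uniform"`, `"logarithmic"` (geometric rank-decay:
#'   abundance of rank `r` proportional to `decay^(r-1)`), or an explicit
#'   numeric vector of relative abundances (one per member).
#' @param decay Rank-decay parameter for the logarithmic model; the default
#'   0.5 halves the abundance per rank.
#' @param n_reads Number of reads to draw (> 0).
#' @param noise_fraction Proportion of reads drawn uniformly from a
#'   contaminant pool instead of the community members, in \[0, 1\].
#' @return A `community_spec` object.
#' @export
community_spec <- function(label, members, abundance = "uniform",
                           decay = 0.5, n_reads = 1000,
                           noise_fraction = 0) {
  m <- length(members)
  if (m < 1) stop("community needs >=1 member genome")
  if (n_reads <= 0) stop("n_reads must be positive")
  if (noise_fraction < 0 || noise_fraction > 1) {
    stop("noise_fraction must lie in [0, 1]")
  }
  ab <- if (is.numeric(abundance)) {
    if (length(abundance) != m) stop("abundance length must match members")
    if (any(abundance <= 0)) stop("abundances must be positive")
    abundance / sum(abundance)
  } else {
    switch(match.arg(abundance, c("uniform", "logarithmic")),
           uniform = rep(1 / m, m),
           logarithmic = {
             w <- decay^(seq_len(m) - 1)
             w / sum(w)
           })
  }
  structure(list(label = label, members = members, abundance = ab,
                 n_reads = as.integer(n_reads),
                 noise_fraction = noise_fraction),
            class = "community_spec")
}

#' Draw pyrosequencing-like reads from a community
#'
#' Samples reads with the error structure of 454-style pyrosequencing:
#' read lengths normal with mean 450 and sd 100 nt (truncated below at
#' `min_length` and above at the genome length), uniform start positions and
#' strands, and a 2% per-base error rate split 85% substitutions / 15%
#' indels.  Within homopolymer runs of 3 nt or more the error probability is
#' inflated by a multiplicative factor, a deliberately simple stand-in for
#' flowgram-resolution homopolymer error models.  Every read records its
#' true genome of origin, position, strand and error counts, so downstream
#' assertions can be exact.
#'
#' @param spec A [community_spec()].
#' @param pool The [make_genome_pool()] pool holding the member genomes.
#' @param seed Integer seed.
#' @param noise_pool Pool supplying contaminant reads; required when
#'   `spec$noise_fraction > 0`.  Contaminant genomes are sampled uniformly.
#' @param read_length_mean,read_length_sd,min_length Read-length model (nt).
#' @param error_rate Per-base error probability.
#' @param sub_fraction Fraction of errors that are substitutions; the rest
#'   are indels (insertions and deletions in equal parts).
#' @param homopolymer_factor Error-rate multiplier inside homopolymer runs
#'   of length >= 3.
#' @return An object of class `simulated_readset`: list with `label`,
#'   `reads` (data frame: id, genome, start, strand, length, n_sub, n_ins,
#'   n_del) and `sequences` (named character vector).
#' @export
sample_reads <- function(spec, pool, seed = 1, noise_pool = NULL,
                         read_length_mean = 450, read_length_sd = 100,
                         min_length = 50, error_rate = 0.02,
                         sub_fraction = 0.85, homopolymer_factor = 3) {
  stopifnot(inherits(spec, "community_spec"), inherits(pool, "genome_pool"))
  if (spec$noise_fraction > 0 && is.null(noise_pool)) {
    stop("noise_fraction > 0 requires a noise_pool")
  }
  missing_members <- setdiff(spec$members, names(pool$genomes))
  if (length(missing_members)) {
    stop("community members absent from pool: ",
         paste(missing_members, collapse = ", "))
  }
  set.seed(seed)
  n <- spec$n_reads
  n_noise <- if (spec$noise_fraction > 0) {
    stats::rbinom(1L, n, spec$noise_fraction)
  } else 0L
  src_signal <- if (n - n_noise > 0) {
    spec$members[sample.int(length(spec$members), n - n_noise,
                            replace = TRUE, prob = spec$abundance)]
  } else character(0)
  src_noise <- if (n_noise > 0) {
    ids <- names(noise_pool$genomes)
    ids[sample.int(length(ids), n_noise, replace = TRUE)]
  } else character(0)
  src <- c(src_signal, src_noise)[sample.int(n)]

  genomes <- c(pool$genomes,
               if (!is.null(noise_pool)) noise_pool$genomes)
  gseq <- genomes[src]
  glen <- nchar(gseq)

  len <- round(stats::rnorm(n, read_length_mean, read_length_sd))
  for (it in 1:100) {
    bad <- len < min_length | len > glen
    if (!any(bad)) break
    len[bad] <- round(stats::rnorm(sum(bad), read_length_mean,
                                   read_length_sd))
  }
  len <- pmin(pmax(len, min_length), glen)

  start <- floor(stats::runif(n) * (glen - len + 1)) + 1
  seqs <- substr(gseq, start, start + len - 1L)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  minus <- strand == "-"
  if (any(minus)) {
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))
  }

  n_sub <- n_ins <- n_del <- integer(n)
  if (error_rate > 0) {
    for (i in seq_len(n)) {
      e <- apply_read_errors(seqs[i], error_rate, sub_fraction,
                             homopolymer_factor)
      seqs[i] <- e$seq
      n_sub[i] <- e$n_sub; n_ins[i] <- e$n_ins; n_del[i] <- e$n_del
    }
  }
  ids <- sprintf("%s_r%05d", spec$label, seq_len(n))
  names(seqs) <- ids
  reads <- data.frame(id = ids, genome = src, start = start,
                      strand = strand, length = len,
                      n_sub = n_sub, n_ins = n_ins, n_del = n_del,
                      stringsAsFactors = FALSE)
  structure(list(label = spec$label, reads = reads, sequences = seqs,
                 spec = spec),
            class = "simulated_readset")
}

# substitution/indel error process on one read; homopolymer runs >= 3 nt get
# an inflated per-base rate
apply_read_errors <- function(s, rate, sub_fraction, homopolymer_factor) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (L == 0L) return(list(seq = s, n_sub = 0L, n_ins = 0L, n_del = 0L))
  runs <- rle(chars)
  in_run <- rep(runs$lengths >= 3L, runs$lengths)
  prate <- ifelse(in_run, pmin(rate * homopolymer_factor, 1), rate)
  hit <- which(stats::runif(L) < prate)
  if (!length(hit)) return(list(seq = s, n_sub = 0L, n_ins = 0L, n_del = 0L))
  bases <- c("A", "C", "G", "T")
  is_sub <- stats::runif(length(hit)) < sub_fraction
  is_del <- !is_sub & stats::runif(length(hit)) < 0.5
  is_ins <- !is_sub & !is_del
  sub_pos <- hit[is_sub]
  if (length(sub_pos)) {
    chars[sub_pos] <- vapply(chars[sub_pos], function(b) {
      sample(setdiff(bases, b), 1L)
    }, "", USE.NAMES = FALSE)
  }
  if (any(is_del) || any(is_ins)) {
    out <- as.list(chars)
    for (p in hit[is_del]) out[[p]] <- character(0)
    for (p in hit[is_ins]) out[[p]] <- c(chars[p], sample(bases, 1L))
    chars <- unlist(out, use.names = FALSE)
  }
  list(seq = paste(chars, collapse = ""),
       n_sub = sum(is_sub), n_ins = sum(is_ins), n_del = sum(is_del))
}

#' Toy cross-assembler: single-linkage clustering over shared k-mers
#'
#' Clusters the pooled reads of several samples by single linkage: two reads
#' are linked when they share at least `min_shared` exact canonical k-mers
#' (a k-mer and its reverse complement are the same word).  Each multi-read
#' cluster becomes a contig; unclustered reads are the singletons.  The
#' default `min_shared = 2` is deliberately conservative: a single chance
#' k-mer collision between unrelated genomic positions would otherwise
#' merge two whole coverage islands into one chimeric contig, whereas two
#' independent collisions between the same read pair are vanishingly
#' unlikely.  The true genome-of-origin composition of every contig is
#' returned alongside, so every downstream count can be checked exactly.
#'
#' This is deliberately not a sequence assembler: no consensus, no layout.
#' It reproduces only the property the accounting needs -- reads from the
#' same or homologous genome regions end up in the same contig.
#'
#' @param readsets List of `simulated_readset` objects (>= 1, with
#'   sequences).
#' @param k K-mer word size, in \[15, 31\].
#' @param min_shared Minimum number of distinct shared canonical k-mers for
#'   a link (>= 1).
#' @return An object of class `toy_assembly`: list with `membership` (a
#'   `contig_membership` as from [parse_ace()]), `truth` (data frame:
#'   contig_id, genome, sample, n_reads -- the exact provenance
#'   composition), `singletons` (read ids in no contig) and the parameters.
#' @export
toy_cross_assemble <- function(readsets, k = 21, min_shared = 2) {
  if (!length(readsets)) stop("no read sets supplied")
  if (k < 15 || k > 31) stop("k must lie in [15, 31]")
  if (min_shared < 1) stop("min_shared must be >= 1")
  ids <- unlist(lapply(readsets, function(rs) rs$reads$id), use.names = FALSE)
  seqs <- unlist(lapply(readsets, function(rs) unname(rs$sequences)),
                 use.names = FALSE)
  sample_of <- rep(vapply(readsets, `[[`, "", "label"),
                   vapply(readsets, function(rs) nrow(rs$reads), 0L))
  genome_of <- unlist(lapply(readsets, function(rs) rs$reads$genome),
                      use.names = FALSE)
  n <- length(ids)
  if (anyDuplicated(ids)) stop("read identifiers are not globally unique")

  lens <- nchar(seqs)
  usable <- which(lens >= k)
  kml <- vector("list", length(usable))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs[usable])))
  for (u in seq_along(usable)) {
    i <- usable[u]
    m <- lens[i] - k + 1L
    kf <- substring(seqs[i], 1:m, k:lens[i])
    kr <- substring(rc[u], 1:m, k:lens[i])
    kml[[u]] <- unique(pmin(kf, rev(kr)))
  }
  dt <- data.table::data.table(
    read = rep(usable, lengths(kml)),
    kmer = unlist(kml, use.names = FALSE))
  # k-mers seen in a single read can never link anything
  dt <- dt[, if (.N >= 2L) .SD, by = "kmer"]

  edges <- if (nrow(dt) == 0L) {
    data.table::data.table(a = integer(0), b = integer(0))
  } else if (min_shared == 1L) {
    # connectivity only: chain each k-mer's reads
    ed <- dt[, list(a = rep(read[1L], .N - 1L), b = read[-1L]), by = "kmer"]
    ed[, c("a", "b") := list(pmin(a, b), pmax(a, b))]
    unique(ed[, list(a, b)])
  } else {
    pairs <- dt[dt, on = "kmer", allow.cartesian = TRUE][read < i.read]
    pairs <- pairs[, list(nsh = .N), by = list(a = read, b = i.read)]
    pairs[nsh >= min_shared, list(a, b)]
  }

  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(n))))
  comp <- igraph::components(g)$membership[as.character(seq_len(n))]

  tab <- table(comp)
  multi <- as.integer(names(tab)[tab >= 2L])
  # deterministic contig order: by first (smallest-index) member read
  first_read <- vapply(multi, function(cl) min(which(comp == cl)), 0L)
  multi <- multi[order(first_read)]
  contig_ids <- sprintf("contig%05d", seq_along(multi))

  members <- lapply(multi, function(cl) ids[comp == cl])
  names(members) <- contig_ids
  membership <- structure(
    list(contig_ids = contig_ids, reads_by_contig = members,
         declared_counts = stats::setNames(lengths(members), contig_ids)),
    class = "contig_membership")

  truth <- if (length(multi)) {
    idx <- which(comp %in% multi)
    agg <- stats::aggregate(
      list(n_reads = idx),
      by = list(contig_id = contig_ids[match(comp[idx], multi)],
                genome = genome_of[idx], sample = sample_of[idx]),
      FUN = length)
    agg[order(agg$contig_id, agg$genome, agg$sample), , drop = FALSE]
  } else {
    data.frame(contig_id = character(0), genome = character(0),
               sample = character(0), n_reads = integer(0))
  }
  rownames(truth) <- NULL
  singletons <- ids[!(comp %in% multi)]
  structure(list(membership = membership, truth = truth,
                 singletons = singletons, k = k, min_shared = min_shared),
            class = "toy_assembly")
}

#' @export
print.toy_assembly <- function(x, ...) {
  cat("Toy cross-assembly (k =", x$k, ", min_shared =", x$min_shared, "):",
      length(x$membership$contig_ids), "contigs,",
      length(x$singletons), "singleton reads\n")
  invisible(x)
}

#' Write contig membership as a consed-style ACE file
#'
#' Emits `AS`/`CO`/`AF` records.  Offsets are dummies and the contig length
#' field is a crude estimate; only the membership information is meaningful,
#' which is all the accounting consumes.
#'
#' @param x A `toy_assembly` or `contig_membership`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_ace <- function(x, path) {
  membership <- if (inherits(x, "toy_assembly")) x$membership else x
  stopifnot(inherits(membership, "contig_membership"))
  con <- file(path, "wt", encoding = "UTF-8")
  on.exit(close(con))
  nreads <- sum(lengths(membership$reads_by_contig))
  writeLines(sprintf("AS %d %d", length(membership$contig_ids), nreads), con)
  writeLines("", con)
  for (cid in membership$contig_ids) {
    ids <- membership$reads_by_contig[[cid]]
    writeLines(sprintf("CO %s %d %d 1 U", cid, 450L * length(ids),
                       length(ids)), con)
    writeLines(sprintf("AF %s U %d", ids, seq_along(ids)), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write simulated reads as FASTA or FASTQ
#'
#' @param readset A `simulated_readset`.
#' @param path Output file (`.gz` suffix writes gzip).
#' @param format `"fasta"` or `"fastq"` (dummy qualities).
#' @param strip When `TRUE`, sequence lines are written empty, producing the
#'   sequence-stripped files the parser must accept.
#' @return The path, invisibly.
#' @export
write_reads <- function(readset, path, format = c("fasta", "fastq"),
                        strip = FALSE) {
  stopifnot(inherits(readset, "simulated_readset"))
  format <- match.arg(format)
  seqs <- if (strip) stats::setNames(rep("", length(readset$sequences)),
                                     names(readset$sequences))
          else readset$sequences
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else
           file(path, "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (format == "fasta") {
    writeLines(paste0(">", names(seqs), "\n", seqs), con)
  } else {
    qual <- vapply(nchar(seqs), function(l) strrep("I", l), "")
    writeLines(paste0("@", names(seqs), "\n", seqs, "\n+\n", qual), con)
  }
  invisible(path)
}

#' Convert simulated read sets into a read inventory
#'
#' @param readsets List of `simulated_readset` objects.
#' @return A `read_inventory` carrying the simulated sequences.
#' @export
readsets_inventory <- function(readsets) {
  build_inventory(lapply(readsets, function(rs) {
    structure(list(label = rs$label, ids = rs$reads$id,
                   sequences = rs$sequences),
              class = "sample_reads")
  }))
}
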