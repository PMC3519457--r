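#' Build the contig-by-sample read-count profile
#'
#' Resolves every ACE read identifier to its sample of origin and tabulates
#' `r[k, i]`, the number of reads in contig `k` that come from metagenome
#' `i`.  Reads of the inventory absent from every contig are recorded as
#' singletons; they appear in the accounting table but are excluded from all
#' distance calculations.
#'
#' Identifier matching is exact first; an ACE identifier that fails exact
#' matching is retried after stripping a single trailing `.<digits>` suffix
#' (some assembler dialects append fragment suffixes).  Identifiers that
#' still match nothing are a hard error: a silent mismatch would corrupt
#' every downstream count.
#'
#' @param inventory A `read_inventory` (see [build_inventory()]).
#' @param membership A `contig_membership` (see [parse_ace()]).
#' @return An object of class `cross_profile`: list with `samples`,
#'   `contig_ids`, `R` (integer matrix, contigs x samples) and `singletons`
#'   (named list of unassembled read identifiers per sample).
#' @export
build_profile <- function(inventory, membership) {
  stopifnot(inherits(inventory, "read_inventory"),
            inherits(membership, "contig_membership"))
  samples <- inventory$samples
  sample_of <- rep(samples, lengths(inventory$reads_by_sample[samples]))
  names(sample_of) <- unlist(inventory$reads_by_sample[samples],
                             use.names = FALSE)

  ace_ids <- unlist(membership$reads_by_contig, use.names = FALSE)
  contig_of <- rep(membership$contig_ids,
                   lengths(membership$reads_by_contig))

  resolved <- sample_of[ace_ids]
  miss <- is.na(resolved)
  if (any(miss)) {
    stripped <- sub("\\.[0-9]+$", "", ace_ids[miss])
    resolved[miss] <- sample_of[stripped]
    miss <- is.na(resolved)
    if (any(miss)) {
      offenders <- unique(ace_ids[miss])
      stop("ACE read identifier(s) not found in any sample (",
           length(offenders), " total): ",
           paste(utils::head(offenders, 20L), collapse = ", "))
    }
  }

  R <- table(factor(contig_of, levels = membership$contig_ids),
             factor(resolved, levels = samples))
  R <- matrix(as.integer(R), nrow = length(membership$contig_ids),
              dimnames = list(membership$contig_ids, samples))

  # which inventory reads were assembled (match the same way: a stripped ACE
  # id marks the corresponding inventory read as used)
  used <- unique(c(ace_ids, sub("\\.[0-9]+$", "", ace_ids)))
  singles <- lapply(inventory$reads_by_sample[samples],
                    function(ids) ids[!(ids %in% used)])
  names(singles) <- samples
  structure(list(samples = samples, contig_ids = membership$contig_ids,
                 R = R, singletons = singles),
            class = "cross_profile")
}

#' @export
print.cross_profile <- function(x, ...) {
  cat("Cross-assembly profile:", nrow(x$R), "contigs x", ncol(x$R),
      "samples;", sum(lengths(x$singletons)), "singleton reads\n")
  invisible(x)
}

#' Pairwise contig and read counts for two samples
#'
#' Computes the quantities that the presence/absence and read-fraction
#' distance formulas consume for a pair of metagenomes `i`, `j`:
#' \describe{
#'   \item{`c_i`, `c_j`}{contigs containing at least one read of that sample}
#'   \item{`c_ij`}{cross-contigs: contigs with reads from both samples}
#'   \item{`r_i`, `r_j`}{assembled reads of each sample}
#'   \item{`r_ij`, `r_ji`}{reads of `i` (resp. `j`) lying in the shared
#'     cross-contigs}
#' }
#'
#' @param profile A `cross_profile`.
#' @param i,j Sample labels (or column indices); must differ.
#' @return An object of class `pairwise_counts` (a named list of the above).
#' @export
pairwise_counts <- function(profile, i, j) {
  stopifnot(inherits(profile, "cross_profile"))
  if (is.numeric(i)) i <- profile$samples[i]
  if (is.numeric(j)) j <- profile$samples[j]
  if (!all(c(i, j) %in% profile$samples)) {
    stop("unknown sample label(s): ",
         paste(setdiff(c(i, j), profile$samples), collapse = ", "))
  }
  if (identical(i, j)) stop("pairwise counts need two distinct samples")
  ri <- profile$R[, i]
  rj <- profile$R[, j]
  r_i <- sum(ri); r_j <- sum(rj)
  if (r_i == 0L) stop("sample '", i, "' has no assembled reads")
  if (r_j == 0L) stop("sample '", j, "' has no assembled reads")
  shared <- ri > 0L & rj > 0L
  structure(list(i = i, j = j,
                 c_i = sum(ri > 0L), c_j = sum(rj > 0L), c_ij = sum(shared),
                 r_i = r_i, r_j = r_j,
                 r_ij = sum(ri[shared]), r_ji = sum(rj[shared])),
            class = "pairwise_counts")
}

#' Per-sample contig abundance vectors
#'
#' Normalises each sample's column of the count matrix by its assembled-read
#' total, giving `p[k, i]`, the fraction of metagenome `i`'s assembled reads
#' incorporated into contig `k` -- a probability vector over contigs that
#' characterises the sample.  Singletons never enter the denominator.
#'
#' @param profile A `cross_profile`.
#' @return Numeric matrix (contigs x samples) with columns summing to 1.
#' @export
abundance_vectors <- function(profile) {
  stopifnot(inherits(profile, "cross_profile"))
  totals <- colSums(profile$R)
  if (any(totals == 0)) {
    stop("sample(s) with no assembled reads: ",
         paste(profile$samples[totals == 0], collapse = ", "))
  }
  sweep(profile$R, 2L, totals, "/")
}
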