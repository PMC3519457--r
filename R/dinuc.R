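#' Dinucleotide odds-ratio signature of a read set
#'
#' Computes the strand-symmetric dinucleotide relative-abundance signature
#' (Karlin's rho-star): each read is counted together with its reverse
#' complement (separately per read -- no windows are formed across read
#' junctions or between a read and its own reverse complement), giving
#' corrected mononucleotide frequencies `f*_X` and dinucleotide frequencies
#' `f*_XY` over the overlapping windows, and the odds ratio
#' `rho*_XY = f*_XY / (f*_X * f*_Y)`.  Short dinucleotide signatures are a
#' classical reference-independent genome signature; `k = 2` separates
#' microbial communities well and serves here as the baseline the
#' cross-assembly distances are compared against.
#'
#' Windows containing ambiguous bases (anything outside A, C, G, T) are
#' skipped, in both the mono- and dinucleotide counts.  By construction the
#' profile is strand-symmetric: `rho*_XY` equals `rho*` of the reverse
#' complement of `XY`, and the profile is invariant under
#' reverse-complementing any read.  Ratios whose expected frequency
#' `f*_X * f*_Y` is zero are reported as 0.
#'
#' @param sequences Character vector of nucleotide strings or a
#'   [Biostrings::DNAStringSet].
#' @return An object of class `dinuc_profile`: list with `rho` (named vector
#'   of 16 odds ratios), `mono` (4 corrected mononucleotide frequencies) and
#'   `total_nt` (nucleotides counted, including the reverse strand).
#' @examples
#' p <- dinuc_profile(c("ACGTACGT", "GGGCCC"))
#' p$rho
#' @export
dinuc_profile <- function(sequences) {
  if (!inherits(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
  }
  if (!length(sequences)) stop("no sequences supplied")
  dn <- colSums(Biostrings::oligonucleotideFrequency(sequences, width = 2L))
  mono <- colSums(Biostrings::letterFrequency(sequences, c("A", "C", "G", "T")))

  # counting every read together with its reverse complement is a
  # permutation of the forward counts
  rc2 <- vapply(names(dn), revcomp_string, "")
  dn <- dn + dn[rc2]
  names(dn) <- names(rc2)
  mono <- mono + mono[c(A = "T", C = "G", G = "C", T = "A")]
  names(mono) <- c("A", "C", "G", "T")

  if (sum(dn) == 0) stop("zero usable dinucleotide windows in input")
  f_mono <- mono / sum(mono)
  f_dn <- dn / sum(dn)
  expected <- as.vector(outer(f_mono, f_mono))  # column-major: X varies fastest
  names(expected) <- as.vector(outer(names(f_mono), names(f_mono),
                                     function(a, b) paste0(a, b)))
  expected <- expected[names(f_dn)]
  rho <- ifelse(expected > 0, f_dn / expected, 0)
  structure(list(rho = rho, mono = f_mono, total_nt = sum(mono)),
            class = "dinuc_profile")
}

revcomp_string <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

#' @export
print.dinuc_profile <- function(x, ...) {
  cat("Dinucleotide odds-ratio profile over", x$total_nt, "nt (both strands)\n")
  print(round(x$rho, 3))
  invisible(x)
}

#' Signature distance between two dinucleotide profiles
#'
#' Karlin's delta-star dissimilarity: the mean absolute difference of the 16
#' dinucleotide odds ratios, `d = (1/16) * sum_XY |rho*a_XY - rho*b_XY|`.
#' It is a pseudometric (symmetric, zero on identical profiles, triangle
#' inequality) and is used as the reference-independent baseline distance.
#'
#' @param a,b `dinuc_profile` objects.
#' @return Nonnegative distance (dimensionless).
#' @export
dist_dinuc <- function(a, b) {
  stopifnot(inherits(a, "dinuc_profile"), inherits(b, "dinuc_profile"))
  mean(abs(a$rho - b$rho[names(a$rho)]))
}

#' Dinucleotide distance matrix across all samples of an inventory
#'
#' @param inventory A `read_inventory` whose samples all carry sequences.
#' @return Symmetric distance matrix with `attr(, "formula") == "dinuc"`.
#' @export
dinuc_distance_matrix <- function(inventory) {
  stopifnot(inherits(inventory, "read_inventory"))
  no_seq <- vapply(inventory$sequences_by_sample, is.null, NA)
  if (any(no_seq)) {
    stop("sample(s) without sequence data: ",
         paste(inventory$samples[no_seq], collapse = ", "),
         " (the dinucleotide distance needs raw sequences)")
  }
  profs <- lapply(inventory$sequences_by_sample, dinuc_profile)
  n <- length(profs)
  D <- matrix(0, n, n, dimnames = list(inventory$samples, inventory$samples))
  for (a in seq_len(n - 1L)) {
    for (b in seq(a + 1L, n)) {
      D[a, b] <- D[b, a] <- dist_dinuc(profs[[a]], profs[[b]])
    }
  }
  attr(D, "formula") <- "dinuc"
  D
}

#' Export dinucleotide profiles as a tab-separated table
#'
#' One row per sample, one column per dinucleotide odds ratio.
#'
#' @param profiles Named list of `dinuc_profile` objects.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_dinuc_profiles <- function(profiles, path) {
  dns <- names(profiles[[1]]$rho)
  con <- file(path, "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("sample", dns), collapse = "\t"), con)
  for (s in names(profiles)) {
    writeLines(paste(c(s, format(profiles[[s]]$rho[dns], digits = 8,
                                 trim = TRUE)), collapse = "\t"), con)
  }
  invisible(path)
}
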