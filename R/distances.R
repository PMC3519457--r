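#' Cross-assembly distance formulas
#'
#' Four formulas turn the pairwise cross-assembly counts into a distance in
#' \[0, 1\].  Two are presence/absence based ("shot", "minimum": a contig
#' either contains a sample's reads or it does not) and two are quantitative
#' ("wootters", "reads": the number of reads is taken as a measure of
#' abundance).
#'
#' \describe{
#'   \item{shot}{`d = 1 - c_ij * sqrt((c_i^2 + c_j^2) / (2 c_i^2 c_j^2))`.
#'     The similarity is the root mean square of the separately normalised
#'     fractions `c_ij/c_i` and `c_ij/c_j`, i.e. the shared-contig signal is
#'     divided by a size-corrected mean (the squared geometric mean over the
#'     root mean square) that never strays far above `min(c_i, c_j)`, so a
#'     large sample does not drown the signal of a small one.  This
#'     genome-size correction has a history in gene-content phylogenetics.}
#'   \item{minimum}{`d = 1 - c_ij / min(c_i, c_j)`: the shared-contig signal
#'     normalised by the smaller of the two samples.  Because the RMS mean is
#'     at least the minimum, `d_shot >= d_minimum` always holds.}
#'   \item{wootters}{`d = (2/pi) * acos(sum_k sqrt(p_ki * p_kj))` on the
#'     contig abundance vectors: the statistical distance between two
#'     probability distributions measured as the angle between their
#'     square-root embeddings (the Bhattacharyya coefficient), interpretable
#'     as the number of distinguishable intermediate distributions under
#'     sampling fluctuation.  Scaled by `2/pi` so disjoint support gives 1.}
#'   \item{reads}{`d = 1 - sqrt(((r_ij/r_i)^2 + (r_ji/r_j)^2) / 2)`: the
#'     "shot" formula on read fractions instead of contig fractions, which
#'     damps the bias of long contigs attracting reads from unrelated
#'     samples by chance.}
#' }
#'
#' @param pc A `pairwise_counts` object (see [pairwise_counts()]).
#' @return A single distance in \[0, 1\].
#' @seealso [distance_matrix()] to apply a formula to every pair.
#' @name cross_assembly_distances
NULL

#' @rdname cross_assembly_distances
#' @export
dist_shot <- function(pc) {
  stopifnot(inherits(pc, "pairwise_counts"))
  ci <- pc$c_i; cj <- pc$c_j
  if (ci <= 0 || cj <= 0) stop("both samples must contain >=1 contig")
  s <- pc$c_ij * sqrt((ci^2 + cj^2) / (2 * ci^2 * cj^2))
  1 - s
}

#' @rdname cross_assembly_distances
#' @export
dist_minimum <- function(pc) {
  stopifnot(inherits(pc, "pairwise_counts"))
  if (pc$c_i <= 0 || pc$c_j <= 0) stop("both samples must contain >=1 contig")
  1 - pc$c_ij / min(pc$c_i, pc$c_j)
}

#' @rdname cross_assembly_distances
#' @param p_i,p_j Probability vectors over the same ordered contig set
#'   (columns of [abundance_vectors()]); each must be nonnegative and sum
#'   to 1 within `1e-9`.
#' @param scale `"unit"` (default) scales by `2/pi` so the maximum is 1;
#'   `"radians"` returns the raw Bhattacharyya angle in \[0, pi/2\].
#' @export
dist_wootters <- function(p_i, p_j, scale = c("unit", "radians")) {
  scale <- match.arg(scale)
  if (length(p_i) != length(p_j)) {
    stop("probability vectors differ in length (", length(p_i), " vs ",
         length(p_j), ")")
  }
  if (any(p_i < 0) || any(p_j < 0)) stop("probability vectors must be nonnegative")
  if (abs(sum(p_i) - 1) > 1e-9 || abs(sum(p_j) - 1) > 1e-9) {
    stop("probability vectors must each sum to 1 (within 1e-9)")
  }
  # the Bhattacharyya angle acos(sum sqrt(p q)) evaluated in its chordal
  # form 2*asin(||sqrt(p)-sqrt(q)||/2): algebraically identical, but exact
  # for identical inputs where acos near 1 loses half the significant
  # digits; sums accumulate in sorted order for bit-reproducibility
  chord <- sqrt(sum(sort((sqrt(p_i) - sqrt(p_j))^2)))
  ang <- 2 * asin(min(chord / 2, 1))
  if (scale == "unit") 2 / pi * ang else ang
}

#' @rdname cross_assembly_distances
#' @export
dist_reads <- function(pc) {
  stopifnot(inherits(pc, "pairwise_counts"))
  if (pc$r_i <= 0 || pc$r_j <= 0) stop("both samples must have assembled reads")
  1 - sqrt(((pc$r_ij / pc$r_i)^2 + (pc$r_ji / pc$r_j)^2) / 2)
}

#' Full symmetric distance matrix for one formula
#'
#' Applies one of the four cross-assembly distance formulas (see
#' [cross_assembly_distances]) to every unordered sample pair of a profile.
#'
#' @param profile A `cross_profile` with at least two samples, all with
#'   assembled reads.
#' @param formula One of `"shot"`, `"minimum"`, `"wootters"`, `"reads"`.
#' @return A symmetric numeric matrix with zero diagonal, sample labels as
#'   dimnames, and the formula name in `attr(, "formula")`.
#' @export
distance_matrix <- function(profile,
                            formula = c("shot", "minimum", "wootters",
                                        "reads")) {
  stopifnot(inherits(profile, "cross_profile"))
  formula <- match.arg(formula)
  samples <- profile$samples
  n <- length(samples)
  if (n < 2L) stop("need >=2 samples")
  D <- matrix(0, n, n, dimnames = list(samples, samples))
  P <- if (formula == "wootters") abundance_vectors(profile) else NULL
  for (a in seq_len(n - 1L)) {
    for (b in seq(a + 1L, n)) {
      d <- if (formula == "wootters") {
        dist_wootters(P[, a], P[, b])
      } else {
        pc <- pairwise_counts(profile, samples[a], samples[b])
        switch(formula,
               shot = dist_shot(pc),
               minimum = dist_minimum(pc),
               reads = dist_reads(pc))
      }
      D[a, b] <- D[b, a] <- d
    }
  }
  attr(D, "formula") <- formula
  D
}

#' Write a distance matrix as TSV or PHYLIP
#'
#' @param D Symmetric labeled distance matrix.
#' @param path Output file path.
#' @param format `"tsv"` (labeled square matrix with a header row) or
#'   `"phylip"` (relaxed PHYLIP distance format for external tree tools).
#' @return The path, invisibly.
#' @export
write_distance_matrix <- function(D, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  labels <- rownames(D)
  con <- file(path, "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (format == "tsv") {
    writeLines(paste(c("sample", labels), collapse = "\t"), con)
    for (a in seq_along(labels)) {
      writeLines(paste(c(labels[a], format(D[a, ], digits = 10,
                                           trim = TRUE, scientific = FALSE)),
                       collapse = "\t"), con)
    }
  } else {
    writeLines(sprintf("%5d", nrow(D)), con)
    for (a in seq_along(labels)) {
      writeLines(paste(c(labels[a], sprintf("%.6f", D[a, ])),
                       collapse = "  "), con)
    }
  }
  invisible(path)
}
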