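#' BioNJ cladogram from a distance matrix
#'
#' Builds an unrooted binary tree from a symmetric distance matrix using the
#' BioNJ agglomeration (neighbor joining with variance-weighted reduction of
#' the distance matrix; exact on additive matrices).  The two-sample case,
#' below the reach of any NJ implementation, is serialised as a single edge
#' split equally across the two pendant branches.
#'
#' @param D Symmetric numeric matrix with zero diagonal, nonnegative
#'   entries and unique row/column labels; at least 2 labels.
#' @return An [ape::phylo] tree whose tips carry the sample labels.  Branch
#'   lengths may be slightly negative on non-additive input; see
#'   [to_newick()] for clamping at serialisation.
#' @details The agglomeration is implemented here in double precision: at
#'   every step the pair minimising the Q-criterion is joined (ties broken
#'   towards the lexicographically smallest label pair, for determinism),
#'   pendant branch lengths follow the standard neighbor-joining estimate,
#'   and the reduced distances are the variance-weighted BioNJ update with
#'   the mixing weight `lambda` given by its closed form, clamped to
#'   \[0, 1\].  On additive input the original tree is recovered to
#'   round-off (~1e-12), which the exactness tests rely on.
#' @export
bionj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  if (is.null(rownames(D))) stop("D must carry sample labels as dimnames")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(D < 0)) stop("distance matrix has negative entries")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal must be zero")
  n <- nrow(D)
  if (n < 2L) stop("need >=2 samples to build a tree")
  labels <- rownames(D)
  if (n == 2L) {
    tr <- structure(list(edge = matrix(c(3L, 3L, 1L, 2L), 2L, 2L),
                         edge.length = rep(D[1L, 2L] / 2, 2L),
                         tip.label = labels, Nnode = 1L),
                    class = "phylo", order = "cladewise")
    return(tr)
  }

  storage.mode(D) <- "double"
  V <- D                       # distance-estimate variances, initially D
  # active node bookkeeping: my ids are 1..n for tips, n+1, n+2, ... for
  # agglomerated nodes; 'name' carries the smallest member label for the
  # deterministic tie-break
  active_id <- seq_len(n)
  active_name <- labels
  next_id <- n + 1L
  parent <- child <- integer(0)
  elen <- numeric(0)

  while (length(active_id) > 3L) {
    m <- length(active_id)
    S <- rowSums(D)
    Q <- (m - 2) * D - outer(S, S, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand) > 1L) {
      key <- vapply(seq_len(nrow(cand)), function(r) {
        paste(sort(active_name[cand[r, ]]), collapse = "\r")
      }, "")
      cand <- cand[order(key)[1L], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]

    b_i <- D[i, j] / 2 + (S[i] - S[j]) / (2 * (m - 2))
    b_j <- D[i, j] - b_i
    lambda <- if (V[i, j] > 0) {
      others <- setdiff(seq_len(m), c(i, j))
      0.5 + sum(V[j, others] - V[i, others]) / (2 * (m - 2) * V[i, j])
    } else 0.5
    lambda <- min(max(lambda, 0), 1)

    parent <- c(parent, next_id, next_id)
    child <- c(child, active_id[i], active_id[j])
    elen <- c(elen, b_i, b_j)

    others <- setdiff(seq_len(m), c(i, j))
    d_new <- lambda * (D[i, others] - b_i) +
      (1 - lambda) * (D[j, others] - b_j)
    v_new <- lambda * V[i, others] + (1 - lambda) * V[j, others] -
      lambda * (1 - lambda) * V[i, j]

    D <- D[others, others, drop = FALSE]
    V <- V[others, others, drop = FALSE]
    D <- rbind(cbind(D, d_new), c(d_new, 0))
    V <- rbind(cbind(V, v_new), c(v_new, 0))
    active_name <- c(active_name[others],
                     min(active_name[c(i, j)]))
    active_id <- c(active_id[others], next_id)
    next_id <- next_id + 1L
  }

  # final star: three nodes joined at a center
  center <- next_id
  if (length(active_id) == 3L) {
    b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    parent <- c(parent, center, center, center)
    child <- c(child, active_id)
    elen <- c(elen, b1, b2, b3)
  }

  # renumber to ape convention: tips 1..n, basal node n+1, then the
  # remaining internal nodes
  n_internal <- center - n
  remap <- integer(center)
  remap[seq_len(n)] <- seq_len(n)
  remap[center] <- n + 1L
  inner <- setdiff(seq.int(n + 1L, center), center)
  remap[inner] <- n + 1L + seq_along(inner)
  tr <- structure(list(edge = cbind(remap[parent], remap[child]),
                       edge.length = unname(elen), tip.label = labels,
                       Nnode = n_internal),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Serialise a tree as Newick
#'
#' @param tree An [ape::phylo] tree.
#' @param with_branch_lengths When `FALSE`, branch lengths are omitted
#'   entirely, giving the topology-only cladogram variant (useful when the
#'   differences between samples dwarf the similarities and internal
#'   branches become too short to see).
#' @param clamp_negative When `TRUE` (default), negative branch lengths --
#'   which NJ-family methods can produce on non-additive input -- are
#'   clamped to zero in the output; the stored tree is untouched.
#' @return A Newick string terminated by `";"`.
#' @export
to_newick <- function(tree, with_branch_lengths = TRUE,
                      clamp_negative = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (!with_branch_lengths) {
    tree$edge.length <- NULL
  } else if (clamp_negative && !is.null(tree$edge.length)) {
    tree$edge.length <- pmax(tree$edge.length, 0)
  }
  ape::write.tree(tree)
}

#' Length of the internal branch inducing a given leaf bipartition
#'
#' Looks up the internal edge of an unrooted tree whose removal splits the
#' leaves into exactly the two given sets, and returns its branch length --
#' the quantity tracked in the noise-contamination experiment, where the
#' branch separating the two community types shrinks as contamination grows
#' until the bipartition disappears altogether.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param partition A list of two character vectors of tip labels; together
#'   they must cover all tips, be disjoint, and each have at least 2 labels
#'   (a singleton side would be a pendant edge, not an internal bipartition).
#' @return The branch length (numeric), or `NA_real_` when no internal edge
#'   induces the bipartition.
#' @export
internal_branch_length <- function(tree, partition) {
  stopifnot(inherits(tree, "phylo"), is.list(partition),
            length(partition) == 2L)
  side1 <- as.character(partition[[1]])
  side2 <- as.character(partition[[2]])
  tips <- tree$tip.label
  if (length(intersect(side1, side2))) {
    stop("partition sides overlap: ",
         paste(intersect(side1, side2), collapse = ", "))
  }
  if (!setequal(c(side1, side2), tips)) {
    stop("partition does not cover exactly the tree's tips")
  }
  if (length(side1) < 2L || length(side2) < 2L) {
    stop("both sides of an internal bipartition need >=2 tips")
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")

  ntip <- length(tips)
  # tips below each node, accumulated in postorder
  post <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (v in seq_len(ntip)) below[[v]] <- tips[v]
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1L]; chd <- post$edge[e, 2L]
    below[[par]] <- c(below[[par]], below[[chd]])
  }
  internal <- which(tree$edge[, 2L] > ntip)
  for (e in internal) {
    clade <- below[[tree$edge[e, 2L]]]
    if (setequal(clade, side1) || setequal(clade, side2)) {
      return(unname(tree$edge.length[e]))
    }
  }
  NA_real_
}
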