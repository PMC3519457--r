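#' Scatter plot of per-contig read counts (2 or 3 samples)
#'
#' Plots one marker per contig at its per-sample read counts on logarithmic
#' axes.  Zero counts are substituted by `log_floor` (default 0.9) so that
#' sample-specific contigs remain visible hugging the axes.  With three
#' samples a projected 3D scatter is drawn, with the projections of each
#' marker onto the coordinate planes shown as small dots.  A companion
#' tab-separated table of the plotted coordinates is written next to the
#' image so every plotted value is machine-checkable.
#'
#' @param profile A `cross_profile` with 2 or 3 samples.
#' @param path Output image path; the device is chosen by extension
#'   (`.png`, `.pdf` or `.svg`).
#' @param log_floor Positive value substituted for zero counts on the log
#'   axes.
#' @return Invisibly, a list with the image `path` and the companion
#'   `data_path`.
#' @export
scatter_plot <- function(profile, path, log_floor = 0.9) {
  stopifnot(inherits(profile, "cross_profile"))
  if (log_floor <= 0) stop("log_floor must be positive")
  n <- length(profile$samples)
  if (n > 3L) {
    stop("scatter plots support 2 or 3 samples; use a cladogram for more")
  }
  if (n < 2L) stop("need >=2 samples")
  M <- profile$R
  Mf <- ifelse(M == 0, log_floor, M)
  data_path <- sub("\\.[^.]+$", ".tsv", path)
  utils::write.table(
    data.frame(contig_id = profile$contig_ids, M, check.names = FALSE),
    data_path, sep = "\t", quote = FALSE, row.names = FALSE)

  open_device(path)
  on.exit(grDevices::dev.off())
  if (n == 2L) {
    graphics::plot(Mf[, 1], Mf[, 2], log = "xy", pch = 5, col = "grey40",
                   xlab = paste("reads from", profile$samples[1]),
                   ylab = paste("reads from", profile$samples[2]),
                   main = "Per-contig read counts")
  } else {
    lg <- log10(Mf)
    rng <- range(lg)
    pm <- graphics::persp(x = rng, y = rng, z = matrix(rng[1], 2, 2),
                          xlim = rng, ylim = rng, zlim = rng,
                          theta = 40, phi = 25, expand = 0.8,
                          border = NA, col = NA,
                          xlab = paste0("log10 reads ", profile$samples[1]),
                          ylab = paste0("log10 reads ", profile$samples[2]),
                          zlab = paste0("log10 reads ", profile$samples[3]))
    # plane projections first (small dots), then the markers
    pr <- function(x, y, z) grDevices::trans3d(x, y, z, pm)
    for (plane in 1:3) {
      q <- lg
      q[, plane] <- rng[1]
      p2 <- pr(q[, 1], q[, 2], q[, 3])
      graphics::points(p2, pch = 16, cex = 0.3, col = "black")
    }
    p3 <- pr(lg[, 1], lg[, 2], lg[, 3])
    graphics::points(p3, pch = 5, col = "grey40")
    graphics::title(main = "Per-contig read counts")
  }
  invisible(list(path = path, data_path = data_path))
}

#' Triangle (barycentric) plot of three-sample contig composition
#'
#' Places each contig inside a simplex at barycentric coordinates
#' proportional to its read counts from the three samples: sample-specific
#' contigs sit at the vertices, two-way cross-contigs on the edges and
#' three-way cross-contigs in the interior.  Marker area scales with the
#' contig's total read count.
#'
#' @param profile A `cross_profile` with exactly 3 samples.
#' @param path Output image path (`.png`, `.pdf` or `.svg`).
#' @return Invisibly, a list with `path` and the companion `data_path`.
#' @export
triangle_plot <- function(profile, path) {
  stopifnot(inherits(profile, "cross_profile"))
  if (length(profile$samples) != 3L) {
    stop("triangle plot requires exactly 3 samples")
  }
  M <- profile$R
  tot <- rowSums(M)
  W <- M / tot
  # equilateral simplex vertices
  vx <- c(0, 1, 0.5)
  vy <- c(0, 0, sqrt(3) / 2)
  px <- as.vector(W %*% vx)
  py <- as.vector(W %*% vy)
  data_path <- sub("\\.[^.]+$", ".tsv", path)
  utils::write.table(
    data.frame(contig_id = profile$contig_ids, x = px, y = py,
               total_reads = tot),
    data_path, sep = "\t", quote = FALSE, row.names = FALSE)

  open_device(path)
  on.exit(grDevices::dev.off())
  graphics::plot(NA, xlim = c(-0.08, 1.08), ylim = c(-0.1, sqrt(3) / 2 + 0.1),
                 axes = FALSE, xlab = "", ylab = "", asp = 1,
                 main = "Contig composition")
  graphics::polygon(vx, vy, border = "black")
  graphics::text(vx, vy, labels = profile$samples,
                 pos = c(1, 1, 3), offset = 0.6)
  graphics::points(px, py, pch = 5, col = "grey40",
                   cex = 0.5 + sqrt(tot / max(tot)) * 1.8)
  invisible(list(path = path, data_path = data_path))
}

#' Draw a cladogram from a tree
#'
#' Unrooted radial layout of the BioNJ tree; with `with_branch_lengths =
#' FALSE` all edges are drawn at unit length, the topology-only variant.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output image path (`.png`, `.pdf` or `.svg`).
#' @param with_branch_lengths Draw edges proportional to branch lengths?
#' @return Invisibly, the image path.
#' @export
cladogram_plot <- function(tree, path, with_branch_lengths = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  tr <- tree
  if (!is.null(tr$edge.length)) tr$edge.length <- pmax(tr$edge.length, 0)
  open_device(path)
  on.exit(grDevices::dev.off())
  ape::plot.phylo(tr, type = "unrooted",
                  use.edge.length = with_branch_lengths &&
                    !is.null(tr$edge.length),
                  lab4ut = "axial", cex = 0.9, no.margin = TRUE)
  invisible(path)
}

open_device <- function(path, width = 7, height = 7) {
  ext <- tolower(sub("^.*\\.", "", path))
  switch(ext,
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = 150),
         pdf = grDevices::pdf(path, width = width, height = height),
         svg = grDevices::svg(path, width = width, height = height),
         stop("unsupported image format: .", ext,
              " (use .png, .pdf or .svg)"))
}


#' Export a Gnuplot-compatible data and script pair
#'
#' Writes the per-contig counts as whitespace-separated data plus a minimal
#' Gnuplot script reproducing the XY (2 samples) or XYZ (3 samples) scatter
#' on logarithmic axes, for users who want the classic toolchain instead of
#' the native plots.  Zeros are written at the `log_floor` value.
#'
#' @param profile A `cross_profile` with 2 or 3 samples.
#' @param dir Output directory (created if missing).
#' @param log_floor Positive value substituted for zero counts.
#' @return Invisibly, the paths of the `.dat` and `.gp` files.
#' @export
write_gnuplot_scatter <- function(profile, dir, log_floor = 0.9) {
  stopifnot(inherits(profile, "cross_profile"))
  n <- length(profile$samples)
  if (n < 2L || n > 3L) stop("gnuplot export supports 2 or 3 samples")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Mf <- ifelse(profile$R == 0, log_floor, profile$R)
  dat <- file.path(dir, "scatter.dat")
  utils::write.table(Mf, dat, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  gp <- file.path(dir, "scatter.gp")
  lab <- profile$samples
  lines <- c("set logscale xy",
             sprintf("set xlabel 'reads from %s'", lab[1]),
             sprintf("set ylabel 'reads from %s'", lab[2]))
  if (n == 2L) {
    lines <- c(lines,
               "plot 'scatter.dat' using 1:2 with points pt 5 notitle")
  } else {
    lines <- c(lines, "set logscale z",
               sprintf("set zlabel 'reads from %s'", lab[3]),
               "splot 'scatter.dat' using 1:2:3 with points pt 5 notitle")
  }
  writeLines(lines, gp)
  invisible(c(dat, gp))
}
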