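#' Run the full cross-assembly comparison pipeline
#'
#' Orchestrates the complete analysis: reads the per-sample read files and
#' the ACE cross-assembly, builds the contig-by-sample profile, writes the
#' accounting table (`output.contigs2reads.txt`), one distance matrix per
#' formula (TSV and PHYLIP), Newick cladograms in two variants (with branch
#' lengths and topology-only) when more than three samples are compared,
#' scatter/triangle plots when two or three are, and a machine-readable run
#' summary (JSON).
#'
#' On any failure the partial outputs created by this run are removed and
#' the error is re-thrown, so an output directory never holds a half-written
#' result set.
#'
#' @param read_files Character vector of per-sample FASTA/FASTQ paths
#'   (>= 2; `.gz` accepted).
#' @param ace_file Path to the ACE file of the cross-assembly of all reads.
#' @param out_dir Output directory (created if missing).
#' @param labels Sample labels in `read_files` order; defaults to file
#'   basenames.  This order fixes column order everywhere downstream.
#' @param formulas Cross-assembly distance formulas to compute.
#' @param dinuc Also compute the dinucleotide odds-ratio baseline distance?
#'   `NA` (default) computes it exactly when every read file carries
#'   sequences.
#' @param tree Build BioNJ cladograms (only applies with > 3 samples)?
#' @param plots Write images (scatter/triangle for <= 3 samples, cladogram
#'   images otherwise)?
#' @param image_format `"png"`, `"pdf"` or `"svg"`.
#' @return Invisibly, a list with the `profile`, the distance matrices,
#'   trees (if any) and the paths written.
#' @export
run_crossassembly <- function(read_files, ace_file, out_dir,
                              labels = NULL,
                              formulas = c("shot", "minimum", "wootters",
                                           "reads"),
                              dinuc = NA, tree = TRUE, plots = TRUE,
                              image_format = c("png", "pdf", "svg")) {
  image_format <- match.arg(image_format)
  formulas <- match.arg(formulas, several.ok = TRUE)
  if (length(read_files) < 2L) stop("need >=2 read files")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  note <- function(p) { written <<- c(written, p); p }

  result <- tryCatch({
    per_sample <- lapply(seq_along(read_files), function(s) {
      read_sample_reads(read_files[s],
                        sample_label = if (is.null(labels)) NULL
                                       else labels[s])
    })
    inv <- build_inventory(per_sample)
    n <- length(inv$samples)
    membership <- parse_ace(ace_file)
    profile <- build_profile(inv, membership)
    note(write_contigs2reads(profile,
                             file.path(out_dir,
                                       "output.contigs2reads.txt")))

    have_seqs <- !any(vapply(inv$sequences_by_sample, is.null, NA))
    if (isTRUE(dinuc) && !have_seqs) {
      stop("dinuc distance requested but some read files are ",
           "sequence-stripped")
    }
    do_dinuc <- isTRUE(dinuc) || (is.na(dinuc) && have_seqs)

    Ds <- lapply(formulas, function(f) distance_matrix(profile, f))
    names(Ds) <- formulas
    if (do_dinuc) Ds$dinuc <- dinuc_distance_matrix(inv)
    for (f in names(Ds)) {
      note(write_distance_matrix(
        Ds[[f]], file.path(out_dir, sprintf("distance.%s.tsv", f)), "tsv"))
      note(write_distance_matrix(
        Ds[[f]], file.path(out_dir, sprintf("distance.%s.phylip", f)),
        "phylip"))
    }

    trees <- list()
    if (tree && n > 3L) {
      for (f in names(Ds)) {
        tr <- bionj_tree(Ds[[f]])
        trees[[f]] <- tr
        writeLines(to_newick(tr, with_branch_lengths = TRUE),
                   note(file.path(out_dir, sprintf("tree.%s.nwk", f))))
        writeLines(to_newick(tr, with_branch_lengths = FALSE),
                   note(file.path(out_dir,
                                  sprintf("tree.%s.topology.nwk", f))))
        if (plots) {
          note(cladogram_plot(
            tr, file.path(out_dir, sprintf("cladogram.%s.%s", f,
                                           image_format))))
          note(cladogram_plot(
            tr, file.path(out_dir, sprintf("cladogram.%s.topology.%s", f,
                                           image_format)),
            with_branch_lengths = FALSE))
        }
      }
    }
    if (plots && n <= 3L) {
      sp <- scatter_plot(profile,
                         file.path(out_dir, paste0("scatter.",
                                                   image_format)))
      note(sp$path); note(sp$data_path)
      if (n == 3L) {
        tp <- triangle_plot(profile,
                            file.path(out_dir, paste0("triangle.",
                                                      image_format)))
        note(tp$path); note(tp$data_path)
      }
    }

    summary <- list(
      samples = inv$samples,
      n_reads = as.list(lengths(inv$reads_by_sample)),
      n_assembled = as.list(colSums(profile$R)),
      assembled_fraction = as.list(colSums(profile$R) /
                                     lengths(inv$reads_by_sample)[
                                       inv$samples]),
      n_contigs = nrow(profile$R),
      contig_counts = lapply(inv$samples, function(s) {
        list(sample = s, c_i = sum(profile$R[, s] > 0))
      }),
      cross_contigs = {
        prs <- utils::combn(inv$samples, 2L, simplify = FALSE)
        lapply(prs, function(p) {
          pc <- pairwise_counts(profile, p[1], p[2])
          list(i = p[1], j = p[2], c_ij = pc$c_ij,
               r_ij = pc$r_ij, r_ji = pc$r_ji)
        })
      },
      formulas = names(Ds))
    jsonlite::write_json(summary,
                         note(file.path(out_dir, "run_summary.json")),
                         auto_unbox = TRUE, digits = NA)
    list(profile = profile, distances = Ds, trees = trees,
         paths = written)
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
  invisible(result)
}
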