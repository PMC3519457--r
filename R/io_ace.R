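#' Read the identifiers (and optionally sequences) of one sample's reads
#'
#' Reads a FASTA or FASTQ file belonging to a single metagenomic sample and
#' returns the set of read identifiers, plus the sequences when the file
#' contains any.  Only identifiers are required downstream, so
#' "sequence-stripped" files -- records whose sequence lines are empty --
#' are accepted; this lets users withhold privacy-sensitive sequence data
#' while still running the cross-assembly accounting.
#'
#' The identifier of a record is the token up to the first whitespace of its
#' header line.  FASTQ quality lines are ignored entirely.  Files ending in
#' `.gz` are decompressed transparently.
#'
#' @param path Path to the read file (FASTA, FASTQ, optionally gzipped).
#' @param sample_label Label identifying the sample; defaults to the file
#'   basename without extension.
#' @param format One of `"auto"`, `"fasta"`, `"fastq"`.  With `"auto"` the
#'   format is detected from the first non-blank character (`>` vs `@`).
#' @return An object of class `sample_reads`: a list with elements `label`,
#'   `ids` (character vector of read identifiers) and `sequences` (named
#'   character vector, or `NULL` when the file carries no sequence data).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "ACGT", ">r2 description", "GGCC"), fa)
#' sr <- read_sample_reads(fa, "gut1")
#' sr$ids
#' @export
read_sample_reads <- function(path, sample_label = NULL,
                              format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read file does not exist: ", path)
  if (is.null(sample_label)) {
    sample_label <- sub("\\.(fa|fasta|fq|fastq)(\\.gz)?$", "",
                        basename(path), ignore.case = TRUE)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)

  if (format == "auto") {
    first <- lines[nzchar(trimws(lines))][1]
    if (is.na(first)) stop("empty read file: ", path)
    lead <- substr(trimws(first), 1, 1)
    format <- switch(lead, ">" = "fasta", "@" = "fastq",
                     stop("cannot detect format of ", path,
                          ": first record starts with '", lead, "'"))
  }

  parsed <- if (format == "fasta") parse_fasta_lines(lines, path)
            else parse_fastq_lines(lines, path)

  dup <- parsed$ids[duplicated(parsed$ids)]
  if (length(dup)) {
    stop("duplicate read identifier(s) within ", path, ": ",
         paste(unique(dup)[seq_len(min(5, length(unique(dup))))],
               collapse = ", "))
  }
  seqs <- parsed$seqs
  if (!is.null(seqs)) {
    if (!any(nzchar(seqs))) {
      seqs <- NULL   # fully stripped file
    } else {
      names(seqs) <- parsed$ids
    }
  }
  structure(list(label = sample_label, ids = parsed$ids, sequences = seqs),
            class = "sample_reads")
}

parse_fasta_lines <- function(lines, path) {
  hdr <- startsWith(lines, ">")
  if (!any(hdr)) stop("no FASTA records found in ", path)
  pre <- which(nzchar(trimws(lines)) & !hdr)
  if (length(pre) && pre[1] < which(hdr)[1]) {
    stop("unparseable FASTA record structure in ", path,
         " at line ", pre[1], ": sequence before first header")
  }
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  if (any(ids == ">" | !nzchar(sub("^>", "", lines[hdr])))) {
    bad <- which(hdr)[!nzchar(sub("^>\\s*", "", lines[hdr]))][1]
    stop("unparseable FASTA record structure in ", path,
         " at line ", bad, ": empty header")
  }
  # assign every non-header line to the preceding record
  rec <- cumsum(hdr)
  body <- !hdr & nzchar(trimws(lines))
  seqs <- rep("", length(ids))
  if (any(body)) {
    agg <- vapply(split(lines[body], rec[body]), paste0, "", collapse = "")
    seqs[as.integer(names(agg))] <- toupper(gsub("\\s", "", agg))
  }
  list(ids = ids, seqs = seqs)
}

parse_fastq_lines <- function(lines, path) {
  # strict 4-line records; empty sequence/quality lines are legal, so only
  # drop trailing blank lines that cannot be record content
  while (length(lines) %% 4L != 0L && length(lines) &&
         !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) %% 4L != 0L) {
    stop("unparseable FASTQ record structure in ", path, " at line ",
         (length(lines) %/% 4L) * 4L + 1L,
         ": file length is not a multiple of 4 lines")
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  bad_h <- which(!startsWith(hdr, "@"))
  if (length(bad_h)) {
    stop("unparseable FASTQ record structure in ", path,
         " at line ", (bad_h[1] - 1L) * 4L + 1L, ": header must start with '@'")
  }
  bad_p <- which(!startsWith(plus, "+"))
  if (length(bad_p)) {
    stop("unparseable FASTQ record structure in ", path,
         " at line ", (bad_p[1] - 1L) * 4L + 3L,
         ": separator line must start with '+'")
  }
  ids <- sub("^@\\s*(\\S*).*$", "\\1", hdr)
  if (any(!nzchar(ids))) {
    bad <- which(!nzchar(ids))[1]
    stop("unparseable FASTQ record structure in ", path,
         " at line ", (bad - 1L) * 4L + 1L, ": empty identifier")
  }
  seqs <- toupper(gsub("\\s", "", lines[seq(2L, by = 4L, length.out = n)]))
  list(ids = ids, seqs = seqs)
}

#' Combine per-sample read sets into a cross-assembly read inventory
#'
#' Validates that read identifiers are unique across all samples combined --
#' a prerequisite for attributing contig membership to samples -- and that at
#' least two samples are present (a single metagenome cannot be compared).
#'
#' @param per_sample_reads A list of `sample_reads` objects (see
#'   [read_sample_reads()]), in the sample order to be used everywhere
#'   downstream (matrix columns, tables, plots).
#' @return An object of class `read_inventory`: list with `samples` (ordered
#'   labels), `reads_by_sample` (named list of identifier vectors) and
#'   `sequences_by_sample` (named list; entries may be `NULL`).
#' @export
build_inventory <- function(per_sample_reads) {
  if (length(per_sample_reads) < 2L) {
    stop("need >=2 metagenomes to compare (got ", length(per_sample_reads), ")")
  }
  labels <- vapply(per_sample_reads, function(x) x$label, "")
  if (any(!nzchar(labels))) stop("sample labels must be non-empty")
  if (anyDuplicated(labels)) {
    stop("duplicate sample label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  all_ids <- unlist(lapply(per_sample_reads, `[[`, "ids"), use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    dup <- all_ids[duplicated(all_ids)][1]
    in_samples <- labels[vapply(per_sample_reads,
                                function(x) dup %in% x$ids, NA)]
    stop("read identifier '", dup, "' occurs in more than one sample: ",
         paste(in_samples, collapse = ", "),
         " (identifiers must be unique across all datasets combined)")
  }
  reads <- lapply(per_sample_reads, `[[`, "ids")
  seqs <- lapply(per_sample_reads, `[[`, "sequences")
  names(reads) <- names(seqs) <- labels
  structure(list(samples = labels, reads_by_sample = reads,
                 sequences_by_sample = seqs),
            class = "read_inventory")
}

#' @export
print.read_inventory <- function(x, ...) {
  cat("Cross-assembly read inventory:", length(x$samples), "samples,",
      sum(lengths(x$reads_by_sample)), "reads\n")
  for (s in x$samples) {
    cat("  ", s, ": ", length(x$reads_by_sample[[s]]), " reads",
        if (is.null(x$sequences_by_sample[[s]])) " (identifiers only)" else "",
        "\n", sep = "")
  }
  invisible(x)
}

#' Parse a consed-style ACE assembly file into contig membership
#'
#' Extracts, for every contig (`CO` block), the identifiers of its member
#' reads.  `AF` placement lines are authoritative; `RD` read blocks are used
#' as a fallback when a contig has no `AF` lines.  A read listed more than
#' once within one contig (re-aligned duplicate) is counted once: membership,
#' not multiplicity, defines the accounting.
#'
#' @param path Path to the ACE file.
#' @return An object of class `contig_membership`: list with `contig_ids`,
#'   `reads_by_contig` (named list of read-identifier vectors) and
#'   `declared_counts` (named integer vector from the `CO` headers).
#'   A warning is recorded when the actual member count disagrees with the
#'   declared count; membership always follows the actual lines.
#' @export
parse_ace <- function(path) {
  if (!file.exists(path)) stop("ACE file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  co <- which(startsWith(lines, "CO "))
  if (!length(co)) stop("no CO contig records found in ACE file ", path)

  block_end <- c(co[-1] - 1L, length(lines))
  contig_ids <- character(length(co))
  declared <- integer(length(co))
  members <- vector("list", length(co))

  for (b in seq_along(co)) {
    fields <- strsplit(trimws(lines[co[b]]), "\\s+")[[1]]
    if (length(fields) < 4L) {
      stop("truncated ACE file ", path, ": incomplete CO header at line ",
           co[b], " ('", lines[co[b]], "')")
    }
    contig_ids[b] <- fields[2]
    declared[b] <- suppressWarnings(as.integer(fields[4]))
    if (is.na(declared[b])) {
      stop("truncated ACE file ", path, ": unreadable read count on CO line ",
           co[b])
    }
    block <- lines[co[b]:block_end[b]]
    af <- block[startsWith(block, "AF ")]
    if (length(af)) {
      ids <- vapply(strsplit(af, "\\s+"), `[`, "", 2L)
    } else {
      rd <- block[startsWith(block, "RD ")]
      ids <- if (length(rd)) vapply(strsplit(rd, "\\s+"), `[`, "", 2L)
             else character(0)
    }
    ids <- unique(ids[!is.na(ids) & nzchar(ids)])
    if (!length(ids)) {
      stop("contig '", contig_ids[b], "' (line ", co[b],
           ") has no member reads")
    }
    if (length(ids) != declared[b]) {
      warning("contig '", contig_ids[b], "': CO line declares ", declared[b],
              " reads but ", length(ids),
              " member read(s) found; using the actual membership",
              call. = FALSE)
    }
    members[[b]] <- ids
  }
  if (anyDuplicated(contig_ids)) {
    stop("duplicate contig identifier(s) in ", path, ": ",
         paste(unique(contig_ids[duplicated(contig_ids)]), collapse = ", "))
  }
  names(members) <- names(declared) <- contig_ids
  structure(list(contig_ids = contig_ids, reads_by_contig = members,
                 declared_counts = declared),
            class = "contig_membership")
}

#' @export
print.contig_membership <- function(x, ...) {
  cat("Contig membership:", length(x$contig_ids), "contigs,",
      sum(lengths(x$reads_by_contig)), "read placements\n")
  invisible(x)
}

#' Write the per-contig read accounting table
#'
#' Writes the main tabular output: one row per contig giving the number of
#' member reads contributed by each sample, followed by the identifiers of
#' the unassembled singleton reads per sample (listed for reference; they
#' take no part in any distance).  The singleton section is prefixed with
#' `#` so the contig table reads cleanly with `read.delim(comment.char =
#' "#")`.
#'
#' @param profile A `cross_profile` (see [build_profile()]).
#' @param path Output file, or a directory in which the default name
#'   `output.contigs2reads.txt` is used.
#' @return The path written, invisibly.
#' @export
write_contigs2reads <- function(profile, path) {
  stopifnot(inherits(profile, "cross_profile"))
  if (dir.exists(path)) path <- file.path(path, "output.contigs2reads.txt")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("contig_id", profile$samples), collapse = "\t"), con)
  if (length(profile$contig_ids)) {
    rows <- paste(profile$contig_ids,
                  apply(profile$R, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(rows, con)
  }
  writeLines("# singletons", con)
  for (s in profile$samples) {
    ids <- profile$singletons[[s]]
    if (length(ids)) {
      writeLines(paste("# singleton", s, ids, sep = "\t"), con)
    }
  }
  invisible(path)
}
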