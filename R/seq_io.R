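# Sequence and table input/output.
#
# Internal alphabet is DNA: U is converted to T on input because the printed
# small-RNA tables in the wet-lab literature use DNA, while prose uses RNA.
# `normalize_seq()` converts between the two views.

#' Normalize a nucleotide string
#'
#' Upper-cases a sequence and converts it to the requested alphabet
#' (`"DNA"` turns U into T, `"RNA"` turns T into U). All package functions
#' store sequences as DNA internally.
#'
#' @param x character vector of nucleotide sequences.
#' @param alphabet target alphabet, `"DNA"` (default) or `"RNA"`.
#' @return character vector of the same length.
#' @export
#' @examples
#' normalize_seq("ugUugg")            # "TGTTGG"
#' normalize_seq("TGTTGG", "RNA")     # "UGUUGG"
normalize_seq <- function(x, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  x <- toupper(x)
  if (alphabet == "DNA") chartr("U", "T", x) else chartr("T", "U", x)
}

#' Reverse complement
#'
#' @param x character vector of DNA/RNA sequences (returned as DNA).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(normalize_seq(x))))
  unname(out)
}

#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that upper-cases,
#' converts U to T and validates that every record has a non-empty sequence.
#'
#' @param path path to a FASTA file.
#' @return a `data.frame` with columns `id` and `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("no FASTA records in ", path)
  empty <- which(Biostrings::width(set) == 0L)
  if (length(empty)) {
    stop("empty sequence for FASTA record '", names(set)[empty[1L]],
         "' (record ", empty[1L], ") in ", path)
  }
  data.frame(id = names(set),
             sequence = normalize_seq(as.character(set)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path path to a 4-line-record FASTQ file.
#' @return a `data.frame` with columns `id`, `sequence` and a list column
#'   `quality` of integer Phred scores (one vector per read).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred")),
    error = function(e) stop("malformed FASTQ in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  quals <- suppressWarnings(as(Biostrings::quality(set), "IntegerList"))
  out <- data.frame(id = names(set),
                    sequence = normalize_seq(as.character(set)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$quality <- as.list(quals)
  bad <- which(nchar(out$sequence) != lengths(out$quality))
  if (length(bad)) {
    stop("sequence/quality length mismatch for record ", bad[1L], " in ", path)
  }
  out
}

#' Collapse identical reads into unique sequences with counts
#'
#' Aggregates a read set into one row per unique sequence. The operation is
#' idempotent: collapsing an already-collapsed library (any input with a
#' `count` column) sums the existing counts and leaves totals unchanged.
#'
#' @param records a character vector of sequences, a `data.frame` with a
#'   `sequence` column (one row per read), or a collapsed `data.frame` with
#'   `sequence` and `count` columns.
#' @return a `data.frame` with columns `sequence`, `count`, sorted by
#'   decreasing count with ties broken lexicographically.
#' @export
#' @examples
#' collapse_reads(c("ACG", "ACG", "TTT"))
collapse_reads <- function(records) {
  if (is.character(records)) {
    records <- data.frame(sequence = records, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(records), "sequence" %in% names(records))
  if (nrow(records) == 0L) stop("collapse_reads(): empty input")
  seqs <- normalize_seq(records$sequence)
  counts <- if ("count" %in% names(records)) records$count else rep(1L, length(seqs))
  agg <- tapply(as.integer(counts), seqs, sum)
  out <- data.frame(sequence = names(agg), count = as.integer(agg),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$count, out$sequence), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Write/read a rectangular TSV table with header
#'
#' Round-trip companions used by all report emitters; text and integer
#' columns survive a write/read cycle unchanged.
#'
#' @param rows a `data.frame`.
#' @param path output (or input) path.
#' @return `read_table()` returns a `data.frame`; `write_table()` returns
#'   `path` invisibly.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows)) stop("write_table() expects a data.frame")
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a collapsed small-RNA library from TSV
#'
#' Expects columns `sequence` and `count`; any additional columns (for
#' example a clone id) are ignored.
#'
#' @param path TSV path.
#' @return collapsed library `data.frame` (`sequence`, `count`).
#' @export
read_collapsed <- function(path) {
  tab <- read_table(path)
  need <- c("sequence", "count")
  if (!all(need %in% names(tab))) {
    stop("collapsed library TSV needs columns 'sequence' and 'count'")
  }
  collapse_reads(tab[need])
}

#' Hairpin precursor object
#'
#' A single-stranded precursor sequence (5' to 3') with an optional
#' dot-bracket secondary structure and optional named regions (1-based,
#' inclusive intervals), e.g. arms, loop and small-RNA blocks.
#'
#' @param name precursor name.
#' @param sequence nucleotide string (stored as DNA).
#' @param structure optional dot-bracket string of the same length.
#' @param regions optional `data.frame` with columns `region`, `start`, `end`.
#' @return an object of class `hairpin` (a list with the validated fields).
#' @export
hairpin <- function(name, sequence, structure = NULL, regions = NULL) {
  sequence <- normalize_seq(sequence)
  if (nchar(sequence) < 1L) stop("hairpin sequence must be non-empty")
  if (!is.null(structure)) {
    if (nchar(structure) != nchar(sequence)) {
      stop("structure length must equal sequence length")
    }
    chars <- strsplit(structure, "", fixed = TRUE)[[1L]]
    if (!all(chars %in% c("(", ")", "."))) {
      stop("structure may only contain '(', ')' and '.'")
    }
    depth <- cumsum((chars == "(") - (chars == ")"))
    if (any(depth < 0) || depth[length(depth)] != 0L) {
      stop("unbalanced brackets in dot-bracket structure")
    }
  }
  if (!is.null(regions)) {
    stopifnot(is.data.frame(regions),
              all(c("region", "start", "end") %in% names(regions)))
    if (any(regions$start < 1L) || any(regions$end > nchar(sequence)) ||
        any(regions$start > regions$end)) {
      stop("region intervals must lie within [1, ", nchar(sequence), "]")
    }
  }
  structure(list(name = name, sequence = sequence,
                 structure = structure, regions = regions),
            class = "hairpin")
}

#' @export
print.hairpin <- function(x, ...) {
  cat("<hairpin> ", x$name, " (", nchar(x$sequence), " nt",
      if (!is.null(x$structure)) ", with structure" else "",
      if (!is.null(x$regions)) paste0(", ", nrow(x$regions), " regions") else "",
      ")\n", sep = "")
  invisible(x)
}

#' Look up a named region interval on a hairpin
#'
#' @param hp a [hairpin()] object.
#' @param region region name.
#' @return integer vector `c(start, end)` (1-based, inclusive).
#' @export
hairpin_region <- function(hp, region) {
  stopifnot(inherits(hp, "hairpin"))
  if (is.null(hp$regions) || !region %in% hp$regions$region) {
    stop("hairpin '", hp$name, "' has no region named '", region, "'")
  }
  row <- hp$regions[hp$regions$region == region, , drop = FALSE][1L, ]
  c(start = as.integer(row$start), end = as.integer(row$end))
}

#' Read a hairpin from a two-line companion file
#'
#' Format: an optional `>name` header line, then the sequence line, then an
#' optional dot-bracket line of equal length.
#'
#' @param path file path.
#' @param name name used when the file has no header line.
#' @return a [hairpin()] object.
#' @export
read_hairpin <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty hairpin file: ", path)
  if (startsWith(lines[1L], ">")) {
    name <- sub("^>\\s*", "", lines[1L])
    lines <- lines[-1L]
  }
  if (!length(lines)) stop("no sequence line in ", path)
  hairpin(name, lines[1L],
          structure = if (length(lines) >= 2L) lines[2L] else NULL)
}
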