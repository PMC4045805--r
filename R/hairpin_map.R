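# Mapping collapsed reads onto precursors (perfect match) and transcripts
# (mismatch-tolerant), plus coverage and the secondary-siRNA scan.
#
# Coordinates are 1-based inclusive intervals on the reference sense strand;
# antisense hits are reported at their sense-strand interval with strand "-".
# Multi-hit reads count fully at every hit (tallies stay integral).

map_hits_one <- function(sequence, count, subject, subject_chr, ref,
                         max_mm, strand) {
  pat <- if (strand == "-") revcomp(sequence) else sequence
  if (nchar(pat) > length(subject)) return(NULL)
  m <- Biostrings::matchPattern(pat, subject, max.mismatch = max_mm,
                                with.indels = FALSE)
  if (length(m) == 0L) return(NULL)
  starts <- Biostrings::start(m)
  ends <- Biostrings::end(m)
  # drop edge-hanging partial matches reported at high mismatch allowances
  keep <- starts >= 1L & ends <= length(subject)
  if (!any(keep)) return(NULL)
  starts <- starts[keep]; ends <- ends[keep]
  pat_chars <- strsplit(pat, "", fixed = TRUE)[[1L]]
  mism <- vapply(seq_along(starts), function(i) {
    s <- substr(subject_chr, starts[i], ends[i])
    sum(strsplit(s, "", fixed = TRUE)[[1L]] != pat_chars)
  }, 0L, USE.NAMES = FALSE)
  data.frame(sequence = sequence, count = count, ref = ref,
             start = starts, end = ends, strand = strand,
             mismatches = as.integer(mism), stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(sequence = character(0), count = integer(0), ref = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             mismatches = integer(0), stringsAsFactors = FALSE)
}

#' Map reads onto a precursor allowing only perfect matches
#'
#' Every exact substring occurrence of every read is reported; reads with no
#' exact occurrence are simply omitted (candidates for tailed-variant
#' decomposition, see [decompose_tail()]).
#'
#' @param collapsed collapsed library (`sequence`, `count`).
#' @param hp a [hairpin()] object (or a plain sequence string).
#' @return a `data.frame` of hits: `sequence`, `count`, `ref`, `start`,
#'   `end`, `strand`, `mismatches` (always 0 here).
#' @export
map_exact <- function(collapsed, hp) {
  ref_name <- if (inherits(hp, "hairpin")) hp$name else "reference"
  ref_seq <- if (inherits(hp, "hairpin")) hp$sequence else normalize_seq(hp)
  subject <- Biostrings::DNAString(ref_seq)
  rows <- lapply(seq_len(nrow(collapsed)), function(i) {
    map_hits_one(collapsed$sequence[i], collapsed$count[i], subject, ref_seq,
                 ref_name, 0L, "+")
  })
  out <- do.call(rbind, c(list(empty_hits()), rows))
  rownames(out) <- NULL
  out
}

#' Map reads onto a transcript allowing mismatches
#'
#' Gap-free alignment at every offset on the sense and (by default) the
#' antisense strand, keeping hits with Hamming distance at most `max_mm`.
#'
#' @param collapsed collapsed library (`sequence`, `count`).
#' @param transcript reference sequence (character, optionally named) or a
#'   single-row `data.frame` from [read_fasta()].
#' @param max_mm maximum mismatches (default 4).
#' @param strands `"both"`, `"sense"` or `"antisense"`.
#' @return hits `data.frame` as in [map_exact()], with `mismatches` filled
#'   and `strand` in `{"+", "-"}`.
#' @export
map_mismatch <- function(collapsed, transcript, max_mm = 4,
                         strands = c("both", "sense", "antisense")) {
  strands <- match.arg(strands)
  stopifnot(max_mm >= 0)
  if (is.data.frame(transcript)) {
    ref_name <- transcript$id[1L]
    ref_seq <- transcript$sequence[1L]
  } else {
    ref_name <- if (!is.null(names(transcript))) names(transcript)[1L] else "reference"
    ref_seq <- normalize_seq(transcript[[1L]])
  }
  subject <- Biostrings::DNAString(ref_seq)
  want <- switch(strands, both = c("+", "-"), sense = "+", antisense = "-")
  rows <- list(empty_hits())
  for (i in seq_len(nrow(collapsed))) {
    for (s in want) {
      rows[[length(rows) + 1L]] <- map_hits_one(
        collapsed$sequence[i], collapsed$count[i], subject, ref_seq,
        ref_name, as.integer(max_mm), s)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-position read depth on a hairpin
#'
#' `depth[i]` sums the counts of all reads covering position `i`, so that
#' `sum(depth)` equals `sum(count * read length)` over the hits.
#'
#' @param mapped hits `data.frame` (from [map_exact()]).
#' @param hp the [hairpin()] the hits refer to.
#' @return integer vector of length `nchar(hp$sequence)`.
#' @export
coverage_profile <- function(mapped, hp) {
  stopifnot(inherits(hp, "hairpin"))
  depth <- integer(nchar(hp$sequence))
  for (i in seq_len(nrow(mapped))) {
    idx <- mapped$start[i]:mapped$end[i]
    depth[idx] <- depth[idx] + mapped$count[i]
  }
  depth
}

#' Scan for secondary (phased) siRNAs outside the primary amiRNA site
#'
#' Maps the abundance-filtered library onto a target transcript (both
#' strands, mismatch-tolerant) and returns hits falling outside the primary
#' small-RNA complementary site. An empty result mirrors the absence of
#' transitive phasiRNA production from the target.
#'
#' @param collapsed collapsed library.
#' @param transcript target transcript (character or [read_fasta()] row).
#' @param primary_site_interval integer `c(start, end)` of the primary
#'   amiRNA complementary site on the transcript.
#' @param min_reads abundance floor (default 5).
#' @param max_mm maximum mismatches (default 4).
#' @return hits `data.frame`; zero rows means no secondary siRNAs.
#' @export
secondary_sirna_scan <- function(collapsed, transcript, primary_site_interval,
                                 min_reads = 5, max_mm = 4) {
  stopifnot(length(primary_site_interval) == 2L)
  lib <- abundance_filter(collapsed, min_reads)
  if (nrow(lib) == 0L) return(empty_hits())
  hits <- map_mismatch(lib, transcript, max_mm = max_mm, strands = "both")
  keep <- hits$end < primary_site_interval[1L] |
    hits$start > primary_site_interval[2L]
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
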