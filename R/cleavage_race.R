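# 5'-RACE cleavage-site mapping and processing-intermediate analysis.
#
# A cleavage position is encoded as the 1-based index of the FIRST
# nucleotide of the downstream (3') fragment -- the base a 5'-RACE adapter
# ligates to. Slicer cleavage is expected between the target bases pairing
# positions 10 and 11 of the guide small RNA.

#' Map 5' ends of RACE fragments onto a reference
#'
#' Each fragment is anchored by an exact match of its 5'-terminal k-mer
#' (left-most occurrence); clones are aggregated per anchored position.
#' Fragments whose anchor does not occur are counted as non-specific
#' amplification products.
#'
#' @param race_reads character vector of fragment sequences (adapter
#'   removed; the 5' end is the ligation point), or a `data.frame` with a
#'   `sequence` column.
#' @param reference reference sequence (character, optionally named).
#' @param k anchor length (default 20).
#' @return list with `sites` (`ref`, `position`, `clones`, sorted by
#'   position), `nonspecific` (count) and `n_mapped`.
#' @export
map_5p_ends <- function(race_reads, reference, k = 20) {
  if (is.data.frame(race_reads)) race_reads <- race_reads$sequence
  ref_name <- if (!is.null(names(reference))) names(reference)[1L] else "reference"
  ref_seq <- normalize_seq(reference[[1L]])
  if (nchar(ref_seq) < k) stop("reference shorter than anchor length k = ", k)
  race_reads <- normalize_seq(race_reads)
  pos <- vapply(race_reads, function(sq) {
    if (nchar(sq) < k) return(NA_integer_)
    at <- regexpr(substr(sq, 1L, k), ref_seq, fixed = TRUE)
    if (at > 0L) as.integer(at) else NA_integer_
  }, 0L, USE.NAMES = FALSE)
  ok <- !is.na(pos)
  sites <- data.frame(ref = character(0), position = integer(0),
                      clones = integer(0), stringsAsFactors = FALSE)
  if (any(ok)) {
    agg <- table(pos[ok])
    sites <- data.frame(ref = ref_name,
                        position = as.integer(names(agg)),
                        clones = as.integer(agg), stringsAsFactors = FALSE)
    sites <- sites[order(sites$position), , drop = FALSE]
    rownames(sites) <- NULL
  }
  list(sites = sites, nonspecific = sum(!ok), n_mapped = sum(ok))
}

#' Expected slicer cleavage position on the target
#'
#' For a gap-free antiparallel duplex of a small RNA (length L) with a
#' target site starting at `offset`, position p of the small RNA pairs
#' target position `offset + L - p`. Cleavage between the bases opposite
#' positions 10 and 11 leaves a downstream fragment whose first base pairs
#' position 10, i.e. `offset + L - 10`.
#'
#' @param smallrna the guide sequence, or a `duplex_alignment` from
#'   [align_duplex()] (in which case `offset` is taken from it).
#' @param offset 1-based start of the target site on the transcript.
#' @return integer position of the first base of the 3' cleavage fragment.
#' @export
#' @examples
#' canonical_site(strrep("A", 21), offset = 1)  # 12
canonical_site <- function(smallrna, offset = NULL) {
  if (inherits(smallrna, "duplex_alignment")) {
    offset <- smallrna$offset
    L <- length(smallrna$states)
  } else {
    L <- nchar(smallrna)
  }
  if (is.null(offset)) stop("offset is required")
  if (L < 11L) stop("alignment shorter than 11 positions")
  as.integer(offset + L - 10L)
}

#' Classify cleavage sites against the canonical position
#'
#' Partitions clone counts into those at, upstream (5', smaller coordinate)
#' of, and downstream (3') of the canonical slicer position.
#'
#' @param sites sites `data.frame` from [map_5p_ends()] (or with `position`
#'   and `clones` columns).
#' @param canonical canonical position from [canonical_site()].
#' @return named integer vector `c(at, upstream, downstream)`.
#' @export
classify_sites <- function(sites, canonical) {
  if (is.list(sites) && !is.data.frame(sites) && !is.null(sites$sites)) {
    sites <- sites$sites
  }
  if (nrow(sites) == 0L) {
    return(c(at = 0L, upstream = 0L, downstream = 0L))
  }
  c(at = sum(sites$clones[sites$position == canonical]),
    upstream = sum(sites$clones[sites$position < canonical]),
    downstream = sum(sites$clones[sites$position > canonical]))
}

#' Processing-intermediate spacing and direction on a hairpin
#'
#' Orders cleavage sites by increasing distance from the annotated terminal
#' loop, reports successive distances, flags those outside the 20-23 nt
#' range typical of sequential DICER-LIKE cuts, and infers the processing
#' direction: `"loop-to-base"` when all sites fall on one arm of the
#' hairpin, `"undetermined"` otherwise.
#'
#' @param hairpin_sites numeric vector of cleavage positions (or a sites
#'   `data.frame` with a `position` column).
#' @param hp [hairpin()] with a region named `"loop"`.
#' @param expected_range distances outside this window are flagged.
#' @return list of class `intermediate_profile`: `positions` (ordered
#'   loop-proximal first), `distances`, `direction`, `within_range`.
#' @export
intermediate_profile <- function(hairpin_sites, hp,
                                 expected_range = c(20, 23)) {
  if (is.data.frame(hairpin_sites)) hairpin_sites <- hairpin_sites$position
  stopifnot(inherits(hp, "hairpin"))
  if (length(hairpin_sites) < 2L) stop("need at least 2 cleavage sites")
  n <- nchar(hp$sequence)
  if (any(hairpin_sites < 1L | hairpin_sites > n)) {
    stop("cleavage sites fall outside the hairpin")
  }
  loop <- hairpin_region(hp, "loop")
  arm3 <- all(hairpin_sites > loop["end"])
  arm5 <- all(hairpin_sites < loop["start"])
  if (arm3) {
    positions <- sort(hairpin_sites)            # loop-proximal first
    direction <- "loop-to-base"
  } else if (arm5) {
    positions <- sort(hairpin_sites, decreasing = TRUE)
    direction <- "loop-to-base"
  } else {
    positions <- sort(hairpin_sites)
    direction <- "undetermined"
  }
  distances <- abs(diff(positions))
  structure(list(positions = positions, distances = distances,
                 direction = direction,
                 within_range = distances >= expected_range[1L] &
                   distances <= expected_range[2L]),
            class = "intermediate_profile")
}

#' @export
print.intermediate_profile <- function(x, ...) {
  cat("<intermediate_profile> ", length(x$positions), " sites, direction: ",
      x$direction, "\n  distances: ", paste(x$distances, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
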