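# Quality, adapter, length and abundance filtering of raw small-RNA reads.

#' Filtering configuration for raw small-RNA reads
#'
#' Defaults correspond to a standard plant small-RNA workflow: drop reads of
#' mean Phred below 20, drop reads containing N, trim the 3' adapter, keep
#' 18-32 nt inserts, and (after collapsing) keep sequences supported by at
#' least 5 reads.
#'
#' @param min_quality Phred threshold; reads failing the quality rule are
#'   rejected. 0 disables the rule.
#' @param min_len,max_len insert length bounds (nt), inclusive.
#' @param adapter optional 3' adapter sequence to trim.
#' @param min_reads abundance floor applied by [abundance_filter()].
#' @param quality_mode `"mean"` rejects reads whose mean Phred is below
#'   `min_quality`; `"min"` rejects reads with any base below it.
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(min_quality = 20, min_len = 18, max_len = 32,
                          adapter = NULL, min_reads = 5,
                          quality_mode = c("mean", "min")) {
  quality_mode <- match.arg(quality_mode)
  stopifnot(min_len <= max_len, min_quality >= 0, min_reads >= 1)
  structure(list(min_quality = min_quality, min_len = min_len,
                 max_len = max_len,
                 adapter = if (is.null(adapter)) NULL else normalize_seq(adapter),
                 min_reads = min_reads, quality_mode = quality_mode),
            class = "filter_config")
}

# Position at which the 3' adapter starts within a read, or NA.
# Exact match of the adapter's first 8 nt, searched in the 3' half of the
# read (adapter read-through lands there for small-RNA inserts).
adapter_hit <- function(sequence, adapter) {
  probe <- substr(adapter, 1L, min(8L, nchar(adapter)))
  n <- nchar(sequence)
  from <- n %/% 2L + 1L
  if (from > n) return(NA_integer_)
  m <- regexpr(probe, substr(sequence, from, n), fixed = TRUE)
  if (m < 0L) NA_integer_ else from + as.integer(m) - 1L
}

#' Filter raw reads by quality, ambiguity, adapter and length
#'
#' Rules are applied in a fixed order (quality, ambiguous bases, adapter
#' trimming, length) and every rejected read is attributed to the first rule
#' it fails, so that `nrow(kept) + sum(rejected)` always equals the input
#' size. Adapter matching trims at the first exact occurrence of the
#' adapter's leading 8 nt within the 3' half of the read; reads without an
#' adapter hit are kept untrimmed and counted in `no_adapter`.
#'
#' @param records read `data.frame` from [read_fastq()] (or [read_fasta()]
#'   when `min_quality = 0`).
#' @param config a [filter_config()].
#' @return a list with `kept` (filtered, trimmed records), `rejected`
#'   (named integer vector: `quality`, `ambiguous`, `length`) and
#'   `no_adapter` (informational count of kept reads lacking an adapter hit).
#' @export
filter_reads <- function(records, config = filter_config()) {
  stopifnot(is.data.frame(records), "sequence" %in% names(records))
  stopifnot(inherits(config, "filter_config"))
  seqs <- normalize_seq(records$sequence)
  n <- length(seqs)
  alive <- rep(TRUE, n)
  rejected <- c(quality = 0L, ambiguous = 0L, length = 0L)

  if (config$min_quality > 0) {
    if (is.null(records$quality)) {
      stop("min_quality > 0 but records carry no qualities")
    }
    stat <- vapply(records$quality,
                   if (config$quality_mode == "mean") mean else min, 0)
    bad <- alive & stat < config$min_quality
    rejected["quality"] <- sum(bad)
    alive[bad] <- FALSE
  }

  bad <- alive & grepl("N", seqs, fixed = TRUE)
  rejected["ambiguous"] <- sum(bad)
  alive[bad] <- FALSE

  no_adapter <- 0L
  if (!is.null(config$adapter)) {
    for (i in which(alive)) {
      at <- adapter_hit(seqs[i], config$adapter)
      if (is.na(at)) {
        no_adapter <- no_adapter + 1L
      } else {
        seqs[i] <- substr(seqs[i], 1L, at - 1L)
        if (!is.null(records$quality)) {
          records$quality[[i]] <- records$quality[[i]][seq_len(at - 1L)]
        }
      }
    }
  }

  len <- nchar(seqs)
  bad <- alive & (len < config$min_len | len > config$max_len)
  rejected["length"] <- sum(bad)
  alive[bad] <- FALSE

  kept <- records[alive, , drop = FALSE]
  kept$sequence <- seqs[alive]
  rownames(kept) <- NULL
  list(kept = kept, rejected = rejected, no_adapter = no_adapter)
}

#' Abundance filter on a collapsed library
#'
#' Keeps unique sequences supported by at least `min_reads` reads. The
#' default floor of 5 keeps sequences cloned 5 or more times, the operative
#' reading of "more than five reads" used throughout: the printed tailed
#' variant tables contain 5-read entries.
#'
#' @param collapsed collapsed library (`sequence`, `count`).
#' @param min_reads minimum count kept.
#' @return subset of `collapsed`.
#' @export
abundance_filter <- function(collapsed, min_reads = 5) {
  stopifnot(all(c("sequence", "count") %in% names(collapsed)), min_reads >= 1)
  out <- collapsed[collapsed$count >= min_reads, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read-length distribution of a collapsed library
#'
#' @param collapsed collapsed library (`sequence`, `count`).
#' @return named integer vector mapping length (nt) to total reads, with the
#'   modal length(s) in attribute `modes`.
#' @export
size_distribution <- function(collapsed) {
  stopifnot(all(c("sequence", "count") %in% names(collapsed)))
  if (nrow(collapsed) == 0L) {
    return(structure(integer(0), modes = integer(0)))
  }
  len <- nchar(collapsed$sequence)
  agg <- tapply(collapsed$count, len, sum)
  out <- as.integer(agg)
  names(out) <- names(agg)
  out <- out[order(as.integer(names(out)))]
  attr(out, "modes") <- as.integer(names(out)[out == max(out)])
  out
}
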