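# Decomposition of non-matching reads into a 5' genome-matched component
# (5GMC) plus a non-templated 3' tail, and Table-style tailing reports.
#
# The 5GMC is the longest prefix of the read that occurs exactly in the
# precursor (left-most occurrence on ties). By maximality, the first tail
# base always differs from the templated base following the 5GMC -- except
# when the 5GMC ends at the precursor 3' terminus, where any appended bases
# are treated as tail.

#' Decompose reads into 5' genome-matched component and 3' tail
#'
#' For each read that does not match the precursor in full, the longest
#' exactly-matching prefix is located. A tailed variant is emitted when that
#' prefix is at least `min_gmc` nt and the remainder is between 1 and
#' `max_tail` nt; otherwise the read is reported as unexplained (reason
#' `"short_gmc"` or `"long_tail"`), never silently dropped. Reads that match
#' in full are returned under reason `"templated"` (they belong to
#' [map_exact()], not here).
#'
#' @param collapsed collapsed library (`sequence`, `count`).
#' @param hp the precursor [hairpin()].
#' @param min_gmc minimum 5GMC length (nt, default 17).
#' @param max_tail maximum tail length (nt, default 3).
#' @param blocks optional blocks `data.frame`; when given, each variant's
#'   5GMC interval is labelled via [assign_block()].
#' @param b3plus optional B3+ rule, see [assign_block()].
#' @return list with `variants` (`sequence`, `count`, `gmc_start`,
#'   `gmc_end`, `gmc_len`, `gmc`, `tail`, `block`) and `unexplained`
#'   (`sequence`, `count`, `reason`).
#' @export
decompose_tail <- function(collapsed, hp, min_gmc = 17, max_tail = 3,
                           blocks = NULL, b3plus = NULL) {
  stopifnot(inherits(hp, "hairpin"))
  ref <- hp$sequence
  vrows <- list(); urows <- list()
  for (i in seq_len(nrow(collapsed))) {
    sq <- normalize_seq(collapsed$sequence[i])
    ct <- collapsed$count[i]
    L <- nchar(sq)
    if (regexpr(sq, ref, fixed = TRUE) > 0L) {
      urows[[length(urows) + 1L]] <- data.frame(
        sequence = sq, count = ct, reason = "templated",
        stringsAsFactors = FALSE)
      next
    }
    gmc_len <- 0L; gmc_start <- NA_integer_
    for (k in if (L >= 2L) seq.int(L - 1L, 1L) else integer(0)) {
      at <- regexpr(substr(sq, 1L, k), ref, fixed = TRUE)
      if (at > 0L) { gmc_len <- k; gmc_start <- as.integer(at); break }
    }
    tail_len <- L - gmc_len
    if (gmc_len < min_gmc) {
      urows[[length(urows) + 1L]] <- data.frame(
        sequence = sq, count = ct, reason = "short_gmc",
        stringsAsFactors = FALSE)
    } else if (tail_len > max_tail) {
      urows[[length(urows) + 1L]] <- data.frame(
        sequence = sq, count = ct, reason = "long_tail",
        stringsAsFactors = FALSE)
    } else {
      vrows[[length(vrows) + 1L]] <- data.frame(
        sequence = sq, count = ct,
        gmc_start = gmc_start, gmc_end = gmc_start + gmc_len - 1L,
        gmc_len = gmc_len,
        gmc = substr(sq, 1L, gmc_len),
        tail = substr(sq, gmc_len + 1L, L),
        stringsAsFactors = FALSE)
    }
  }
  variants <- do.call(rbind, c(list(data.frame(
    sequence = character(0), count = integer(0), gmc_start = integer(0),
    gmc_end = integer(0), gmc_len = integer(0), gmc = character(0),
    tail = character(0), stringsAsFactors = FALSE)), vrows))
  if (!is.null(blocks) && nrow(variants)) {
    iv <- data.frame(start = variants$gmc_start, end = variants$gmc_end)
    asg <- assign_block(iv, blocks, b3plus = b3plus)
    variants$block <- asg$block
  } else {
    variants$block <- rep(NA_character_, nrow(variants))
  }
  unexplained <- do.call(rbind, c(list(data.frame(
    sequence = character(0), count = integer(0), reason = character(0),
    stringsAsFactors = FALSE)), urows))
  rownames(variants) <- rownames(unexplained) <- NULL
  list(variants = variants, unexplained = unexplained)
}

#' Nucleotide composition of 3' tails
#'
#' Each tail contributes each of its nucleotides, weighted by the variant's
#' read count (unless `weight_by_reads = FALSE`). Percentages are reported
#' in the RNA alphabet (T counted as U) and sum to 100.
#'
#' @param variants variants `data.frame` from [decompose_tail()].
#' @param weight_by_reads weight each tail by its read count (default TRUE).
#' @return named numeric vector of percentages over `c(U, A, C, G)`.
#' @export
tail_composition <- function(variants, weight_by_reads = TRUE) {
  if (nrow(variants) == 0L) stop("no tailed variants supplied")
  w <- if (weight_by_reads) variants$count else rep(1L, nrow(variants))
  nts <- strsplit(normalize_seq(variants$tail, "RNA"), "", fixed = TRUE)
  tot <- c(U = 0, A = 0, C = 0, G = 0)
  for (i in seq_along(nts)) {
    for (b in nts[[i]]) tot[b] <- tot[b] + w[i]
  }
  100 * tot / sum(tot)
}

#' Distribution of tail lengths
#'
#' @param variants variants `data.frame` from [decompose_tail()].
#' @param weight_by_reads weight by read counts (default TRUE).
#' @return named integer vector mapping tail length (nt) to reads.
#' @export
tail_length_distribution <- function(variants, weight_by_reads = TRUE) {
  if (nrow(variants) == 0L) return(integer(0))
  w <- if (weight_by_reads) variants$count else rep(1L, nrow(variants))
  agg <- tapply(w, nchar(variants$tail), sum)
  out <- as.integer(agg)
  names(out) <- names(agg)
  out[order(as.integer(names(out)))]
}

#' Tabulate tailed variants per block
#'
#' Renders a per-block report in the style of a published tailed-variant
#' table: the 5GMC in lower case with the tail capitalized, read counts,
#' block label, and the block's total tailed reads.
#'
#' @param variants block-labelled variants from [decompose_tail()].
#' @return `data.frame` with columns `sequence`, `reads`, `block`,
#'   `block_total`, sorted by block (canonical miR319 order) and then by
#'   decreasing reads.
#' @export
tabulate_tailed <- function(variants) {
  stopifnot(nrow(variants) > 0L, !anyNA(variants$block))
  out <- data.frame(
    sequence = paste0(tolower(variants$gmc), toupper(variants$tail)),
    reads = variants$count,
    block = variants$block,
    stringsAsFactors = FALSE)
  totals <- tapply(out$reads, out$block, sum)
  out$block_total <- as.integer(totals[out$block])
  out <- out[order(block_rank(out$block), -out$reads, out$sequence), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
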