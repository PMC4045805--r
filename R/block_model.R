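# Block-wise classification of precursor-derived small RNAs.
#
# A block is a precursor region with a representative sequence (the most
# abundant small RNA of the region). A read belongs to a block when its
# mapped interval overlaps the representative interval by MORE than 15 nt
# (i.e. >= 16) and extends no more than 6 nt beyond it at either end.
# Block naming follows the miR319-family convention: B1/B1* are the
# miRNA/miRNA* duplex regions at the hairpin base, B2/B2* the loop-proximal
# duplex, B3/B3* the regions in between, and B3+ holds reads that start in
# B3 but whose 3' ends stretch into the middle of B1.

#' Select block representatives from mapped reads
#'
#' Within each hinted region, the highest-count read becomes the block
#' representative; ties are broken by longer read, then lexicographically.
#' Reads are attributed to the hint region with which their mapped interval
#' overlaps most.
#'
#' @param mapped hits `data.frame` from [map_exact()] on one precursor.
#' @param region_hints `data.frame` with columns `region`, `start`, `end`
#'   (coarse intervals, e.g. arms/blocks from a structure annotation).
#' @return blocks `data.frame`: `name`, `representative`, `rep_start`,
#'   `rep_end`. Regions without mapped reads are omitted with a warning.
#' @export
select_representatives <- function(mapped, region_hints) {
  stopifnot(all(c("region", "start", "end") %in% names(region_hints)))
  if (nrow(mapped) == 0L) stop("no mapped reads supplied")
  ov <- function(a1, a2, b1, b2) pmax(0L, pmin(a2, b2) - pmax(a1, b1) + 1L)
  blocks <- list()
  for (r in seq_len(nrow(region_hints))) {
    hint <- region_hints[r, ]
    ovs <- ov(mapped$start, mapped$end, hint$start, hint$end)
    # a read belongs to the hint it overlaps most; demand majority overlap
    best_hint <- vapply(seq_len(nrow(mapped)), function(i) {
      all_ov <- ov(mapped$start[i], mapped$end[i],
                   region_hints$start, region_hints$end)
      which.max(all_ov)
    }, 0L)
    cand <- mapped[ovs > 0L & best_hint == r, , drop = FALSE]
    if (nrow(cand) == 0L) {
      warning("region '", hint$region, "' has no mapped reads; omitted")
      next
    }
    cand <- cand[order(-cand$count, -nchar(cand$sequence), cand$sequence), ,
                 drop = FALSE]
    blocks[[length(blocks) + 1L]] <- data.frame(
      name = hint$region, representative = cand$sequence[1L],
      rep_start = cand$start[1L], rep_end = cand$end[1L],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Assign mapped reads to precursor blocks
#'
#' Implements the block membership rule: a read is assigned to a block iff
#' its precursor interval overlaps the representative interval by at least
#' `min_overlap` nt (default 16, i.e. "more than 15") AND extends no more
#' than `max_extension` nt (default 6) beyond the representative at either
#' end. When several blocks qualify, the largest overlap wins (ties go to
#' the left-most block). The special B3+ category is evaluated first when
#' `b3plus` is given: a read whose start lies within the B3 region and whose
#' end reaches at least 1 nt into B1 is labelled `"B3+"` so it is not
#' swallowed by B1's extension allowance.
#'
#' @param mapped hits `data.frame` (needs `start`, `end`; `sequence` and
#'   `count` are carried through when present).
#' @param blocks blocks `data.frame` from [select_representatives()] (or
#'   hand-built: `name`, `representative`, `rep_start`, `rep_end`).
#' @param b3plus optional list `list(b3 = c(start, end), b1_start = pos)`
#'   activating the B3+ rule.
#' @param min_overlap minimum overlap (nt) with the representative.
#' @param max_extension maximum extension (nt) beyond either end.
#' @return `mapped` with added columns `block` (name or `"unassigned"`),
#'   `overlap`, `left_ext`, `right_ext` (relative to the winning block's
#'   representative; for B3+ reads, relative to the B3 block when defined).
#' @export
assign_block <- function(mapped, blocks, b3plus = NULL,
                         min_overlap = 16, max_extension = 6) {
  stopifnot(all(c("start", "end") %in% names(mapped)),
            all(c("name", "rep_start", "rep_end") %in% names(blocks)))
  n <- nrow(mapped)
  block <- rep("unassigned", n)
  overlap <- integer(n); lext <- integer(n); rext <- integer(n)
  for (i in seq_len(n)) {
    s <- mapped$start[i]; e <- mapped$end[i]
    if (!is.null(b3plus) &&
        s >= b3plus$b3[1L] && s <= b3plus$b3[2L] && e >= b3plus$b1_start) {
      block[i] <- "B3+"
      ref <- blocks[blocks$name == "B3", , drop = FALSE]
      if (nrow(ref)) {
        overlap[i] <- max(0L, min(e, ref$rep_end) - max(s, ref$rep_start) + 1L)
        lext[i] <- max(0L, ref$rep_start - s)
        rext[i] <- max(0L, e - ref$rep_end)
      } else {
        overlap[i] <- NA_integer_; lext[i] <- NA_integer_; rext[i] <- NA_integer_
      }
      next
    }
    ov <- pmax(0L, pmin(e, blocks$rep_end) - pmax(s, blocks$rep_start) + 1L)
    le <- pmax(0L, blocks$rep_start - s)
    re <- pmax(0L, e - blocks$rep_end)
    ok <- ov >= min_overlap & le <= max_extension & re <= max_extension
    if (any(ok)) {
      cand <- which(ok)
      cand <- cand[order(-ov[cand], blocks$rep_start[cand])]
      j <- cand[1L]
      block[i] <- blocks$name[j]
      overlap[i] <- ov[j]; lext[i] <- le[j]; rext[i] <- re[j]
    }
  }
  out <- mapped
  out$block <- block
  out$overlap <- overlap
  out$left_ext <- lext
  out$right_ext <- rext
  out
}

#' Relative block proportions
#'
#' Fractions are computed over read counts (not unique sequences). With
#' `denominator = "matched"` (default) the denominator is every mapped read
#' including unassigned ones, which are reported as their own row; with
#' `"assigned"` only block-assigned reads enter and the fractions sum to 1.
#'
#' @param assignments output of [assign_block()] with a `count` column.
#' @param denominator `"matched"` or `"assigned"`.
#' @return `data.frame` with columns `block`, `reads`, `fraction`.
#' @export
block_proportions <- function(assignments, denominator = c("matched", "assigned")) {
  denominator <- match.arg(denominator)
  stopifnot(all(c("block", "count") %in% names(assignments)))
  assigned <- assignments[assignments$block != "unassigned", , drop = FALSE]
  if (nrow(assigned) == 0L) stop("no reads were assigned to any block")
  use <- if (denominator == "matched") assignments else assigned
  agg <- tapply(use$count, use$block, sum)
  out <- data.frame(block = names(agg), reads = as.integer(agg),
                    stringsAsFactors = FALSE)
  out$fraction <- out$reads / sum(out$reads)
  out <- out[order(block_rank(out$block)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# canonical ordering for miR319-style block names; unknown names go last,
# alphabetically
block_rank <- function(x) {
  canon <- c("B1", "B1*", "B2", "B2*", "B3", "B3*", "B3+", "unassigned")
  r <- match(x, canon)
  r[is.na(r)] <- length(canon) + rank(x[is.na(r)])
  r
}
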