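# Shared fixtures and independent brute-force oracles. The oracles
# re-derive expected results by direct enumeration and stay independent of
# the implementation paths they check.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# all gap-free alignments of `read` on `ref` (both strands) with Hamming
# distance <= max_mm, by scanning every offset
brute_hamming_hits <- function(read, ref, max_mm, strands = c("+", "-")) {
  ref_ch <- strsplit(ref, "")[[1]]
  out <- list()
  for (s in strands) {
    pat <- if (s == "-") revcomp(read) else read
    pat_ch <- strsplit(pat, "")[[1]]
    L <- length(pat_ch)
    if (L > length(ref_ch)) next
    for (off in seq_len(length(ref_ch) - L + 1)) {
      mm <- sum(ref_ch[off:(off + L - 1)] != pat_ch)
      if (mm <= max_mm) {
        out[[length(out) + 1]] <- data.frame(
          start = off, end = off + L - 1, strand = s, mismatches = mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(list(data.frame(start = integer(0), end = integer(0),
                                   strand = character(0),
                                   mismatches = integer(0))), out))
}

# direct evaluation of the block-membership predicate for one read interval
# against one representative interval
brute_block_member <- function(s, e, rep_s, rep_e,
                               min_overlap = 16, max_extension = 6) {
  ov <- min(e, rep_e) - max(s, rep_s) + 1
  lext <- max(0, rep_s - s)
  rext <- max(0, e - rep_e)
  ov >= min_overlap && lext <= max_extension && rext <= max_extension
}

table2_library <- function() {
  tab <- tailed_variant_table("amirchs1")
  data.frame(sequence = tab$sequence, count = tab$reads,
             stringsAsFactors = FALSE)
}

table3_library <- function() {
  tab <- tailed_variant_table("phy")
  data.frame(sequence = tab$sequence, count = tab$reads,
             stringsAsFactors = FALSE)
}
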