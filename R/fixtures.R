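# Packaged worked-example data: the amiRchs1 artificial miRNA (miR319a
# backbone), the published tailed-variant tables, and SYNTHETIC precursor
# scaffolds stitched in code from the cloning-primer sequences plus the
# sequenced reads. The full precursor sequences were never published, so the
# scaffolds are reconstructions that preserve exactly the local sequence
# context the analyses depend on (block geometry, templated/tail junctions);
# linker, loop and star-arm filler segments are invented and marked so.

#' The amiRchs1 artificial miRNA sequence
#'
#' The 21-nt guide designed against petunia chalcone synthase transcripts,
#' as it appears (DNA alphabet) in the cloning primers.
#'
#' @return character scalar.
#' @export
amirchs1_sequence <- function() "TGTTGGTACATCATGAGTCGC"

#' Cloning primers used to build the amiRchs1 precursor
#'
#' @return `data.frame` with columns `name`, `sequence`, `comment`.
#' @export
study_primers <- function() {
  read_table(system.file("extdata", "primers.tsv", package = "amiRtrace",
                         mustWork = TRUE))
}

#' Published tailed-variant tables
#'
#' The unique 3'-tailed small-RNA sequences (tail capitalized) with read
#' counts recovered from an amiRchs1-transgenic petunia petal library, for
#' the amiRchs1 precursor (27 variants) and the endogenous phy-miR319a
#' precursor (11 variants). The `position` column is the block label
#' reported with the data; the package re-derives it independently.
#'
#' @param which `"amirchs1"` or `"phy"`.
#' @return `data.frame` with columns `id`, `sequence`, `reads`, `position`.
#' @export
tailed_variant_table <- function(which = c("amirchs1", "phy")) {
  which <- match.arg(which)
  file <- c(amirchs1 = "amirchs1_tailed.tsv", phy = "phy_tailed.tsv")[[which]]
  read_table(system.file("extdata", file, package = "amiRtrace",
                         mustWork = TRUE))
}

# merge two sequences over their maximal exact suffix/prefix overlap
merge_overlap <- function(a, b, min_overlap = 12L) {
  a <- normalize_seq(a); b <- normalize_seq(b)
  for (k in seq.int(min(nchar(a), nchar(b)), min_overlap)) {
    if (substr(a, nchar(a) - k + 1L, nchar(a)) == substr(b, 1L, k)) {
      return(paste0(a, substr(b, k + 1L, nchar(b))))
    }
  }
  stop("sequences do not overlap by at least ", min_overlap, " nt")
}

region_df <- function(seqs, names_, full) {
  start <- vapply(seqs, function(s) as.integer(regexpr(s, full, fixed = TRUE)),
                  0L, USE.NAMES = FALSE)
  if (any(start < 1L)) stop("internal error: scaffold region not found")
  data.frame(region = names_, start = start,
             end = start + nchar(seqs) - 1L, stringsAsFactors = FALSE)
}

#' Synthetic amiRchs1 precursor scaffold
#'
#' Reconstructs the precursor context around the amiRchs1/amiRchs1* duplex
#' from the overlap-PCR primers (5' arm: revcomp(IV) merged with III;
#' 3' arm: revcomp(II) merged with I), places the backbone-derived B2 and B3
#' segments recovered from the sequenced tailed reads between them, and
#' fills the star-side B2*/B3* segments and the terminal loop with synthetic
#' sequence. Block representatives and the B3+ rule are attached.
#'
#' @return list with `hairpin` (a [hairpin()] with regions incl. `"loop"`),
#'   `blocks` (for [assign_block()]) and `b3plus` (the B3+ rule).
#' @export
amirchs1_scaffold <- function() {
  pr <- study_primers()
  p <- setNames(normalize_seq(pr$sequence), pr$name)
  arm5 <- merge_overlap(revcomp(p[["amiRchs1-IV"]]), p[["amiRchs1-III"]])
  arm3 <- merge_overlap(revcomp(p[["amiRchs1-II"]]), p[["amiRchs1-I"]])
  b2 <- "AATGAATGATGCGGTAGACAAAT"      # backbone B2 region, from reads
  # 3' arm: B2 then B3 running into B1 (the B3+ reads span this junction);
  # arm3 begins inside B3 ("tcattgattctcttt..."), so only its overhang is new
  arm3_full <- merge_overlap(paste0(b2, "TGGATCATTGATTCTCTTT"), arm3)
  # synthetic star-side filler and loop (invented; nothing maps here)
  b3star_fill <- "CGTGTCATCTT"
  b2star <- "ATTCGTCTACCGCATCATACATT"   # mutated revcomp of B2 (synthetic)
  loop <- "GTCCAATCTTGG"
  full <- paste0(arm5, b3star_fill, b2star, loop, arm3_full)

  rep_b1 <- amirchs1_sequence()
  rep_b1s <- "AACTCATGATGAACCAACTTC"
  rep_b2 <- "AATGAATGATGCGGTAGACAA"
  rep_b3 <- "TTGGATCATTGATTCTCTTT"
  reps <- c(rep_b1, rep_b1s, rep_b2, rep_b3, b2star)
  bdf <- region_df(reps, c("B1", "B1*", "B2", "B3", "B2*"), full)
  blocks <- data.frame(name = bdf$region, representative = reps,
                       rep_start = bdf$start, rep_end = bdf$end,
                       stringsAsFactors = FALSE)
  regions <- region_df(
    c(rep_b1s, paste0(b3star_fill), b2star, loop, b2, rep_b3, rep_b1),
    c("B1*", "B3*", "B2*", "loop", "B2", "B3", "B1"), full)
  hp <- hairpin("amiRchs1_scaffold", full, regions = regions)
  b1_start <- regions$start[regions$region == "B1"]
  b3 <- regions[regions$region == "B3", ]
  list(hairpin = hp, blocks = blocks,
       b3plus = list(b3 = c(b3$start, b3$end), b1_start = b1_start))
}

#' Synthetic phy-miR319a precursor scaffold
#'
#' Minimal reconstruction of the endogenous petunia miR319a precursor
#' around its B1 (mature miR319) and B1* regions, built from the sequenced
#' tailed reads; the mid-hairpin segments and loop are synthetic filler.
#'
#' @return list with `hairpin` and `blocks` as in [amirchs1_scaffold()].
#' @export
phy_mir319a_scaffold <- function() {
  rep_b1s <- "ATTCAACGATGCATGAGCTGT"   # star arm, from reads
  rep_b1 <- "TTGGACTGAAGGGAGCTCCCT"    # mature miR319
  arm5 <- paste0("GCGAACC", rep_b1s, "A")
  filler <- "CATCGTACGTACCTAGG"        # synthetic mid-hairpin
  loop <- "GTTCAAGTCG"                 # synthetic loop
  arm3 <- paste0("C", rep_b1, "G", "AATCGA")
  full <- paste0(arm5, filler, loop, "CAGGTACGTACGATGC", arm3)
  blocks <- region_df(c(rep_b1, rep_b1s), c("B1", "B1*"), full)
  blocks <- data.frame(name = blocks$region,
                       representative = c(rep_b1, rep_b1s),
                       rep_start = blocks$start, rep_end = blocks$end,
                       stringsAsFactors = FALSE)
  regions <- region_df(c(rep_b1s, loop, rep_b1),
                       c("B1*", "loop", "B1"), full)
  hp <- hairpin("phy_miR319a_scaffold", full, regions = regions)
  list(hairpin = hp, blocks = blocks)
}

#' Bundle of packaged fixtures
#'
#' Convenience accessor returning the published tables, both precursor
#' scaffolds and the amiRchs1 sequence; optionally writes them to `dir` as
#' FASTA/TSV.
#'
#' @param dir optional output directory.
#' @return list: `table_amirchs1`, `table_phy`, `amirchs1`, `scaffold`,
#'   `phy_scaffold`.
#' @export
make_fixtures <- function(dir = NULL) {
  fx <- list(table_amirchs1 = tailed_variant_table("amirchs1"),
             table_phy = tailed_variant_table("phy"),
             amirchs1 = amirchs1_sequence(),
             scaffold = amirchs1_scaffold(),
             phy_scaffold = phy_mir319a_scaffold())
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_table(fx$table_amirchs1, file.path(dir, "amirchs1_tailed.tsv"))
    write_table(fx$table_phy, file.path(dir, "phy_tailed.tsv"))
    writeLines(c(">amiRchs1_scaffold", fx$scaffold$hairpin$sequence,
                 ">phy_miR319a_scaffold", fx$phy_scaffold$hairpin$sequence),
               file.path(dir, "scaffolds.fa"))
  }
  fx
}
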