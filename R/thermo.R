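# Gap-free small-RNA/target duplex alignment, nearest-neighbor free energy,
# amiRNA design-rule checks and transcriptome scanning.
#
# Energy model (packaged, versioned via nn_params()$version):
#   dG = duplex initiation
#      + sum of stacked-pair terms over adjacent paired (WC or GU) positions
#      + a per-position internal-loop-like penalty for each mismatch
#      + a terminal penalty when a helix-terminal pair is A:U or G:U.
# Stacks are the published Turner 2004 RNA nearest-neighbor dG(37 C) values
# including G:U wobbles; no bulges are modelled (gap-free duplexes only).
# The mismatch penalty (+3.0 kcal/mol) exceeds the worst-case stabilization
# a lost stack pair could have provided, so adding a mismatch can never make
# a duplex more stable.

# 6x6 stack table, kcal/mol at 37 C. Entry [P, Q] is the energy of the
# stacked pairs 5'-a b-3' / 3'-a' b'-5' where P names the pair (a, a') and
# Q names the pair (b', b). Pair names: first letter = 5' strand base.
.nn_stack <- local({
  p <- c("CG", "GC", "GU", "UG", "AU", "UA")
  m <- matrix(c(
    -2.40, -3.30, -2.10, -1.40, -2.10, -2.10,
    -3.30, -3.40, -2.50, -1.50, -2.20, -2.40,
    -2.10, -2.50,  1.30, -0.50, -1.40, -1.30,
    -1.40, -1.50, -0.50,  0.30, -0.60, -1.00,
    -2.10, -2.20, -1.40, -0.60, -1.10, -0.90,
    -2.10, -2.40, -1.30, -1.00, -0.90, -1.30),
    nrow = 6, byrow = TRUE, dimnames = list(p, p))
  m
})

#' Nearest-neighbor duplex parameters
#'
#' The packaged parameter set: Turner 2004 RNA stacked-pair free energies at
#' 37 C (Watson-Crick and G:U wobble pairs), duplex initiation
#' +4.10 kcal/mol, terminal A:U / G:U penalty +0.50 kcal/mol, and an
#' internal-loop-like penalty of +3.0 kcal/mol per mismatched position.
#'
#' @return list with `stack` (6x6 matrix), `init`, `terminal_au`,
#'   `mismatch_penalty`, `temperature` (reference, Celsius) and `version`.
#' @export
nn_params <- function() {
  list(stack = .nn_stack, init = 4.10, terminal_au = 0.50,
       mismatch_penalty = 3.0, temperature = 37,
       version = "Turner 2004 dG37 stacks + GU wobbles")
}

.rna_complement <- c(A = "U", U = "A", G = "C", C = "G")

pair_name <- function(top, bottom) paste0(top, bottom)

pair_state_one <- function(a, b) {
  if (.rna_complement[[a]] == b) return("WC")
  if ((a == "G" && b == "U") || (a == "U" && b == "G")) return("GU")
  "MM"
}

#' Align a small RNA against a target site (gap-free, antiparallel)
#'
#' Positions are numbered from the small RNA 5' end (position 1). Position p
#' pairs the target base at `offset + L - p`. Each position is classified
#' WC (A:U or G:C), GU (G:U wobble) or MM (mismatch). The duplex free
#' energy, the energy of the same small RNA bound to its perfect complement,
#' and the energy fraction (100 * dG / dG_perfect) are attached.
#'
#' @param smallrna guide sequence (5' to 3'; DNA or RNA, handled as RNA).
#' @param transcript target transcript sequence (character).
#' @param offset 1-based start of the site window on the transcript.
#' @return object of class `duplex_alignment`: `smallrna`, `site` (target
#'   window, 5' to 3'), `offset`, `states`, `dG`, `dG_perfect`,
#'   `energy_fraction`.
#' @export
align_duplex <- function(smallrna, transcript, offset) {
  sm <- normalize_seq(smallrna, "RNA")
  tx <- normalize_seq(transcript[[1L]], "RNA")
  L <- nchar(sm)
  if (offset < 1L || offset + L - 1L > nchar(tx)) {
    stop("site window [", offset, ", ", offset + L - 1L,
         "] does not fit the transcript")
  }
  site <- substr(tx, offset, offset + L - 1L)
  sm_ch <- strsplit(sm, "", fixed = TRUE)[[1L]]
  si_ch <- strsplit(site, "", fixed = TRUE)[[1L]]
  states <- vapply(seq_len(L), function(p) {
    pair_state_one(sm_ch[p], si_ch[L - p + 1L])
  }, "")
  al <- structure(list(smallrna = sm, site = site, offset = as.integer(offset),
                       states = states),
                  class = "duplex_alignment")
  al$dG <- duplex_energy(al)
  al$dG_perfect <- perfect_energy(sm)
  al$energy_fraction <- 100 * al$dG / al$dG_perfect
  al
}

# energy over a run of positions (no initiation/terminal terms): stacks for
# adjacent paired positions + per-mismatch penalties
window_energy <- function(sm_ch, partner_ch, states, positions, par) {
  e <- 0
  for (p in positions) {
    if (states[p] == "MM") e <- e + par$mismatch_penalty
  }
  for (j in seq_len(length(positions) - 1L)) {
    p <- positions[j]; q <- positions[j + 1L]
    if (q != p + 1L) next
    if (states[p] != "MM" && states[q] != "MM") {
      row <- pair_name(sm_ch[p], partner_ch[p])
      col <- pair_name(partner_ch[q], sm_ch[q])
      e <- e + par$stack[row, col]
    }
  }
  e
}

duplex_energy_core <- function(sm, partner_by_pos, states, par) {
  L <- length(states)
  sm_ch <- strsplit(sm, "", fixed = TRUE)[[1L]]
  e <- par$init + window_energy(sm_ch, partner_by_pos, states, seq_len(L), par)
  paired <- which(states != "MM")
  if (length(paired)) {
    for (p in c(paired[1L], paired[length(paired)])) {
      pr <- pair_name(sm_ch[p], partner_by_pos[p])
      if (pr %in% c("AU", "UA", "GU", "UG")) e <- e + par$terminal_au
    }
  }
  e
}

# partner base opposite each small-RNA position (site read 3'->5')
partner_by_position <- function(al) {
  si_ch <- strsplit(al$site, "", fixed = TRUE)[[1L]]
  rev(si_ch)
}

perfect_energy <- function(sm, par = nn_params()) {
  sm_ch <- strsplit(sm, "", fixed = TRUE)[[1L]]
  duplex_energy_core(sm, unname(.rna_complement[sm_ch]),
                     rep("WC", length(sm_ch)), par)
}

#' Nearest-neighbor free energy of a duplex alignment
#'
#' @param alignment a `duplex_alignment` from [align_duplex()].
#' @param temperature Celsius. Only the packaged 37 C reference table is
#'   available (no enthalpy table is shipped); requesting another
#'   temperature attaches a `note` attribute recording the limitation and
#'   returns the reference-scale value.
#' @return dG in kcal/mol.
#' @export
duplex_energy <- function(alignment, temperature = 37) {
  stopifnot(inherits(alignment, "duplex_alignment"))
  par <- nn_params()
  e <- duplex_energy_core(alignment$smallrna, partner_by_position(alignment),
                          alignment$states, par)
  if (!isTRUE(all.equal(temperature, par$temperature))) {
    attr(e, "note") <- paste0(
      "no enthalpy table packaged; value is on the ", par$temperature,
      " C reference scale, not rescaled to ", temperature, " C")
  }
  e
}

#' Duplex energy as a fraction of the perfect-complement duplex
#'
#' @param alignment a `duplex_alignment`.
#' @return percentage `100 * dG / dG_perfect`; exactly 100 for an all-WC
#'   duplex.
#' @export
energy_fraction <- function(alignment) {
  stopifnot(inherits(alignment, "duplex_alignment"))
  if (alignment$dG_perfect >= 0) {
    stop("perfect-complement duplex energy must be negative")
  }
  100 * as.numeric(alignment$dG) / alignment$dG_perfect
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat("<duplex_alignment> offset ", x$offset, "\n",
      "  5'-", x$smallrna, "-3' (guide)\n",
      "     ", states_string(x$states), "\n",
      "  3'-", paste(rev(strsplit(x$site, "")[[1L]]), collapse = ""),
      "-5' (target)\n",
      "  dG = ", round(as.numeric(x$dG), 2), " kcal/mol (",
      round(x$energy_fraction, 1), "% of perfect)\n", sep = "")
  invisible(x)
}

#' Compact per-position state string (W = WC, G = GU, M = mismatch)
#'
#' @param states character vector of states from a `duplex_alignment`.
#' @return single string such as `"WWWWWWWWWWWWWWWWWWWGM"`.
#' @export
states_string <- function(states) {
  paste(c(WC = "W", GU = "G", MM = "M")[states], collapse = "")
}

#' Check amiRNA design rules against a candidate
#'
#' The classical backbone-design rules for a 21-nt artificial miRNA:
#' a U at position 1, an A at position 10, no mismatch to the target at
#' positions 2 and 12, and 5' instability (the 5-nt duplex window at the
#' small RNA 5' end binds more weakly than the one at its 3' end, which
#' biases guide-strand selection).
#'
#' @param candidate candidate small RNA sequence.
#' @param alignment optional `duplex_alignment` of the candidate to its
#'   intended target; without it the pairing-dependent rules are `NA`.
#' @return list of class `design_rule_report` with logical fields
#'   `length_ok`, `u_at_1`, `a_at_10`, `match_at_2`, `match_at_12`,
#'   `five_prime_instability`, `overall` (conjunction over non-NA parts).
#' @export
check_design_rules <- function(candidate, alignment = NULL) {
  sm <- normalize_seq(candidate, "RNA")
  if (nchar(sm) < 12L) stop("candidate must be at least 12 nt")
  rep <- list(
    length_ok = nchar(sm) == 21L,
    u_at_1 = substr(sm, 1L, 1L) == "U",
    a_at_10 = substr(sm, 10L, 10L) == "A",
    match_at_2 = NA, match_at_12 = NA, five_prime_instability = NA)
  if (!is.null(alignment)) {
    stopifnot(inherits(alignment, "duplex_alignment"))
    st <- alignment$states
    rep$match_at_2 <- st[2L] != "MM"
    rep$match_at_12 <- st[12L] != "MM"
    L <- length(st)
    par <- nn_params()
    sm_ch <- strsplit(alignment$smallrna, "", fixed = TRUE)[[1L]]
    partner <- partner_by_position(alignment)
    dg5 <- window_energy(sm_ch, partner, st, 1:5, par)
    dg3 <- window_energy(sm_ch, partner, st, (L - 4L):L, par)
    rep$five_prime_instability <- dg5 > dg3
  }
  parts <- unlist(rep)
  rep$overall <- all(parts[!is.na(parts)])
  class(rep) <- "design_rule_report"
  rep
}

#' Target-selection criteria
#'
#' The empirical plant miRNA target-recognition criteria: no mismatch at the
#' cleavage site (positions 10-11), at most one mismatch in positions 2-12,
#' at most 4 mismatches downstream of position 13 with no more than two in a
#' row, and duplex free energy at least `energy_fraction_ge` percent of the
#' perfect-complement duplex.
#'
#' @param no_mm_10_11 require positions 10 and 11 matched.
#' @param max_mm_2_12 mismatch allowance in positions 2-12.
#' @param max_mm_after_13 mismatch allowance downstream of position 13.
#' @param max_run_mm longest tolerated run of consecutive mismatches.
#' @param energy_fraction_ge minimum energy fraction (percent).
#' @param gu_as_mismatch count G:U wobbles as mismatches (strict mode);
#'   by default wobbles pair for energy and do not count as mismatches,
#'   but are still reported separately in alignment states.
#' @return list of class `target_criteria`.
#' @export
target_criteria <- function(no_mm_10_11 = TRUE, max_mm_2_12 = 1,
                            max_mm_after_13 = 4, max_run_mm = 2,
                            energy_fraction_ge = 70,
                            gu_as_mismatch = FALSE) {
  stopifnot(energy_fraction_ge > 0)
  structure(list(no_mm_10_11 = no_mm_10_11, max_mm_2_12 = max_mm_2_12,
                 max_mm_after_13 = max_mm_after_13, max_run_mm = max_run_mm,
                 energy_fraction_ge = energy_fraction_ge,
                 gu_as_mismatch = gu_as_mismatch),
            class = "target_criteria")
}

#' Evaluate the target-selection criteria on a duplex alignment
#'
#' @param alignment a `duplex_alignment`.
#' @param criteria a [target_criteria()].
#' @return list with `pass` (logical) and `detail` (named logical vector of
#'   the individual rules). Alignments that are not 21 nt raise a warning.
#' @export
check_target_criteria <- function(alignment, criteria = target_criteria()) {
  stopifnot(inherits(alignment, "duplex_alignment"),
            inherits(criteria, "target_criteria"))
  st <- alignment$states
  L <- length(st)
  if (L != 21L) warning("alignment is ", L, " nt; criteria assume 21")
  mm <- st == "MM" | (criteria$gu_as_mismatch & st == "GU")
  runs <- rle(mm)
  longest_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  detail <- c(
    no_mm_10_11 = !criteria$no_mm_10_11 || !any(mm[10:11]),
    le_mm_2_12 = sum(mm[2:min(12L, L)]) <= criteria$max_mm_2_12,
    le_mm_after_13 = if (L >= 14L) sum(mm[14:L]) <= criteria$max_mm_after_13 else TRUE,
    le_run_mm = longest_run <= criteria$max_run_mm,
    energy_ok = alignment$energy_fraction >= criteria$energy_fraction_ge)
  list(pass = all(detail), detail = detail)
}

#' Scan transcripts for target sites of a small RNA
#'
#' Every offset of every transcript is evaluated as a gap-free antiparallel
#' site. Sites with at most `max_mm` mismatches that pass the
#' target-selection criteria are returned, ranked by energy fraction.
#'
#' @param smallrna guide sequence.
#' @param transcripts named character vector of transcript sequences, or a
#'   `data.frame` from [read_fasta()].
#' @param max_mm pre-filter on the mismatch count (default 5). G:U wobbles
#'   count according to `criteria$gu_as_mismatch`.
#' @param criteria a [target_criteria()].
#' @return `data.frame`: `transcript`, `offset`, `site`, `states`
#'   (compact string, see [states_string()]), `mismatches`, `gu`, `dG`,
#'   `energy_fraction`, sorted by decreasing energy fraction.
#' @export
scan_targets <- function(smallrna, transcripts, max_mm = 5,
                         criteria = target_criteria()) {
  if (is.data.frame(transcripts)) {
    transcripts <- setNames(transcripts$sequence, transcripts$id)
  }
  if (length(transcripts) == 0L) stop("no transcripts supplied")
  if (is.null(names(transcripts))) {
    names(transcripts) <- paste0("tx", seq_along(transcripts))
  }
  sm <- normalize_seq(smallrna, "RNA")
  L <- nchar(sm)
  sm_ch <- strsplit(sm, "", fixed = TRUE)[[1L]]
  rows <- list()
  for (tx_name in names(transcripts)) {
    tx <- normalize_seq(transcripts[[tx_name]], "RNA")
    tx_ch <- strsplit(tx, "", fixed = TRUE)[[1L]]
    n <- nchar(tx)
    if (n < L) next
    for (off in seq_len(n - L + 1L)) {
      # partner of position p is the site base at offset + L - p
      partner <- tx_ch[(off + L - 1L):off]
      states <- vapply(seq_len(L), function(p) {
        pair_state_one(sm_ch[p], partner[p])
      }, "")
      mm_vec <- states == "MM" | (criteria$gu_as_mismatch & states == "GU")
      if (sum(mm_vec) > max_mm) next
      al <- suppressWarnings(align_duplex(sm, tx, off))
      chk <- suppressWarnings(check_target_criteria(al, criteria))
      if (!chk$pass) next
      rows[[length(rows) + 1L]] <- data.frame(
        transcript = tx_name, offset = off, site = al$site,
        states = states_string(states),
        mismatches = sum(states == "MM"), gu = sum(states == "GU"),
        dG = as.numeric(al$dG), energy_fraction = al$energy_fraction,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(list(data.frame(
    transcript = character(0), offset = integer(0), site = character(0),
    states = character(0), mismatches = integer(0), gu = integer(0),
    dG = numeric(0), energy_fraction = numeric(0),
    stringsAsFactors = FALSE)), rows))
  out <- out[order(-out$energy_fraction, out$transcript, out$offset), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
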