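# Seeded simulator of loop-to-base hairpin processing: sequential DCL cuts
# below the terminal loop at ~21-nt intervals, block-proportional library
# sampling, non-templated 3' tailing, and RACE fragment generation.
#
# All randomness flows through an explicit seed; the global RNG state is
# saved and restored around every stochastic operation.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate loop-to-base processing of a hairpin precursor
#'
#' Processing starts with a cut just below the annotated terminal loop and
#' proceeds toward the base: `n_cuts` sequential cleavage positions are
#' placed on the 3' arm at intervals of `interval_mean` plus a jitter drawn
#' from `jitter` (defaults reproduce the observed 20-23 nt spacing).
#' Small RNAs are excised between successive cuts on the 3' arm and, with a
#' 3' overhang of `overhang` nt, at the mirrored intervals of the 5' arm.
#' Blocks are named loop-outward: B2/B2* (loop-proximal duplex), B3/B3*,
#' B1/B1* (base duplex).
#'
#' @param hp a [hairpin()] with a region named `"loop"`.
#' @param n_cuts number of sequential cuts (default 4, giving 3 duplexes).
#' @param interval_mean mean cut spacing (nt, default 21).
#' @param jitter integer offsets added to `interval_mean`.
#' @param jitter_prob sampling probabilities over `jitter`.
#' @param overhang 3' overhang of the excised duplexes (nt, default 2).
#' @param seed integer seed (`NULL` leaves the RNG untouched).
#' @return list with `products` (`block`, `arm`, `start`, `end`,
#'   `sequence`), `sites3` and `sites5` (cut positions per arm; a cut
#'   position is the first base of the downstream fragment).
#' @export
simulate_processing <- function(hp, n_cuts = 4, interval_mean = 21,
                                jitter = c(-1L, 0L, 1L, 2L),
                                jitter_prob = c(0.15, 0.55, 0.20, 0.10),
                                overhang = 2, seed = NULL) {
  stopifnot(inherits(hp, "hairpin"), n_cuts >= 2)
  loop <- hairpin_region(hp, "loop")
  n <- nchar(hp$sequence)
  with_seed(seed, {
    ivals <- interval_mean + if (length(jitter) == 1L) {
      rep(jitter, n_cuts - 1L)
    } else {
      sample(jitter, n_cuts - 1L, replace = TRUE, prob = jitter_prob)
    }
    sites3 <- cumsum(c(loop["end"] + 1L, ivals))
    if (max(sites3) > n + 1L) {
      stop("hairpin too short for ", n_cuts, " cuts below the loop")
    }
    # mirror position of x on the 5' arm, assuming arms of symmetric length
    mirror <- loop["start"] + loop["end"] - sites3
    sites5 <- sort(as.integer(mirror - overhang + 1L))
    if (min(sites5) < 1L) stop("hairpin 5' arm too short for ", n_cuts, " cuts")
    blocks3 <- c("B2", "B3", "B1")
    blocks5 <- c("B2*", "B3*", "B1*")
    prods <- list()
    for (k in seq_len(n_cuts - 1L)) {
      b <- if (k <= 3L) blocks3[k] else paste0("D", k)
      s <- sites3[k]; e <- sites3[k + 1L] - 1L
      prods[[length(prods) + 1L]] <- data.frame(
        block = b, arm = "3p", start = s, end = e,
        sequence = substr(hp$sequence, s, e), stringsAsFactors = FALSE)
      b5 <- if (k <= 3L) blocks5[k] else paste0("D", k, "*")
      e5 <- as.integer(mirror[k] - overhang)
      s5 <- as.integer(mirror[k + 1L] - overhang + 1L)
      prods[[length(prods) + 1L]] <- data.frame(
        block = b5, arm = "5p", start = s5, end = e5,
        sequence = substr(hp$sequence, s5, e5), stringsAsFactors = FALSE)
    }
    products <- do.call(rbind, prods)
    rownames(products) <- NULL
    list(products = products, sites3 = unname(as.integer(sites3)),
         sites5 = unname(sites5))
  })
}

#' Sample a sequencing library from processing products
#'
#' Reads are drawn by multinomial sampling over blocks according to
#' `proportions`; within a block, reads are split uniformly across that
#' block's products.
#'
#' @param products products `data.frame` from [simulate_processing()].
#' @param proportions named probability vector over block names (must sum
#'   to 1; blocks absent from `products` are an error).
#' @param depth total reads.
#' @param seed integer seed.
#' @return collapsed library `data.frame` (`sequence`, `count`) with
#'   attribute `block_truth` (reads drawn per block).
#' @export
sample_library <- function(products, proportions, depth, seed = NULL) {
  stopifnot(nrow(products) > 0L, depth >= 1)
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  if (!all(names(proportions) %in% products$block)) {
    stop("proportions name blocks absent from the products: ",
         paste(setdiff(names(proportions), products$block), collapse = ", "))
  }
  with_seed(seed, {
    draws <- as.integer(stats::rmultinom(1L, depth, proportions))
    names(draws) <- names(proportions)
    rows <- list()
    for (b in names(draws)) {
      if (draws[[b]] == 0L) next
      seqs <- products$sequence[products$block == b]
      if (length(seqs) == 1L) {
        per <- draws[[b]]
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = seqs, count = per, stringsAsFactors = FALSE)
      } else {
        split <- as.integer(stats::rmultinom(1L, draws[[b]],
                                             rep(1, length(seqs))))
        keep <- split > 0L
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = seqs[keep], count = split[keep], stringsAsFactors = FALSE)
      }
    }
    lib <- collapse_reads(do.call(rbind, rows))
    attr(lib, "block_truth") <- draws
    lib
  })
}

#' Append non-templated 3' tails to sampled reads
#'
#' Each read is tailed with probability `tail_prob`; tail length is drawn
#' from `len_dist` and tail bases from `nt_dist`. With
#' `resample_ambiguous = TRUE` (default) the first tail base is redrawn
#' until it differs from the templated base following the read on the
#' precursor, which keeps [decompose_tail()] recovery exact; the realistic
#' mode (`FALSE`) allows ambiguous tails, for which decomposition recall
#' below 100 percent is expected.
#'
#' @param collapsed collapsed library of templated reads.
#' @param hp the precursor [hairpin()] (for the next templated base).
#' @param tail_prob per-read tailing probability.
#' @param len_dist named probabilities over tail lengths `1..3`.
#' @param nt_dist named probabilities over tail nucleotides
#'   `c(U =, A =, C =, G =)`; the default is the uridine-dominated spectrum
#'   typical of plant small-RNA 3' tailing.
#' @param resample_ambiguous see Details.
#' @param seed integer seed.
#' @return collapsed library with tailed reads merged in.
#' @export
add_tails <- function(collapsed, hp, tail_prob = 0.1,
                      len_dist = c("1" = 0.80, "2" = 0.15, "3" = 0.05),
                      nt_dist = c(U = 0.45, A = 0.28, C = 0.16, G = 0.11),
                      resample_ambiguous = TRUE, seed = NULL) {
  stopifnot(inherits(hp, "hairpin"),
            abs(sum(len_dist) - 1) < 1e-8, abs(sum(nt_dist) - 1) < 1e-8)
  nts <- normalize_seq(names(nt_dist))   # DNA alphabet internally
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(collapsed))) {
      sq <- collapsed$sequence[i]
      ct <- collapsed$count[i]
      n_tailed <- stats::rbinom(1L, ct, tail_prob)
      if (ct - n_tailed > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = sq, count = ct - n_tailed, stringsAsFactors = FALSE)
      }
      if (n_tailed == 0L) next
      at <- regexpr(sq, hp$sequence, fixed = TRUE)
      next_base <- if (at > 0L && at + nchar(sq) <= nchar(hp$sequence)) {
        substr(hp$sequence, at + nchar(sq), at + nchar(sq))
      } else NA_character_
      for (r in seq_len(n_tailed)) {
        len <- as.integer(sample(names(len_dist), 1L, prob = len_dist))
        tail <- sample(nts, len, replace = TRUE, prob = nt_dist)
        if (resample_ambiguous && !is.na(next_base)) {
          if (all(nts[nt_dist > 0] == next_base)) {
            stop("cannot avoid ambiguous tail: only base '", next_base,
                 "' has probability mass")
          }
          while (tail[1L] == next_base) {
            tail[1L] <- sample(nts, 1L, prob = nt_dist)
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = paste0(sq, paste(tail, collapse = "")), count = 1L,
          stringsAsFactors = FALSE)
      }
    }
    collapse_reads(do.call(rbind, rows))
  })
}

#' Simulate 5'-RACE fragments from a sliced target
#'
#' A fraction `accuracy` of fragments start exactly at the canonical slicer
#' position (between the target bases pairing guide positions 10 and 11);
#' the remainder are displaced by 1-5 nt in either direction, uniformly.
#'
#' @param target target transcript sequence.
#' @param smallrna guide small RNA.
#' @param site_offset 1-based start of the complementary site on the target.
#' @param accuracy fraction of canonical 5' ends.
#' @param n number of fragments.
#' @param seed integer seed.
#' @param read_len fragment length emitted (nt, truncated at target end).
#' @return `data.frame` with `id` and `sequence` (possibly zero rows).
#' @export
simulate_race <- function(target, smallrna, site_offset, accuracy = 1.0,
                          n = 20, seed = NULL, read_len = 40) {
  stopifnot(accuracy >= 0, accuracy <= 1, n >= 0)
  tgt <- normalize_seq(target[[1L]])
  canon <- canonical_site(smallrna, site_offset)
  if (n == 0L) {
    return(data.frame(id = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    pos <- vapply(seq_len(n), function(i) {
      if (stats::runif(1) < accuracy) return(canon)
      canon + sample(c(-5:-1, 1:5), 1L)
    }, 0)
    pos <- pmin(pmax(as.integer(pos), 1L), nchar(tgt))
    data.frame(id = paste0("race_", seq_len(n)),
               sequence = substr(rep(tgt, n), pos,
                                 pmin(pos + read_len - 1L, nchar(tgt))),
               stringsAsFactors = FALSE)
  })
}
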