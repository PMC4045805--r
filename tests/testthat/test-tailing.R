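test_that("tail decomposition splits known variants into 5GMC + tail", {
  sc <- amirchs1_scaffold()
  lib <- data.frame(sequence = c("tgttggtacatcatgagtcgcA",
                                 "tgttggtacatcatgagtcgTTC"),
                    count = c(23L, 5L))
  dec <- decompose_tail(lib, sc$hairpin, blocks = sc$blocks,
                        b3plus = sc$b3plus)
  v <- dec$variants
  expect_equal(v$gmc, c("TGTTGGTACATCATGAGTCGC", "TGTTGGTACATCATGAGTCG"))
  expect_equal(v$tail, c("A", "TTC"))
  expect_equal(v$block, c("B1", "B1"))
  expect_equal(v$gmc_len, c(21L, 20L))
})

test_that("decomposition reconstructs reads and 5GMCs are maximal", {
  sc <- amirchs1_scaffold()
  dec <- decompose_tail(table2_library(), sc$hairpin, blocks = sc$blocks,
                        b3plus = sc$b3plus)
  v <- dec$variants
  expect_equal(nrow(v), 27)
  expect_identical(paste0(v$gmc, v$tail), v$sequence)      # reconstruction
  ref <- sc$hairpin$sequence
  for (i in seq_len(nrow(v))) {
    ext <- substr(v$sequence[i], 1, v$gmc_len[i] + 1L)      # one base longer
    expect_equal(regexpr(ext, ref, fixed = TRUE)[1], -1)    # never templated
    # first tail base differs from the next templated base
    nxt <- substr(ref, v$gmc_end[i] + 1L, v$gmc_end[i] + 1L)
    expect_false(substr(v$tail[i], 1, 1) == nxt)
  }
})

test_that("fully templated, short-5GMC and long-tail reads are reported, not dropped", {
  sc <- amirchs1_scaffold()
  lib <- data.frame(sequence = c(amirchs1_sequence(),                # templated
                                 paste0("TGTTGGTACATCATGA", "CCC"),  # gmc 16
                                 paste0("TGTTGGTACATCATGAGTCG", "AAAA")),
                    count = c(10L, 2L, 3L))
  dec <- decompose_tail(lib, sc$hairpin)
  expect_equal(nrow(dec$variants), 0)
  expect_setequal(dec$unexplained$reason,
                  c("templated", "short_gmc", "long_tail"))
  expect_equal(sum(dec$unexplained$count) + sum(dec$variants$count),
               sum(lib$count))
})

test_that("tail composition is read-weighted and reported as RNA", {
  v <- data.frame(sequence = c("xT", "yTT", "zA"), count = c(1L, 1L, 2L),
                  gmc_start = 1L, gmc_end = 1L, gmc_len = 1L,
                  gmc = c("x", "y", "z"), tail = c("T", "TT", "A"),
                  block = "B1", stringsAsFactors = FALSE)
  comp <- tail_composition(v)                      # weighted: 3 U, 2 A of 5
  expect_equal(unname(comp[c("U", "A")]), c(60, 40))
  unw <- tail_composition(v, weight_by_reads = FALSE)  # 3 U, 1 A of 4
  expect_equal(unname(unw[c("U", "A")]), c(75, 25))
  expect_equal(sum(comp), 100)
  expect_error(tail_composition(v[0, ]), "no tailed")
  single <- v[1, ]
  expect_equal(unname(tail_composition(single)["U"]), 100)
})

test_that("published phy-miR319a tails give 84/14/2 composition and
           the hand-tallied length distribution", {
  ph <- phy_mir319a_scaffold()
  dec <- decompose_tail(table3_library(), ph$hairpin, blocks = ph$blocks)
  expect_equal(nrow(dec$variants), 11)
  comp <- round(tail_composition(dec$variants))
  expect_equal(unname(comp[c("U", "C", "G")]), c(84, 14, 2))
  expect_equal(unname(comp["A"]), 0)
  # hand tally over the 11 printed rows: 2-nt tails 112+80 = 192 reads,
  # 1-nt tails the remaining 332
  expect_equal(tail_length_distribution(dec$variants),
               c("1" = 332L, "2" = 192L))
})

test_that("tabulated tailed variants carry correct block totals and order", {
  sc <- amirchs1_scaffold()
  dec <- decompose_tail(table2_library(), sc$hairpin, blocks = sc$blocks,
                        b3plus = sc$b3plus)
  tab <- tabulate_tailed(dec$variants)
  totals <- unique(tab[c("block", "block_total")])
  expect_equal(setNames(totals$block_total, totals$block),
               c(B1 = 116L, "B1*" = 142L, B2 = 311L, "B3+" = 12L))
  # within-block ordering by descending reads
  for (b in unique(tab$block)) {
    expect_true(all(diff(tab$reads[tab$block == b]) <= 0))
  }
  # tails upper-cased, 5GMC lower-cased, mirroring the published table
  expect_true("aatgaatgatgcggtagacaaaA" %in% tab$sequence)
  one <- tabulate_tailed(dec$variants[1, , drop = FALSE])
  expect_equal(one$block_total, one$reads)
})

test_that("simulated tails are recovered exactly in anti-ambiguity mode", {
  sc <- amirchs1_scaffold()
  sim <- simulate_processing(sc$hairpin, jitter = 0L, seed = 21)
  base <- sample_library(sim$products,
                         c(B1 = 0.6, "B1*" = 0.4), depth = 4000, seed = 22)
  tailed <- add_tails(base, sc$hairpin, tail_prob = 0.5, seed = 23)
  expect_equal(sum(tailed$count), 4000)            # tailing conserves reads
  unmapped <- tailed[!tailed$sequence %in% sim$products$sequence, ]
  dec <- decompose_tail(unmapped, sc$hairpin)
  expect_equal(nrow(dec$unexplained), 0)           # every tailed read explained
  expect_true(all(dec$variants$gmc %in% sim$products$sequence))
  # composition recovered within 3 sigma of the generator's expectation:
  # first tail bases are drawn from the configured distribution conditioned
  # on differing from the next templated base; later bases unconditionally
  comp <- tail_composition(dec$variants)
  p_nt <- c(T = 0.45, A = 0.28, C = 0.16, G = 0.11)
  n_tails <- tapply(dec$variants$count, dec$variants$gmc, sum)
  ref <- sc$hairpin$sequence
  expected <- c(T = 0, A = 0, C = 0, G = 0)
  for (g in names(n_tails)) {
    at <- regexpr(g, ref, fixed = TRUE)
    nxt <- substr(ref, at + nchar(g), at + nchar(g))
    q <- p_nt
    q[nxt] <- 0
    expected <- expected + n_tails[[g]] * q / sum(q)
  }
  total_nt <- sum(dec$variants$count * nchar(dec$variants$tail))
  expected <- expected + (total_nt - sum(n_tails)) * p_nt
  names(expected) <- chartr("T", "U", names(expected))
  tol <- 100 * 3 * sqrt(0.25 / total_nt)
  for (nt in c("U", "A", "C", "G")) {
    expect_lt(abs(comp[[nt]] - 100 * expected[[nt]] / total_nt), tol)
  }
  # fixed tail length: all tails length 3
  t3 <- add_tails(base, sc$hairpin, tail_prob = 1,
                  len_dist = c("3" = 1), seed = 24)
  dec3 <- decompose_tail(t3[!t3$sequence %in% sim$products$sequence, ],
                         sc$hairpin)
  expect_true(all(nchar(dec3$variants$tail) == 3))
  # tailing probability 0 leaves the library untouched
  expect_equal(add_tails(base, sc$hairpin, tail_prob = 0, seed = 25), base,
               ignore_attr = TRUE)
})
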