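toy_blocks <- function() {
  data.frame(name = c("BL", "BR"), representative = c("x", "y"),
             rep_start = c(50L, 120L), rep_end = c(70L, 140L),
             stringsAsFactors = FALSE)
}

test_that("representatives are the most abundant read per region, with tie rules", {
  mapped <- data.frame(
    sequence = c("AAAAAAAAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCCCCCCCC",
                 "GGGGGGGGGGGGGGGGGGGG", "GGGGGGGGGGGGGGGGGGGGGG"),
    count = c(3885L, 100L, 50L, 50L),
    ref = "h", start = c(10L, 12L, 60L, 58L),
    end = c(30L, 32L, 79L, 79L), strand = "+", mismatches = 0L,
    stringsAsFactors = FALSE)
  hints <- data.frame(region = c("B1", "B2"), start = c(5L, 55L),
                      end = c(35L, 85L))
  blocks <- select_representatives(mapped, hints)
  expect_equal(blocks$representative[blocks$name == "B1"],
               "AAAAAAAAAAAAAAAAAAAAA")
  # tie at 50 reads: longer sequence wins
  expect_equal(blocks$representative[blocks$name == "B2"],
               "GGGGGGGGGGGGGGGGGGGGGG")
  hints2 <- rbind(hints, data.frame(region = "empty", start = 150L, end = 180L))
  expect_warning(select_representatives(mapped, hints2), "empty")
})

test_that("single-read region yields that read as representative", {
  mapped <- data.frame(sequence = "ACGTACGTACGTACGTACGTA", count = 1L,
                       ref = "h", start = 10L, end = 30L, strand = "+",
                       mismatches = 0L, stringsAsFactors = FALSE)
  hints <- data.frame(region = "only", start = 1L, end = 60L)
  expect_equal(select_representatives(mapped, hints)$representative,
               "ACGTACGTACGTACGTACGTA")
})

test_that("block assignment agrees with the brute-force overlap/extension
           oracle over every placement of every 18-32-nt read", {
  blocks <- toy_blocks()
  prec_len <- 200L
  cases <- expand.grid(len = 18:32, start = 1:prec_len)
  cases <- cases[cases$start + cases$len - 1L <= prec_len, ]
  mapped <- data.frame(start = cases$start, end = cases$start + cases$len - 1L)
  got <- assign_block(mapped, blocks)
  for (i in seq_len(nrow(mapped))) {
    s <- mapped$start[i]; e <- mapped$end[i]
    in_l <- brute_block_member(s, e, 50, 70)
    in_r <- brute_block_member(s, e, 120, 140)
    want <- if (in_l && in_r) stop("toy blocks should not both qualify") else
      if (in_l) "BL" else if (in_r) "BR" else "unassigned"
    expect_identical(got$block[i], want)
  }
  # boundary cases called out explicitly: 15-nt overlap is NOT enough,
  # 16 is; a 7-nt extension disqualifies, 6 does not
  bd <- assign_block(data.frame(start = c(56L, 55L, 43L, 44L),
                                end = c(76L, 75L, 65L, 65L)), blocks)
  expect_equal(bd$block, c("unassigned", "BL", "unassigned", "BL"))
})

test_that("largest overlap wins when several blocks qualify; ties go left", {
  blocks <- data.frame(name = c("A", "B"), representative = c("x", "y"),
                       rep_start = c(10L, 16L), rep_end = c(30L, 36L),
                       stringsAsFactors = FALSE)
  # read 13..33: overlap 18 with both -> tie broken toward left-most (A)
  tie <- assign_block(data.frame(start = 13L, end = 33L), blocks)
  expect_equal(tie$block, "A")
  # read 11..31: overlap A = 20, B = 16, both qualify -> larger overlap (A)
  expect_equal(assign_block(data.frame(start = 11L, end = 31L), blocks)$block,
               "A")
})

test_that("B3+ reads are recognized before the generic rule", {
  sc <- amirchs1_scaffold()
  b3p <- sc$b3plus
  read <- data.frame(start = b3p$b3[1], end = b3p$b1_start + 8L)
  expect_equal(assign_block(read, sc$blocks, b3plus = b3p)$block, "B3+")
  # without the rule the same read is not B3+
  expect_false(assign_block(read, sc$blocks)$block == "B3+")
})

test_that("assignment is invariant to input order; proportions to scaling", {
  blocks <- toy_blocks()
  set.seed(5)
  mapped <- data.frame(start = sample(30:130, 40, TRUE))
  mapped$end <- mapped$start + sample(18:24, 40, TRUE) - 1L
  mapped$count <- sample(1:50, 40, TRUE)
  perm <- sample(nrow(mapped))
  a1 <- assign_block(mapped, blocks)
  a2 <- assign_block(mapped[perm, ], blocks)
  expect_equal(a1$block[perm], a2$block)
  if (any(a1$block != "unassigned")) {
    p1 <- block_proportions(a1)
    scaled <- mapped; scaled$count <- scaled$count * 7L
    p2 <- block_proportions(assign_block(scaled, blocks))
    expect_equal(p1$fraction, p2$fraction)
  }
})

test_that("block proportions over counts: one block = 100%, 43/57 split", {
  one <- data.frame(block = "B1", count = 10L)
  expect_equal(block_proportions(one)$fraction, 1)
  two <- data.frame(block = c("B1", "B2"), count = c(43L, 57L))
  p <- block_proportions(two)
  expect_equal(p$fraction[p$block == "B1"], 0.43)
  expect_error(block_proportions(data.frame(block = "unassigned", count = 5L)),
               "assigned")
})

test_that("simulated libraries recover configured block proportions", {
  sc <- amirchs1_scaffold()
  sim <- simulate_processing(sc$hairpin, jitter = 0L, seed = 101)
  props <- c(B1 = 0.43, "B1*" = 0.25, B2 = 0.20, "B2*" = 0.12)
  lib <- sample_library(sim$products, props, depth = 1e5, seed = 102)
  blocks <- data.frame(name = sim$products$block,
                       representative = sim$products$sequence,
                       rep_start = sim$products$start,
                       rep_end = sim$products$end, stringsAsFactors = FALSE)
  asg <- assign_block(map_exact(lib, sc$hairpin), blocks)
  est <- block_proportions(asg, denominator = "assigned")
  for (b in names(props)) {
    p <- props[[b]]
    tol <- 3 * sqrt(p * (1 - p) / 1e5)
    expect_lt(abs(est$fraction[est$block == b] - p), tol + 1e-12)
  }
})
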