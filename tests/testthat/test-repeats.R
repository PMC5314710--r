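# dot plots, block-tiling repeat discovery, consensus, tandem arrays,
# max-pairing fold, architecture maps

test_that("dotplot reports diagonals, planted offsets, and null emptiness", {
  set.seed(21)
  s <- random_dna(50)
  d <- dotplot(s, s, window_bp = 10, min_identity = 1)
  expect_true(all(d$i[d$i == d$j] == 0:40))      # full main diagonal
  d2 <- dotplot(s, s, window_bp = 10, exclude_self_diagonal = TRUE)
  expect_false(any(d2$i == d2$j & d2$strand == 1))
  # planted 30 bp repeat at two offsets -> off-diagonal run of 21 points
  rep30 <- random_dna(30)
  seq2 <- paste0(random_dna(40), rep30, random_dna(60), rep30, random_dna(40))
  dd <- dotplot(seq2, seq2, window_bp = 10, exclude_self_diagonal = TRUE)
  off <- dd[dd$j - dd$i == 90 & dd$strand == 1, ]
  expect_true(all(40:60 %in% off$i))  # 21 windows inside the planted copies
  expect_true(all(off$i >= 39 & off$i <= 61))  # flank bases may extend by 1
  # unrelated random 200-mers at w=15: expected matches ~ positions/4^15 ~ 0
  n_hits <- vapply(1:20, function(k) {
    nrow(dotplot(random_dna(200), random_dna(200), window_bp = 15))
  }, 0L)
  expect_equal(sum(n_hits), 0)
  expect_error(dotplot(s, s, window_bp = 0), "window")
})

test_that("dotplot minus-strand coordinates map back to forward coords", {
  set.seed(22)
  a <- random_dna(80)
  frag <- substr(a, 21, 40)
  b <- paste0(random_dna(30), revcomp(frag), random_dna(30))
  d <- dotplot(a, b, window_bp = 20, both_strands = TRUE)
  hit <- d[d$strand == -1, ]
  expect_true(any(hit$i == 20 & hit$j == 30))
})

test_that("find_repeats recovers planted dispersed repeats", {
  set.seed(33)
  master <- random_dna(100)
  bg <- random_dna(2000)
  at <- c(300, 1400)
  for (p in at) bg <- paste0(substr(bg, 1, p), master,
                             substr(bg, p + 101, nchar(bg)))
  fams <- find_repeats(list(id = "r", seq = bg), list(list(id = "r", seq = bg)))
  expect_equal(length(fams), 1)
  f <- fams[[1]]
  expect_equal(nrow(f$members), 2)
  for (k in 1:2) {
    ov <- span_overlap_frac(c(f$members$start[k], f$members$end[k]),
                            c(at[k], at[k] + 100))
    expect_gte(ov, 0.9)
  }
  expect_equal(f$label, "RF_1")
  expect_gte(f$mean_identity, 0.99)
})

test_that("find_repeats: no family from the trivial self-match", {
  set.seed(34)
  s <- random_dna(400)
  fams <- find_repeats(list(id = "x", seq = s), list(list(id = "x", seq = s)))
  expect_equal(length(fams), 0)
  expect_error(find_repeats(s, list(s), block_bp = 3), "uninformative")
})

test_that("minus-strand repeat copies are reported with strand -1", {
  set.seed(35)
  master <- random_dna(80)
  bg <- paste0(random_dna(200), master, random_dna(300), revcomp(master),
               random_dna(200))
  fams <- find_repeats(list(id = "r", seq = bg), list(list(id = "r", seq = bg)))
  expect_equal(length(fams), 1)
  strands <- sort(fams[[1]]$members$strand)
  expect_equal(strands, c(-1L, 1L))
  # strand symmetry: reverse-complementing the whole region flips nothing
  # about family structure (member count preserved)
  fams_rc <- find_repeats(list(id = "r", seq = revcomp(bg)),
                          list(list(id = "r", seq = revcomp(bg))))
  expect_equal(nrow(fams_rc[[1]]$members), 2)
})

test_that("find_repeats with zero mismatches agrees with the dotplot view", {
  set.seed(36)
  master <- random_dna(60)
  bg <- paste0(random_dna(150), master, random_dna(200), master,
               random_dna(100))
  fams <- find_repeats(list(id = "r", seq = bg),
                       list(list(id = "r", seq = bg)), max_mismatch = 0)
  expect_equal(length(fams), 1)
  d <- dotplot(bg, bg, window_bp = 10, exclude_self_diagonal = TRUE)
  # every exact off-diagonal dotplot window must fall inside a family member
  m <- fams[[1]]$members
  inside <- function(p) any(p >= m$start & p + 10 <= m$end)
  expect_true(all(vapply(d$i[d$strand == 1], inside, TRUE)))
})

test_that("consensus takes the majority and flags ties", {
  expect_equal(as.character(consensus(c("ACGT", "ACGT"))), "ACGT")
  cons <- consensus(c("AAGT", "AAGT", "AGGT"))
  expect_equal(as.character(cons), "AAGT")
  tied <- consensus(c("AT", "GT"))
  expect_equal(as.character(tied), "AT")  # tie broken A < G
  expect_equal(attr(tied, "ties"), 0L)
  expect_error(consensus("ACGT"), ">= 2")
  expect_error(consensus(c("ACGTACGTAC", "ACG")), "2x")
  # 10 copies mutated at 0.1 from a master: majority vote recovers it
  set.seed(44)
  master <- random_dna(200)
  copies <- vapply(1:10, function(i) mutate_copy(master, 0.1), "")
  expect_gte(1 - str_mismatches_oracle(as.character(consensus(copies)),
                                       master) / 200, 0.99)
})

test_that("find_tandem detects planted arrays and stays silent on noise", {
  t1 <- find_tandem(strrep("ACGT", 10), min_period = 2)
  expect_equal(nrow(t1), 1)
  expect_equal(c(t1$start, t1$end, t1$period, t1$copies, t1$identity),
               c(0, 40, 4, 10, 1))
  # random 500-mers at defaults: no array (20 seeds)
  set.seed(55)
  hits <- vapply(1:20, function(k) nrow(find_tandem(random_dna(500))), 0L)
  expect_equal(sum(hits), 0)
  # period-50 array, 6 copies, 5% per-copy mutation -> period 50 +/- 1
  set.seed(56)
  unit <- random_dna(50)
  arr <- paste(vapply(1:6, function(i) mutate_copy(unit, 0.05), ""),
               collapse = "")
  s <- paste0(random_dna(120), arr, random_dna(120))
  t2 <- find_tandem(s, min_period = 10, max_period = 120)
  expect_gte(nrow(t2), 1)
  best <- t2[which.max(t2$end - t2$start), ]
  expect_lte(abs(best$period - 50), 1)
  expect_gte(span_overlap_frac(c(best$start, best$end), c(120, 120 + 300)), 0.8)
  expect_error(find_tandem("ACGTACGT", min_period = 1), "min_period")
})

test_that("fold_propensity equals exhaustive enumeration and handles edges", {
  f <- fold_propensity("GGGAAACCC")
  expect_equal(f$pair_count, 3)
  expect_equal(f$structure, "(((...)))")
  expect_equal(f$pair_count, oracle_max_pairs("GGGAAACCC"))
  expect_equal(fold_propensity("AAAAAA")$pair_count, 0)
  expect_error(fold_propensity("ACGTB"), "alphabet")
  set.seed(66)
  for (k in 1:25) {
    n <- sample(7:15, 1)
    s <- random_dna(n)
    f <- fold_propensity(s)
    expect_equal(f$pair_count, oracle_max_pairs(s), label = s)
    # structural sanity: balanced non-crossing dot-bracket, loops >= 3
    if (f$pair_count > 0) {
      expect_equal(nrow(f$pairs), f$pair_count)
      expect_true(all(f$pairs[, 2] - f$pairs[, 1] > 3))
    }
  }
})

test_that("architecture maps order elements deterministically", {
  empty <- build_architecture(list(id = "r", seq = random_dna(100)))
  expect_equal(nrow(empty), 0)
  region <- list(id = "r", seq = random_dna(200))
  hits <- data.frame(label = c("TAS", "CSB-II"), start = c(10, 50),
                     end = c(24, 65), strand = 1L)
  trna <- data.frame(start = c(10, 150), end = c(24, 180),
                     label = c("Phe-degenerate", "Phe"), strand = 1L,
                     kind = c("degenerate-tRNA", "tRNA"))
  map <- build_architecture(region, motif_hits = hits, trna_hits = trna)
  expect_equal(map$start, c(10, 10, 50, 150))
  # identical starts tie-break by (start, end, label)
  expect_equal(map$label[1:2], c("Phe-degenerate", "TAS"))
  expect_error(build_architecture(region,
                                  motif_hits = data.frame(label = "x",
                                                          start = -5, end = 2,
                                                          strand = 1L)),
               "outside")
  txt <- architecture_text(map)
  expect_length(txt, 4)
})
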