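# degenerate motif scanning: TAS and CSB queries, A/C context, conservation

test_that("TAS scanning finds the planted minimal sites", {
  # minimal planted match: 3 + 8 + 3 bp
  h <- scan_tas("ATGAAAAAAAACAT")
  expect_equal(nrow(h), 1)
  expect_equal(c(h$start, h$end, h$spacer), c(0, 14, 8))
  expect_equal(h$match, "ATGAAAAAAAACAT")
  expect_equal(nrow(scan_tas("")), 0)
  # the TAS query is its own reverse complement (revcomp(CAT) = ATG), so a
  # site is seen from both strands; both-strand scans report the +/- pair
  site <- "ATGTTCCGGAACAT"
  rc_region <- paste0("GG", revcomp(site), "GG")
  hm <- scan_tas(rc_region, both_strands = TRUE)
  expect_equal(nrow(hm), 2)
  expect_setequal(hm$strand, c(1, -1))
  expect_equal(unique(hm$start), 2)
  expect_equal(hm$match[hm$strand == -1], site)
})

test_that("strand mapping is correct for an asymmetric motif", {
  m <- degenerate_motif("X", list("AACG", spacer(2, 3), "TTGC"),
                        strand_policy = "both")
  site <- paste0("AACG", "GA", "TTGC")
  region <- paste0("TTTT", revcomp(site), "TTTT")
  expect_equal(nrow(scan_degenerate(region, m, both_strands = FALSE)), 0)
  h <- scan_degenerate(region, m)
  expect_equal(nrow(h), 1)
  expect_equal(c(h$start, h$end, h$strand, h$spacer), c(4, 14, -1, 2))
  expect_equal(h$match, site)
})

test_that("scan_degenerate equals regex enumeration on random regions", {
  set.seed(101)
  for (rep in 1:10) {
    region <- random_dna(2000, gc = 0.5)
    # plant 4 TAS sites, 2 per strand
    plant <- function(region, site, at) {
      paste0(substr(region, 1, at), site, substr(region, at + nchar(site) + 1,
                                                 nchar(region)))
    }
    for (at in c(100, 600)) region <- plant(region, "ATGACGTACGTCAT", at)
    for (at in c(1200, 1700)) region <- plant(region, revcomp("ATGACGTACGCAT"), at)
    got <- scan_tas(region, both_strands = TRUE)
    exp <- oracle_scan_regex(region, "ATG", 8:9, "CAT", both_strands = TRUE)
    expect_identical(hit_signature(got), hit_signature(exp))
    expect_gte(nrow(got), 4)
  }
})

test_that("genome N never matches pattern literals, only pattern N", {
  expect_equal(nrow(scan_tas("ATGNNNNNNNNCAT")), 1)  # spacer N's match N
  expect_equal(nrow(scan_tas("ATNAAAAAAAACAT")), 0)  # N vs literal G fails
  expect_error(degenerate_motif("bad", list("AXG")), "invalid IUPAC")
})

test_that("CSB I canonical and relaxed modes behave as specified", {
  hit <- paste0("AT", random_dna(20), "GACA")
  set.seed(8)
  region <- paste0(random_dna(50, gc = 0.3), hit, random_dna(50, gc = 0.3))
  h <- scan_csb(region, "I")
  expect_gte(nrow(h), 1)
  expect_true(has_exact_span(h, c(50, 50 + nchar(hit))))
  # GATA-like third-base variant: canonical misses, relaxed finds
  v <- paste0("ATG", strrep("T", 15), "GATA")
  expect_equal(nrow(scan_csb(v, "I")), 0)
  hr <- scan_csb(v, "I", mode = "relaxed", free_third_base = TRUE)
  # both the AT (spacer 16) and ATG (spacer 15) alternatives realize the site
  expect_equal(nrow(hr), 2)
  expect_true(has_exact_span(hr, c(0, 22)))
  expect_equal(unique(hr$mode), "relaxed")
  # relaxed spacer cap: 60 bp distance only matches in relaxed mode
  far <- paste0("AT", strrep("T", 60), "GACA")
  expect_equal(nrow(scan_csb(far, "I")), 0)
  expect_equal(nrow(scan_csb(far, "I", mode = "relaxed")), 1)
  expect_error(scan_csb(far, "IV"), "unknown CSB")
})

test_that("CSB II matches its own literal with NNN free", {
  h <- scan_csb("AAACCCCCCTTTCCC", "II")
  expect_equal(nrow(h), 1)
  expect_equal(c(h$start, h$end), c(0, 15))
})

test_that("CSB III context rule filters by pooled flank A/C fraction", {
  # flanks engineered to exactly 60% A/C (12 of 20 per side)
  flank <- paste0(strrep("AC", 6), strrep("GT", 4))
  region <- paste0(flank, "AAACCCC", flank)
  expect_equal(ac_fraction(region, 20, 27, 20), 0.6)
  expect_equal(nrow(scan_csb(region, "III")), 0)              # threshold 0.8
  expect_equal(nrow(scan_csb(region, "III", min_ac = 0.5)), 1)
  h <- scan_csb(region, "III", min_ac = 0.5)
  expect_equal(h$context_score, 0.6)
})

test_that("ac_fraction equals a per-base count oracle", {
  expect_equal(ac_fraction("AAAAXXCCCC", 4, 6, 4), 1.0)
  expect_equal(ac_fraction("ATGCXXATGC", 4, 6, 4), 0.5)
  set.seed(12)
  s <- random_dna(1000)
  for (rep in 1:10) {
    a <- sample(0:900, 1); b <- a + sample(1:50, 1)
    fl <- sample(0:30, 1)
    left <- substring(s, max(1, a - fl + 1), a)
    right <- substring(s, b + 1, min(1000, b + fl))
    ch <- strsplit(paste0(left, right), "")[[1]]
    want <- if (length(ch)) sum(ch %in% c("A", "C")) / length(ch) else NA_real_
    expect_equal(ac_fraction(s, a, b, fl), want)
  }
  expect_error(ac_fraction("ACGT", 2, 9, 5), "outside")
})

test_that("hits are invariant under linear shift of the region", {
  set.seed(31)
  core <- paste0(random_dna(60), "ATGAAAAAAAACAT", random_dna(60))
  h0 <- scan_tas(core)
  for (off in c(5, 37)) {
    h <- scan_tas(paste0(random_dna(off, gc = 1), core))  # GC-only pad, no ATG
    expect_equal(h$start - off, h0$start)
  }
})

test_that("conservation_profile matches hand-computed column fractions", {
  expect_equal(conservation_profile(c("ACGT", "ACGT", "ACGT"), 2)$column,
               rep(1, 4))
  expect_equal(conservation_profile(c("AAAA", "CCCC"), 2)$column, rep(0.5, 4))
  # 4 sequences, 10 columns, hand-tallied modal fractions
  aln <- c("AAAAACGT-T",
           "AACAACGTAT",
           "AACTACGA-T",
           "AAC-ACGAAT")
  prof <- conservation_profile(aln, 5)
  expect_equal(prof$column,
               c(1, 1, 0.75, 0.5, 1, 1, 1, 0.5, 0.5, 1))
  expect_equal(prof$window[1], mean(c(1, 1, 0.75, 0.5, 1)))
  expect_equal(length(prof$window), 6)
  expect_error(conservation_profile(c("ACG", "AC")), "ragged")
  expect_error(conservation_profile("ACG"), ">= 2")
})
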