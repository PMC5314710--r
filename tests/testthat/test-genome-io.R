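# genome container, GenBank round trip, circular regions, feature tables

test_that("minimal GenBank records parse with the stated conventions", {
  gb <- c(
    "LOCUS       test01 140 bp DNA circular VRT",
    "DEFINITION  toy genome",
    "FEATURES             Location/Qualifiers",
    "     source          1..140",
    "     tRNA            1..70",
    "                     /gene=\"tRNA-Phe\"",
    "     tRNA            complement(71..140)",
    "                     /gene=\"trnQ\"",
    "ORIGIN",
    paste("        1", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste("       61", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste("      121", "acgtacgtac acgtacgtac"),
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  g <- read_genbank(path)
  expect_equal(nchar(g$sequence), 140)
  expect_true(g$circular)
  # 1-based inclusive -> 0-based half-open
  phe <- g$features[g$features$locus == "Phe", ]
  expect_equal(c(phe$start, phe$end, phe$strand), c(0, 70, 1))
  # synonym normalization + complement strand
  gln <- g$features[g$features$locus == "Gln", ]
  expect_equal(c(gln$start, gln$end, gln$strand), c(70, 140, -1))
})

test_that("GenBank parse errors name the problem", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       bad 10 bp", "FEATURES",
               "     tRNA            5..x",
               "                     /gene=\"trnF\"",
               "ORIGIN", "        1 acgtacgtac", "//"), path)
  expect_error(read_genbank(path), "line 3.*malformed")
  writeLines(c("LOCUS       bad 10 bp", "FEATURES"), path)
  expect_error(read_genbank(path), "ORIGIN")
})

test_that("duplicate identical core spans are rejected", {
  feats <- data.frame(locus = c("Phe", "Val"), start = c(0, 0), end = c(70, 70),
                      strand = 1L, feature_class = "tRNA")
  expect_error(mito_genome("x", strrep("ACGT", 50), feats),
               "duplicate identical spans")
})

test_that("GenBank round trip preserves spans, strands and locus ids", {
  sim <- simulate_genome(sim_config(seed = 11, insert_spec = list(length = 300)))
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(sim$genome, path)
  g2 <- read_genbank(path)
  expect_equal(g2$sequence, sim$genome$sequence)
  f1 <- sim$genome$features[, c("locus", "start", "end", "strand")]
  f2 <- g2$features[, c("locus", "start", "end", "strand")]
  expect_equal(f2, f1)
})

test_that("region_between matches the study geometry and the base walk", {
  # round-goby-like geometry: Pro ends at 15000, Phe starts at 16920 on a
  # 19000 bp circle -> 1920 bp control region (720 bp in the small genome)
  mk <- function(L, pro_end, phe_start) {
    feats <- data.frame(locus = c("Pro", "Phe"),
                        start = c(pro_end - 69, phe_start),
                        end = c(pro_end, phe_start + 69),
                        strand = c(-1L, 1L), feature_class = "tRNA")
    mito_genome("toy", random_dna(L), feats)
  }
  set.seed(42)
  g <- mk(19000, 15000, 16920)
  r <- region_between(g, "Pro", "Phe")
  expect_equal(c(r$start, r$end - r$start), c(15000, 1920))
  expect_equal(nchar(r$seq), 1920)
  g2 <- mk(17000, 15900, 16620)
  expect_equal(with(region_between(g2, "Pro", "Phe"), end - start), 720)

  # wrapping span: b upstream of a on the linearization; oracle = base walk
  g3 <- mk(1000, 900, 150)
  r3 <- region_between(g3, "Pro", "Phe")
  expect_equal(r3$end - r3$start, oracle_walk_distance(1000, 900, 150))
  expect_equal(nchar(r3$seq), 250)
  expect_equal(r3$seq, paste0(substr(g3$sequence, 901, 1000),
                              substr(g3$sequence, 1, 150)))

  # adjacent loci share a boundary -> empty region
  g4 <- mk(1000, 500, 500)
  expect_equal(with(region_between(g4, "Pro", "Phe"), end - start), 0)

  # absent or duplicated locus errors list candidates
  expect_error(region_between(g, "Pro", "Val"), "available loci")
})

test_that("extract_span wrap equals per-base walk on random cases", {
  set.seed(7)
  for (rep in 1:20) {
    L <- sample(50:200, 1)
    s <- random_dna(L)
    start <- sample(0:(L - 1), 1)
    len <- sample(1:L, 1)
    got <- extract_span(s, start, start + len)
    chars <- strsplit(s, "")[[1]]
    idx <- ((start + seq_len(len) - 1L) %% L) + 1L
    expect_equal(got, paste(chars[idx], collapse = ""))
  }
})

test_that("feature tables are BED-style, sorted, and split wrapping rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(data.frame(start = integer(), end = integer()), path)
  expect_equal(nrow(utils::read.delim(path)), 0)

  hits <- data.frame(start = c(90, 5), end = c(110, 19),
                     label = c("wrap", "hit"), strand = c(1L, 1L))
  write_feature_table(hits, path, seq_id = "s", seq_length = 100)
  tab <- utils::read.delim(path)
  expect_equal(tab$start, c(0, 5, 90))   # wrap split into [90,100)+[0,10)
  expect_equal(tab$end, c(10, 19, 100))
  expect_equal(sum(tab$group == "wrap"), 2)
  expect_equal(tab$strand[tab$group == "hit"], "+")
})
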