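# Independent oracles used across the suite. These deliberately take
# different routes than the package implementation: regex enumeration for
# motif scanning, leftmost-first exhaustive structure enumeration for
# folding, direct adjacency listing for breakpoints, per-base walks for
# circular regions.

# enumerate all (start, end, spacer, strand) matches of
# prefix + N{spacer} + suffix via perl lookahead regexes (overlap-safe);
# prefixes may be a vector (alternatives). 0-based half-open coordinates.
oracle_scan_regex <- function(seq, prefixes, spacers, suffix = "",
                              both_strands = FALSE) {
  one_strand <- function(s) {
    out <- list()
    for (p in prefixes) for (sp in spacers) {
      rx <- sprintf("(?=%s.{%d}%s)", p, sp, suffix)
      m <- gregexpr(rx, s, perl = TRUE)[[1]]
      if (m[1] == -1) next
      w <- nchar(p) + sp + nchar(suffix)
      out[[length(out) + 1L]] <- data.frame(start = as.integer(m) - 1L,
                                            end = as.integer(m) - 1L + w,
                                            spacer = sp)
    }
    if (!length(out)) return(data.frame(start = integer(), end = integer(),
                                        spacer = integer()))
    do.call(rbind, out)
  }
  fwd <- one_strand(seq); fwd$strand <- rep(1L, nrow(fwd))
  res <- fwd
  if (both_strands) {
    n <- nchar(seq)
    rev <- one_strand(mitoarch::revcomp(seq))
    if (nrow(rev)) {
      res <- rbind(fwd, data.frame(start = n - rev$end, end = n - rev$start,
                                   spacer = rev$spacer, strand = -1L))
    }
  }
  res[order(res$start, res$end, res$spacer, res$strand), , drop = FALSE]
}

# canonical sortable signature of a hit set, for set equality checks
hit_signature <- function(df) {
  if (!nrow(df)) return(character())
  sort(sprintf("%d:%d:%d:%d", df$start, df$end, df$spacer, df$strand))
}

# exhaustive maximum base pairing: leftmost position either unpaired or
# paired with every compatible partner; non-crossing by construction
oracle_max_pairs <- function(seq, min_loop = 3) {
  ch <- strsplit(toupper(seq), "")[[1]]
  pairs_ok <- function(a, b) paste0(a, b) %in%
    c("AT", "TA", "GC", "CG", "GT", "TG", "AU", "UA", "GU", "UG")
  rec <- function(idx) {
    if (length(idx) < 2) return(0L)
    i <- idx[1]
    best <- rec(idx[-1])  # i unpaired
    for (j in idx[-1]) {
      if (j - i - 1 < min_loop) next
      if (!pairs_ok(ch[i], ch[j])) next
      inside <- idx[idx > i & idx < j]
      outside <- idx[idx > j]
      best <- max(best, 1L + rec(inside) + rec(outside))
    }
    best
  }
  rec(seq_along(ch))
}

# brute-force signed circular breakpoint count: list every neighbouring
# pair of the reference in both reading directions, then count observed
# neighbour pairs not present
oracle_breakpoints <- function(obs_loci, obs_strand, ref_loci, ref_strand) {
  lab <- function(l, s) paste0(ifelse(s > 0, "+", "-"), l)
  ref_pairs <- character()
  n <- length(ref_loci)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ref_pairs <- c(ref_pairs,
                   paste(lab(ref_loci[i], ref_strand[i]),
                         lab(ref_loci[j], ref_strand[j])),
                   paste(lab(ref_loci[j], -ref_strand[j]),
                         lab(ref_loci[i], -ref_strand[i])))
  }
  m <- length(obs_loci)
  bad <- 0L
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    p <- paste(lab(obs_loci[i], obs_strand[i]), lab(obs_loci[j], obs_strand[j]))
    if (!(p %in% ref_pairs)) bad <- bad + 1L
  }
  bad
}

# per-base walk around the circle from `from` (0-based) until hitting `to`
oracle_walk_distance <- function(L, from, to) {
  d <- 0L; i <- from
  while (i != to) { i <- (i + 1L) %% L; d <- d + 1L; if (d > L) stop("loop") }
  d
}

# plain per-position mismatch count (equal lengths)
str_mismatches_oracle <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# overlap fraction of a found span over a truth span (both 0-based half-open)
span_overlap_frac <- function(found, truth) {
  ov <- max(0, min(found[2], truth[2]) - max(found[1], truth[1]))
  ov / (truth[2] - truth[1])
}

# convenience: does any hit row reproduce the truth span exactly?
has_exact_span <- function(hits, span) {
  any(hits$start == span[1] & hits$end == span[2])
}
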