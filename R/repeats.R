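# Repeat discovery in non-coding regions: windowed dot plots, 10-nt-block
# seed-and-chain search for dispersed repeat families, majority consensus,
# period-scan tandem array detection, a maximum-pairing fold stand-in, and
# assembly of the ordered architecture map of a region.

.as_region <- function(x, id = "region") {
  if (inherits(x, "mito_region"))
    return(list(id = x$label, seq = toupper(x$seq)))
  if (is.character(x) && length(x) == 1L)
    return(list(id = id, seq = toupper(x)))
  if (is.list(x) && !is.null(x$seq))
    return(list(id = x$id %||% x$label %||% id, seq = toupper(x$seq)))
  stop("cannot interpret region input")
}

#' Windowed dot plot of two sequences
#'
#' Reports every window pair (i, j) whose identity reaches `min_identity`,
#' the classic repeat-discovery view at window lengths of 10 and 15 nt.
#'
#' @param seq_a,seq_b sequences (strings or `mito_region`s)
#' @param window_bp window length (>= 1)
#' @param min_identity minimum window identity in \[0,1\]
#' @param both_strands also compare `seq_a` to the reverse complement of
#'   `seq_b` (reported with `strand = -1`, `j` in `seq_b` forward coordinates)
#' @param exclude_self_diagonal drop the trivial i == j diagonal (self plots)
#' @return data.frame with `i`, `j` (0-based window starts), `strand`,
#'   `identity`
#' @export
dotplot <- function(seq_a, seq_b = seq_a, window_bp = 10, min_identity = 1.0,
                    both_strands = FALSE, exclude_self_diagonal = FALSE) {
  if (window_bp < 1) stop("window_bp must be >= 1")
  a <- .as_region(seq_a)$seq
  b <- .as_region(seq_b)$seq
  w <- as.integer(window_bp)
  if (w > nchar(a) || w > nchar(b)) stop("window longer than a sequence")
  va <- strsplit(a, "")[[1]]
  res <- list(data.frame(i = integer(), j = integer(), strand = integer(),
                         identity = double()))
  scan_vs <- function(vb, strand) {
    na <- length(va); nb <- length(vb)
    for (d in (-(na - w)):(nb - w)) {
      iA <- max(1L, 1L - d):min(na, nb - d)
      if (length(iA) < w) next
      m <- va[iA] == vb[iA + d]
      cs <- cumsum(c(0L, m))
      roll <- (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
      keep <- which(roll >= min_identity)
      if (!length(keep)) next
      i0 <- iA[keep] - 1L
      j0 <- i0 + d
      if (strand == -1L) j0 <- nb - j0 - w  # back to forward coords of b
      res[[length(res) + 1L]] <<- data.frame(i = i0, j = j0, strand = strand,
                                             identity = roll[keep])
    }
  }
  scan_vs(strsplit(b, "")[[1]], 1L)
  if (both_strands) scan_vs(strsplit(revcomp(b), "")[[1]], -1L)
  out <- do.call(rbind, res)
  if (exclude_self_diagonal)
    out <- out[!(out$strand == 1L & out$i == out$j), ]
  out <- out[order(out$i, out$j, -out$strand), ]
  rownames(out) <- NULL
  out
}

# block hits of `block` (length w) in target char vector, <= max_mismatch;
# returns 0-based start positions
.block_hits <- function(tchars, block, max_mismatch) {
  w <- nchar(block)
  n <- length(tchars)
  if (w > n) return(integer())
  bp <- strsplit(block, "")[[1]]
  mism <- integer(n - w + 1L)
  idx <- seq_len(n - w + 1L)
  for (j in seq_len(w)) mism <- mism + (tchars[idx + j - 1L] != bp[j])
  idx[mism <= max_mismatch] - 1L
}

#' Discover dispersed repeat families by block tiling
#'
#' Tiles the query region into consecutive non-overlapping `block_bp` blocks,
#' locates every near-exact occurrence of each block in all target regions on
#' both strands, chains hits with consistent query/target offsets into
#' matching segments, and groups mutually overlapping segment end-points into
#' repeat families. This automates the manual seed-at-10-nt-granularity
#' repeat mapping used for non-coding mitogenome regions.
#'
#' @param query_region a `mito_region`, string, or list(id=, seq=)
#' @param target_regions list of regions (same forms); typically the
#'   non-coding regions of several genomes, possibly including the query
#' @param block_bp block (seed) length; must be >= 4
#' @param max_mismatch mismatches tolerated per block (default 1)
#' @param chain_gap offset consistency tolerance between chained hits,
#'   in blocks
#' @param max_gap_blocks largest run of unmatched blocks bridged by a chain
#' @param min_blocks minimum matched blocks per reported segment; the default
#'   3 (~30 bp at 10-nt blocks) keeps chance two-block diagonals out of
#'   random sequence
#' @param min_occ_overlap occurrence-merge overlap fraction
#' @return list of `repeat_family` objects: `label`, `members` (data.frame
#'   region_id, start, end, strand, seq; strand is the member's orientation
#'   relative to the family reference member), `consensus`, `mean_identity`
#' @export
find_repeats <- function(query_region, target_regions, block_bp = 10,
                         max_mismatch = 1, chain_gap = 1, max_gap_blocks = 5,
                         min_blocks = 3, min_occ_overlap = 0.5) {
  if (block_bp < 4) stop("block_bp < 4 is an uninformative seed")
  q <- .as_region(query_region, "query")
  targets <- lapply(seq_along(target_regions), function(i)
    .as_region(target_regions[[i]],
               names(target_regions)[i] %||% paste0("target", i)))
  w <- as.integer(block_bp)
  nq <- nchar(q$seq)
  qstarts <- seq(0L, nq - w, by = w)
  blocks <- substring(q$seq, qstarts + 1L, qstarts + w)

  hits <- list()
  for (tg in targets) {
    for (strand in c(1L, -1L)) {
      tseq <- if (strand == 1L) tg$seq else revcomp(tg$seq)
      tchars <- strsplit(tseq, "")[[1]]
      nt <- length(tchars)
      for (bi in seq_along(blocks)) {
        pos <- .block_hits(tchars, blocks[bi], max_mismatch)
        if (!length(pos)) next
        tpos <- if (strand == 1L) pos else nt - (pos + w)  # forward coords
        qpos <- qstarts[bi]
        if (identical(tg$seq, q$seq) && tg$id == q$id && strand == 1L)
          tpos <- tpos[tpos != qpos]  # drop the trivial self-identity
        if (!length(tpos)) next
        hits[[length(hits) + 1L]] <- data.frame(
          target = tg$id, strand = strand, qpos = qpos, tpos = tpos)
      }
    }
  }
  if (!length(hits)) return(list())
  hits <- do.call(rbind, hits)
  # diagonal: constant along a co-linear repeat (anti-diagonal on minus)
  hits$diag <- ifelse(hits$strand == 1L, hits$tpos - hits$qpos,
                      hits$tpos + hits$qpos)

  # chain within (target, strand) by offset consistency and bounded gaps
  segs <- list()
  for (key in unique(paste(hits$target, hits$strand))) {
    h <- hits[paste(hits$target, hits$strand) == key, ]
    h <- h[order(h$qpos, h$tpos), ]
    assigned <- rep(0L, nrow(h)); nch <- 0L
    chains <- list()
    for (i in seq_len(nrow(h))) {
      placed <- FALSE
      for (ci in rev(seq_len(nch))) {
        last <- chains[[ci]][length(chains[[ci]])]
        if (h$qpos[i] - h$qpos[last] <= (max_gap_blocks + 1L) * w &&
            abs(h$diag[i] - h$diag[last]) <= chain_gap * w &&
            h$qpos[i] > h$qpos[last]) {
          chains[[ci]] <- c(chains[[ci]], i); placed <- TRUE; break
        }
      }
      if (!placed) { nch <- nch + 1L; chains[[nch]] <- i }
    }
    for (ch in chains) {
      if (length(ch) < min_blocks) next
      qs <- range(h$qpos[ch]); ts <- range(h$tpos[ch])
      segs[[length(segs) + 1L]] <- data.frame(
        target = h$target[ch[1]], strand = h$strand[ch[1]],
        q_start = qs[1], q_end = qs[2] + w, t_start = ts[1], t_end = ts[2] + w)
    }
  }
  if (!length(segs)) return(list())
  segs <- do.call(rbind, segs)

  # occurrences: both end-points of every segment
  occ <- rbind(
    data.frame(region = q$id, start = segs$q_start, end = segs$q_end,
               strand = 1L, seg = seq_len(nrow(segs))),
    data.frame(region = segs$target, start = segs$t_start, end = segs$t_end,
               strand = segs$strand, seg = seq_len(nrow(segs))))

  # union-find: same-region overlapping occurrences merge; each segment links
  # its two end-points
  n <- nrow(occ)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (occ$region[i] != occ$region[j]) next
    ov <- min(occ$end[i], occ$end[j]) - max(occ$start[i], occ$start[j])
    if (ov >= min_occ_overlap * min(occ$end[i] - occ$start[i],
                                    occ$end[j] - occ$start[j]))
      union_(i, j)
  }
  occ$node <- vapply(seq_len(n), find, 0L)
  # merged node extents
  nodes <- do.call(rbind, lapply(split(occ, occ$node), function(d) data.frame(
    node = d$node[1], region = d$region[1], start = min(d$start),
    end = max(d$end))))
  # connect nodes through segments, then components = families
  parent2 <- stats::setNames(nodes$node, nodes$node)
  find2 <- function(i) { i <- as.character(i)
    while (parent2[i] != i) { parent2[i] <<- parent2[as.character(parent2[i])]; i <- as.character(parent2[i]) }
    as.integer(i) }
  for (s in seq_len(nrow(segs))) {
    pair <- occ$node[occ$seg == s]
    r1 <- find2(pair[1]); r2 <- find2(pair[2])
    if (r1 != r2) parent2[as.character(r1)] <- r2
  }
  nodes$family <- vapply(nodes$node, find2, 0L)

  # segment edges between merged nodes; sign -1 when the segment matched the
  # reverse complement, so member orientation propagates from a reference
  edges <- do.call(rbind, lapply(seq_len(nrow(segs)), function(s) {
    pair <- occ$node[occ$seg == s]
    data.frame(n1 = pair[1], n2 = pair[2], sign = segs$strand[s])
  }))

  target_seqs <- stats::setNames(
    c(list(q$seq), lapply(targets, `[[`, "seq")),
    c(q$id, vapply(targets, `[[`, "", "id")))
  fams <- list()
  for (fid in unique(nodes$family)) {
    mem <- nodes[nodes$family == fid, c("node", "region", "start", "end")]
    mem <- unique(mem)
    if (nrow(mem) < 2) next
    mem <- mem[order(mem$region, mem$start), ]
    # orient members by BFS over segment links from the first member
    orient <- stats::setNames(rep(NA_integer_, nrow(mem)), mem$node)
    orient[1] <- 1L
    queue <- mem$node[1]
    fedges <- edges[edges$n1 %in% mem$node & edges$n2 %in% mem$node, ]
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      touch <- fedges[fedges$n1 == cur | fedges$n2 == cur, , drop = FALSE]
      for (e in seq_len(nrow(touch))) {
        other <- if (touch$n1[e] == cur) touch$n2[e] else touch$n1[e]
        key <- as.character(other)
        if (is.na(orient[key])) {
          orient[key] <- orient[as.character(cur)] * touch$sign[e]
          queue <- c(queue, other)
        }
      }
    }
    orient[is.na(orient)] <- 1L
    mem$strand <- unname(orient[as.character(mem$node)])
    mem$node <- NULL
    mem$seq <- vapply(seq_len(nrow(mem)), function(i) {
      s <- substr(target_seqs[[mem$region[i]]], mem$start[i] + 1L, mem$end[i])
      if (mem$strand[i] == -1L) revcomp(s) else s
    }, "")
    rownames(mem) <- NULL
    fam <- structure(list(label = NA_character_, members = mem,
                          consensus = NA_character_,
                          mean_identity = NA_real_),
                     class = "repeat_family")
    fam$consensus <- tryCatch(consensus(fam), error = function(e) NA_character_)
    ids <- utils::combn(seq_len(nrow(mem)), 2, function(p) {
      l <- min(nchar(mem$seq[p]))
      str_identity(substr(mem$seq[p[1]], 1, l), substr(mem$seq[p[2]], 1, l))
    })
    fam$mean_identity <- mean(ids)
    fams[[length(fams) + 1L]] <- fam
  }
  if (!length(fams)) return(list())
  sizes <- vapply(fams, function(f) sum(f$members$end - f$members$start), 0)
  fams <- fams[order(-sizes)]
  for (i in seq_along(fams)) fams[[i]]$label <- paste0("RF_", i)
  fams
}

#' @export
print.repeat_family <- function(x, ...) {
  cat(sprintf("<repeat_family> %s: %d members, consensus %d bp, mean identity %.3f\n",
              x$label, nrow(x$members), nchar(x$consensus), x$mean_identity))
  invisible(x)
}

#' Majority-vote consensus of a repeat family
#'
#' Gapless column mapping anchored at the members' chained start offsets:
#' member sequences (minus-strand members reverse-complemented at extraction)
#' are stacked left-aligned and each column takes the majority base. Ties are
#' broken by the fixed base order A < C < G < T and flagged in the
#' `"ties"` attribute.
#'
#' @param family a `repeat_family`, or a character vector of >= 2 member
#'   sequences
#' @return consensus DNA string with a `ties` attribute (0-based tied columns)
#' @export
consensus <- function(family) {
  seqs <- if (inherits(family, "repeat_family")) family$members$seq else family
  if (length(seqs) < 2) stop("consensus needs >= 2 members")
  lens <- nchar(seqs)
  if (max(lens) > 2 * min(lens))
    stop("member lengths differ by more than 2x; consider splitting the family")
  wmax <- max(lens)
  mat <- do.call(rbind, lapply(seqs, function(s)
    c(strsplit(s, "")[[1]], rep(NA, wmax - nchar(s)))))
  bases <- c("A", "C", "G", "T")
  ties <- integer()
  cons <- vapply(seq_len(wmax), function(j) {
    col <- mat[, j]; col <- col[!is.na(col)]
    tab <- table(factor(col, levels = bases))
    top <- which(tab == max(tab))
    if (length(top) > 1) ties <<- c(ties, j - 1L)
    bases[top[1]]
  }, "")
  structure(paste(cons, collapse = ""), ties = ties)
}

#' Detect tandem repeat arrays by period scanning
#'
#' For each candidate period p the sequence is compared to itself shifted by
#' p; maximal runs where the rolling adjacent-copy identity stays above
#' `min_adjacent_identity` are reported as arrays. Overlapping reports across
#' periods are merged keeping the highest-identity period, with a small
#' per-bp penalty so the fundamental period wins over its harmonics.
#'
#' @param seq sequence (string or `mito_region`)
#' @param min_period,max_period period bounds in bp (`min_period >= 2`). The
#'   default floor of 20 bp exists because two adjacent windows below ~20 bp
#'   reach 0.8 identity by chance in random sequence (binomial tail); lower
#'   it only when hunting short-period arrays deliberately
#' @param min_copies minimum copy number (may be fractional)
#' @param min_adjacent_identity minimum mean adjacent-copy identity
#' @param harmonic_penalty identity penalty per bp of period at selection
#' @return data.frame with `start`, `end`, `period`, `copies`, `identity`
#' @export
find_tandem <- function(seq, min_period = 20, max_period = NULL,
                        min_copies = 2.0, min_adjacent_identity = 0.8,
                        harmonic_penalty = 5e-4) {
  if (min_period < 2) stop("min_period must be >= 2")
  s <- .as_region(seq)$seq
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  if (is.null(max_period)) max_period <- n %/% 2
  cand <- list()
  for (p in seq.int(min_period, max(min_period, max_period))) {
    if (2L * p > n) break
    m <- ch[1:(n - p)] == ch[(p + 1):n]
    cs <- cumsum(c(0L, m))
    K <- length(m) - p + 1L  # rolling window of width p
    if (K < 1L) next
    roll <- (cs[(p + 1):(p + K)] - cs[1:K]) / p
    ok <- roll >= min_adjacent_identity
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (ri in which(r$values)) {
      k1 <- starts[ri]; k2 <- ends[ri]
      a_start <- k1 - 1L
      a_end <- (k2 - 1L) + 2L * p
      copies <- (a_end - a_start) / p
      if (copies < min_copies) next
      cand[[length(cand) + 1L]] <- data.frame(
        start = a_start, end = a_end, period = p, copies = copies,
        identity = mean(roll[k1:k2]))
    }
  }
  empty <- data.frame(start = integer(), end = integer(), period = integer(),
                      copies = double(), identity = double())
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  score <- cand$identity - harmonic_penalty * cand$period
  cand <- cand[order(-score, cand$period, cand$start), ]
  kept <- empty
  for (i in seq_len(nrow(cand))) {
    ov <- nrow(kept) && any(pmin(kept$end, cand$end[i]) -
                            pmax(kept$start, cand$start[i]) >
                            0.5 * pmin(kept$end - kept$start,
                                       cand$end[i] - cand$start[i]))
    if (!ov) kept <- rbind(kept, cand[i, ])
  }
  kept <- kept[order(kept$start), ]
  rownames(kept) <- NULL
  kept
}

# ---- Maximum-pairing fold stand-in ----------------------------------------

.PAIRS <- c(AT = TRUE, TA = TRUE, AU = TRUE, UA = TRUE, GC = TRUE, CG = TRUE,
            GT = TRUE, TG = TRUE, GU = TRUE, UG = TRUE)

can_pair <- function(a, b) isTRUE(.PAIRS[paste0(a, b)])

#' Folding propensity by maximum base pairing
#'
#' A deliberately simple stand-in for free-energy folding: the maximum
#' number of non-crossing Watson-Crick + GU pairs with hairpin loops of at
#' least `min_loop` unpaired bases, by dynamic programming. The result
#' records `method = "max-pairing"` so scores are never mistaken for
#' minimum-free-energy values.
#'
#' @param seq DNA or RNA string
#' @param min_loop minimum hairpin loop length (default 3)
#' @return list of class `fold_result`: `pairs` (2-column 0-based index
#'   matrix), `pair_count`, `structure` (dot-bracket), `method`
#' @export
fold_propensity <- function(seq, min_loop = 3) {
  s <- toupper(if (inherits(seq, "mito_region")) seq$seq else seq)
  if (grepl("[^ACGTUN]", s)) stop("non-DNA/RNA alphabet in sequence")
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (n < min_loop + 2)
    stop("sequence shorter than min_loop + 2")
  M <- matrix(0L, n, n)
  for (len in (min_loop + 1L):(n - 1L)) {
    for (i in 1:(n - len)) {
      j <- i + len
      best <- M[i, j - 1L]
      for (k in i:(j - min_loop - 1L)) {
        if (can_pair(ch[k], ch[j])) {
          v <- 1L + (if (k > i) M[i, k - 1L] else 0L) +
            (if (k + 1L <= j - 1L) M[k + 1L, j - 1L] else 0L)
          if (v > best) best <- v
        }
      }
      M[i, j] <- best
    }
  }
  pairs <- matrix(integer(), 0, 2)
  tb <- function(i, j) {
    while (i < j) {
      if (M[i, j] == M[i, j - 1L]) { j <- j - 1L; next }
      for (k in i:(j - min_loop - 1L)) {
        if (can_pair(ch[k], ch[j])) {
          v <- 1L + (if (k > i) M[i, k - 1L] else 0L) +
            (if (k + 1L <= j - 1L) M[k + 1L, j - 1L] else 0L)
          if (v == M[i, j]) {
            pairs <<- rbind(pairs, c(k - 1L, j - 1L))
            if (k > i) tb(i, k - 1L)
            i <- k + 1L; j <- j - 1L
            break
          }
        }
      }
    }
  }
  if (n >= 2) tb(1L, n)
  db <- rep(".", n)
  if (nrow(pairs)) { db[pairs[, 1] + 1L] <- "("; db[pairs[, 2] + 1L] <- ")" }
  structure(list(pairs = pairs, pair_count = nrow(pairs),
                 structure = paste(db, collapse = ""),
                 method = "max-pairing"),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result> %d pairs (%s)\n%s\n", x$pair_count, x$method,
              x$structure))
  invisible(x)
}

# ---- Architecture map ------------------------------------------------------

#' Assemble the ordered architecture map of a region
#'
#' Merges motif hits, repeat-family members, tandem arrays and tRNA
#' annotations (all in the same region-local coordinates) into one ordered
#' element list, the machine-readable counterpart of a to-scale architecture
#' drawing of a control region.
#'
#' @param region a `mito_region` (or list(id=, seq=)); elements must lie in
#'   \[0, region length\]
#' @param motif_hits hit data.frame from the scanners (optional)
#' @param families list of `repeat_family` (optional); only members on this
#'   region are included
#' @param tandems data.frame from [find_tandem()] (optional)
#' @param trna_hits data.frame with `start`, `end`, `label`, `strand`,
#'   optional `kind` ("tRNA" or "degenerate-tRNA"; default "tRNA")
#' @return data.frame of class `architecture_map`: `kind`, `start`, `end`,
#'   `label`, `strand`, sorted by (start, end, label); overlaps preserved
#' @export
build_architecture <- function(region, motif_hits = NULL, families = NULL,
                               tandems = NULL, trna_hits = NULL) {
  rg <- .as_region(region)
  L <- nchar(rg$seq)
  rows <- list(data.frame(kind = character(), start = integer(),
                          end = integer(), label = character(),
                          strand = integer(), stringsAsFactors = FALSE))
  if (!is.null(motif_hits) && nrow(motif_hits))
    rows[[length(rows) + 1L]] <- data.frame(
      kind = motif_hits$label, start = motif_hits$start, end = motif_hits$end,
      label = motif_hits$label, strand = motif_hits$strand)
  if (!is.null(families)) for (f in families) {
    m <- f$members[f$members$region == rg$id, , drop = FALSE]
    if (nrow(m))
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "repeat", start = m$start, end = m$end, label = f$label,
        strand = m$strand)
  }
  if (!is.null(tandems) && nrow(tandems))
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "tandem", start = tandems$start, end = tandems$end,
      label = sprintf("tandem_p%d", tandems$period), strand = 1L)
  if (!is.null(trna_hits) && nrow(trna_hits))
    rows[[length(rows) + 1L]] <- data.frame(
      kind = trna_hits$kind %||% rep("tRNA", nrow(trna_hits)),
      start = trna_hits$start, end = trna_hits$end, label = trna_hits$label,
      strand = trna_hits$strand)
  map <- do.call(rbind, rows)
  if (nrow(map) && (any(map$start < 0) || any(map$end > L)))
    stop("element outside region [0,", L, ")")
  map <- map[order(map$start, map$end, map$label), ]
  rownames(map) <- NULL
  class(map) <- c("architecture_map", class(map))
  attr(map, "region_id") <- rg$id
  attr(map, "region_length") <- L
  map
}

#' Render an architecture map as a scaled text diagram
#'
#' @param map an `architecture_map`
#' @param width diagram width in characters
#' @return character vector of lines, one per element
#' @export
architecture_text <- function(map, width = 80) {
  L <- attr(map, "region_length")
  vapply(seq_len(nrow(map)), function(i) {
    a <- max(1L, round(map$start[i] / L * width))
    b <- max(a, round(map$end[i] / L * width))
    bar <- paste0(strrep(" ", a - 1L), strrep("=", b - a + 1L))
    sprintf("%-*s %s [%d,%d)", width, bar, map$label[i], map$start[i], map$end[i])
  }, "")
}
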