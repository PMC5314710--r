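# Degenerate motif scanning for control-region elements: TAS sites
# (ATG + 8-9 arbitrary bases + CAT) and CSB I/II/III queries, plus the
# A/C-context score used to localize CSB III and alignment conservation
# profiles used to narrow the search region.

#' Build a degenerate motif
#'
#' A motif is an ordered list of elements, each either an IUPAC literal or a
#' bounded spacer; optional alternatives allow queries like "AT or ATG
#' followed by GACA". Spacers match any bases (including N).
#'
#' @param label motif name (e.g. "TAS", "CSB-I")
#' @param elements list; each element is either a character scalar (IUPAC
#'   literal) or `spacer(min, max)`
#' @param alternatives optional list of element-lists; the motif matches if
#'   any alternative matches (`elements` is ignored when given)
#' @param context_rule optional list(flank_bp=, min_ac=): keep hits only when
#'   the pooled A/C fraction of both flanks reaches `min_ac`
#' @param strand_policy "given" (forward only) or "both"
#' @return object of class `degenerate_motif`
#' @export
degenerate_motif <- function(label, elements, alternatives = NULL,
                             context_rule = NULL, strand_policy = "given") {
  alts <- if (is.null(alternatives)) list(elements) else alternatives
  for (alt in alts) {
    for (el in alt) {
      if (is.character(el)) {
        if (!nzchar(el)) stop("empty IUPAC literal in motif ", label)
        bad <- setdiff(strsplit(toupper(el), "")[[1]], names(IUPAC_SETS))
        if (length(bad))
          stop("invalid IUPAC character(s) in motif ", label, ": ",
               paste(bad, collapse = ""))
      } else if (is.list(el) && identical(el$type, "spacer")) {
        if (el$min > el$max || el$min < 0) stop("invalid spacer bounds in ", label)
      } else stop("motif elements must be IUPAC literals or spacer()")
    }
  }
  structure(list(label = label, alternatives = alts,
                 context_rule = context_rule, strand_policy = strand_policy),
            class = "degenerate_motif")
}

#' Bounded spacer element for [degenerate_motif()]
#' @param min,max spacer length bounds in bp
#' @export
spacer <- function(min, max = min) list(type = "spacer", min = as.integer(min),
                                        max = as.integer(max))

# expand one alternative into concrete templates: strings over IUPAC where
# spacer bases are 'N'; returns data.frame(template, spacer_len)
.expand_templates <- function(alt) {
  lits <- vapply(alt, function(el) if (is.character(el)) toupper(el) else NA_character_, "")
  spacer_ranges <- lapply(alt, function(el)
    if (is.list(el)) seq.int(el$min, el$max) else 0L)
  grid <- expand.grid(rev(spacer_ranges))[, rev(seq_along(alt)), drop = FALSE]
  templates <- apply(grid, 1L, function(row) {
    paste(vapply(seq_along(alt), function(i) {
      if (is.na(lits[i])) strrep("N", row[i]) else lits[i]
    }, ""), collapse = "")
  })
  spl <- apply(grid, 1L, function(row) sum(row[is.na(lits)]))
  unique(data.frame(template = templates, spacer_len = spl,
                    stringsAsFactors = FALSE))
}

# all 0-based starts where `template` (IUPAC, N = wildcard-incl-N) matches
# the char vector `chars`; genome N matches only pattern N
.match_template <- function(chars, template) {
  w <- nchar(template)
  n <- length(chars)
  if (w > n) return(integer())
  pat <- strsplit(template, "")[[1]]
  ok <- rep(TRUE, n - w + 1L)
  idx <- seq_len(n - w + 1L)
  for (j in seq_len(w)) {
    p <- pat[j]
    if (p == "N") next
    ok <- ok & (chars[idx + j - 1L] %in% IUPAC_SETS[[p]])
    if (!any(ok)) return(integer())
  }
  idx[ok] - 1L
}

#' Scan a region for a degenerate motif
#'
#' Reports every distinct (start, spacer-assignment, alternative) match on
#' the requested strand(s). Overlapping hits are all reported (tandem-embedded
#' TAS arrays require this); no greedy masking is applied.
#'
#' @param region_seq region sequence (plain string) or a `mito_region`
#' @param motif a [degenerate_motif()]
#' @param both_strands override the motif's strand policy
#' @param mode tag recorded on the hits ("canonical" or "relaxed")
#' @return data.frame of hits: `label`, `start`, `end` (region-local 0-based
#'   half-open), `strand`, `match`, `spacer`, `context_score`, `mode`,
#'   ordered by (start, strand)
#' @export
scan_degenerate <- function(region_seq, motif, both_strands = NULL,
                            mode = "canonical") {
  if (inherits(region_seq, "mito_region")) region_seq <- region_seq$seq
  region_seq <- toupper(region_seq)
  n <- nchar(region_seq)
  both <- both_strands %||% identical(motif$strand_policy, "both")
  empty <- data.frame(label = character(), start = integer(), end = integer(),
                      strand = integer(), match = character(),
                      spacer = integer(), context_score = double(),
                      mode = character(), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  strands <- if (both) c(1L, -1L) else 1L
  out <- list(empty)
  for (strand in strands) {
    s <- if (strand == 1L) region_seq else revcomp(region_seq)
    chars <- strsplit(s, "")[[1]]
    for (alt in motif$alternatives) {
      tpl <- .expand_templates(alt)
      for (k in seq_len(nrow(tpl))) {
        w <- nchar(tpl$template[k])
        starts <- .match_template(chars, tpl$template[k])
        if (!length(starts)) next
        st <- if (strand == 1L) starts else n - (starts + w)
        hits <- data.frame(label = motif$label, start = st, end = st + w,
                           strand = strand,
                           match = substring(s, starts + 1L, starts + w),
                           spacer = tpl$spacer_len[k],
                           context_score = NA_real_, mode = mode,
                           stringsAsFactors = FALSE)
        out[[length(out) + 1L]] <- hits
      }
    }
  }
  hits <- do.call(rbind, out)
  hits <- unique(hits)
  if (!is.null(motif$context_rule) && nrow(hits)) {
    cr <- motif$context_rule
    hits$context_score <- vapply(seq_len(nrow(hits)), function(i)
      ac_fraction(region_seq, hits$start[i], hits$end[i], cr$flank_bp), 0)
    hits <- hits[!is.na(hits$context_score) & hits$context_score >= cr$min_ac, ]
  }
  hits <- hits[order(hits$start, -hits$strand, hits$end, hits$spacer), ]
  rownames(hits) <- NULL
  hits
}

#' TAS motif query
#'
#' The termination-associated-site query ATG, an 8-9 bp spacer, then CAT.
#' @param strand_policy "given" or "both"
#' @return a [degenerate_motif()]
#' @export
tas_motif <- function(strand_policy = "given") {
  degenerate_motif("TAS", list("ATG", spacer(8, 9), "CAT"),
                   strand_policy = strand_policy)
}

#' Scan for TAS sites
#'
#' Convenience wrapper fixing the TAS query (`ATG N(8-9) CAT`).
#' @inheritParams scan_degenerate
#' @param both_strands search both strands
#' @return hit data.frame as in [scan_degenerate()]
#' @export
scan_tas <- function(region_seq, both_strands = FALSE) {
  scan_degenerate(region_seq, tas_motif(), both_strands = both_strands)
}

#' CSB motif queries
#'
#' Canonical queries: CSB I is "AT or ATG followed in some distance by GACA"
#' (the unstated distance is made concrete as a 10-40 bp spacer, relaxed cap
#' 80 bp); CSB II is the literal AAACCCCCCNNNCCC; CSB III is AAACCCC within
#' an otherwise A/C-homopolymer rich region (pooled flank A/C fraction >= 0.8
#' over 20 bp flanks by default). Relaxed CSB I optionally frees the third
#' base of the GACA core to N.
#'
#' @param which "I", "II" or "III"
#' @param mode "canonical" or "relaxed"
#' @param spacer_min,spacer_max CSB I spacer bounds; `spacer_max` defaults to
#'   40 (canonical) or 80 (relaxed)
#' @param free_third_base relaxed CSB I: free position 3 of the GACA core
#' @param flank_bp,min_ac CSB III context rule parameters
#' @param strand_policy "given" or "both"
#' @return a [degenerate_motif()]
#' @export
csb_motif <- function(which = c("I", "II", "III"),
                      mode = c("canonical", "relaxed"),
                      spacer_min = 10, spacer_max = NULL,
                      free_third_base = FALSE,
                      flank_bp = 20, min_ac = 0.8,
                      strand_policy = "given") {
  which <- match.arg(which)
  mode <- match.arg(mode)
  if (which == "I") {
    if (is.null(spacer_max)) spacer_max <- if (mode == "relaxed") 80 else 40
    core <- if (mode == "relaxed" && free_third_base) "GANA" else "GACA"
    sp <- spacer(spacer_min, spacer_max)
    degenerate_motif("CSB-I", NULL,
                     alternatives = list(list("AT", sp, core),
                                         list("ATG", sp, core)),
                     strand_policy = strand_policy)
  } else if (which == "II") {
    degenerate_motif("CSB-II", list("AAACCCCCC", spacer(3), "CCC"),
                     strand_policy = strand_policy)
  } else {
    degenerate_motif("CSB-III", list("AAACCCC"),
                     context_rule = list(flank_bp = flank_bp, min_ac = min_ac),
                     strand_policy = strand_policy)
  }
}

#' Scan for CSB-like motifs
#'
#' @inheritParams scan_degenerate
#' @param which CSB id: "I", "II" or "III"
#' @param mode "canonical" or "relaxed"; relaxed hits carry `mode = "relaxed"`
#' @param ... passed to [csb_motif()] (spacer bounds, `free_third_base`,
#'   context thresholds)
#' @param both_strands search both strands
#' @return hit data.frame; CSB III hits carry `context_score`
#' @export
scan_csb <- function(region_seq, which, mode = "canonical", ...,
                     both_strands = FALSE) {
  if (!which %in% c("I", "II", "III")) stop("unknown CSB id: ", which)
  m <- csb_motif(which, mode = mode, ...)
  scan_degenerate(region_seq, m, both_strands = both_strands, mode = mode)
}

#' A/C fraction of the flanks of a span
#'
#' Pools both flanks (clipped at the sequence edges) and returns
#' (A count + C count) / flank bases examined. Used as the CSB III context
#' score for "an otherwise A/C-homopolymer rich region".
#'
#' @param seq sequence string
#' @param start,end 0-based half-open span within `seq`
#' @param flank_bp flank width on each side
#' @return fraction in \[0,1\]; `NA` if no flank bases exist
#' @export
ac_fraction <- function(seq, start, end, flank_bp = 20) {
  n <- nchar(seq)
  stopifnot(flank_bp >= 0)
  if (start < 0 || end > n || end < start)
    stop("span [", start, ",", end, ") outside sequence of length ", n)
  left <- substr(seq, max(1L, start - flank_bp + 1L), start)
  right <- substr(seq, end + 1L, min(n, end + flank_bp))
  flank <- paste0(left, right)
  if (!nchar(flank)) return(NA_real_)
  ch <- strsplit(flank, "")[[1]]
  sum(ch %in% c("A", "C")) / length(ch)
}

#' Conservation profile of an alignment
#'
#' Per-column identity (fraction of sequences carrying the column's modal
#' residue; gaps never win and count as mismatch) and a sliding-window mean,
#' as used to localize conserved control-region elements in a percentage-
#' identity coloured alignment.
#'
#' @param alignment character vector (or list) of equal-length aligned
#'   sequences; `-` and `.` are gaps
#' @param window_bp sliding window width
#' @return list with `column` (per-column identity) and `window`
#'   (mean over each window, length ncol - window_bp + 1)
#' @export
conservation_profile <- function(alignment, window_bp = 10) {
  alignment <- toupper(unlist(alignment))
  if (length(alignment) < 2) stop("need >= 2 sequences")
  w <- unique(nchar(alignment))
  if (length(w) != 1) stop("ragged alignment: lengths ", paste(w, collapse = ", "))
  mat <- do.call(rbind, strsplit(alignment, ""))
  mat[mat == "."] <- "-"
  col_id <- apply(mat, 2L, function(col) {
    bases <- col[col != "-"]
    if (!length(bases)) return(0)
    max(table(bases)) / length(col)
  })
  win <- NULL
  if (window_bp >= 1 && window_bp <= length(col_id)) {
    cs <- cumsum(c(0, col_id))
    win <- (cs[(window_bp + 1):length(cs)] - cs[1:(length(cs) - window_bp)]) / window_bp
  }
  list(column = unname(col_id), window = unname(win))
}
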