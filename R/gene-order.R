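# Signed circular gene orders and deviations from the canonical vertebrate
# arrangement: extraction from annotations, breakpoint counting, deviation
# window localization/classification, and collection-wide screening.

#' Extract the signed circular gene order of a genome
#'
#' Canonical loci ordered by start position around the circle, linearized at
#' the anchor locus (tRNA-Phe by default, the conventional vertebrate start).
#' Non-canonical / noncoding features are excluded with a warning.
#'
#' @param g a [mito_genome]
#' @param anchor locus id used to rotate the circular order
#' @return object of class `signed_order`: data.frame `locus`, `strand`, plus
#'   an `anchor` attribute
#' @export
extract_order <- function(g, anchor = "Phe") {
  canon <- canonical_order()$locus
  f <- g$features
  known <- f[f$locus %in% canon, , drop = FALSE]
  unknown <- setdiff(unique(f$locus), c(canon, "noncoding"))
  if (length(unknown))
    warning("excluding unknown loci: ", paste(unknown, collapse = ", "))
  if (nrow(known) < 2) stop("genome has fewer than 2 canonical features")
  dup <- unique(known$locus[duplicated(known$locus)])
  if (length(dup)) stop("duplicated canonical locus: ", paste(dup, collapse = ", "))
  known <- known[order(known$start), ]
  ord <- data.frame(locus = known$locus, strand = known$strand,
                    stringsAsFactors = FALSE)
  if (anchor %in% ord$locus) {
    i <- match(anchor, ord$locus)
    if (i > 1) ord <- rbind(ord[i:nrow(ord), ], ord[1:(i - 1), ])
  }
  rownames(ord) <- NULL
  structure(ord, class = c("signed_order", "data.frame"), anchor = anchor)
}

#' Construct a signed order directly
#'
#' @param loci character vector of locus ids in circular order
#' @param strand integer vector of +1/-1
#' @param anchor anchor locus
#' @return a `signed_order`
#' @export
signed_order <- function(loci, strand = rep(1L, length(loci)), anchor = loci[1]) {
  structure(data.frame(locus = loci, strand = as.integer(strand),
                       stringsAsFactors = FALSE),
            class = c("signed_order", "data.frame"), anchor = anchor)
}

# signed adjacency set of a circular order: each adjacency stored in a
# reversal-invariant canonical form, so (a+,b+) == (b-,a-)
.adjacency_keys <- function(loci, strand) {
  n <- length(loci)
  nxt <- c(2:n, 1L)
  vapply(seq_len(n), function(i) {
    a <- paste0(loci[i], "/", strand[i])
    b <- paste0(loci[nxt[i]], "/", strand[nxt[i]])
    ra <- paste0(loci[nxt[i]], "/", -strand[nxt[i]])
    rb <- paste0(loci[i], "/", -strand[i])
    fwd <- paste(a, b, sep = ">")
    rev <- paste(ra, rb, sep = ">")
    min(fwd, rev)
  }, "")
}

# does `obs` equal `exp` with exactly one contiguous sub-interval reversed
# and strand-flipped (including the whole window)?
.is_single_reversal <- function(obs, exp) {
  n <- nrow(exp)
  if (!identical(sort(obs$locus), sort(exp$locus))) return(FALSE)
  for (i in seq_len(n)) for (j in i:n) {
    cand <- exp
    seg <- exp[j:i, , drop = FALSE]
    seg$strand <- -seg$strand
    cand[i:j, ] <- seg
    if (identical(cand$locus, obs$locus) &&
        identical(cand$strand, obs$strand)) return(TRUE)
  }
  FALSE
}

#' Compare a signed order to the canonical vertebrate order
#'
#' Computes the signed circular breakpoint count (an observed adjacency is
#' conserved when the reference contains it directly or jointly reversed),
#' localizes minimal windows containing runs of non-canonical adjacencies,
#' and classifies each window: "swap/strand-flip" when the observed window
#' equals a single signed reversal of the reference sub-order, otherwise
#' "shuffle".
#'
#' @param order a `signed_order` covering >= 3 canonical loci
#' @param reference reference order data.frame (`locus`, `strand`); default
#'   the packaged canonical vertebrate order
#' @param cluster_gap breakpoints separated by at most this many conserved
#'   adjacencies are grouped into one deviation window
#' @return list of class `gene_order_diff`: `breakpoint_count`, `deviations`
#'   (data.frame window_loci, observed, expected, classification)
#' @export
compare_to_canonical <- function(order, reference = canonical_order(),
                                 cluster_gap = 2) {
  ref <- data.frame(locus = reference$locus, strand = reference$strand,
                    stringsAsFactors = FALSE)
  obs <- data.frame(locus = order$locus, strand = order$strand,
                    stringsAsFactors = FALSE)
  common <- intersect(obs$locus, ref$locus)
  if (length(common) < 3) stop("order must cover >= 3 canonical loci")
  obs <- obs[obs$locus %in% common, , drop = FALSE]
  refc <- ref[ref$locus %in% common, , drop = FALSE]
  n <- nrow(obs)
  ref_keys <- .adjacency_keys(refc$locus, refc$strand)
  obs_keys <- .adjacency_keys(obs$locus, obs$strand)
  bad <- !(obs_keys %in% ref_keys)  # adjacency i = (obs[i], obs[i+1 mod n])
  bp <- sum(bad)

  deviations <- data.frame(window_loci = character(), observed = character(),
                           expected = character(),
                           classification = character(),
                           stringsAsFactors = FALSE)
  if (bp > 0) {
    idx <- which(bad)
    # cluster circular breakpoint indices with gaps <= cluster_gap
    rot_gap <- (idx[1] + n - idx[length(idx)])
    groups <- list(idx[1])
    for (k in idx[-1]) {
      last <- groups[[length(groups)]]
      if (k - last[length(last)] - 1L <= cluster_gap)
        groups[[length(groups)]] <- c(last, k)
      else groups[[length(groups) + 1L]] <- k
    }
    if (length(groups) > 1 && rot_gap - 1L <= cluster_gap) {
      groups[[1]] <- c(groups[[length(groups)]], groups[[1]])
      groups[[length(groups)]] <- NULL
    }
    fmt <- function(d) paste(sprintf("%s(%s)", d$locus,
                                     ifelse(d$strand > 0, "+", "-")),
                             collapse = ",")
    for (grp in groups) {
      # window = loci strictly inside the first..last bad adjacency of the run
      first <- grp[1]; last <- grp[length(grp)]
      pos <- if (last == first) c(first, first %% n + 1L)  # isolated breakpoint
             else ((first + seq_len((last - first) %% n) - 1L) %% n) + 1L
      win_obs <- obs[pos, , drop = FALSE]
      win_ref <- refc[refc$locus %in% win_obs$locus, , drop = FALSE]
      cls <- if (nrow(win_ref) == nrow(win_obs) &&
                 .is_single_reversal(win_obs, win_ref)) "swap/strand-flip"
             else "shuffle"
      deviations <- rbind(deviations, data.frame(
        window_loci = paste(win_obs$locus, collapse = ","),
        observed = fmt(win_obs), expected = fmt(win_ref),
        classification = cls, stringsAsFactors = FALSE))
    }
  }
  structure(list(breakpoint_count = bp, deviations = deviations),
            class = "gene_order_diff")
}

#' @export
print.gene_order_diff <- function(x, ...) {
  cat(sprintf("<gene_order_diff> %d breakpoint(s), %d deviation window(s)\n",
              x$breakpoint_count, nrow(x$deviations)))
  if (nrow(x$deviations)) print.data.frame(x$deviations)
  invisible(x)
}

#' Screen a collection of genomes for gene-order deviations
#'
#' @param genomes list of [mito_genome] objects
#' @param reference reference order (default canonical)
#' @return data.frame (one row per genome, ordered by genome_id):
#'   `genome_id`, `n_loci`, `breakpoints`, `n_deviations`, `classes`,
#'   `windows`, `status`; attribute `n_flagged` counts genomes with any
#'   deviation. Unparsable/failing genomes are flagged `status = "error"`
#'   and the screen continues.
#' @export
screen_collection <- function(genomes, reference = canonical_order()) {
  rows <- lapply(genomes, function(g) {
    res <- tryCatch({
      ord <- extract_order(g)
      d <- compare_to_canonical(ord, reference)
      data.frame(genome_id = g$genome_id, n_loci = nrow(ord),
                 breakpoints = d$breakpoint_count,
                 n_deviations = nrow(d$deviations),
                 classes = paste(d$deviations$classification, collapse = ";"),
                 windows = paste(d$deviations$window_loci, collapse = ";"),
                 status = "ok", stringsAsFactors = FALSE)
    }, error = function(e) data.frame(
      genome_id = if (!is.null(g$genome_id)) g$genome_id else NA_character_,
      n_loci = NA_integer_, breakpoints = NA_integer_,
      n_deviations = NA_integer_, classes = "", windows = "",
      status = paste0("error: ", conditionMessage(e)),
      stringsAsFactors = FALSE))
    res
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$genome_id), ]
  rownames(tab) <- NULL
  attr(tab, "n_flagged") <- sum(tab$n_deviations > 0, na.rm = TRUE)
  tab
}
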