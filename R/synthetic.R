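# Synthetic circular mitogenome generator with planted ground truth:
# canonical 37-locus vertebrate order (optionally rearranged), a control
# region between tRNA-Pro and tRNA-Phe carrying TAS sites, CSB I/II/III and
# a tandem array, and an optional non-coding insert between tRNA-Phe and the
# 12S rRNA formed by partial duplication of the control region's 3' end plus
# a degenerate tRNA-Phe copy.

#' Simulation configuration
#'
#' Defaults describe a typical ~16.5 kb vertebrate mitogenome. Coding-locus
#' lengths come from the packaged canonical-order table; the control region
#' takes up `genome_length` minus the coding total, and an insert (if any)
#' extends the genome beyond `genome_length` (the extension is reported as
#' `slack` in the truth record).
#'
#' @param genome_length target length in bp excluding any insert
#' @param seed integer seed; every random draw derives from it
#' @param gc_fraction background base composition
#' @param tas_copies number of TAS sites planted (spacers drawn from 8-9 bp)
#' @param csb_set subset of c("I","II","III") to plant
#' @param csb1_spacer CSB I planted spacer length (bp)
#' @param tandem_spec list(period=, copies=, mut_rate=): tandem array planted
#'   in the control region
#' @param insert_spec NULL, or list(length=, copy_mut=, trna_mut=): total
#'   insert length between tRNA-Phe and 12S; per-base substitution rate of
#'   the duplicated control-region 3' end (recent duplication, default 0.05)
#'   and of the degenerate tRNA-Phe copy at the insert's end (default 0.15)
#' @param rearrangement NULL or one of "gln_ile_swap_round",
#'   "gln_ile_swap_bighead", "ser_leu_his_shuffle"
#' @return list of class `sim_config`
#' @export
sim_config <- function(genome_length = 16500, seed = 1, gc_fraction = 0.45,
                       tas_copies = 3, csb_set = c("I", "II", "III"),
                       csb1_spacer = 20,
                       tandem_spec = list(period = 40, copies = 5,
                                          mut_rate = 0.02),
                       insert_spec = NULL,
                       rearrangement = NULL) {
  rates <- c(gc_fraction, tandem_spec$mut_rate,
             insert_spec$copy_mut %||% 0, insert_spec$trna_mut %||% 0)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0,1]")
  if (!is.null(rearrangement))
    rearrangement <- match.arg(rearrangement,
                               c("gln_ile_swap_round", "gln_ile_swap_bighead",
                                 "ser_leu_his_shuffle"))
  if (!is.null(insert_spec)) {
    insert_spec$copy_mut <- insert_spec$copy_mut %||% 0.05
    insert_spec$trna_mut <- insert_spec$trna_mut %||% 0.15
  }
  structure(list(genome_length = genome_length, seed = seed,
                 gc_fraction = gc_fraction, tas_copies = tas_copies,
                 csb_set = csb_set, csb1_spacer = csb1_spacer,
                 tandem_spec = tandem_spec, insert_spec = insert_spec,
                 rearrangement = rearrangement),
            class = "sim_config")
}

#' Mutate a sequence copy by per-base substitution
#'
#' Substitution-only (no indels), so planted truth spans stay exact. At
#' `rate = 1` every base is replaced by a uniformly drawn different base.
#'
#' @param seq DNA string
#' @param rate per-base substitution probability in \[0,1\]
#' @param seed optional seed (uses the current RNG stream when NULL)
#' @return mutated copy of `seq`
#' @export
mutate_copy <- function(seq, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(ch)) < rate
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  }
  paste(ch, collapse = "")
}

# apply a named tRNA rearrangement to the canonical locus table
.apply_rearrangement <- function(tab, move) {
  if (is.null(move)) return(tab)
  if (move %in% c("gln_ile_swap_round", "gln_ile_swap_bighead")) {
    i <- match(c("Ile", "Gln", "Met"), tab$locus)
    stopifnot(!anyNA(i), identical(i, i[1] + 0:2))
    if (move == "gln_ile_swap_round") {
      # canonical Ile(+)/Gln(-)/Met(+) -> Gln(+)/Ile(-)/Met(+): a single
      # signed reversal of the Ile-Gln block
      tab$locus[i[1:2]] <- c("Gln", "Ile")
      tab$strand[i[1:2]] <- c(1L, -1L)
    } else {
      # bighead-style: Gln(-)/Ile(+)/Met(+), order swapped, strands kept
      tab$locus[i[1:2]] <- c("Gln", "Ile")
      tab$strand[i[1:2]] <- c(-1L, 1L)
    }
  } else if (move == "ser_leu_his_shuffle") {
    i <- match(c("His", "SerAGY", "LeuCUN"), tab$locus)
    stopifnot(!anyNA(i), identical(i, i[1] + 0:2))
    # His/Ser/Leu -> Ser/Leu/His, strands unchanged (all heavy)
    tab$locus[i] <- c("SerAGY", "LeuCUN", "His")
  }
  tab
}

#' Simulate an annotated mitogenome with planted truth
#'
#' Deterministic for a fixed seed. The genome is linearized at tRNA-Phe;
#' coding loci follow the canonical vertebrate order (or the configured
#' rearrangement), the control region sits between tRNA-Pro and tRNA-Phe at
#' the end of the linearization (so it wraps the origin as a region walk),
#' and an optional insert is placed between tRNA-Phe and the 12S rRNA.
#'
#' Control-region layout, 5' (Pro side) to 3' (Phe side): TAS sites with
#' random 8/9 bp spacers, the tandem array, CSB I (`AT`/`ATG` + spacer +
#' `GACA`), CSB II (`AAACCCCCC` + NNN + `CCC`), CSB III (`AAACCCC` inside
#' planted pure-A/C 20 bp flanks), then a background 3' tail from which the
#' insert is copied.
#'
#' @param cfg a [sim_config()]
#' @return list with `genome` (a [mito_genome]) and `truth` (planted spans in
#'   absolute 0-based half-open genome coordinates: `tas`, `csb`, `tandem`,
#'   `control_region`, `insert`, `order`, `slack`)
#' @export
simulate_genome <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  canon <- .apply_rearrangement(canonical_order(), cfg$rearrangement)
  coding_total <- sum(canon$typical_bp)
  cr_len <- cfg$genome_length - coding_total
  gc <- cfg$gc_fraction

  # ---- control region assembly (local coordinates) ----
  gap <- function(n) random_dna(n, gc)
  parts <- character(); kinds <- character(); labels <- character()
  add <- function(s, kind, label) {
    parts[length(parts) + 1L] <<- s
    kinds[length(kinds) + 1L] <<- kind
    labels[length(labels) + 1L] <<- label
  }
  add(gap(25), "gap", "")
  for (k in seq_len(cfg$tas_copies)) {
    sp <- sample(8:9, 1L)
    add(paste0("ATG", gap(sp), "CAT"), "TAS", paste0("TAS_", k))
    add(gap(12), "gap", "")
  }
  ts <- cfg$tandem_spec
  if (!is.null(ts) && ts$copies >= 2) {
    unit <- random_dna(ts$period, gc)
    arr <- paste(vapply(seq_len(ts$copies), function(i)
      mutate_copy(unit, ts$mut_rate), ""), collapse = "")
    add(arr, "tandem", sprintf("tandem_p%d", ts$period))
    add(gap(15), "gap", "")
  }
  if ("I" %in% cfg$csb_set) {
    prefix <- sample(c("AT", "ATG"), 1L)
    add(paste0(prefix, gap(cfg$csb1_spacer), "GACA"), "CSB-I", "CSB-I")
    add(gap(15), "gap", "")
  }
  if ("II" %in% cfg$csb_set) {
    add(paste0("AAACCCCCC", gap(3), "CCC"), "CSB-II", "CSB-II")
    add(gap(15), "gap", "")
  }
  if ("III" %in% cfg$csb_set) {
    acflank <- function(n) paste(sample(c("A", "C"), n, replace = TRUE),
                                 collapse = "")
    add(paste0(acflank(20), "AAACCCC", acflank(20)), "CSB-III-block", "CSB-III")
    add(gap(10), "gap", "")
  }
  planted_len <- sum(nchar(parts))
  tail_len <- cr_len - planted_len
  if (tail_len < 0)
    stop("planted control-region elements (", planted_len,
         " bp) do not fit in the ", cr_len, " bp control region; ",
         "increase genome_length or reduce elements")
  add(gap(tail_len), "gap", "3p-tail")
  cr_seq <- paste(parts, collapse = "")
  offs <- cumsum(c(0L, nchar(parts)))  # local starts of each part

  cr_elements <- data.frame(kind = kinds, label = labels,
                            start = offs[seq_along(parts)],
                            end = offs[-1], stringsAsFactors = FALSE)
  # CSB-III span is the core heptamer inside its planted A/C block
  i3 <- which(cr_elements$kind == "CSB-III-block")
  if (length(i3)) {
    cr_elements$start[i3] <- cr_elements$start[i3] + 20L
    cr_elements$end[i3] <- cr_elements$start[i3] + 7L
    cr_elements$kind[i3] <- "CSB-III"
  }

  # ---- locus sequences ----
  locus_seqs <- stats::setNames(
    vapply(canon$typical_bp, function(n) random_dna(n, gc), ""),
    canon$locus)

  # ---- insert (copied from the CR 3' tail + degenerate tRNA-Phe) ----
  ins <- cfg$insert_spec
  insert_seq <- ""
  insert_truth <- NULL
  if (!is.null(ins)) {
    phe_len <- nchar(locus_seqs[["Phe"]])
    src_len <- ins$length - phe_len
    if (src_len < 1 || src_len > tail_len)
      stop("insert source (", src_len, " bp) exceeds the control region 3' ",
           "tail (", tail_len, " bp); enlarge genome_length or shrink insert")
    src_start_local <- cr_len - src_len  # the last src_len bases of the CR
    src_seq <- substr(cr_seq, src_start_local + 1L, cr_len)
    insert_seq <- paste0(mutate_copy(src_seq, ins$copy_mut),
                         mutate_copy(locus_seqs[["Phe"]], ins$trna_mut))
    insert_truth <- list(src_start_local = src_start_local, src_len = src_len,
                         phe_len = phe_len)
  }

  # ---- genome assembly: Phe at 0, [insert], ..., Pro, control region ----
  phe_row <- match("Phe", canon$locus)
  stopifnot(phe_row == 1L)  # canonical table is Phe-anchored
  pieces <- character(); feats <- list(); pos <- 0L
  emit <- function(seq, locus, cls, strand, label = locus) {
    pieces[length(pieces) + 1L] <<- seq
    if (!is.na(locus))
      feats[[length(feats) + 1L]] <<- data.frame(
        locus = locus, start = pos, end = pos + nchar(seq), strand = strand,
        feature_class = cls, label = label, stringsAsFactors = FALSE)
    pos <<- pos + nchar(seq)
  }
  emit(locus_seqs[["Phe"]], "Phe", "tRNA", canon$strand[1])
  insert_abs <- NULL
  if (nchar(insert_seq)) {
    ins_start <- pos
    emit(insert_seq, "noncoding", "noncoding", 1L, "Phe-12S insert")
    insert_abs <- list(
      span = c(ins_start, pos),
      degenerate_phe = c(pos - insert_truth$phe_len, pos),
      source_local = c(insert_truth$src_start_local,
                       insert_truth$src_start_local + insert_truth$src_len))
  }
  for (r in 2:nrow(canon)) {
    emit(locus_seqs[[canon$locus[r]]], canon$locus[r],
         canon$feature_class[r], canon$strand[r])
  }
  cr_start <- pos
  emit(cr_seq, "noncoding", "noncoding", 1L, "control region")
  L <- pos
  genome <- mito_genome(
    genome_id = sprintf("sim%08d", cfg$seed),
    sequence = paste(pieces, collapse = ""),
    features = do.call(rbind, feats),
    species = "synthetic mitogenome", circular = TRUE)

  tocr <- function(local) local + cr_start  # CR-local -> absolute
  el <- cr_elements
  truth <- list(
    control_region = c(cr_start, L),
    tas = lapply(which(el$kind == "TAS"),
                 function(i) tocr(c(el$start[i], el$end[i]))),
    csb = stats::setNames(
      lapply(which(el$kind %in% c("CSB-I", "CSB-II", "CSB-III")),
             function(i) tocr(c(el$start[i], el$end[i]))),
      el$kind[el$kind %in% c("CSB-I", "CSB-II", "CSB-III")]),
    tandem = if (any(el$kind == "tandem")) {
      i <- which(el$kind == "tandem")
      list(span = tocr(c(el$start[i], el$end[i])),
           period = cfg$tandem_spec$period, copies = cfg$tandem_spec$copies)
    } else NULL,
    insert = if (!is.null(insert_abs)) list(
      span = insert_abs$span,
      source_span = tocr(insert_abs$source_local),
      degenerate_phe = insert_abs$degenerate_phe) else NULL,
    order = data.frame(locus = canon$locus, strand = canon$strand,
                       stringsAsFactors = FALSE),
    slack = L - cfg$genome_length)
  list(genome = genome, truth = truth)
}

#' Write a simulation (GenBank + FASTA + truth JSON) to a directory
#'
#' @param sim result of [simulate_genome()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- sim$genome$genome_id
  write_genbank(sim$genome, file.path(dir, paste0(id, ".gb")))
  write_fasta_genome(sim$genome, file.path(dir, paste0(id, ".fasta")))
  jsonlite::write_json(sim$truth, file.path(dir, paste0(id, ".truth.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
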