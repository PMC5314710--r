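# Annotated mitogenome container, GenBank flat-file IO, circular-coordinate
# region extraction and BED-style feature tables.

.mitoarch_env <- new.env(parent = emptyenv())

read_pkg_tsv <- function(file) {
  utils::read.delim(system.file("extdata", file, package = "mitoarch",
                                mustWork = TRUE),
                    comment.char = "#", stringsAsFactors = FALSE)
}

#' Canonical vertebrate mitochondrial gene order
#'
#' The shared 37-locus arrangement (13 CDS, 2 rRNA, 22 tRNA) linearized at
#' tRNA-Phe, with heavy (+1) / light (-1) strand assignments, shipped as an
#' editable TSV. Users may pass their own table of the same shape wherever a
#' reference order is accepted.
#'
#' @return data.frame with columns `locus`, `feature_class`, `strand`,
#'   `typical_bp`
#' @export
canonical_order <- function() {
  if (is.null(.mitoarch_env$canon)) {
    .mitoarch_env$canon <- read_pkg_tsv("canonical_vertebrate_order.tsv")
  }
  .mitoarch_env$canon
}

# normalized key for synonym lookup: case-insensitive, punctuation-free
.norm_key <- function(x) gsub("[ _()'\\-]", "", tolower(x))

locus_synonyms <- function() {
  if (is.null(.mitoarch_env$syn)) {
    tab <- read_pkg_tsv("locus_synonyms.tsv")
    map <- tab$locus
    names(map) <- .norm_key(tab$synonym)
    # canonical ids map to themselves
    self <- canonical_order()$locus
    extra <- self[!(.norm_key(self) %in% names(map))]
    map <- c(map, stats::setNames(extra, .norm_key(extra)))
    .mitoarch_env$syn <- map
  }
  .mitoarch_env$syn
}

#' Normalize an annotation label to a canonical locus id
#'
#' @param x character vector of gene/product labels (e.g. "trnP", "tRNA-Pro")
#' @return canonical locus ids; `NA` where no synonym matches
#' @export
normalize_locus <- function(x) {
  map <- locus_synonyms()
  out <- unname(map[.norm_key(x)])
  out
}

#' Construct an annotated (circular) mitogenome
#'
#' @param genome_id record identifier
#' @param sequence DNA string over A/C/G/T/N
#' @param features data.frame with columns `locus`, `start`, `end`, `strand`,
#'   `feature_class`, optional `label`; 0-based half-open spans, `end` may
#'   exceed the genome length for origin-wrapping features
#' @param species species name
#' @param circular logical
#' @return object of class `mito_genome`
#' @export
mito_genome <- function(genome_id, sequence, features, species = genome_id,
                        circular = TRUE) {
  stopifnot(nchar(sequence) > 0)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) stop("sequence contains non-ACGTN characters")
  if (is.null(features$label)) features$label <- features$locus
  needed <- c("locus", "start", "end", "strand", "feature_class", "label")
  stopifnot(all(needed %in% names(features)))
  features <- features[, needed]
  L <- nchar(sequence)
  if (nrow(features)) {
    len <- features$end - features$start
    if (any(len < 1) || any(len >= L))
      stop("feature span lengths must be >= 1 and < genome length")
    features <- features[order(features$start, features$end, features$label), ]
    key <- paste(features$start, features$end)
    core <- features$feature_class %in% c("CDS", "tRNA", "rRNA")
    if (anyDuplicated(key[core]))
      stop("duplicate identical spans among CDS/tRNA/rRNA features: ",
           key[core][duplicated(key[core])][1])
    rownames(features) <- NULL
  }
  structure(list(genome_id = genome_id, species = species, sequence = sequence,
                 circular = circular, features = features),
            class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s (%s): %d bp, %s, %d features\n",
              x$genome_id, x$species, nchar(x$sequence),
              if (x$circular) "circular" else "linear", nrow(x$features)))
  invisible(x)
}

# ---- GenBank flat file IO --------------------------------------------------

# parse a GenBank location string into (start, end, strand) with the
# 0-based half-open, un-modded-end convention; supports a..b,
# complement(...), and two-part join(a..L,1..y) for origin wrapping
.parse_location <- function(loc, L, lineno) {
  strand <- 1L
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1]]
    if (length(parts) != 2L)
      stop("line ", lineno, ": unsupported multi-part location: ", loc)
    m <- regmatches(parts, regexec("^(\\d+)\\.\\.(\\d+)$", parts))
    if (any(lengths(m) != 3L))
      stop("line ", lineno, ": malformed location: ", loc)
    a <- as.integer(m[[1]][2]); b <- as.integer(m[[1]][3])
    c_ <- as.integer(m[[2]][2]); d <- as.integer(m[[2]][3])
    if (b != L || c_ != 1L)
      stop("line ", lineno, ": join() is only supported for origin wrapping")
    return(list(start = a - 1L, end = L + d, strand = strand))
  }
  m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
  if (length(m) != 3L) stop("line ", lineno, ": malformed location: ", loc)
  list(start = as.integer(m[2]) - 1L, end = as.integer(m[3]), strand = strand)
}

#' Read a GenBank flat file into a `mito_genome`
#'
#' CDS, tRNA, rRNA and D-loop features are mapped to canonical locus ids via
#' the packaged name-normalization table; unmappable features become
#' `noncoding` with their original label retained. GenBank 1-based inclusive
#' coordinates are converted to 0-based half-open at this boundary.
#'
#' @param path GenBank flat file
#' @return a [mito_genome]
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus_line <- grep("^LOCUS", lines, value = TRUE)[1]
  if (is.na(locus_line)) stop("not a GenBank flat file (no LOCUS line): ", path)
  toks <- strsplit(trimws(locus_line), "\\s+")[[1]]
  genome_id <- toks[2]
  circular <- any(tolower(toks) == "circular")
  def <- grep("^DEFINITION", lines, value = TRUE)
  species <- if (length(def)) trimws(sub("^DEFINITION", "", def[1])) else genome_id

  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) stop("missing ORIGIN sequence in ", path)
  seq_lines <- lines[(ostart[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(sequence)) stop("missing ORIGIN sequence in ", path)
  L <- nchar(sequence)

  fstart <- grep("^FEATURES", lines)
  feats <- list()
  if (length(fstart)) {
    i <- fstart[1] + 1L
    while (i < ostart[1]) {
      ln <- lines[i]
      if (grepl("^ {5}\\S", ln)) {
        key <- trimws(substr(ln, 1, 20))
        loc <- trimws(substr(ln, 21, nchar(ln)))
        # continuation lines of the location (no '/')
        j <- i + 1L
        while (j < ostart[1] && grepl("^ {21}", lines[j]) &&
               !grepl("^ {21}/", lines[j]) && !grepl("^ {5}\\S", lines[j])) {
          loc <- paste0(loc, trimws(lines[j])); j <- j + 1L
        }
        quals <- character()
        while (j < ostart[1] && grepl("^ {21}/", lines[j])) {
          quals <- c(quals, trimws(lines[j])); j <- j + 1L
        }
        if (key %in% c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature")) {
          qv <- function(name) {
            hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
            if (!length(hit)) return(NA_character_)
            gsub("\"", "", sub(paste0("^/", name, "="), "", hit[1]))
          }
          lab <- qv("gene")
          if (is.na(lab)) lab <- qv("product")
          if (is.na(lab)) lab <- qv("note")
          if (is.na(lab)) lab <- key
          pl <- .parse_location(loc, L, i)
          feats[[length(feats) + 1L]] <- data.frame(
            key = key, label = lab, start = pl$start, end = pl$end,
            strand = pl$strand, stringsAsFactors = FALSE)
        }
        i <- j
      } else i <- i + 1L
    }
  }
  if (length(feats)) {
    ftab <- do.call(rbind, feats)
    locus <- normalize_locus(ftab$label)
    cls <- ifelse(ftab$key %in% c("CDS", "tRNA", "rRNA"), ftab$key, "noncoding")
    cls[is.na(locus)] <- "noncoding"
    locus[is.na(locus)] <- "noncoding"
    # a D-loop mapping to "noncoding" keeps its class noncoding
    cls[locus == "noncoding"] <- "noncoding"
    features <- data.frame(locus = locus, start = ftab$start, end = ftab$end,
                           strand = ftab$strand, feature_class = cls,
                           label = ftab$label, stringsAsFactors = FALSE)
  } else {
    features <- data.frame(locus = character(), start = integer(),
                           end = integer(), strand = integer(),
                           feature_class = character(), label = character(),
                           stringsAsFactors = FALSE)
  }
  mito_genome(genome_id, sequence, features, species = species,
              circular = circular)
}

#' Write a `mito_genome` as a GenBank flat file
#'
#' Inverse of [read_genbank()]: features are emitted with their canonical
#' locus id as `/gene`, origin-wrapping spans as `join(a..L,1..y)`, light
#' strand features as `complement(...)`.
#'
#' @param g a [mito_genome]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_genbank <- function(g, path) {
  L <- nchar(g$sequence)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s VRT",
                     g$genome_id, L, if (g$circular) "circular" else "linear"),
             con)
  writeLines(paste0("DEFINITION  ", g$species), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  f <- g$features
  if (nrow(f)) for (i in seq_len(nrow(f))) {
    loc <- if (f$end[i] <= L) sprintf("%d..%d", f$start[i] + 1L, f$end[i])
           else sprintf("join(%d..%d,1..%d)", f$start[i] + 1L, L, f$end[i] - L)
    if (f$strand[i] < 0) loc <- sprintf("complement(%s)", loc)
    key <- if (f$feature_class[i] == "noncoding") "misc_feature" else f$feature_class[i]
    writeLines(sprintf("     %-16s%s", key, loc), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$label[i]), con)
  }
  writeLines("ORIGIN", con)
  for (off in seq(1L, L, by = 60L)) {
    chunk <- substr(g$sequence, off, min(off + 59L, L))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", off, tolower(paste(blocks, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Write genome sequence(s) to FASTA
#'
#' @param g a [mito_genome] or list of them
#' @param path output FASTA
#' @return `path`, invisibly
#' @export
write_fasta_genome <- function(g, path) {
  if (inherits(g, "mito_genome")) g <- list(g)
  seqs <- Biostrings::DNAStringSet(vapply(g, function(x) x$sequence, ""))
  names(seqs) <- vapply(g, function(x) x$genome_id, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read aligned or unaligned sequences from FASTA
#'
#' @param path FASTA file (gaps allowed)
#' @return named character vector of upper-case sequences
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

# ---- Regions ---------------------------------------------------------------

.find_locus <- function(g, locus) {
  idx <- which(g$features$locus == locus)
  if (length(idx) != 1L) {
    cand <- sort(unique(g$features$locus))
    stop("locus '", locus, "' present ", length(idx), " times in ",
         g$genome_id, "; available loci: ", paste(cand, collapse = ", "))
  }
  idx
}

#' Extract the region between two loci
#'
#' Walks forward around the circle from the 3' end of `a` (in genome
#' orientation) to the 5' start of `b`. The returned region may wrap the
#' origin and may have length 0.
#'
#' @param g a [mito_genome]
#' @param a,b canonical locus ids, each present exactly once
#' @param label region label (default "a-b")
#' @return object of class `mito_region` with fields `genome_id`, `start`,
#'   `end`, `label`, `seq`
#' @export
region_between <- function(g, a, b, label = paste0(a, "-", b)) {
  L <- nchar(g$sequence)
  fa <- g$features[.find_locus(g, a), ]
  fb <- g$features[.find_locus(g, b), ]
  start <- fa$end %% L
  blen <- (fb$start - start) %% L
  region <- list(genome_id = g$genome_id, start = start, end = start + blen,
                 label = label,
                 seq = if (blen > 0) extract_span(g$sequence, start, start + blen) else "")
  class(region) <- "mito_region"
  region
}

#' @export
print.mito_region <- function(x, ...) {
  cat(sprintf("<mito_region> %s [%d,%d) %d bp on %s\n", x$label, x$start,
              x$end, x$end - x$start, x$genome_id))
  invisible(x)
}

#' Write features or motif hits as a BED-style table
#'
#' 0-based half-open TSV with columns seq_id, start, end, label, score,
#' strand, group; rows ordered by (start, end, label). Features wrapping the
#' origin are emitted as two rows sharing a `group` label.
#'
#' @param x data.frame with at least `start` and `end`; optional `label`,
#'   `score`, `strand` columns (hit tables from the scanners work directly)
#' @param path output TSV
#' @param seq_id sequence identifier for column 1
#' @param seq_length circular sequence length, needed to split wrapping rows
#' @return `path`, invisibly
#' @export
write_feature_table <- function(x, path, seq_id = "seq", seq_length = NULL) {
  cols <- function(nm, default) if (!is.null(x[[nm]])) x[[nm]] else rep(default, nrow(x))
  tab <- data.frame(seq_id = rep(seq_id, nrow(x)), start = cols("start", NA),
                    end = cols("end", NA),
                    label = cols("label", if (!is.null(x$locus)) NULL else "."),
                    score = cols("score", "."),
                    strand = ifelse(cols("strand", 1L) >= 0, "+", "-"),
                    stringsAsFactors = FALSE)
  if (!is.null(x$locus) && is.null(x$label)) tab$label <- x$locus
  tab$group <- tab$label
  if (nrow(tab)) {
    wraps <- !is.null(seq_length) & tab$end > (seq_length %||% Inf)
    if (any(wraps)) {
      w <- tab[wraps, ]
      first <- w; first$end <- seq_length
      second <- w; second$start <- 0L; second$end <- w$end - seq_length
      tab <- rbind(tab[!wraps, ], first, second)
    }
    tab <- tab[order(tab$start, tab$end, tab$label), ]
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
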