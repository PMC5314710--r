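# Concatenated protein-coding codon supermatrix: drop excluded genes
# (ND6 by default, it evolves under different constraints), remove whole
# codon columns containing a gap in any taxon, and validate reading frames
# under the vertebrate mitochondrial genetic code.

#' Build a concatenated codon supermatrix
#'
#' Genes are concatenated in fixed (sorted) name order so the result is
#' independent of input iteration order. A codon column is removed whole, in
#' all taxa, as soon as any taxon has a gap in any of its three positions:
#' per-base gap removal would break the reading frames the matrix is meant
#' to preserve.
#'
#' @param per_gene_alignments named list: gene -> named character vector of
#'   equal-length aligned sequences (or a `DNAStringSet`); all genes must
#'   share the same taxa and have aligned length divisible by 3
#' @param exclude genes to drop (default "ND6")
#' @return list of class `codon_matrix`: `taxa`, `sequences` (named,
#'   gap-free, equal length divisible by 3), `boundaries` (data.frame gene,
#'   start, end in post-removal 0-based codon-matrix coordinates),
#'   `excluded`, `removed_codons` (per gene)
#' @export
build_matrix <- function(per_gene_alignments, exclude = "ND6") {
  aln <- lapply(per_gene_alignments, function(a) {
    if (!is.character(a)) a <- stats::setNames(as.character(a), names(a))
    toupper(a)
  })
  if (is.null(names(aln)) || any(!nzchar(names(aln))))
    stop("per-gene alignments must be named by gene")
  excluded <- intersect(names(aln), exclude)
  aln <- aln[setdiff(names(aln), exclude)]
  if (!length(aln)) stop("no genes left after exclusion")
  aln <- aln[order(names(aln))]

  taxa <- sort(names(aln[[1]]))
  for (gene in names(aln)) {
    t2 <- sort(names(aln[[gene]]))
    if (!identical(taxa, t2)) {
      d <- c(setdiff(taxa, t2), setdiff(t2, taxa))
      stop("taxa mismatch at gene ", gene, ": ", paste(d, collapse = ", "))
    }
    w <- unique(nchar(aln[[gene]]))
    if (length(w) != 1) stop("ragged alignment in gene ", gene)
    if (w %% 3 != 0)
      stop("frame violation: aligned length of gene ", gene,
           " (", w, ") is not divisible by 3")
  }

  seqs <- stats::setNames(rep("", length(taxa)), taxa)
  bounds <- data.frame(gene = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
  removed <- stats::setNames(integer(length(aln)), names(aln))
  col0 <- 0L
  for (gene in names(aln)) {
    mat <- do.call(rbind, strsplit(aln[[gene]][taxa], ""))
    gapcol <- apply(mat == "-" | mat == ".", 2L, any)
    ncod <- ncol(mat) %/% 3L
    codon_has_gap <- vapply(seq_len(ncod), function(k)
      any(gapcol[(3L * k - 2L):(3L * k)]), TRUE)
    keep_cols <- rep(!codon_has_gap, each = 3L)
    removed[gene] <- sum(codon_has_gap)
    kept <- mat[, keep_cols, drop = FALSE]
    glen <- ncol(kept)
    seqs[] <- paste0(seqs, apply(kept, 1L, paste, collapse = ""))
    bounds <- rbind(bounds, data.frame(gene = gene, start = col0,
                                       end = col0 + glen))
    col0 <- col0 + glen
  }
  structure(list(taxa = taxa, sequences = seqs, boundaries = bounds,
                 excluded = excluded, removed_codons = removed),
            class = "codon_matrix")
}

#' @export
print.codon_matrix <- function(x, ...) {
  cat(sprintf("<codon_matrix> %d taxa x %d columns (%d codons), %d genes%s\n",
              length(x$taxa), nchar(x$sequences[1]), nchar(x$sequences[1]) / 3,
              nrow(x$boundaries),
              if (length(x$excluded)) paste0("; excluded: ",
                                             paste(x$excluded, collapse = ","))
              else ""))
  invisible(x)
}

#' Validate reading frames of a codon matrix
#'
#' Translates every gene of every taxon under the vertebrate mitochondrial
#' genetic code (NCBI table 2) and reports internal stop codons; a terminal
#' stop in the final codon of a gene is tolerated.
#'
#' @param matrix a `codon_matrix`
#' @param code NCBI genetic code id (default "2", vertebrate mitochondrial)
#' @return data.frame (report, possibly empty): `taxon`, `gene`,
#'   `codon_index` (0-based within gene), `codon`
#' @export
validate_frames <- function(matrix, code = "2") {
  gcode <- Biostrings::getGeneticCode(code)
  rows <- list(data.frame(taxon = character(), gene = character(),
                          codon_index = integer(), codon = character(),
                          stringsAsFactors = FALSE))
  for (i in seq_len(nrow(matrix$boundaries))) {
    b <- matrix$boundaries[i, ]
    for (tx in matrix$taxa) {
      s <- substr(matrix$sequences[[tx]], b$start + 1L, b$end)
      ncod <- nchar(s) %/% 3L
      if (ncod == 0) next
      codons <- substring(s, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
      aa <- gcode[codons]
      aa[is.na(aa)] <- "X"  # ambiguous codons are not stops
      internal <- which(aa == "*")
      internal <- internal[internal < ncod]  # terminal stop tolerated
      if (length(internal))
        rows[[length(rows) + 1L]] <- data.frame(
          taxon = tx, gene = b$gene, codon_index = internal - 1L,
          codon = codons[internal], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a codon matrix as FASTA, relaxed PHYLIP and a partition file
#'
#' @param matrix a `codon_matrix`
#' @param dir output directory
#' @param basename file stem
#' @return paths of the written files, invisibly
#' @export
write_matrix <- function(matrix, dir, basename = "supermatrix") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, paste0(basename, ".fasta"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(matrix$sequences), fa)
  phy <- file.path(dir, paste0(basename, ".phy"))
  con <- file(phy, "w")
  writeLines(sprintf("%d %d", length(matrix$taxa),
                     nchar(matrix$sequences[1])), con)
  writeLines(sprintf("%s  %s", matrix$taxa, matrix$sequences[matrix$taxa]),
             con)
  close(con)
  part <- file.path(dir, paste0(basename, ".partitions.txt"))
  writeLines(sprintf("DNA, %s = %d-%d", matrix$boundaries$gene,
                     matrix$boundaries$start + 1L, matrix$boundaries$end),
             part)
  invisible(c(fasta = fa, phylip = phy, partitions = part))
}
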