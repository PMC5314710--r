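# Mitogenome size statistics: per-species median deduplication, class-wise
# five-number summaries, and percentile-of-value statements such as "only
# x% of species have a larger mitochondrial genome".

#' Deduplicate size records to one median length per species
#'
#' Species with several database entries of differing length are collapsed
#' to their median (even counts: mean of the two central values), removing
#' overrepresentation bias. Records flagged `partial` are dropped first.
#'
#' @param records data.frame with `species`, `length`, optional `group`
#'   and logical `partial`
#' @return data.frame with one row per species (`species`, `length`,
#'   `group`), ordered by species; input order is irrelevant
#' @export
dedupe_median <- function(records) {
  stopifnot(all(c("species", "length") %in% names(records)))
  if (!is.null(records$partial)) records <- records[!records$partial, ]
  if (any(records$length <= 0)) stop("lengths must be > 0")
  sp <- sort(unique(records$species))
  out <- do.call(rbind, lapply(sp, function(s) {
    r <- records[records$species == s, ]
    data.frame(species = s, length = stats::median(r$length),
               group = if (!is.null(r$group)) r$group[1] else "unassigned",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fraction of species with a strictly larger genome
#'
#' @param deduped one record per species (see [dedupe_median()])
#' @param query_length query genome size in bp
#' @return list: `fraction`, `count` (numerator), `n` (denominator)
#' @export
percent_larger <- function(deduped, query_length) {
  if (!nrow(deduped)) stop("empty input")
  count <- sum(deduped$length > query_length)
  list(fraction = count / nrow(deduped), count = count, n = nrow(deduped))
}

#' Per-group five-number size summaries
#'
#' Quantiles use linear interpolation (R type 7), the documented convention.
#'
#' @param deduped one record per species; missing `group` values become
#'   "unassigned"
#' @param query_length optional bp value; adds the per-group fraction of
#'   species with a strictly larger genome
#' @return data.frame: `group`, `n`, `min`, `q1`, `median`, `q3`, `max`
#'   (and `frac_larger` when `query_length` is given), ordered by group
#' @export
group_summary <- function(deduped, query_length = NULL) {
  g <- deduped$group %||% rep("unassigned", nrow(deduped))
  g[is.na(g) | g == ""] <- "unassigned"
  out <- do.call(rbind, lapply(sort(unique(g)), function(grp) {
    x <- deduped$length[g == grp]
    q <- stats::quantile(x, c(0, .25, .5, .75, 1), type = 7, names = FALSE)
    row <- data.frame(group = grp, n = length(x), min = q[1], q1 = q[2],
                      median = q[3], q3 = q[4], max = q[5],
                      stringsAsFactors = FALSE)
    if (!is.null(query_length)) row$frac_larger <- mean(x > query_length)
    row
  }))
  rownames(out) <- NULL
  out
}
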