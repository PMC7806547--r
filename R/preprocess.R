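# Rarefaction, relative abundance, and the prevalence filter that defines the
# ASV set entering SparCC.

#' Rarefy a feature table to even depth
#'
#' Subsamples each sample's reads uniformly without replacement (multivariate
#' hypergeometric) down to `depth`. Samples with fewer than `depth` total reads
#' are dropped and reported. Each sample gets its own RNG stream derived from
#' the master seed and its `sample_id`, so the result does not depend on
#' sample order.
#'
#' @param counts Feature table (samples x ASVs, integer counts).
#' @param depth Target reads per sample (default 16500).
#' @param seed Master seed; `NULL` uses the current RNG state (order-dependent).
#' @return Rarefied table with every row summing to `depth`. Dropped sample
#'   ids are attached as `attr(, "dropped")`.
#' @export
rarefy <- function(counts, depth = 16500, seed = NULL) {
  validate_feature_table(counts)
  if (length(depth) != 1L || depth < 1) stop("depth must be >= 1", call. = FALSE)
  depth <- as.integer(round(depth))
  totals <- rowSums(counts)
  drop <- totals < depth
  kept <- counts[!drop, , drop = FALSE]
  out <- kept
  for (i in seq_len(nrow(kept))) {
    x <- kept[i, ]
    if (sum(x) == depth) next
    sid <- rownames(kept)[i]
    # draw in canonical (sorted-id) ASV order so the result depends only on
    # the sample's id -> count map, not on column order
    ord <- order(colnames(kept))
    draw <- function() {
      reads <- rep.int(seq_along(ord), x[ord])
      got <- tabulate(sample(reads, depth), nbins = length(x))
      got[order(ord)]
    }
    out[i, ] <- if (is.null(seed)) draw() else
      .with_seed(.child_seed(seed, sid), draw())
  }
  dropped <- rownames(counts)[drop]
  if (length(dropped)) {
    message("rarefy: dropped ", length(dropped), " sample(s) below depth ",
            depth, ": ", paste(dropped, collapse = ", "))
    attr(out, "dropped") <- dropped
  }
  out
}

#' Convert counts to relative abundances
#'
#' Divides each sample row by its own total; every row then sums to 1.
#'
#' @param counts Feature table (samples x ASVs).
#' @return Matrix of fractions with the same dimnames.
#' @export
to_relative <- function(counts) {
  totals <- rowSums(counts)
  if (any(totals <= 0))
    stop("sample(s) with zero total counts: ",
         paste(rownames(counts)[totals <= 0], collapse = ", "), call. = FALSE)
  counts / totals
}

#' Filter ASVs by prevalence
#'
#' Keeps ASVs present (count > 0) in at least `ceiling(threshold * n_samples)`
#' samples — "shared among at least" is an inclusive bound. The report records
#' what was removed and, per sample, the fraction of its reads carried by the
#' retained ASVs.
#'
#' @param counts Feature table (samples x ASVs).
#' @param threshold Prevalence fraction in (0, 1]; default 0.2.
#' @return List with `table` (filtered counts), `retained` / `removed` ASV
#'   ids, `min_samples` (the inclusive presence cutoff), and `reads_retained`
#'   (named per-sample fraction of total reads kept).
#' @export
prevalence_filter <- function(counts, threshold = 0.2) {
  validate_feature_table(counts)
  if (length(threshold) != 1L || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  n <- nrow(counts)
  need <- ceiling(threshold * n)
  presence <- colSums(counts > 0)
  keep <- presence >= need
  filtered <- counts[, keep, drop = FALSE]
  totals <- rowSums(counts)
  frac <- ifelse(totals > 0, rowSums(filtered) / totals, NA_real_)
  names(frac) <- rownames(counts)
  list(table = filtered,
       retained = colnames(counts)[keep],
       removed = colnames(counts)[!keep],
       min_samples = need,
       reads_retained = frac)
}
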