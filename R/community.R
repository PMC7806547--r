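# Alpha/beta diversity and group-level community comparisons.

#' Shannon diversity (bits)
#'
#' `H = -sum p_i log2 p_i` over the sample's relative abundances, zero counts
#' ignored. Log base 2 by default (the QIIME2 convention); `base = exp(1)`
#' covers the natural-log convention.
#'
#' @param x Count (or abundance) vector for one sample, or a samples x ASVs
#'   matrix.
#' @param base Logarithm base (default 2).
#' @return Entropy per sample.
#' @export
shannon <- function(x, base = 2) {
  if (is.matrix(x)) {
    if (any(rowSums(x) <= 0))
      stop("sample(s) with zero total counts: ",
           paste(rownames(x)[rowSums(x) <= 0], collapse = ", "), call. = FALSE)
    return(vegan::diversity(x, index = "shannon", base = base))
  }
  if (sum(x) <= 0) stop("sample has zero total count", call. = FALSE)
  as.numeric(vegan::diversity(rbind(x), index = "shannon", base = base))
}

#' Observed ASVs (richness)
#'
#' Number of ASVs with a strictly positive count.
#'
#' @param x Count vector or samples x ASVs matrix.
#' @return Integer count(s).
#' @export
observed_asvs <- function(x) {
  if (is.matrix(x)) vegan::specnumber(x) else sum(x > 0)
}

#' Alpha-diversity table
#'
#' @param counts Feature table (samples x ASVs); typically rarefied.
#' @param base Shannon log base (default 2).
#' @return Data frame: `sample_id`, `shannon`, `observed_asvs`.
#' @export
alpha_diversity <- function(counts, base = 2) {
  validate_feature_table(counts)
  data.frame(sample_id = rownames(counts),
             shannon = as.numeric(shannon(counts, base = base)),
             observed_asvs = as.integer(observed_asvs(counts)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(u, v) = 1 - 2 sum min(u_i, v_i) / (sum u + sum v)`, bounded in
#' \[0, 1\].
#'
#' @param x Feature table or relative-abundance matrix (samples x ASVs).
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(x) {
  if (nrow(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(rowSums(x) <= 0))
    stop("sample(s) with zero total: ",
         paste(rownames(x)[rowSums(x) <= 0], collapse = ", "), call. = FALSE)
  vegan::vegdist(x, method = "bray")
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centers `-d^2 / 2` and eigendecomposes. All eigenvalues are
#' reported (negative ones included, never silently dropped); coordinates are
#' returned for positive-eigenvalue axes only, and the proportion explained
#' is relative to the sum of positive eigenvalues.
#'
#' @param d Distance matrix or `dist`.
#' @return List of class `"pcoa"`: `points` (samples x axes), `eig` (all
#'   eigenvalues, decreasing), `prop_explained` (per retained axis,
#'   non-increasing).
#' @export
pcoa <- function(d) {
  dm <- .as_distance_matrix(d)
  n <- nrow(dm)
  res <- suppressWarnings(
    stats::cmdscale(stats::as.dist(dm), k = n - 1L, eig = TRUE))
  eig <- res$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  pts <- res$points[, seq_along(pos), drop = FALSE]
  colnames(pts) <- paste0("PCo", seq_along(pos))
  structure(list(points = pts, eig = eig,
                 prop_explained = eig[pos] / sum(eig[pos])),
            class = "pcoa")
}

#' Kruskal-Wallis alpha-diversity comparisons per timepoint
#'
#' For each metric and timepoint, a Kruskal-Wallis rank test across groups
#' (tie-corrected H), with Benjamini-Hochberg adjustment across timepoints
#' within each metric. Timepoints with fewer than 2 groups are skipped with a
#' warning.
#'
#' @param alpha_tab Alpha-diversity table from [alpha_diversity()].
#' @param metadata Sample metadata (`sample_id`, `group`, `timepoint`).
#' @param metrics Metric columns to test (default both).
#' @return Data frame: `metric`, `timepoint`, `statistic`, `df`, `p_value`,
#'   `p_adjusted`.
#' @export
kruskal_by_timepoint <- function(alpha_tab, metadata,
                                 metrics = c("shannon", "observed_asvs")) {
  md <- metadata[match(alpha_tab$sample_id, metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id))
    stop("metadata missing for some samples in the alpha table", call. = FALSE)
  tp <- if ("timepoint" %in% names(md)) as.character(md$timepoint) else "all"
  rows <- list()
  for (metric in metrics) {
    for (t_ in unique(tp)) {
      idx <- tp == t_
      groups <- factor(md$group[idx])
      if (nlevels(droplevels(groups)) < 2L) {
        warning("timepoint '", t_, "' has fewer than 2 groups; skipped")
        next
      }
      kt <- stats::kruskal.test(alpha_tab[[metric]][idx], droplevels(groups))
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, timepoint = t_,
        statistic = unname(kt$statistic), df = unname(kt$parameter),
        p_value = kt$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::ave(out$p_value, out$metric,
                               FUN = function(p) stats::p.adjust(p, "BH"))
  out
}

#' Pairwise PERMANOVA between groups, per timepoint
#'
#' For every timepoint, runs [permanova()] on each pair of groups using the
#' sample subset of that timepoint, and BH-adjusts the pairwise p-values
#' within the timepoint's family of comparisons.
#'
#' @param d Sample distance matrix (e.g. [bray_curtis()]).
#' @param metadata Sample metadata (`sample_id`, `group`, `timepoint`); order
#'   must cover the distance ids.
#' @param n_perm Permutations per test (default 9999).
#' @param seed Master seed; per-test streams are derived from it.
#' @return Data frame: `timepoint`, `group1`, `group2`, `pseudo_F`, `p_value`,
#'   `p_adjusted`.
#' @export
pairwise_permanova <- function(d, metadata, n_perm = 9999, seed = NULL) {
  dm <- .as_distance_matrix(d)
  ids <- rownames(dm)
  if (is.null(ids)) stop("distance matrix needs sample ids", call. = FALSE)
  md <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id))
    stop("metadata missing for some samples in the distance matrix",
         call. = FALSE)
  tp <- if ("timepoint" %in% names(md)) as.character(md$timepoint) else "all"
  rows <- list()
  for (t_ in unique(tp)) {
    idx <- which(tp == t_)
    groups <- sort(unique(as.character(md$group[idx])))
    if (length(groups) < 2L) {
      warning("timepoint '", t_, "' has fewer than 2 groups; skipped")
      next
    }
    prs <- utils::combn(groups, 2L)
    ps <- numeric(ncol(prs)); Fs <- numeric(ncol(prs))
    for (c_ in seq_len(ncol(prs))) {
      sel <- idx[md$group[idx] %in% prs[, c_]]
      res <- permanova(dm[sel, sel, drop = FALSE],
                       as.character(md$group[sel]), n_perm = n_perm,
                       seed = if (is.null(seed)) NULL else
                         .child_seed(seed, paste(t_, prs[1L, c_], prs[2L, c_])))
      ps[c_] <- res$p_value; Fs[c_] <- res$pseudo_F
    }
    rows[[length(rows) + 1L]] <- data.frame(
      timepoint = t_, group1 = prs[1L, ], group2 = prs[2L, ],
      pseudo_F = Fs, p_value = ps,
      p_adjusted = stats::p.adjust(ps, "BH"), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
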