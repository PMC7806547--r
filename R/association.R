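# Guild-phenotype association (Spearman + BH), differential guild abundance
# (Mann-Whitney + BH), and the Z-score representation of group means.

#' Spearman association between guild abundances and phenotypes
#'
#' For every (CAG, phenotype) cell: Spearman's rho with average ranks on
#' ties, two-sided p (exact permutation null for n <= 9 without ties, t
#' approximation otherwise), pairwise-complete handling of missing phenotype
#' values. BH adjustment spans the whole CAG x variable family by default;
#' `family = "per_variable"` adjusts within each phenotype instead. Cells
#' with fewer than 3 complete pairs are marked untestable and excluded from
#' the BH family.
#'
#' @param gab Guild-abundance matrix (samples x CAGs).
#' @param phenotypes Phenotype data frame (`sample_id` + numeric columns).
#' @param variables Phenotype columns to test (default: all numeric columns).
#' @param family `"global"` (default) or `"per_variable"` BH family.
#' @return Data frame: `cag`, `variable`, `rho`, `n`, `p_value`, `fdr`
#'   (`NA` rho/p for untestable cells).
#' @export
spearman_assoc <- function(gab, phenotypes, variables = NULL,
                           family = c("global", "per_variable")) {
  family <- match.arg(family)
  if (is.null(variables))
    variables <- names(phenotypes)[vapply(phenotypes, is.numeric, logical(1))]
  idx <- match(rownames(gab), phenotypes$sample_id)
  if (anyNA(idx))
    stop("phenotypes missing for samples: ",
         paste(utils::head(rownames(gab)[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  ph <- phenotypes[idx, , drop = FALSE]
  rows <- expand.grid(cag = colnames(gab), variable = variables,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(rows)), function(k) {
    x <- gab[, rows$cag[k]]
    y <- ph[[rows$variable[k]]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 3L)
      return(data.frame(rho = NA_real_, n = n, p_value = NA_real_))
    x <- x[ok]; y <- y[ok]
    ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman",
                      exact = (n <= 9L && !ties), alternative = "two.sided"))
    data.frame(rho = unname(ct$estimate), n = n,
               p_value = min(1, ct$p.value))
  })
  out <- cbind(rows, do.call(rbind, res))
  testable <- !is.na(out$p_value)
  out$fdr <- NA_real_
  if (family == "global") {
    out$fdr[testable] <- stats::p.adjust(out$p_value[testable], "BH")
  } else {
    for (v in variables) {
      sel <- testable & out$variable == v
      out$fdr[sel] <- stats::p.adjust(out$p_value[sel], "BH")
    }
  }
  out
}

#' Differential guild abundance between groups (Mann-Whitney)
#'
#' Two-sided Wilcoxon rank-sum test for each CAG and group pair: exact when
#' `n1 * n2 <= 400` and there are no ties, normal approximation with tie
#' correction (and continuity correction) otherwise. All-equal values give
#' p = 1. BH adjustment is across CAGs within each group pair by default
#' (`family = "global"` pools every pair into one family). Direction reports
#' which group has the higher median.
#'
#' @param gab Guild-abundance matrix (samples x CAGs).
#' @param metadata Sample metadata (`sample_id`, `group`, optionally
#'   `timepoint`).
#' @param pairs Optional 2-row matrix / list of group pairs; default all
#'   pairs.
#' @param timepoint Optional timepoint to subset samples to before testing.
#' @param family `"per_pair"` (default) or `"global"` BH family.
#' @return Data frame: `cag`, `group1`, `group2`, `U`, `p_value`, `fdr`,
#'   `direction`.
#' @export
mann_whitney_da <- function(gab, metadata, pairs = NULL, timepoint = NULL,
                            family = c("per_pair", "global")) {
  family <- match.arg(family)
  al <- align_samples(gab, metadata, intersect = !is.null(timepoint))
  gab <- al$table; md <- al$metadata
  if (!is.null(timepoint)) {
    keep <- as.character(md$timepoint) == as.character(timepoint)
    if (!any(keep)) stop("no samples at timepoint '", timepoint, "'",
                         call. = FALSE)
    gab <- gab[keep, , drop = FALSE]; md <- md[keep, , drop = FALSE]
  }
  groups <- sort(unique(as.character(md$group)))
  if (is.null(pairs)) pairs <- utils::combn(groups, 2L)
  pairs <- as.matrix(pairs)
  rows <- list()
  for (c_ in seq_len(ncol(pairs))) {
    g1 <- pairs[1L, c_]; g2 <- pairs[2L, c_]
    i1 <- md$group == g1; i2 <- md$group == g2
    if (sum(i1) < 2L || sum(i2) < 2L)
      stop("each group needs >= 2 samples (", g1, " vs ", g2, ")",
           call. = FALSE)
    for (cg in colnames(gab)) {
      x <- gab[i1, cg]; y <- gab[i2, cg]
      if (all(c(x, y) == c(x, y)[1L])) {
        U <- length(x) * length(y) / 2; p <- 1
      } else {
        ties <- anyDuplicated(c(x, y)) > 0
        wt <- suppressWarnings(
          stats::wilcox.test(x, y, alternative = "two.sided",
                             exact = (length(x) * length(y) <= 400 && !ties),
                             correct = TRUE))
        U <- unname(wt$statistic); p <- min(1, wt$p.value)
      }
      dir_ <- if (stats::median(x) > stats::median(y)) g1
      else if (stats::median(x) < stats::median(y)) g2 else "tie"
      rows[[length(rows) + 1L]] <- data.frame(
        cag = cg, group1 = g1, group2 = g2, U = U, p_value = p,
        direction = dir_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- if (family == "per_pair") {
    stats::ave(out$p_value, paste(out$group1, out$group2),
               FUN = function(p) stats::p.adjust(p, "BH"))
  } else stats::p.adjust(out$p_value, "BH")
  out[, c("cag", "group1", "group2", "U", "p_value", "fdr", "direction")]
}

#' Z scores of per-group guild means
#'
#' For each CAG, the group means are standardised across groups:
#' `Z_g = (mean_g - mean(group means)) / sd(group means)`. A CAG whose group
#' means are all equal gets Z = 0 for every group and is flagged.
#'
#' @param gab Guild-abundance matrix (samples x CAGs).
#' @param metadata Sample metadata (`sample_id`, `group`, optionally
#'   `timepoint`).
#' @param timepoint Optional timepoint to subset to.
#' @return CAGs x groups matrix of Z scores; flat CAGs are listed in
#'   `attr(, "flat")`.
#' @export
zscore_table <- function(gab, metadata, timepoint = NULL) {
  al <- align_samples(gab, metadata, intersect = !is.null(timepoint))
  gab <- al$table; md <- al$metadata
  if (!is.null(timepoint)) {
    keep <- as.character(md$timepoint) == as.character(timepoint)
    if (!any(keep)) stop("no samples at timepoint '", timepoint, "'",
                         call. = FALSE)
    gab <- gab[keep, , drop = FALSE]; md <- md[keep, , drop = FALSE]
  }
  groups <- sort(unique(as.character(md$group)))
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  means <- sapply(groups, function(g)
    colMeans(gab[md$group == g, , drop = FALSE]))
  means <- matrix(means, nrow = ncol(gab),
                  dimnames = list(colnames(gab), groups))
  ctr <- means - rowMeans(means)
  sdv <- apply(means, 1L, stats::sd)
  flat <- sdv == 0
  z <- ctr / ifelse(sdv > 0, sdv, 1)
  z[flat, ] <- 0
  structure(z, flat = rownames(z)[flat])
}
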