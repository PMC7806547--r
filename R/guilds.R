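# Co-abundance guild (CAG) detection: correlation -> distance -> Ward tree ->
# recursive PERMANOVA tree-cut -> guild abundances and the display network.

#' Correlation matrix to SparCC distance
#'
#' `d = 1 - r`: perfectly co-abundant pairs sit at distance 0, perfectly
#' anti-correlated pairs at 2. The diagonal is forced to 0.
#'
#' @param corr Correlation matrix (or the list returned by [sparcc()]).
#' @return Square symmetric distance matrix in \[0, 2\].
#' @export
to_distance <- function(corr) {
  if (is.list(corr)) corr <- corr$r
  .assert_square_symmetric(corr, "correlation matrix")
  d <- 1 - corr
  diag(d) <- 0
  d[d < 0] <- 0
  d
}

#' Ward hierarchical clustering (ward.D2) with deterministic tie-breaking
#'
#' Agglomerative clustering under the Ward minimum-variance criterion in its
#' ward.D2 dialect: Lance-Williams updates on squared dissimilarities, merge
#' heights on the original distance scale. When several cluster pairs tie at
#' the minimal merge cost, the pair whose members contain the smallest
#' original leaf indices (lexicographically) is merged, so the tree is fully
#' determined by the input order.
#'
#' @param d Distance matrix (square symmetric) or `dist` object.
#' @param dialect `"ward.D2"` (default, the textbook Ward criterion) or
#'   `"ward.D"` (Lance-Williams on raw dissimilarities) for sensitivity
#'   checks.
#' @return An `hclust` object (merge, height, order, labels).
#' @export
ward_linkage <- function(d, dialect = c("ward.D2", "ward.D")) {
  dialect <- match.arg(dialect)
  d <- .as_distance_matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 items to cluster", call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  # working matrix: squared distances for ward.D2, raw for ward.D
  W <- if (dialect == "ward.D2") d^2 else d
  diag(W) <- Inf
  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  minleaf <- seq_len(n)              # smallest original leaf in each cluster
  id <- -seq_len(n)                  # hclust node id: -leaf or merge row
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    Wa <- W[active, active, drop = FALSE]
    m <- min(Wa)
    idx_active <- which(active)
    cand <- which(W == m & outer(active, active) & upper.tri(W), arr.ind = TRUE)
    # lexicographic tie-break on (smaller minleaf, larger minleaf)
    keys <- cbind(pmin(minleaf[cand[, 1L]], minleaf[cand[, 2L]]),
                  pmax(minleaf[cand[, 1L]], minleaf[cand[, 2L]]))
    pick <- order(keys[, 1L], keys[, 2L])[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    hij <- if (dialect == "ward.D2") sqrt(m) else m
    a <- id[i]; b <- id[j]
    merge[step, ] <- if (a < 0 && b < 0) c(max(a, b), min(a, b))
    else if (a < 0) c(a, b) else if (b < 0) c(b, a) else c(min(a, b), max(a, b))
    height[step] <- hij
    # Lance-Williams update of cluster i (absorbing j) against every other k
    others <- setdiff(idx_active, c(i, j))
    if (length(others)) {
      ni <- sizes[i]; nj <- sizes[j]; nk <- sizes[others]
      newW <- ((ni + nk) * W[i, others] + (nj + nk) * W[j, others] -
                 nk * m) / (ni + nj + nk)
      W[i, others] <- newW
      W[others, i] <- newW
    }
    active[j] <- FALSE
    sizes[i] <- sizes[i] + sizes[j]
    minleaf[i] <- min(minleaf[i], minleaf[j])
    id[i] <- step
  }
  order_ <- .hclust_order(merge)
  structure(list(merge = merge, height = height, order = order_,
                 labels = labels, method = dialect,
                 call = match.call(), dist.method = "sparcc"),
            class = "hclust")
}

#' @keywords internal
#' @noRd
.hclust_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(nrow(merge))
}

# All distinct labelings with the group sizes of `g` (complete enumeration).
# Returns an integer matrix N x n_labelings of level indices.
#' @keywords internal
#' @noRd
.all_labelings <- function(g) {
  g <- as.integer(factor(g))
  n <- length(g)
  lvls <- sort(unique(g))
  sizes <- tabulate(g)
  fill <- function(slots, remaining_lvls) {
    lv <- remaining_lvls[1L]
    sz <- sizes[lv]
    if (length(remaining_lvls) == 1L) {
      lab <- integer(n); lab[slots] <- lv
      return(matrix(lab, ncol = 1L))
    }
    picks <- utils::combn(slots, sz)
    out <- lapply(seq_len(ncol(picks)), function(c_) {
      sub <- fill(setdiff(slots, picks[, c_]), remaining_lvls[-1L])
      sub[picks[, c_], ] <- lv
      sub
    })
    do.call(cbind, out)
  }
  fill(seq_len(n), lvls)
}

# F statistic(s) from squared distances for one or many labelings.
# `labs` is an N x B matrix of integer group codes.
#' @keywords internal
#' @noRd
.permanova_F <- function(D2, labs, a) {
  N <- nrow(D2)
  SS_total <- sum(D2[upper.tri(D2)]) / N
  ss_w <- numeric(ncol(labs))
  for (lv in seq_len(a)) {
    X <- (labs == lv) * 1
    n_g <- colSums(X)
    ss_w <- ss_w + colSums(X * (D2 %*% X)) / (2 * n_g)
  }
  SS_between <- SS_total - ss_w
  (SS_between / (a - 1)) / (ss_w / (N - a))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the sum of squared dissimilarities:
#' `SS_total = sum_{i<j} d_ij^2 / N`, `SS_within = sum_g sum_{i<j in g}
#' d_ij^2 / n_g`, `SS_between = SS_total - SS_within`, and
#' `pseudo-F = (SS_between / (a - 1)) / (SS_within / (N - a))`. Significance
#' comes from random label permutations with the add-one correction
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)` (minimum attainable p is
#' `1 / (n_perm + 1)`), or from complete enumeration of all distinct
#' labelings (`complete = TRUE`), where `p = #\{F >= F_obs\} / n_labelings`
#' with the observed labeling included.
#'
#' @param d Distance matrix or `dist` over the observations.
#' @param grouping Group label per observation (>= 2 groups, at least one of
#'   size >= 2).
#' @param n_perm Number of random permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param complete Enumerate every distinct labeling instead of sampling.
#' @return List of class `"permanova"`: `pseudo_F`, `p_value`,
#'   `n_permutations`, `group_sizes`, `SS` (total/within/between).
#' @export
permanova <- function(d, grouping, n_perm = 999, seed = NULL, complete = FALSE) {
  d <- .as_distance_matrix(d)
  N <- nrow(d)
  if (length(grouping) != N)
    stop("grouping length must match the number of observations", call. = FALSE)
  g <- as.integer(factor(grouping))
  a <- length(unique(g))
  if (a < 2L) stop("PERMANOVA needs at least 2 groups", call. = FALSE)
  sizes <- tabulate(g)
  if (max(sizes) < 2L)
    stop("PERMANOVA needs at least one group with >= 2 observations",
         call. = FALSE)
  D2 <- d^2
  F_obs <- .permanova_F(D2, matrix(g, ncol = 1L), a)
  SS_total <- sum(D2[upper.tri(D2)]) / N
  ss_w <- 0
  for (lv in seq_len(a)) {
    idx <- which(g == lv)
    ss_w <- ss_w + sum(D2[idx, idx][upper.tri(D2[idx, idx, drop = FALSE])]) /
      length(idx)
  }
  if (complete) {
    labs <- .all_labelings(g)
    F_all <- .permanova_F(D2, labs, a)
    p <- mean(F_all >= F_obs)
    n_used <- ncol(labs)
  } else {
    perm <- function() replicate(n_perm, sample(g))
    labs <- if (is.null(seed)) perm() else .with_seed(seed, perm())
    F_perm <- .permanova_F(D2, labs, a)
    p <- (1 + sum(F_perm >= F_obs)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(pseudo_F = as.numeric(F_obs), p_value = p,
                 n_permutations = n_used, group_sizes = sizes,
                 SS = c(total = SS_total, within = ss_w,
                        between = SS_total - ss_w)),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA: pseudo-F =", format(x$pseudo_F, digits = 6),
      " p =", format(x$p_value, digits = 4),
      " (", x$n_permutations, "permutations; groups",
      paste(x$group_sizes, collapse = "/"), ")\n")
  invisible(x)
}

#' Cut a Ward tree into guilds by recursive PERMANOVA
#'
#' Walks the tree depth-first from the root. At each internal node the two
#' child subtrees define a two-group labeling of that node's leaves; PERMANOVA
#' on the corresponding distance sub-matrix decides whether the split is real:
#' if `p > alpha` the node's leaves collapse into a single CAG and descent
#' stops, otherwise both children are visited. Nodes with at most
#' `min_node_size` leaves become CAGs without testing (a 2-leaf split has no
#' permutation resolution). The stop rule is strictly `p > alpha`: with 999
#' permutations the smallest attainable p is 1/1000 = 0.001, which does not
#' exceed alpha = 0.001, so a maximally significant node always recurses.
#' CAG labels are assigned in traversal order (left subtree before right).
#'
#' @param tree `hclust` tree from [ward_linkage()].
#' @param d The distance matrix the tree was built from (ids must match
#'   `tree$labels`).
#' @param alpha Stop threshold on the PERMANOVA p-value (default 0.001).
#' @param n_perm Permutations per node test (default 999).
#' @param seed Master seed; each node's permutation stream is derived from
#'   (seed, node id) so the partition is reproducible.
#' @param min_node_size Maximum leaf count collapsed without testing
#'   (default 2).
#' @return Data frame with `asv_id` and `cag` (one row per leaf, tree label
#'   order); tested nodes with their pseudo-F/p and the decision are attached
#'   as `attr(, "nodes")`.
#' @export
cut_tree_by_permanova <- function(tree, d, alpha = 0.001, n_perm = 999,
                                  seed = NULL, min_node_size = 2L) {
  stopifnot(inherits(tree, "hclust"))
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  d <- .as_distance_matrix(d)
  labels <- tree$labels
  if (!is.null(rownames(d))) {
    if (!setequal(rownames(d), labels))
      stop("distance matrix ids do not match tree labels", call. = FALSE)
    d <- d[labels, labels]
  }
  n <- length(labels)
  merge <- tree$merge
  leaves_of <- vector("list", nrow(merge))
  for (k in seq_len(nrow(merge))) {
    kids <- merge[k, ]
    leaves_of[[k]] <- c(if (kids[1L] < 0) -kids[1L] else leaves_of[[kids[1L]]],
                        if (kids[2L] < 0) -kids[2L] else leaves_of[[kids[2L]]])
  }
  cag <- integer(n)
  next_label <- 0L
  node_log <- list()
  assign_cag <- function(leaf_idx) {
    next_label <<- next_label + 1L
    cag[leaf_idx] <<- next_label
  }
  visit <- function(node) {
    if (node < 0) { assign_cag(-node); return(invisible()) }
    leaves <- leaves_of[[node]]
    if (length(leaves) <= min_node_size) { assign_cag(leaves); return(invisible()) }
    kids <- merge[node, ]
    left <- if (kids[1L] < 0) -kids[1L] else leaves_of[[kids[1L]]]
    grouping <- ifelse(leaves %in% left, "L", "R")
    res <- permanova(d[leaves, leaves, drop = FALSE], grouping,
                     n_perm = n_perm,
                     seed = if (is.null(seed)) NULL else
                       .child_seed(seed, paste0("node", node)))
    stop_here <- res$p_value > alpha
    node_log[[length(node_log) + 1L]] <<- data.frame(
      node = node, n_leaves = length(leaves), n_left = length(left),
      pseudo_F = res$pseudo_F, p_value = res$p_value,
      decision = if (stop_here) "collapse" else "split")
    if (stop_here) assign_cag(leaves)
    else { visit(kids[1L]); visit(kids[2L]) }
    invisible()
  }
  visit(nrow(merge))
  out <- data.frame(asv_id = labels, cag = paste0("CAG", cag),
                    stringsAsFactors = FALSE)
  attr(out, "nodes") <- if (length(node_log)) do.call(rbind, node_log) else
    data.frame(node = integer(), n_leaves = integer(), n_left = integer(),
               pseudo_F = numeric(), p_value = numeric(),
               decision = character())
  out
}

#' Per-sample guild abundances
#'
#' Sums member-ASV relative abundances within each CAG. Column order follows
#' CAG discovery order (`CAG1`, `CAG2`, ...).
#'
#' @param rel Relative-abundance matrix (samples x ASVs).
#' @param assignment Data frame from [cut_tree_by_permanova()] (`asv_id`,
#'   `cag`).
#' @return Samples x CAGs matrix; each row totals the summed relative
#'   abundance of all assigned ASVs in that sample (<= 1).
#' @export
guild_abundance <- function(rel, assignment) {
  miss <- setdiff(assignment$asv_id, colnames(rel))
  if (length(miss))
    stop("ASVs in assignment missing from abundance table: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  cags <- unique(assignment$cag)
  out <- sapply(cags, function(cg) {
    members <- assignment$asv_id[assignment$cag == cg]
    rowSums(rel[, members, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(rel),
                dimnames = list(rownames(rel), cags))
  out
}

#' Guild summary per group and timepoint
#'
#' The bubble-plot quantities: mean relative abundance and coefficient of
#' variation of each CAG within every group x timepoint cell.
#'
#' @param gab Guild-abundance matrix from [guild_abundance()].
#' @param metadata Sample metadata with `sample_id`, `group` and (optionally)
#'   `timepoint`.
#' @return Long data frame: `cag`, `group`, `timepoint`, `n`, `mean_abundance`,
#'   `cv` (SD/mean; `NA` when the mean is 0).
#' @export
guild_summary <- function(gab, metadata) {
  al <- align_samples(gab, metadata)
  gab <- al$table; md <- al$metadata
  tp <- if ("timepoint" %in% names(md)) as.character(md$timepoint) else "all"
  key <- interaction(md$group, tp, drop = TRUE, sep = "\r")
  rows <- lapply(levels(key), function(k) {
    idx <- which(key == k)
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    mu <- colMeans(gab[idx, , drop = FALSE])
    sdv <- apply(gab[idx, , drop = FALSE], 2L, stats::sd)
    data.frame(cag = colnames(gab), group = parts[1L], timepoint = parts[2L],
               n = length(idx), mean_abundance = mu,
               cv = ifelse(mu > 0, sdv / mu, NA_real_),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build the guild co-abundance display network
#'
#' Nodes are ASVs annotated with mean relative abundance, CAG label and
#' (optionally) taxonomy; edges connect pairs whose correlation magnitude
#' reaches the display threshold, with the correlation value and its sign.
#'
#' @param corr Correlation matrix (or [sparcc()] result).
#' @param assignment Guild assignment data frame (`asv_id`, `cag`).
#' @param rel Relative-abundance matrix used for node sizes.
#' @param min_abs_r Edge display threshold on `|r|` (default 0.6; edges below
#'   it are omitted).
#' @param taxonomy Optional named character vector ASV -> lineage string.
#' @return An `igraph` graph.
#' @export
build_network <- function(corr, assignment, rel, min_abs_r = 0.6,
                          taxonomy = NULL) {
  if (is.list(corr)) corr <- corr$r
  .assert_square_symmetric(corr, "correlation matrix")
  ids <- rownames(corr)
  cag <- assignment$cag[match(ids, assignment$asv_id)]
  mean_ab <- colMeans(rel[, ids, drop = FALSE])
  ut <- which(upper.tri(corr) & abs(corr) >= min_abs_r, arr.ind = TRUE)
  edges <- data.frame(from = ids[ut[, 1L]], to = ids[ut[, 2L]],
                      r = corr[ut], sign = ifelse(corr[ut] >= 0,
                                                  "positive", "negative"),
                      weight = abs(corr[ut]), stringsAsFactors = FALSE)
  vertices <- data.frame(name = ids, mean_abundance = as.numeric(mean_ab),
                         cag = cag, stringsAsFactors = FALSE)
  if (!is.null(taxonomy))
    vertices$taxonomy <- unname(taxonomy[ids])
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' Write a co-abundance network to disk
#'
#' `graphml` round-trips nodes, edges and attributes (Cytoscape-importable);
#' `sif` writes `node pos|neg node` interaction lines (isolated nodes on their
#' own lines); `edge-tsv` is a plain edge list with attributes.
#'
#' @param graph `igraph` graph from [build_network()].
#' @param path Output path.
#' @param format One of `"graphml"`, `"sif"`, `"edge-tsv"`.
#' @return The path, invisibly.
#' @export
write_network <- function(graph, path, format = c("graphml", "sif", "edge-tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(graph, what = "edges")
    if (format == "sif") {
      lines <- if (nrow(el))
        sprintf("%s\t%s\t%s", el$from,
                ifelse(el$sign == "positive", "pos", "neg"), el$to)
      else character()
      iso <- setdiff(igraph::V(graph)$name, c(el$from, el$to))
      writeLines(c(lines, iso), path)
    } else {
      utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}
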