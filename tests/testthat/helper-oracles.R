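# Shared fixtures and independent oracles.

# Random symmetric distance matrix with zero diagonal.
random_distance <- function(n, seed) {
  set.seed(seed)
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.05, 2)
  d <- d + t(d)
  rownames(d) <- colnames(d) <- paste0("x", seq_len(n))
  d
}

# Small count fixture: 5 samples x 4 ASVs with known presence pattern.
toy_counts <- function() {
  m <- rbind(c(5L, 3L, 0L, 0L),
             c(4L, 0L, 0L, 0L),
             c(6L, 2L, 7L, 0L),
             c(3L, 9L, 0L, 0L),
             c(8L, 0L, 0L, 0L))
  dimnames(m) <- list(paste0("s", 1:5), paste0("a", 1:4))
  m
}

# Exhaustive PERMANOVA oracle: enumerates every distinct labeling with the
# observed group sizes and computes pseudo-F straight from the
# partition-of-sums formula.
oracle_permanova <- function(d, grouping) {
  d <- as.matrix(d)
  N <- nrow(d)
  g <- as.integer(factor(grouping))
  a <- length(unique(g))
  fstat <- function(lab) {
    D2 <- d^2
    ss_tot <- sum(D2[upper.tri(D2)]) / N
    ss_w <- 0
    for (lv in unique(lab)) {
      idx <- which(lab == lv)
      sub <- D2[idx, idx, drop = FALSE]
      ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
    }
    ((ss_tot - ss_w) / (a - 1)) / (ss_w / (N - a))
  }
  F_obs <- fstat(g)
  # enumerate all distinct assignments of the label multiset
  sizes <- tabulate(g)
  labelings <- list(integer(0))
  slots_list <- list(seq_len(N))
  labs <- NULL
  enumerate <- function(slots, lvls) {
    if (length(lvls) == 1L) {
      lab <- integer(N); lab[slots] <- lvls
      return(list(lab))
    }
    lv <- lvls[1L]
    out <- list()
    cmb <- utils::combn(slots, sizes[lv])
    for (c_ in seq_len(ncol(cmb))) {
      rest <- enumerate(setdiff(slots, cmb[, c_]), lvls[-1L])
      for (lab in rest) { lab[cmb[, c_]] <- lv; out[[length(out) + 1L]] <- lab }
    }
    out
  }
  all_labs <- enumerate(seq_len(N), sort(unique(g)))
  F_all <- vapply(all_labs, fstat, numeric(1))
  list(F = F_obs, p = mean(F_all >= F_obs), n_labelings = length(all_labs))
}

# Naive O(n^3) Ward (ward.D2) oracle: at every step recomputes the merge
# cost of every active cluster pair from the ORIGINAL squared distances via
# the centroid identity
#   ||cA - cB||^2 = mean cross d^2 - V(A) - V(B),
#   V(A) = sum_{a<a' in A} d^2 / |A|^2,
# cost(A,B) = |A||B|/(|A|+|B|) * ||cA - cB||^2, height = sqrt(2 * cost).
# Tie-break: lexicographically smallest (smallest leaf, other smallest leaf).
oracle_ward <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  D2 <- d^2
  clusters <- as.list(seq_len(n))
  ids <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  cost <- function(A, B) {
    cross <- mean(D2[A, B, drop = FALSE])
    VA <- sum(D2[A, A]) / (2 * length(A)^2)
    VB <- sum(D2[B, B]) / (2 * length(B)^2)
    (length(A) * length(B) / (length(A) + length(B))) * (cross - VA - VB)
  }
  for (step in seq_len(n - 1L)) {
    k <- length(clusters)
    best <- NULL
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      cc <- cost(clusters[[i]], clusters[[j]])
      key <- c(cc, min(clusters[[i]][1L], clusters[[j]][1L]),
               max(clusters[[i]][1L], clusters[[j]][1L]))
      if (is.null(best) || cc < best$key[1L] - 1e-12 ||
          (abs(cc - best$key[1L]) <= 1e-12 &&
           (key[2L] < best$key[2L] ||
            (key[2L] == best$key[2L] && key[3L] < best$key[3L])))) {
        best <- list(i = i, j = j, key = key)
      }
    }
    i <- best$i; j <- best$j
    a <- ids[i]; b <- ids[j]
    merge[step, ] <- if (a < 0 && b < 0) c(max(a, b), min(a, b))
    else if (a < 0) c(a, b) else if (b < 0) c(b, a) else c(min(a, b), max(a, b))
    height[step] <- sqrt(2 * best$key[1L])
    clusters[[i]] <- sort(c(clusters[[i]], clusters[[j]]))
    ids[i] <- step
    clusters[[j]] <- NULL
    ids <- ids[-j]
  }
  list(merge = merge, height = height)
}

# Block-structured distance matrix: within-block distance w, between b.
block_distance <- function(block_sizes, within = 0.1, between = 1.8) {
  n <- sum(block_sizes)
  lab <- rep(seq_along(block_sizes), block_sizes)
  d <- ifelse(outer(lab, lab, "=="), within, between)
  diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  d
}

# Leaf indices under one child of an hclust internal node.
.hclust_leaves <- function(tree, node, child) {
  walk <- function(k) {
    if (k < 0) return(-k)
    c(walk(tree$merge[k, 1L]), walk(tree$merge[k, 2L]))
  }
  walk(tree$merge[node, child])
}

# Exact two-sided Spearman permutation p by enumerating all n! orderings.
oracle_spearman_p <- function(x, y) {
  rho_obs <- stats::cor(x, y, method = "spearman")
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  rhos <- vapply(perms(y), function(p) stats::cor(x, p, method = "spearman"),
                 numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}
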