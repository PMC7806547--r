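# SparCC: basis ("compositionality-corrected") correlations from count data.
#
# Observed fractions x_i are closed to 1, so their Pearson correlations are
# distorted. SparCC works from the log-ratio variances
#   t_ij = var(log(x_i / x_j)),
# which relate to the latent basis variances w_i and basis correlations r_ij by
#   t_ij = w_i + w_j - 2 r_ij sqrt(w_i w_j).
# Under the sparsity assumption sum_j r_ij ~ 0, summing over j gives the linear
# system ((D - 2) I + 11') w = t_rowsum, solved for w, after which each r_ij
# follows from the displayed identity. Strong pairs violating sparsity are
# removed iteratively and the system re-solved; fractions are resampled from a
# Dirichlet posterior and estimates aggregated by the element-wise median.

#' Log-ratio variance matrix
#'
#' `T[i, j] = var(log(x_i / x_j))` across samples (sample variance, n - 1
#' denominator); the diagonal is 0. Fractions must be strictly positive —
#' zeros are resolved upstream by Dirichlet resampling or pseudocounts.
#'
#' @param fractions Samples x ASVs matrix of strictly positive fractions.
#' @return Symmetric D x D matrix of log-ratio variances.
#' @export
log_ratio_variances <- function(fractions) {
  if (!is.matrix(fractions) || !is.numeric(fractions))
    stop("fractions must be a numeric matrix", call. = FALSE)
  if (any(fractions <= 0))
    stop("all fractions must be strictly positive; resolve zeros upstream",
         call. = FALSE)
  if (nrow(fractions) < 2L)
    stop("need at least 2 samples to compute variances", call. = FALSE)
  L <- log(fractions)
  C <- stats::cov(L)
  v <- diag(C)
  T_ <- outer(v, v, "+") - 2 * C
  T_ <- (T_ + t(T_)) / 2
  diag(T_) <- 0
  dimnames(T_) <- list(colnames(fractions), colnames(fractions))
  T_
}

# Solve the SparCC linear system for basis variances, with excluded pairs
# removed from both the coefficient matrix and the row sums.
#' @keywords internal
#' @noRd
.solve_basis_variances <- function(T_, excluded, var_floor = 1e-8) {
  D <- nrow(T_)
  M <- matrix(1, D, D)
  diag(M) <- D - 1
  t_vec <- rowSums(T_)
  if (nrow(excluded)) {
    for (k in seq_len(nrow(excluded))) {
      i <- excluded[k, 1L]; j <- excluded[k, 2L]
      M[i, j] <- M[j, i] <- M[i, j] - 1
      M[i, i] <- M[i, i] - 1
      M[j, j] <- M[j, j] - 1
      t_vec[i] <- t_vec[i] - T_[i, j]
      t_vec[j] <- t_vec[j] - T_[i, j]
    }
  }
  w <- tryCatch(solve(M, t_vec), error = function(e)
    stop("SparCC basis-variance system is singular (too many excluded pairs)",
         call. = FALSE))
  floored <- w < var_floor
  w[floored] <- var_floor
  list(w = w, floored = which(floored))
}

#' Basis correlations from a log-ratio variance matrix
#'
#' Solves the sparsity-approximation linear system for the basis variances and
#' converts them to basis correlations. Estimates outside \[-1, 1\] are clamped
#' and flagged; negative solved variances are floored at a small positive
#' constant and flagged.
#'
#' @param T_ Log-ratio variance matrix from [log_ratio_variances()].
#' @param excluded Integer matrix (k x 2) of pair indices excluded from the
#'   system (strong pairs violating sparsity), or `NULL`.
#' @return List: `r` (correlation matrix, unit diagonal), `w` (basis
#'   variances), `diagnostics` (`clamped` pair count, `floored` variance
#'   indices).
#' @export
basis_correlations <- function(T_, excluded = NULL) {
  .assert_square_symmetric(T_, "log-ratio variance matrix")
  D <- nrow(T_)
  if (D < 4L)
    stop("SparCC needs at least 4 ASVs: with D < 4 the basis-variance system ",
         "is not identifiable", call. = FALSE)
  if (is.null(excluded)) excluded <- matrix(integer(), 0L, 2L)
  sol <- .solve_basis_variances(T_, excluded)
  w <- sol$w
  r <- (outer(w, w, "+") - T_) / (2 * sqrt(outer(w, w)))
  clamped <- sum(abs(r[upper.tri(r)]) > 1)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r <- (r + t(r)) / 2
  dimnames(r) <- dimnames(T_)
  list(r = r, w = w,
       diagnostics = list(clamped = clamped, floored = sol$floored))
}

# One SparCC estimate from a fraction matrix: iterative exclusion of the
# strongest pair above `threshold`, re-solving after each exclusion.
# Tie-break: the lexicographically smallest (i, j). Each taxon can lose at
# most floor((D - 1) / 2) of its pairs: the sparsity-approximation bias is
# O(1/D), so at small D noise pairs sit above the threshold and unlimited
# exclusion would cascade and destabilise the basis-variance solve.
#' @keywords internal
#' @noRd
.sparcc_one <- function(fractions, n_exclusion_iters, exclusion_threshold) {
  T_ <- log_ratio_variances(fractions)
  D <- nrow(T_)
  excluded <- matrix(integer(), 0L, 2L)
  n_excl_by_taxon <- integer(D)
  est <- basis_correlations(T_, excluded)
  max_iter <- min(n_exclusion_iters, D * (D - 1) / 2)
  for (iter in seq_len(max_iter)) {
    r <- abs(est$r)
    diag(r) <- 0
    if (nrow(excluded))
      r[rbind(excluded, excluded[, 2:1, drop = FALSE])] <- 0
    m <- max(r)
    if (m <= exclusion_threshold) break
    # candidates at the max, lexicographic order; skip near-isolated taxa
    cand <- which(r == m, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    cap <- (D - 1L) %/% 2L
    ok <- n_excl_by_taxon[cand[, 1L]] < cap &
      n_excl_by_taxon[cand[, 2L]] < cap
    if (!any(ok)) break
    pick <- cand[which(ok)[1L], , drop = FALSE]
    excluded <- rbind(excluded, pick)
    n_excl_by_taxon[pick] <- n_excl_by_taxon[pick] + 1L
    est <- basis_correlations(T_, excluded)
  }
  est$diagnostics$n_excluded <- nrow(excluded)
  est
}

#' SparCC basis correlations for a count table
#'
#' The full procedure: for each of `n_dirichlet_draws` repetitions, sample
#' fractions from a per-sample Dirichlet posterior (pseudocount 1 on every
#' count), compute log-ratio variances, estimate basis correlations with
#' iterative strong-pair exclusion, and aggregate by the element-wise median.
#' `fractions = "plugin"` instead uses the deterministic posterior mean
#' `(count + 1) / (total + D)` in a single pass — useful for reproducibility
#' tests and scale-invariance checks.
#'
#' @param counts Feature table (samples x ASVs); should already be
#'   prevalence-filtered. Needs D >= 4 ASVs.
#' @param n_dirichlet_draws Posterior resampling repetitions (default 20).
#' @param n_exclusion_iters Maximum strong-pair exclusions per estimate. The
#'   default `Inf` iterates until no non-excluded pair exceeds the threshold,
#'   which removes the bias a dense correlation block otherwise leaves in the
#'   sparsity system; a finite cap reproduces implementations that stop
#'   early.
#' @param exclusion_threshold Correlation magnitude above which a pair can be
#'   excluded from the sparsity system (default 0.1).
#' @param seed Master seed for the Dirichlet draws.
#' @param fractions `"dirichlet"` (default) or `"plugin"`.
#' @return List: `r` (median basis correlation matrix, unit diagonal, clamped
#'   to \[-1, 1\]), `diagnostics` (per-draw exclusion counts, clamp/floor
#'   totals).
#' @export
sparcc <- function(counts, n_dirichlet_draws = 20, n_exclusion_iters = Inf,
                   exclusion_threshold = 0.1, seed = NULL,
                   fractions = c("dirichlet", "plugin")) {
  fractions <- match.arg(fractions)
  validate_feature_table(counts)
  D <- ncol(counts)
  if (D < 4L) stop("SparCC needs at least 4 ASVs", call. = FALSE)
  if (exclusion_threshold <= 0 || exclusion_threshold >= 1)
    stop("exclusion_threshold must be in (0, 1)", call. = FALSE)
  draws <- if (fractions == "plugin") 1L else as.integer(n_dirichlet_draws)
  if (draws < 1L) stop("n_dirichlet_draws must be >= 1", call. = FALSE)
  ests <- vector("list", draws)
  n_excluded <- integer(draws)
  for (b in seq_len(draws)) {
    fr <- if (fractions == "plugin") {
      (counts + 1) / (rowSums(counts) + D)
    } else {
      draw <- function() {
        g <- matrix(stats::rgamma(length(counts), shape = counts + 1),
                    nrow(counts), D)
        g / rowSums(g)
      }
      if (is.null(seed)) draw() else .with_seed(.child_seed(seed, b), draw())
    }
    est <- .sparcc_one(fr, n_exclusion_iters, exclusion_threshold)
    ests[[b]] <- est$r
    n_excluded[b] <- est$diagnostics$n_excluded
  }
  r <- if (draws == 1L) ests[[1L]] else {
    arr <- array(unlist(ests), dim = c(D, D, draws))
    apply(arr, c(1, 2), stats::median)
  }
  r[r > 1] <- 1; r[r < -1] <- -1
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(colnames(counts), colnames(counts))
  list(r = r,
       diagnostics = list(n_draws = draws, n_excluded = n_excluded,
                          fractions = fractions))
}

#' Permutation pseudo p-values for SparCC correlations
#'
#' The null destroys co-abundance while preserving each ASV's marginal count
#' distribution: every ASV's counts are permuted independently across samples,
#' SparCC is re-estimated, and the two-sided pseudo p-value is
#' `(1 + #\{b : |r_b| >= |r_obs|\}) / (1 + n_bootstrap)` — so the smallest
#' attainable p is `1 / (n_bootstrap + 1)`.
#'
#' @param counts Feature table used to compute `observed`.
#' @param observed Observed correlation matrix (`$r` from [sparcc()]).
#' @param n_bootstrap Number of null resamples (default 100).
#' @param seed Master seed; the null stream is independent of the estimate
#'   stream.
#' @param ... Passed to [sparcc()] (draws, exclusion settings, fraction mode).
#' @return Symmetric matrix of pseudo p-values (diagonal `NA`).
#' @export
sparcc_pvalues <- function(counts, observed, n_bootstrap = 100, seed = NULL, ...) {
  validate_feature_table(counts)
  if (is.list(observed)) observed <- observed$r
  .assert_square_symmetric(observed, "observed correlation matrix")
  if (n_bootstrap < 1) stop("n_bootstrap must be >= 1", call. = FALSE)
  D <- ncol(counts)
  hits <- matrix(0L, D, D)
  obs <- abs(observed)
  for (b in seq_len(n_bootstrap)) {
    perm <- function() apply(counts, 2L, sample)
    null_counts <- if (is.null(seed)) perm() else
      .with_seed(.child_seed(seed, paste0("boot", b)), perm())
    rownames(null_counts) <- rownames(counts)
    r_b <- sparcc(null_counts, seed = if (is.null(seed)) NULL else
      .child_seed(seed, paste0("bootfit", b)), ...)$r
    hits <- hits + (abs(r_b) >= obs)
  }
  p <- (1 + hits) / (1 + n_bootstrap)
  p <- (p + t(p)) / 2
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(observed)
  p
}
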