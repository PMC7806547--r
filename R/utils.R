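# Internal helpers: seed streams and input validation shared across modules.

#' @keywords internal
#' @noRd
.hash_string <- function(s) {
  # deterministic 31-bit polynomial hash, platform independent
  h <- 0
  for (b in utf8ToInt(enc2utf8(s))) h <- (h * 131 + b) %% 2147483647L
  as.integer(h)
}

# Derive a child seed from a master seed and an integer or string key.
# Keeps every derived seed in [1, 2^31 - 2] so set.seed() is always valid.
#' @keywords internal
#' @noRd
.child_seed <- function(seed, key) {
  if (is.character(key)) key <- .hash_string(key)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271 + as.double(key) * 16807) %% 2147483647
  as.integer(x %% 2147483645) + 1L
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
#' @keywords internal
#' @noRd
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @keywords internal
#' @noRd
.assert_square_symmetric <- function(m, what = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be a square matrix", call. = FALSE)
  if (max(abs(m - t(m))) > tol)
    stop(what, " must be symmetric", call. = FALSE)
  invisible(m)
}

# Accept a dist or a square symmetric matrix; return the matrix form with ids.
#' @keywords internal
#' @noRd
.as_distance_matrix <- function(d, what = "distance matrix") {
  if (inherits(d, "dist")) d <- as.matrix(d)
  .assert_square_symmetric(d, what)
  if (any(d < -1e-12)) stop(what, " has negative entries", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12)) stop(what, " has a non-zero diagonal", call. = FALSE)
  d
}
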