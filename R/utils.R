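#' @keywords internal
"_PACKAGE"

# Epoch length used throughout: the 30-second scoring unit of sleep staging.
EPOCH_SEC <- 30
EPOCHS_PER_DAY <- 24 * 3600 / EPOCH_SEC  # 2880

STAGE_LEVELS <- c("WAKE", "N1", "N2", "N3", "REM", "UNKNOWN")
SLEEP_STAGES <- c("N1", "N2", "N3", "REM")

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded package functions do
#' not perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed below 2^31 from a parent seed.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + stream * 1299709) %% 2147483647
}

#' Run-length segments of a logical/character vector
#'
#' @return data.frame with columns start, end (inclusive indices) and value.
#' @noRd
run_segments <- function(x) {
  r <- rle(as.vector(x))
  end <- cumsum(r$lengths)
  data.frame(start = end - r$lengths + 1L, end = end, value = r$values,
             stringsAsFactors = FALSE)
}

#' Gauss-Hermite quadrature nodes and weights
#'
#' Golub-Welsch: eigen-decomposition of the symmetric tridiagonal Jacobi
#' matrix for the Hermite weight exp(-x^2).
#' @noRd
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- sqrt(pi) * e$vectors[1, ]^2
  ord <- order(nodes)
  list(nodes = nodes[ord], weights = weights[ord])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
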