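#' Derive a sub-seed from a root seed and a stream name
#'
#' All randomness in the simulator flows from one root seed through named
#' streams (one per lectin and stage), so any stage can be regenerated on
#' its own without replaying the whole cohort. The derived seed is always
#' a valid 32-bit integer.
#'
#' @param root integer root seed.
#' @param key character stream name, e.g. "dda-AAL".
#' @return an integer seed in [0, 2^31 - 2].
#' @keywords internal
stream_seed <- function(root, key) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(key))
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(((abs(root) %% 1048573) * 2039 + h) %% 2147483647)
}

#' Evaluate an expression with a temporary RNG state
#'
#' Restores the caller's \code{.Random.seed} afterwards so that seeded
#' internals (fold assignment, imputation draws) never perturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Moore-Penrose pseudoinverse via SVD; tolerance scaled as in base qr.
pinv <- function(A, tol = .Machine$double.eps * 100) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
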