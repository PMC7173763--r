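# internal numeric helpers

# gas constant in kcal/(mol K); RT at 310 K = 0.616032 kcal/mol
R_KCAL <- 0.0019872

#' @noRd
rt_kcal <- function(temperature) R_KCAL * temperature

#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# column-wise logsumexp of a matrix
#' @noRd
col_logsumexp <- function(m) {
  mx <- apply(m, 2, max)
  ok <- is.finite(mx)
  out <- mx
  if (any(ok)) {
    sh <- sweep(m[, ok, drop = FALSE], 2, mx[ok], "-")
    out[ok] <- mx[ok] + log(colSums(exp(sh)))
  }
  out
}

#' @noRd
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' @noRd
vnorm <- function(v) sqrt(sum(v * v))

# run code with a private RNG stream, restoring the caller's state
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
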