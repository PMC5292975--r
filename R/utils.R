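#' @keywords internal
"_PACKAGE"

# Internal call codes: 0 = homozygous parent-A, 1 = heterozygous,
# 2 = homozygous parent-B, NA = missing.
GENO_CODES <- c(0L, 1L, 2L)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gbs <- function(..., class = "gbsmap_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop_gbs(name, " must be a single number in [", lo, ", ", hi, "]",
             class = "gbsmap_validation_error")
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    stop_gbs(name, " must be a single integer >= ", min,
             class = "gbsmap_validation_error")
  invisible(as.integer(x))
}

#' Seeded evaluation helper
#'
#' Runs an expression under a fixed RNG seed and restores the caller's RNG
#' state afterwards, so package functions that accept a `seed` argument do
#' not disturb the user's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Running (centered, partial-at-ends-excluded) window sums along rows of a
# matrix: out[, j] = sum of x[, (j-k)..(j+k)]; columns with incomplete
# windows return NA.
window_row_sums <- function(x, k) {
  m <- ncol(x)
  cs <- cbind(0, t(apply(x, 1L, cumsum)))
  out <- matrix(NA_real_, nrow(x), m)
  if (m >= 2L * k + 1L) {
    j <- (k + 1L):(m - k)
    out[, j] <- cs[, j + k + 1L, drop = FALSE] - cs[, j - k, drop = FALSE]
  }
  out
}
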