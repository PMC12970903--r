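# Internal helpers shared across modules.

#' Run code with a temporarily fixed RNG state
#'
#' Saves and restores `.Random.seed` so that seeded internals do not disturb
#' the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# round-half-away-from-zero (base round() is banker's rounding)
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# deterministic per-stage substream seeds from one root seed
stage_seed <- function(seed, stage) {
  offsets <- c(
    cohort = 101L, scn = 211L, metrics = 307L, compare = 401L,
    correlate = 503L, mediate = 601L, smallworld = 701L
  )
  off <- offsets[[stage]]
  (as.integer(seed) + off * 1009L) %% 2147483629L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_square_symmetric <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}
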