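# shared internal helpers

.fail <- function(...) stop(..., call. = FALSE)

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed tables in sequencing QC
#' reports round half up. This helper matches that convention for
#' non-negative inputs.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Deterministic per-stage seed derived from one user-facing seed, so that
# simulation stages can be regenerated independently. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  cp <- utf8ToInt(stage)
  h <- sum(cp * seq_along(cp))
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

# Evaluate `code` under a fixed RNG state, restoring the caller's state.
# RNG kinds are pinned so generated data is byte-stable across sessions.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  code
}

# whole-number check tolerant of numeric storage
is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}
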