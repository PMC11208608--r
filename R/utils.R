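# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without touching global RNG state.
# seed = NULL leaves the current generator alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Validation error that names the offending field.
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    abort(sprintf("invalid `%s`: %s", field, msg), class = "sliceglia_validation_error")
  }
  invisible(TRUE)
}

check_positive <- function(x, field) {
  check_that(is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0,
             field, "must be a single positive finite number")
}

check_nonneg <- function(x, field) {
  check_that(is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0,
             field, "must be a single non-negative finite number")
}

check_count <- function(x, field, min = 0L) {
  check_that(is.numeric(x) && length(x) == 1L && is.finite(x) &&
               x >= min && x == round(x),
             field, sprintf("must be a whole number >= %d", min))
}

# Indices of strict local maxima of a numeric vector (plateaus take the first
# sample; endpoints are never peaks).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
}

local_minima <- function(x) local_maxima(-x)

# Topographic prominence of the local maxima at indices `peaks`: height above
# the higher of the two key saddles (lowest point separating the peak from the
# nearest higher ground on each side, or from the trace edge).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    base <- function(v) {
      # v runs outward from the peak; stop at the first strictly higher sample
      if (!length(v)) return(h)
      higher <- which(v > h)
      if (length(higher)) v <- v[seq_len(higher[1L] - 1L)]
      if (!length(v)) return(h)
      min(v)
    }
    left <- base(rev(x[seq_len(p - 1L)]))
    right <- base(if (p < length(x)) x[(p + 1L):length(x)] else numeric(0))
    h - max(left, right)
  }, numeric(1))
}

# Linear interpolation of the time at which `x` crosses `level` between
# samples i and i+1 (assumes x[i], x[i+1] bracket the level).
cross_time <- function(t, x, i, level) {
  x0 <- x[i]; x1 <- x[i + 1L]
  if (x1 == x0) return(t[i])
  t[i] + (level - x0) / (x1 - x0) * (t[i + 1L] - t[i])
}
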