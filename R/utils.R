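# Internal helpers: condition classes, seed handling, small numerics.

stop_validation <- function(msg, call. = sys.call(-1)) {
  stop(errorCondition(msg, class = c("oscibp_validation_error", "oscibp_error"),
                      call = call.))
}

stop_numerical <- function(msg, call. = sys.call(-1)) {
  stop(errorCondition(msg, class = c("oscibp_numerical_error", "oscibp_error"),
                      call = call.))
}

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards, so library functions never clobber the
# user's stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_validation("seed must be a single finite number")
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Counter-based derivation of sub-stream seeds from a root seed and integer
# indices, so per-(subject, feature) results do not depend on loop order.
# Constants kept < 2^53 / 2^31 so double arithmetic stays exact.
derive_seed <- function(root, ...) {
  idx <- c(...)
  x <- as.double(abs(root)) %% 2147483647
  for (k in c(idx, 40503)) {
    x <- (x * 69069 + as.double(k) + 12345) %% 2147483647
  }
  as.integer(x)
}

# Stable integer key for a subject identifier, so per-subject random
# streams do not depend on the subject's position in the table.
id_key <- function(id) {
  x <- 7
  for (k in utf8ToInt(as.character(id))) x <- (x * 131 + k) %% 2147483647
  as.integer(x)
}

sigm <- function(x) stats::plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "g")
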