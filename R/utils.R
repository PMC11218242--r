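#' @importFrom rlang %||% abort warn inform
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join n across all_of distinct pull first rename
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats median quantile sd var cor wilcox.test rnorm runif rexp
#'   setNames predict
#' @importFrom utils combn head tail
#' @importFrom grDevices chull
NULL

# Stable 32-bit string hash (djb2 variant). Used to derive child RNG seeds
# from (trial_id, track_id) so a track's trajectory does not depend on how
# many siblings were simulated before it.
hash_string32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(as.character(s)))
  h <- 5381
  for (b in bytes) {
    h <- (h * 33 + b) %% 2147483647
  }
  as.integer(h)
}

# Child seed from a parent seed and any number of string/int parts.
# Always in [0, 2^31 - 1).
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "\x1f")
  hash_string32(parts)
}

# Run code with a local RNG state so library calls never disturb the
# caller's RNG stream.
with_local_seed <- function(seed, code) {
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
  force(code)
}

assert_finite <- function(x, name) {
  if (!all(is.finite(x))) {
    abort(sprintf("`%s` must contain only finite values.", name))
  }
  invisible(x)
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}
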