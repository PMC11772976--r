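# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so library calls never perturb user code.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Deterministic fan-out of a master seed to per-stage, per-position,
#' per-replicate seeds. The mapping is a string hash, so adding replicates or
#' stages never perturbs seeds already handed out (counter-based scheme).
#'
#' @param master_seed integer master seed.
#' @param ... further tokens (stage name, position label, replicate index);
#'   coerced to character and hashed together with the master seed.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @examples
#' stage_seed(17, "tracks", "D20", 3)
#' @export
stage_seed <- function(master_seed, ...) {
  tokens <- paste(c(as.character(master_seed), vapply(list(...), as.character, "")),
                  collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tokens)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
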