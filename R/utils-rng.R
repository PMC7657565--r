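#' Derive a reproducible child seed from a master seed
#'
#' Stages of the pipeline draw from independent, labelled substreams so that
#' changing the settings of one stage (e.g. the fMRI noise level) does not
#' perturb the random draws of another (e.g. the reward schedule). Substream
#' seeds are derived deterministically from the master seed and a label by a
#' small multiplicative hash, kept below 2^31 so the result is a valid R
#' integer seed.
#'
#' @param seed Integer master seed.
#' @param ... Labels (character or integer) identifying the substream, e.g.
#'   `derive_seed(1, "subject", 3, "rewards")`.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "rewards")
#' derive_seed(1, "subject", 2, "sides")
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (lab in list(...)) {
    bytes <- utf8ToInt(paste0(as.character(lab), collapse = "|"))
    for (b in c(bytes, 31L)) {
      # 48271 is the MINSTD multiplier; all arithmetic stays below 2^53
      h <- (h * 48271 + b) %% m
    }
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. seed = NULL uses the current stream.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

# z-score a numeric vector; constant vectors map to all zeros (flagged by the
# caller where that matters).
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}
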