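#' Derive a stage-specific random seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed deterministically
#' from the master seed and a stage name, so that reordering or skipping stages
#' never changes the stream another stage sees.
#'
#' @param seed Master seed (integer).
#' @param stage Character stage name.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(as.numeric(utf8ToInt(stage)) * seq_along(utf8ToInt(stage)) * 131)
  val <- (abs(as.numeric(seed)) * 69069 + h) %% 2147483646
  as.integer(val) + 1L
}

# sign convention used for all latent-variable anchoring: sign(0) = +1
sign0 <- function(x) ifelse(x >= 0, 1, -1)

#' Geometric mean
#' @param x Positive numeric vector.
#' @return `exp(mean(log(x)))`.
#' @export
geometric_mean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

# run code with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
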