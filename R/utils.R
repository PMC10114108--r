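#' @keywords internal
expit <- function(x) stats::plogis(x)

#' @keywords internal
logit <- function(p) stats::qlogis(p)

#' Derive a stage-specific seed from a global seed
#'
#' Stage seeds are a stable integer hash of the stage name folded into the
#' global seed, so adding or reordering pipeline stages never perturbs the
#' random draws of other stages. The result is kept below 2^31 - 1.
#'
#' @param global_seed integer global seed.
#' @param stage character stage name, e.g. "simulate".
#' @return An integer seed.
#' @export
stage_seed <- function(global_seed, stage) {
  stopifnot(is.numeric(global_seed), length(global_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  h <- sum(as.integer(charToRaw(stage)) * (seq_along(charToRaw(stage)) %% 7L + 1L))
  as.integer((abs(as.numeric(global_seed)) * 1009 + h * 9176) %% 2147483647)
}

#' Weighted mean and variance matching sample statistics of a replicated sample
#'
#' With integer weights these equal `mean()` and `var()` of the data set in
#' which row i is repeated w_i times (frequency-weight convention).
#'
#' @param x numeric vector.
#' @param w non-negative weights.
#' @return list with `mean` and `var`.
#' @keywords internal
weighted_stats <- function(x, w) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  v <- if (sw > 1) sum(w * (x - m)^2) / (sw - 1) else NA_real_
  list(mean = m, var = v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
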