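# internal helpers: classed conditions and scoped RNG

lm_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "lipidmix_error"), call = call))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `expr`, and restores the caller's RNG
#' state afterwards, so deterministic generators do not disturb the global
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(seed)
  expr
}

# round() half-away-from-zero, for stable 2-decimal reporting
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
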