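# internal helpers shared across modules

#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
NULL

# population standard deviation (ddof = 0)
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

# run code under a fixed RNG state without disturbing the caller's stream
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

# stop unless `x` is a single positive finite number
check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number, got %s.",
                  name, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

logistic <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a
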