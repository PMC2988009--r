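# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so that seeded package functions do
#' not disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

warn_ <- function(...) warning(sprintf(...), call. = FALSE)

# round-half-up, used by the stratified splitter (base round() is banker's)
round_half_up <- function(x) floor(x + 0.5)

is_binary01 <- function(x) all(x %in% c(0, 1))

# predictor names recorded with a fitted model: NULL when the training
# matrix was unnamed (prediction is then positional), character(0) for a
# true intercept-only model
var_names <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) == 0) character(0) else colnames(x)
}

# largest-remainder apportionment of n into counts proportional to p
largest_remainder <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-8, all(p >= 0))
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    # ties broken by earlier position
    extra <- order(frac, seq_along(p), decreasing = c(TRUE, FALSE),
                   method = "radix")[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
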