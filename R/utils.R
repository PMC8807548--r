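#' @include AllClasses.R
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic per-stage seed derived from a master seed
#'
#' Fans one master seed out to independent stage seeds so that a single
#' `--seed` determines every stochastic stage of a run. The derivation is a
#' multiplicative byte hash of the stage name mod 2^31 - 1, so it is stable
#' across platforms and R versions.
#'
#' @param master integer master seed
#' @param stage character stage name
#' @return an integer in 1 .. 2^31 - 2
#' @export
stageSeed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stage))
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.double(master %% m)
  for (b in utf8ToInt(stage)) s <- (s * 31 + b) %% m
  as.integer(if (s < 1) 1 else s)
}

## Run code with R's RNG locally seeded, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## order-normalize an undirected pair table against a reference node order
canonical_pairs <- function(a, b, node_order = NULL) {
  if (is.null(node_order)) {
    swap <- a > b
  } else {
    ia <- match(a, node_order); ib <- match(b, node_order)
    swap <- ia > ib
  }
  list(src = ifelse(swap, b, a), dst = ifelse(swap, a, b))
}

assert_scalar_int <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x != round(x) || x < min)
    stop(sprintf("`%s` must be a single integer >= %s", name, min), call. = FALSE)
  as.integer(x)
}
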