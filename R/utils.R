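#' @keywords internal
"_PACKAGE"

#' @importFrom stats phyper binom.test hclust dist as.dist cor median pt
#'   rnorm runif sd setNames
#' @importFrom utils read.table write.table
NULL

## Internal validation helper: stop with a consistent error class so tests can
## distinguish validation errors from R-level failures.
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("cotarget_validation_error", "error")))
}

stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("cotarget_usage_error", "error")))
}

#' Derive independent child seeds from one master seed
#'
#' One master seed fans out to a fixed number of child seeds so that each
#' simulation component can be regenerated independently of the others.
#' The split is a draw of distinct integers under the master seed.
#'
#' @param seed Master seed (single integer).
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, n) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_usage("seed must be a single integer")
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

## Run `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}
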