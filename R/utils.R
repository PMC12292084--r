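# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded draws inside library code do
#' not perturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible substream seed below 2^31
#'
#' One RNG stream per logical block: blocks are keyed by name so adding a
#' block never perturbs the draws of another.
#' @noRd
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

stop_oncostage <- function(...) stop(..., call. = FALSE)

check_matrix_ids <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop_oncostage("matrix must carry gene rownames and cell colnames")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop_oncostage("gene and cell ids must be unique")
  invisible(m)
}
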