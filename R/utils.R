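#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's random state
#' afterwards, so no pipeline stage leaks into or reads the global RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Marker-ratio definitions: numerator/denominator ddPCR copy columns per trait.
# stromal = decidual reaction strength, unk = uNK expansion.
ratio_genes <- function() {
  list(
    stromal = c(num = "copies_pla2g2a", den = "copies_dio2"),
    unk     = c(num = "copies_itgad",   den = "copies_cd160")
  )
}

quartile_levels <- function() c("Q1", "Q2", "Q3", "Q4")

stop_endoscore <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "endoscore_error")))
}
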