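`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators stay pure in (spec, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Test whether strings are complete four-field EC numbers
#'
#' A complete EC number has exactly four numeric fields, e.g. `"1.1.1.1"`.
#' Partial identifiers such as `"1.1.1.-"` are incomplete.
#'
#' @param x character vector of putative EC numbers.
#' @return logical vector.
#' @export
#' @examples
#' is_complete_ec(c("1.1.1.1", "2.7.1.-", "3.5.1"))
is_complete_ec <- function(x) {
  grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$", x)
}
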