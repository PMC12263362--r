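# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so generators are deterministic without clobbering
#' the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# scalar predicate checks with a uniform error style
stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x > 0 && x < 1

#' Build a canonical variant key
#'
#' Keys have the form `chrom:pos:ref:alt` and identify one alternate allele
#' of one genomic position (1-based, VCF convention).
#'
#' @param chrom,pos,ref,alt vectors of equal length.
#' @return character vector of keys.
#' @keywords internal
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# superpopulation codes used throughout
SUPERPOPS <- c("AFR", "AMR", "EAS", "EUR", "SAS")
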