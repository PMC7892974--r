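## Small shared helpers.  Percentages and ratios throughout the package
## are printed with round-half-up (base round() is round-half-even).

#' Round half away from zero
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, with exact halves rounded up.
#' @examples
#' roundHalfUp(c(0.125, 1.545, 2.5), c(2, 2, 0))
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @noRd
.assertScalarNumeric <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single numeric value", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}

## Run code under a fixed RNG state, restoring the caller's stream.
#' @noRd
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' @noRd
.segmentLabels <- function() {
  c("five_prime_utr", "start_codon", "cds", "stop_codon", "three_prime_utr")
}
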