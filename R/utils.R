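#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a DNA string (A/C/G/T only, non-empty)
#' @noRd
check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop(what, " must be a single non-empty string", call. = FALSE)
  if (grepl("[^ACGT]", x))
    stop(what, " contains non-ACGT characters", call. = FALSE)
  invisible(x)
}

#' Reverse complement of a DNA character string
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Run code under a local RNG state seeded with `seed`
#'
#' Restores the caller's RNG state afterwards so generators do not perturb
#' the session stream.
#' @noRd
with_seed <- function(seed, code) {
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
  force(code)
}

#' Round to the nearest half-integer, ties away from zero
#' @noRd
round_half <- function(x) {
  sign(x) * floor(abs(x) * 2 + 0.5) / 2
}
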