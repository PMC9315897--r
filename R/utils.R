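# Internal helpers shared across modules.

# Diacritics seen in Spanish/Catalan clinical text, folded to ASCII base
# letters. Input must already be lower case.
.diacritic_from <- "áàäâãéèëêíìïîóòöôõúùüûñç"
.diacritic_to <- "aaaaaeeeeiiiiooooouuuunc"

#' Run code with a private RNG stream
#'
#' Saves the caller's RNG state, seeds a fresh stream, and restores the
#' state on exit, so generator functions are pure in their `seed` argument
#' and never disturb user-level randomness.
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' @noRd
tp_extdata <- function(...) {
  system.file("extdata", ..., package = "textpheno", mustWork = TRUE)
}

#' @noRd
read_lines_nocomment <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- x[!grepl("^\\s*#", x)]
  x[nzchar(trimws(x))]
}

#' Restricted Damerau-Levenshtein (optimal string alignment) distance
#'
#' Edit distance counting substitutions, insertions, deletions, and
#' transpositions of adjacent characters. Computed on the strings as given;
#' matching code always passes normalized (ASCII-folded) strings.
#'
#' @param a,b character vectors of equal length (or either of length 1).
#' @param cap optional non-negative cap; distances above it are reported as
#'   `cap + 1`, which allows early exit. `NULL` means exact distance.
#' @return integer vector of distances.
#' @examples
#' osa_distance("citalopram", "citalopran")
#' @export
osa_distance <- function(a, b, cap = NULL) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  osa_distance_cpp(a, b, if (is.null(cap)) -1L else as.integer(cap))
}
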