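#' Built-in substitution score matrices
#'
#' `builtin_matrix()` returns one of the two DNA substitution matrices that
#' recur throughout this package's examples: `"HoxD70"`, widely used for
#' inter-species genome alignment, and `"Simple"`, the +1 match / -1 mismatch
#' matrix.
#'
#' @param name `"HoxD70"` or `"Simple"`.
#' @return A numeric matrix with row and column names giving the alphabet
#'   (A, C, G, T), in score units.
#' @examples
#' builtin_matrix("Simple")
#' builtin_matrix("HoxD70")["A", "C"]
#' @export
builtin_matrix <- function(name = c("HoxD70", "Simple")) {
  name <- match.arg(name)
  dna <- c("A", "C", "G", "T")
  S <- switch(name,
    HoxD70 = matrix(c(
        91, -114,  -31, -123,
      -114,  100, -125,  -31,
       -31, -125,  100, -114,
      -123,  -31, -114,   91), 4, 4, byrow = TRUE),
    Simple = matrix(-1, 4, 4) + diag(2, 4))
  dimnames(S) <- list(dna, dna)
  S
}

#' Construct an alignment scoring scheme
#'
#' A scoring scheme is a substitution matrix plus affine gap scores and a
#' temperature.  A gap of length k scores `a + b * (k - 1)`: `a` is the score
#' of the first gapped letter and `b` of each further one.  (This differs from
#' the `a + b * k` convention used by some tools; to convert positive
#' open/extend costs, use `a = -(open + extend)` ... `a = -open` depending on
#' that tool's convention.  See [transform_scheme()] for score-preserving
#' transformations.)  The temperature `t` relates scores to probabilities via
#' prob(alignment) proportional to exp(score / t).
#'
#' @param S numeric substitution matrix, square, with identical row and
#'   column names giving the alphabet.  Rows index reference letters,
#'   columns query letters.
#' @param a_D,b_D deletion first/extension scores (reference letter over a
#'   gap).  `NA` for gapless schemes.
#' @param a_I,b_I insertion first/extension scores.
#' @param t temperature, in score units; must be positive.
#' @return An object of class `"score_scheme"`: a list with elements
#'   `alphabet`, `S`, `a_D`, `b_D`, `a_I`, `b_I`, `t`.
#' @examples
#' sch <- score_scheme(builtin_matrix("Simple"), a_D = -6, b_D = -1,
#'                     a_I = -6, b_I = -1, t = 1)
#' @export
score_scheme <- function(S, a_D = NA_real_, b_D = NA_real_,
                         a_I = NA_real_, b_I = NA_real_, t = 1) {
  if (!is.matrix(S) || nrow(S) != ncol(S))
    stop("S must be a square matrix")
  if (is.null(rownames(S)) || is.null(colnames(S)))
    stop("S must have row and column names giving the alphabet")
  if (!identical(rownames(S), colnames(S)))
    stop("row and column names of S must agree")
  if (anyDuplicated(rownames(S)))
    stop("alphabet letters must be distinct")
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t <= 0)
    stop("t must be a positive finite number")
  obj <- list(alphabet = rownames(S), S = S,
              a_D = as.numeric(a_D), b_D = as.numeric(b_D),
              a_I = as.numeric(a_I), b_I = as.numeric(b_I),
              t = as.numeric(t))
  class(obj) <- "score_scheme"
  obj
}

#' @export
print.score_scheme <- function(x, ...) {
  cat("Alignment scoring scheme (", length(x$alphabet), "-letter alphabet)\n",
      sep = "")
  print(x$S)
  if (has_gaps(x))
    cat("gaps: a_D=", x$a_D, " b_D=", x$b_D,
        " a_I=", x$a_I, " b_I=", x$b_I, "\n", sep = "")
  else cat("gapless\n")
  cat("temperature t =", x$t, "\n")
  invisible(x)
}

has_gaps <- function(scheme) {
  !any(is.na(c(scheme$a_D, scheme$b_D, scheme$a_I, scheme$b_I)))
}

#' Map sequence letters to alphabet indices
#'
#' Letters are upper-cased before lookup; any letter outside the alphabet is
#' an error naming the first offending position.
#'
#' @param x a single character string, or a character vector of single
#'   letters.
#' @param alphabet character vector of alphabet letters (order defines the
#'   matrix indexing).
#' @return integer vector of 1-based indices into `alphabet`.
#' @keywords internal
seq_to_idx <- function(x, alphabet) {
  if (length(x) == 1L && nchar(x[1L]) != 1L)
    x <- strsplit(x, "", fixed = TRUE)[[1L]]
  if (length(x) == 0L) return(integer(0))
  idx <- match(toupper(x), toupper(alphabet))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("letter '%s' at position %d is not in the alphabet [%s]",
                 x[bad], bad, paste(alphabet, collapse = "")))
  }
  idx
}

#' Score-preserving transformations of a scoring scheme
#'
#' Three transformations of score parameters leave optimal alignments
#' unchanged.  Scaling all scores by a positive constant k (together with t,
#' so that S/t is unchanged) never affects any alignment.  Adding a constant
#' h to every substitution score and to both deletion scores (`shift_ref`)
#' adds exactly h * m to every global alignment score of an m-letter
#' reference, so global optima are unchanged; `shift_query` is the symmetric
#' operation on insertion scores (adding h * n).  The shifts can be used to
#' set the gap extension scores to zero.
#'
#' @param scheme a [score_scheme()].
#' @param mode one of `"scale"`, `"shift_ref"`, `"shift_query"`.
#' @param value the constant k (positive) or h.
#' @return The transformed `score_scheme`.
#' @export
transform_scheme <- function(scheme,
                             mode = c("scale", "shift_ref", "shift_query"),
                             value) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  out <- scheme
  if (mode == "scale") {
    if (value <= 0) stop("scale factor must be positive")
    out$S <- scheme$S * value
    out$a_D <- scheme$a_D * value; out$b_D <- scheme$b_D * value
    out$a_I <- scheme$a_I * value; out$b_I <- scheme$b_I * value
    out$t <- scheme$t * value
  } else if (mode == "shift_ref") {
    out$S <- scheme$S + value
    out$a_D <- scheme$a_D + value
    out$b_D <- scheme$b_D + value
  } else {
    out$S <- scheme$S + value
    out$a_I <- scheme$a_I + value
    out$b_I <- scheme$b_I + value
  }
  out
}

#' Validate a letter-probability vector
#' @keywords internal
check_letter_probs <- function(p, alphabet, what = "letter probabilities") {
  if (length(p) != length(alphabet))
    stop(what, " must have one entry per alphabet letter")
  if (any(p < 0)) stop(what, " must be non-negative")
  if (abs(sum(p) - 1) > 1e-12) stop(what, " must sum to 1")
  p
}
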