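#' The 20-letter amino-acid alphabet
#'
#' Canonical one-letter codes, in the fixed order used by all frequency
#' tables and profile matrices in this package. `X` is accepted in input
#' sequences as an unknown residue: it never contributes to residue counts
#' and scores 0 bits against any profile column.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Background amino-acid frequencies
#'
#' Background distribution used for log-odds profiles and Jensen-Shannon
#' conservation scoring. `"uniform"` (the default everywhere) assigns 1/20
#' to each residue; `"blosum62"` uses the marginal residue frequencies of
#' the BLOSUM62 substitution data, the customary database background for
#' conservation scoring when one is wanted.
#'
#' @param name `"uniform"` or `"blosum62"`.
#' @return Named numeric vector over [aa_alphabet()], summing to 1.
#' @export
aa_background <- function(name = c("uniform", "blosum62")) {
  name <- match.arg(name)
  aa <- aa_alphabet()
  if (name == "uniform") {
    return(setNames(rep(1 / 20, 20), aa))
  }
  bg <- c(A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025,
          Q = 0.034, E = 0.054, G = 0.074, H = 0.026, I = 0.068,
          L = 0.099, K = 0.058, M = 0.025, F = 0.047, P = 0.039,
          S = 0.057, T = 0.051, W = 0.013, Y = 0.032, V = 0.073)
  bg[aa] / sum(bg)
}

#' Inclusive span length
#'
#' Length of a 1-based inclusive residue span, the coordinate convention
#' used throughout: a span written "positions 280-310" covers 31 residues.
#'
#' @param start,end Residue numbers, `end >= start`.
#' @return Integer count `end - start + 1`.
#' @examples
#' span_length(280, 310)  # 31
#' @export
span_length <- function(start, end) {
  if (any(end < start)) {
    stop("span_length(): end (", end, ") must be >= start (", start, ")")
  }
  as.integer(end - start + 1)
}

# internal: validate a probability vector over the 20-aa alphabet
check_distribution <- function(p, what = "distribution", tol = 1e-9) {
  if (!is.numeric(p) || length(p) != 20L) {
    stop(what, " must be a numeric vector of length 20")
  }
  if (any(p < -tol) || abs(sum(p) - 1) > tol) {
    stop(what, " must be non-negative and sum to 1 (sum = ", sum(p), ")")
  }
  invisible(p)
}
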