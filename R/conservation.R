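# Per-column conservation scoring of a match alignment: Jensen-Shannon
# divergence against a background distribution (gap-penalized and window
# smoothed) and sequence-logo information content in bits.

#' Residue distribution of one alignment column
#'
#' Frequencies over the 20 amino acids among the column's non-gap, non-X
#' occupancies. `X` (unknown residue) counts toward the gap fraction, never
#' toward a residue. Optional per-row weights are renormalized over the
#' contributing rows.
#'
#' @param column Character vector of column symbols (`-` = gap).
#' @param weights Optional non-negative per-row weights.
#' @return List with `p` (named frequency vector over [aa_alphabet()], all
#'   `NA` for an all-gap column), `gap_fraction`, `n_obs` (non-gap, non-X
#'   row count), and `all_gap` flag.
#' @export
column_distribution <- function(column, weights = NULL) {
  aa <- aa_alphabet()
  n <- length(column)
  if (n < 1L) stop("column_distribution(): empty column")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  keep <- column %in% aa
  gap_fraction <- sum(!keep) / n
  n_obs <- sum(keep)
  if (n_obs == 0L) {
    return(list(p = setNames(rep(NA_real_, 20), aa), gap_fraction = 1,
                n_obs = 0L, all_gap = TRUE))
  }
  w <- weights[keep]
  if (sum(w) == 0) w <- rep(1, length(w))
  counts <- vapply(aa, function(a) sum(w[column[keep] == a]), numeric(1))
  list(p = counts / sum(counts), gap_fraction = gap_fraction,
       n_obs = as.integer(n_obs), all_gap = FALSE)
}

#' Jensen-Shannon divergence between a column distribution and background
#'
#' `lambda * KL(p || m) + (1 - lambda) * KL(q || m)` with
#' `m = lambda * p + (1 - lambda) * q`, logarithms base 2. At the default
#' `lambda = 1/2` the score is symmetric and bounded in `[0, 1]`; higher
#' values mean the column deviates more from background, i.e. is more
#' conserved.
#'
#' @param p Column residue distribution (length 20, sums to 1).
#' @param q Background distribution (length 20, sums to 1).
#' @param lambda Mixture weight in `(0, 1)`.
#' @return JSD in bits, in `[0, 1]` for `lambda = 1/2`.
#' @export
jsd_score <- function(p, q, lambda = 0.5) {
  check_distribution(p, "jsd_score() p")
  check_distribution(q, "jsd_score() q")
  if (lambda <= 0 || lambda >= 1) stop("jsd_score(): lambda must be in (0,1)")
  m <- lambda * p + (1 - lambda) * q
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  lambda * kl(p, m) + (1 - lambda) * kl(q, m)
}

#' Penalize a conservation score for column gappiness
#'
#' Multiplies a score by `1 - gap_fraction`, so heavily gapped columns
#' cannot rank as conserved however skewed their few residues are.
#'
#' @param score Conservation score.
#' @param gap_fraction Fraction of gap/X rows in `[0, 1]`.
#' @return Penalized score.
#' @export
gap_penalize <- function(score, gap_fraction) {
  stopifnot(all(gap_fraction >= 0 & gap_fraction <= 1))
  score * (1 - gap_fraction)
}

#' Window-smooth a per-column score track
#'
#' Blends each column's score with its flanking columns:
#' `s'_i = (1 - window_lambda) * s_i + window_lambda * f_i`, where `f_i`
#' aggregates the up-to-`2w` flanking scores (`w` on each side, self
#' excluded). With `pad = "zero"` (default) the flanking sum is always
#' divided by `2w`, so columns near the track ends — which lack part of
#' their window — are pulled toward zero; with `pad = "truncate"` the sum
#' is divided by the number of in-bounds flanking columns, making constant
#' tracks exact fixed points everywhere.
#'
#' @param scores Numeric score track.
#' @param w Window radius in columns (>= 0); `w = 0` returns the input.
#' @param window_lambda Blend weight in `[0, 1]`; 0 returns the input.
#' @param pad `"zero"` or `"truncate"` (see above).
#' @return Smoothed track, same length.
#' @export
window_smooth <- function(scores, w = 3L, window_lambda = 0.5,
                          pad = c("zero", "truncate")) {
  pad <- match.arg(pad)
  stopifnot(w >= 0, window_lambda >= 0, window_lambda <= 1)
  n <- length(scores)
  if (w == 0L || window_lambda == 0 || n == 0L) return(scores)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- setdiff(max(1L, i - w):min(n, i + w), i)
    denom <- if (pad == "zero") 2 * w else length(j)
    flank <- if (length(j) > 0L) sum(scores[j]) / denom else 0
    out[i] <- (1 - window_lambda) * scores[i] + window_lambda * flank
  }
  out
}

#' Sequence-logo information content of a column
#'
#' `log2(20) - H(p)` in bits, where `H` is the Shannon entropy of the
#' column's residue distribution; optionally reduced by the small-sample
#' correction `19 / (2 * ln(2) * n_obs)` used in logo rendering. Floored
#' at 0.
#'
#' @param p Column residue distribution (length 20).
#' @param n_obs Number of observed residues in the column (>= 1).
#' @param correct_small_sample Apply the small-sample correction?
#' @return Information content in bits, in `[0, log2(20)]`.
#' @export
information_content <- function(p, n_obs = NULL, correct_small_sample = FALSE) {
  check_distribution(p, "information_content() p")
  i <- p > 0
  H <- -sum(p[i] * log2(p[i]))
  e_n <- 0
  if (correct_small_sample) {
    if (is.null(n_obs) || n_obs < 1) {
      stop("information_content(): n_obs >= 1 required for the correction")
    }
    e_n <- 19 / (2 * log(2) * n_obs)
  }
  max(0, log2(20) - H - e_n)
}

#' Henikoff position-based sequence weights
#'
#' Classic position-based weights: each residue occupancy contributes
#' `1 / (r * s)` to its sequence, where `r` is the number of distinct
#' residues in the column and `s` the multiplicity of the observed one.
#' Weights are normalized to mean 1.
#'
#' @param a A [match_alignment()].
#' @return Numeric weights, one per row.
#' @export
henikoff_weights <- function(a) {
  n <- nrow(a$match)
  w <- numeric(n)
  aa <- aa_alphabet()
  for (c in seq_len(ncol(a$match))) {
    col <- a$match[, c]
    keep <- col %in% aa
    if (!any(keep)) next
    tab <- table(col[keep])
    r <- length(tab)
    w[keep] <- w[keep] + 1 / (r * as.numeric(tab[col[keep]]))
  }
  if (sum(w) == 0) rep(1, n) else w / mean(w)
}

#' Score per-column conservation of an alignment
#'
#' Computes, for every match column: the residue distribution and gap
#' fraction, the raw Jensen-Shannon conservation score against `background`,
#' its gap-penalized form, a window-smoothed track of the penalized scores,
#' sequence-logo information content in bits, and the consensus residue with
#' its identity fraction (gaps included in the denominator, as in
#' [residue_identity()]). All-gap columns are flagged and score 0.
#'
#' Defaults follow the common conventions of this scoring method:
#' `lambda = 1/2`, window radius `w = 3` with blend weight `1/2`,
#' multiplicative gap penalty, uniform background, and no small-sample
#' correction of the bits track.
#'
#' @param a A [match_alignment()].
#' @param background Background distribution (see [aa_background()]).
#' @param lambda JSD mixture weight.
#' @param w,window_lambda Smoothing parameters, see [window_smooth()].
#' @param weights `NULL`, `"henikoff"`, or a numeric per-row weight vector.
#' @param correct_small_sample Apply the logo small-sample correction to
#'   the bits track?
#' @return Object of class `conservation_profile`: list with `track` (a
#'   per-column `data.frame`), `p` (20 x M frequency matrix), `background`,
#'   and `params`.
#' @export
conservation_profile <- function(a, background = aa_background("uniform"),
                                 lambda = 0.5, w = 3L, window_lambda = 0.5,
                                 weights = NULL,
                                 correct_small_sample = FALSE) {
  check_distribution(background, "background")
  wts <- if (is.null(weights)) NULL
         else if (identical(weights, "henikoff")) henikoff_weights(a)
         else weights
  M <- ncol(a$match)
  aa <- aa_alphabet()
  P <- matrix(NA_real_, 20L, M, dimnames = list(aa, NULL))
  gap_fraction <- numeric(M); n_obs <- integer(M); all_gap <- logical(M)
  jsd_raw <- numeric(M); bits <- numeric(M)
  consensus <- character(M); consensus_identity <- numeric(M)
  n <- nrow(a$match)
  for (c in seq_len(M)) {
    cd <- column_distribution(a$match[, c], wts)
    gap_fraction[c] <- cd$gap_fraction
    n_obs[c] <- cd$n_obs
    all_gap[c] <- cd$all_gap
    if (cd$all_gap) {
      jsd_raw[c] <- 0; bits[c] <- 0
      consensus[c] <- NA_character_; consensus_identity[c] <- 0
      next
    }
    P[, c] <- cd$p
    jsd_raw[c] <- jsd_score(cd$p, background, lambda)
    bits[c] <- information_content(cd$p, cd$n_obs, correct_small_sample)
    best <- which.max(cd$p)
    consensus[c] <- aa[best]
    consensus_identity[c] <- sum(a$match[, c] == aa[best]) / n
  }
  jsd_penalized <- gap_penalize(jsd_raw, gap_fraction)
  jsd_smoothed <- window_smooth(jsd_penalized, w, window_lambda)
  track <- data.frame(column = seq_len(M), gap_fraction = gap_fraction,
                      n_obs = n_obs, all_gap = all_gap, jsd_raw = jsd_raw,
                      jsd_penalized = jsd_penalized,
                      jsd_smoothed = jsd_smoothed, bits = bits,
                      consensus = consensus,
                      consensus_identity = consensus_identity,
                      stringsAsFactors = FALSE)
  structure(list(track = track, p = P, background = background,
                 params = list(lambda = lambda, w = w,
                               window_lambda = window_lambda,
                               weights = if (is.null(weights)) "none"
                                         else if (identical(weights, "henikoff"))
                                           "henikoff" else "user",
                               correct_small_sample = correct_small_sample)),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation_profile> %d columns; mean JSD %.3f, mean bits %.2f\n",
              nrow(x$track), mean(x$track$jsd_penalized), mean(x$track$bits)))
  invisible(x)
}

#' Call conserved columns by information content
#'
#' Columns whose information content lies strictly above the threshold —
#' the "bits over 2" rule used to nominate residues for alanine scanning.
#'
#' @param cp A [conservation_profile()].
#' @param bits_threshold Threshold in bits (default 2).
#' @return Ordered integer vector of conserved column indices.
#' @export
call_conserved <- function(cp, bits_threshold = 2) {
  stopifnot(bits_threshold >= 0)
  which(cp$track$bits > bits_threshold)
}

#' Numeric sequence-logo letter heights
#'
#' `height(a, c) = p_c(a) * bits(c)`: per column, letter heights that sum to
#' the column's information content, i.e. the numbers a logo renderer would
#' draw.
#'
#' @param cp A [conservation_profile()].
#' @return 20 x M numeric matrix (rows = [aa_alphabet()]).
#' @export
logo_matrix <- function(cp) {
  H <- sweep(cp$p, 2, cp$track$bits, `*`)
  H[is.na(H)] <- 0
  H
}

#' Percent identity of a residue at a column
#'
#' Share of alignment rows carrying exactly `residue` at `column`, as a
#' percentage of all rows (gaps and X count in the denominator).
#'
#' @param a A [match_alignment()].
#' @param column Match column index.
#' @param residue One-letter amino-acid code.
#' @return Percentage in `[0, 100]`.
#' @export
residue_identity <- function(a, column, residue) {
  if (column < 1L || column > ncol(a$match)) {
    stop("residue_identity(): column ", column, " outside alignment")
  }
  if (!residue %in% aa_alphabet()) {
    stop("residue_identity(): unknown residue symbol '", residue, "'")
  }
  100 * sum(a$match[, column] == residue) / nrow(a$match)
}

#' Export the conservation track as TSV
#' @param cp A [conservation_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation_track <- function(cp, path) {
  write.table(cp$track, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export the logo matrix as TSV (columns x 20)
#' @param cp A [conservation_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_logo_matrix <- function(cp, path) {
  H <- t(logo_matrix(cp))
  df <- data.frame(column = seq_len(nrow(H)), H, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
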