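# Position-specific profile construction from a seed alignment, and
# affine-gap alignment of candidate sequences against it — the desk-scale
# counterpart of a profile-HMM aligner for assigning match columns.

#' Build a log-odds profile from a seed alignment
#'
#' Per match column, residue frequencies are estimated from the seed with a
#' background-proportional pseudocount:
#' `freq = (counts + pseudocount_weight * background) / (n_eff + pseudocount_weight)`,
#' where `n_eff` is the (weighted) number of observed residues; gaps and X
#' contribute nothing. Scores are `log2(freq / background)` in bits, finite
#' for every residue whenever `pseudocount_weight > 0`.
#'
#' @param seed A [match_alignment()] with at least 2 rows.
#' @param pseudocount_weight Positive pseudocount mass.
#' @param background Background distribution (see [aa_background()]).
#' @param gap_open,gap_extend Affine gap penalties in bits (non-negative);
#'   one penalty set is shared by insertions and deletions. A gap of length
#'   `k` costs `gap_open + (k - 1) * gap_extend`.
#' @param weights `NULL` (each row counts 1), `"henikoff"` for
#'   position-based sequence weights, or a numeric per-row vector.
#' @return Object of class `profile`: list with `log_odds` and `freq`
#'   (20 x M matrices), `background`, `pseudocount_weight`, `gap_open`,
#'   `gap_extend`.
#' @export
build_profile <- function(seed, pseudocount_weight = 1,
                          background = aa_background("uniform"),
                          gap_open = 4, gap_extend = 0.25, weights = NULL) {
  if (!inherits(seed, "match_alignment") || nrow(seed$match) < 2L) {
    stop("build_profile(): seed must be a match_alignment with >= 2 rows")
  }
  if (pseudocount_weight <= 0) {
    stop("build_profile(): pseudocount_weight must be > 0")
  }
  stopifnot(gap_open >= 0, gap_extend >= 0)
  check_distribution(background, "background")
  wts <- if (is.null(weights)) rep(1, nrow(seed$match))
         else if (identical(weights, "henikoff")) henikoff_weights(seed)
         else weights
  aa <- aa_alphabet()
  M <- ncol(seed$match)
  freq <- matrix(NA_real_, 20L, M, dimnames = list(aa, NULL))
  for (c in seq_len(M)) {
    col <- seed$match[, c]
    keep <- col %in% aa
    counts <- vapply(aa, function(a) sum(wts[keep][col[keep] == a]),
                     numeric(1))
    n_eff <- sum(counts)
    freq[, c] <- (counts + pseudocount_weight * background) /
      (n_eff + pseudocount_weight)
  }
  structure(list(log_odds = log2(sweep(freq, 1, background, `/`)),
                 freq = freq, background = background,
                 pseudocount_weight = pseudocount_weight,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "profile")
}

#' @export
print.profile <- function(x, ...) {
  cat(sprintf("<profile> %d columns; gap_open = %g, gap_extend = %g bits\n",
              ncol(x$log_odds), x$gap_open, x$gap_extend))
  invisible(x)
}

#' Align one sequence to a profile
#'
#' Global-in-profile, global-in-sequence dynamic program maximizing the bit
#' score: match steps add the column's log-odds for the residue (0 for X),
#' insert steps emit at background (0 bits), and gaps pay the profile's
#' affine penalties, shared between insertions and deletions. Ties are
#' broken deterministically with preference match > delete > insert.
#'
#' @param p A [build_profile()] result.
#' @param s A [domain_sequence()] (or a plain residue string).
#' @return Object of class `alignment_path`: list with `states` (character
#'   vector over `M`/`I`/`D`; `M`+`I` steps consume the sequence, `M`+`D`
#'   steps consume the profile) and `bit_score`.
#' @export
align_to_profile <- function(p, s) {
  residues <- if (inherits(s, "domain_sequence")) s$residues else s
  if (!is.character(residues) || nchar(residues) == 0L) {
    stop("align_to_profile(): sequence must be non-empty")
  }
  chars <- strsplit(residues, "")[[1]]
  codes <- match(chars, aa_alphabet()) - 1L
  codes[is.na(codes)] <- -1L                   # X and unknowns score 0
  res <- .align_dp(p$log_odds, codes, p$gap_open, p$gap_extend)
  states <- strsplit(res$states, "")[[1]]
  stopifnot(sum(states != "D") == length(chars),
            sum(states != "I") == ncol(p$log_odds))
  structure(list(states = states, bit_score = res$score),
            class = "alignment_path")
}

#' @export
print.alignment_path <- function(x, ...) {
  cat(sprintf("<alignment_path> %d steps, %.2f bits\n",
              length(x$states), x$bit_score))
  invisible(x)
}

#' Align a set of sequences into a match alignment
#'
#' Runs [align_to_profile()] on each sequence and assembles the emitted
#' paths into a [match_alignment()] over the profile's columns: match steps
#' fill the column, delete steps leave `-`, insert steps become insert runs
#' anchored after the most recent match column.
#'
#' @param p A [build_profile()] result.
#' @param sequences List of [domain_sequence()] (or named character vector).
#' @return List with `alignment` (a `match_alignment`) and `scores`
#'   (named numeric bit scores).
#' @export
align_family <- function(p, sequences) {
  if (is.character(sequences)) {
    ids <- names(sequences)
    sequences <- lapply(seq_along(sequences), function(i) {
      domain_sequence(ids[i], sequences[[i]])
    })
  }
  ids <- vapply(sequences, function(s) s$id, character(1))
  M <- ncol(p$log_odds)
  n <- length(sequences)
  match_mat <- matrix("-", n, M)
  ins_row <- integer(0); ins_after <- integer(0); ins_res <- character(0)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    path <- align_to_profile(p, sequences[[i]])
    scores[i] <- path$bit_score
    chars <- strsplit(sequences[[i]]$residues, "")[[1]]
    ri <- 0L; cj <- 0L
    pending <- character(0)
    flush <- function() {
      if (length(pending) > 0L) {
        ins_row <<- c(ins_row, i)
        ins_after <<- c(ins_after, cj)
        ins_res <<- c(ins_res, paste(pending, collapse = ""))
        pending <<- character(0)
      }
    }
    for (st in path$states) {
      if (st == "M") {
        flush()
        ri <- ri + 1L; cj <- cj + 1L
        match_mat[i, cj] <- chars[ri]
      } else if (st == "D") {
        flush()
        cj <- cj + 1L
      } else {
        ri <- ri + 1L
        pending <- c(pending, chars[ri])
      }
    }
    flush()
  }
  aln <- match_alignment(match_mat, ids,
                         data.frame(row = ins_row, after_col = ins_after,
                                    residues = ins_res,
                                    count = nchar(ins_res),
                                    stringsAsFactors = FALSE))
  list(alignment = aln, scores = setNames(scores, ids))
}

#' Filter candidate sequences by profile bit score
#'
#' Retains candidates whose [align_to_profile()] bit score reaches
#' `min_bits`, preserving input order — the package's stand-in for an
#' E-value homology screen, which requires score statistics calibrated on a
#' sequence database and is out of scope here.
#'
#' @param p A [build_profile()] result.
#' @param candidates List of [domain_sequence()].
#' @param min_bits Score threshold in bits (finite, or `-Inf` to keep all).
#' @return List with `sequences` (retained candidates) and `scores` (named
#'   bit scores of the retained candidates).
#' @export
score_filter <- function(p, candidates, min_bits) {
  scores <- vapply(candidates, function(s) align_to_profile(p, s)$bit_score,
                   numeric(1))
  ids <- vapply(candidates, function(s) s$id, character(1))
  keep <- scores >= min_bits
  list(sequences = candidates[keep], scores = setNames(scores[keep], ids[keep]))
}

#' Serialize a profile to JSON
#' @param p A `profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(p, path) {
  jsonlite::write_json(
    list(alphabet = aa_alphabet(),
         log_odds = unname(as.data.frame(t(p$log_odds))),
         background = as.list(p$background),
         pseudocount_weight = p$pseudocount_weight,
         gap_open = p$gap_open, gap_extend = p$gap_extend),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
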