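# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's own code paths: KL sums are written as explicit loops, and
# alignment scores come from exhaustive path enumeration.

# --- tiny hand alignments ---------------------------------------------------

# 2-row Stockholm with RF "xx.x": rows "AC.D" / "AGgD" -> 3 match columns,
# row 2 carries one insert residue between match columns 2 and 3
write_toy_stockholm <- function(path) {
  writeLines(c("# STOCKHOLM 1.0",
               "row1    AC.D",
               "row2    AGgD",
               "#=GC RF xx.x",
               "//"), path)
  path
}

toy_match_alignment <- function() {
  match_alignment(rbind(c("A", "C", "D"), c("A", "G", "D")),
                  ids = c("row1", "row2"),
                  inserts = data.frame(row = 2L, after_col = 2L,
                                       residues = "G", count = 1L))
}

# small planted family used across modules; low n keeps tests fast
small_family <- function(n = 60, seed = 11) {
  sample_family(family_spec(n_sequences = n, seed = seed))
}

# --- independent JSD oracle -------------------------------------------------

# double-loop KL evaluation, independent of jsd_score()'s vectorized form
jsd_oracle <- function(p, q, lambda = 0.5) {
  m <- numeric(20)
  for (i in 1:20) m[i] <- lambda * p[i] + (1 - lambda) * q[i]
  kl_pm <- 0
  kl_qm <- 0
  for (i in 1:20) {
    if (p[i] > 0) kl_pm <- kl_pm + p[i] * log(p[i] / m[i], base = 2)
    if (q[i] > 0) kl_qm <- kl_qm + q[i] * log(q[i] / m[i], base = 2)
  }
  lambda * kl_pm + (1 - lambda) * kl_qm
}

random_distribution <- function() {
  x <- stats::rexp(20)
  x / sum(x)
}

# --- exhaustive alignment-path oracle ---------------------------------------

# enumerate every global path over states M/D/I consuming `n` residues and
# `M` columns; affine score: each maximal run of D or I costs
# open + (len - 1) * ext; M steps add the column log-odds of the consumed
# residue (X scores 0). Returns the best score.
enumerate_best_score <- function(log_odds, codes, open, ext) {
  M <- ncol(log_odds)
  n <- length(codes)
  best <- -Inf
  recurse <- function(i, j, prev, score) {
    if (i == n && j == M) {
      if (score > best) best <<- score
      return(invisible())
    }
    if (i < n && j < M) {   # match
      emit <- if (codes[i + 1] < 0) 0 else log_odds[codes[i + 1] + 1, j + 1]
      recurse(i + 1, j + 1, "M", score + emit)
    }
    if (j < M) {            # delete
      cost <- if (identical(prev, "D")) ext else open
      recurse(i, j + 1, "D", score - cost)
    }
    if (i < n) {            # insert
      cost <- if (identical(prev, "I")) ext else open
      recurse(i + 1, j, "I", score - cost)
    }
  }
  recurse(0, 0, "S", 0)
  as.numeric(best)
}

# residue string -> 0-based codes (-1 for X), mirroring the package encoding
encode_residues <- function(s) {
  codes <- match(strsplit(s, "")[[1]], aa_alphabet()) - 1L
  codes[is.na(codes)] <- -1L
  codes
}

# random profile for DP-vs-enumeration checks
random_profile <- function(M, open = 4, ext = 0.25) {
  seed_rows <- replicate(3, paste(sample(aa_alphabet(), M, replace = TRUE),
                                  collapse = ""))
  seed <- match_alignment(do.call(rbind, strsplit(seed_rows, "")),
                          ids = paste0("s", 1:3))
  build_profile(seed, gap_open = open, gap_extend = ext)
}

# --- structure fixtures -----------------------------------------------------

# synthetic two-residue complex: GLY N (chain A) and SER OG (chain B) placed
# exactly 3.50 Angstrom apart; the carbons sit behind each residue so the
# N-OG pair is the minimum over every atom pair, polar or not
write_contact_fixture <- function(path) {
  writeLines(c(
    "ATOM      1  N   GLY A 240      10.000  10.000  10.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A 240       8.550  10.100  10.000  1.00  0.00           C",
    "ATOM      3  C   GLY A 240       7.800  11.200  10.100  1.00  0.00           C",
    "ATOM      4  OG  SER B 110      13.500  10.000  10.000  1.00  0.00           O",
    "ATOM      5  CB  SER B 110      14.900  10.300  10.100  1.00  0.00           C",
    "ATOM      6  CA  SER B 110      16.200  10.500  10.200  1.00  0.00           C",
    "END"), path)
  path
}
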