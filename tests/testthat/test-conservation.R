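test_that("column distributions handle gaps, X and weights", {
  cd <- column_distribution(c("G", "G", "A", "-"))
  expect_equal(unname(cd$p["G"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(cd$p["A"]), 1 / 3, tolerance = 1e-12)
  expect_equal(cd$gap_fraction, 1 / 4)
  expect_identical(cd$n_obs, 3L)
  # X counts as a gap, never as a residue
  cdx <- column_distribution(c("G", "X", "A", "-"))
  expect_equal(cdx$gap_fraction, 1 / 2)
  expect_identical(cdx$n_obs, 2L)
  # all-gap columns are flagged
  cdg <- column_distribution(c("-", "-", "X"))
  expect_true(cdg$all_gap)
  expect_equal(cdg$gap_fraction, 1)
  expect_true(all(is.na(cdg$p)))
  # weighted counts: weights (2, 1, 1, 0) on {G, G, A, -} give p(G) = 3/4
  cdw <- column_distribution(c("G", "G", "A", "-"), weights = c(2, 1, 1, 0))
  expect_equal(unname(cdw$p["G"]), 3 / 4, tolerance = 1e-12)
})

test_that("jsd_score matches an independent double-loop KL oracle", {
  q <- aa_background("uniform")
  # identical distributions diverge by zero
  expect_equal(jsd_score(q, q), 0, tolerance = 1e-15)
  # point mass vs uniform: frozen value from the closed-form summation
  p <- setNames(c(1, rep(0, 19)), aa_alphabet())
  expect_equal(jsd_score(p, q), 0.854997400485, tolerance = 1e-10)
  # 1000 random pairs against the oracle, and symmetry at lambda = 1/2
  set.seed(101)
  for (i in 1:1000) {
    a <- random_distribution()
    b <- random_distribution()
    expect_equal(jsd_score(a, b), jsd_oracle(a, b), tolerance = 1e-12)
    expect_equal(jsd_score(a, b), jsd_score(b, a), tolerance = 1e-12)
    expect_gte(jsd_score(a, b), 0)
    expect_lte(jsd_score(a, b), 1)
  }
  expect_error(jsd_score(p * 2, q), "sum to 1")
  expect_error(jsd_score(p, q, lambda = 1), "lambda")
})

test_that("gap penalty is multiplicative and range-preserving", {
  expect_equal(gap_penalize(0.8, 0), 0.8)
  expect_equal(gap_penalize(0.8, 1), 0)
  expect_equal(gap_penalize(0.855, 0.25), 0.64125, tolerance = 1e-12)
  set.seed(5)
  s <- runif(50)
  g <- runif(50)
  out <- gap_penalize(s, g)
  expect_true(all(out >= 0 & out <= 1))
  expect_true(all(out <= s))
})

test_that("window smoothing reproduces the hand-computed cases", {
  # w = 1, lambda_w = 1/2 on [0, 1, 0]: flanking sums divided by 2w
  expect_equal(window_smooth(c(0, 1, 0), w = 1, window_lambda = 0.5),
               c(0.25, 0.5, 0.25), tolerance = 1e-12)
  # lambda_w = 0 is the identity
  s <- c(0.2, 0.9, 0.4, 0.7)
  expect_identical(window_smooth(s, w = 3, window_lambda = 0), s)
  expect_identical(window_smooth(s, w = 0, window_lambda = 0.5), s)
  # constant tracks: exact fixed point in the interior under the default,
  # and everywhere under truncated averaging
  const <- rep(0.6, 20)
  sm <- window_smooth(const, w = 3, window_lambda = 0.5)
  expect_equal(sm[4:17], const[4:17], tolerance = 1e-12)
  expect_equal(window_smooth(const, w = 3, window_lambda = 0.5,
                             pad = "truncate"),
               const, tolerance = 1e-12)
  # range preservation
  set.seed(6)
  x <- runif(30)
  out <- window_smooth(x, w = 3, window_lambda = 0.5)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("information content hits the logo closed forms", {
  aa <- aa_alphabet()
  point <- setNames(c(1, rep(0, 19)), aa)
  expect_equal(information_content(point), log2(20), tolerance = 1e-12)
  unif <- setNames(rep(1 / 20, 20), aa)
  expect_equal(information_content(unif), 0, tolerance = 1e-12)
  two <- setNames(c(0.5, 0.5, rep(0, 18)), aa)
  expect_equal(information_content(two), log2(20) - 1, tolerance = 1e-12)
  # small-sample correction subtracts 19 / (2 ln 2 n) and floors at zero
  expect_equal(information_content(point, n_obs = 100,
                                   correct_small_sample = TRUE),
               log2(20) - 19 / (2 * log(2) * 100), tolerance = 1e-12)
  expect_equal(information_content(unif, n_obs = 5,
                                   correct_small_sample = TRUE), 0)
})

test_that("bits and JSD rank point-mass mixtures concordantly", {
  q <- aa_background("uniform")
  alphas <- seq(0.1, 1, by = 0.05)
  jsd <- bits <- numeric(length(alphas))
  for (i in seq_along(alphas)) {
    p <- alphas[i] * c(1, rep(0, 19)) + (1 - alphas[i]) * rep(1 / 20, 20)
    p <- setNames(p, aa_alphabet())
    jsd[i] <- jsd_score(p, q)
    bits[i] <- information_content(p)
  }
  expect_true(all(diff(jsd) > 0))
  expect_true(all(diff(bits) > 0))
})

test_that("conserved-column calls respect the bits threshold", {
  # flat alignment: each column carries all 20 residues once -> 0 bits
  aa <- aa_alphabet()
  flat <- match_alignment(matrix(rep(aa, 10), 20, 10),
                          ids = sprintf("s%02d", 1:20))
  cp_flat <- conservation_profile(flat)
  expect_length(call_conserved(cp_flat, 2), 0L)
  # planted family: invariant sites are always called at n >= 100
  fam <- sample_family(family_spec(n_sequences = 120, seed = 41))
  cp <- conservation_profile(fam$truth$alignment)
  called <- call_conserved(cp, 2)
  expect_true(all(fam$truth$identity$column %in% called))
  # threshold above the maximum yields nothing
  expect_length(call_conserved(cp, log2(20)), 0L)
})

test_that("logo letter heights sum to the column information content", {
  fam <- small_family(n = 30, seed = 43)
  cp <- conservation_profile(fam$truth$alignment)
  H <- logo_matrix(cp)
  expect_equal(unname(colSums(H)), cp$track$bits, tolerance = 1e-9)
  # single-residue column: one letter at full height
  solid <- match_alignment(matrix("W", 5, 1), ids = paste0("s", 1:5))
  Hs <- logo_matrix(conservation_profile(solid, w = 0))
  expect_equal(unname(Hs["W", 1]), log2(20), tolerance = 1e-12)
  expect_equal(sum(Hs[, 1] > 0), 1L)
})

test_that("residue identity counts gaps in the denominator", {
  m <- matrix("G", 50, 1)
  m[50, 1] <- "A"
  a <- match_alignment(m, ids = sprintf("s%02d", 1:50))
  expect_equal(residue_identity(a, 1, "G"), 98)
  allgap <- match_alignment(matrix("-", 4, 1), ids = paste0("s", 1:4))
  expect_equal(residue_identity(allgap, 1, "G"), 0)
  expect_error(residue_identity(a, 1, "Z"), "unknown residue")
  expect_error(residue_identity(a, 9, "G"), "outside")
})

test_that("all-gap columns are flagged and score zero end to end", {
  m <- rbind(c("A", "-", "C"), c("A", "-", "C"), c("G", "-", "C"))
  a <- match_alignment(m, ids = paste0("s", 1:3))
  cp <- conservation_profile(a, w = 0)
  expect_true(cp$track$all_gap[2])
  expect_equal(cp$track$jsd_raw[2], 0)
  expect_equal(cp$track$bits[2], 0)
  expect_equal(cp$track$jsd_penalized[2], 0)
})

test_that("henikoff weights favour rows carrying rare residues", {
  m <- rbind(c("G", "A"), c("G", "A"), c("G", "C"))
  a <- match_alignment(m, ids = paste0("s", 1:3))
  w <- henikoff_weights(a)
  expect_gt(w[3], w[1])           # the divergent row weighs more
  expect_equal(mean(w), 1, tolerance = 1e-12)
})
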