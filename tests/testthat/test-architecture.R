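test_that("templates enforce order, contiguity and coverage", {
  good <- data.frame(region = c("dna_binding", "variable", "alpha", "linker",
                                "beta"),
                     start = c(1, 31, 91, 136, 156),
                     end = c(30, 90, 135, 155, 195))
  t <- architecture_template(good, "user-supplied")
  expect_identical(template_columns(t), 195L)
  # wrong order
  bad <- good[c(1, 3, 2, 4, 5), ]
  expect_error(architecture_template(bad), "order")
  # overlap / hole
  bad2 <- good
  bad2$start[3] <- 90
  expect_error(architecture_template(bad2), "contiguous")
  # an empty variable region is legitimate (end = start - 1)
  empty_var <- data.frame(
    region = c("dna_binding", "variable", "alpha", "linker", "beta"),
    start = c(1, 31, 31, 76, 96),
    end = c(30, 30, 75, 95, 135))
  expect_silent(architecture_template(empty_var))
})

test_that("segmentation recovers planted boundaries within two columns", {
  true_b <- c(dna_end = 30L, var_end = 90L, alpha_end = 135L,
              linker_end = 155L)
  for (seed in 1:5) {
    fam <- sample_family(family_spec(n_sequences = 200, seed = seed))
    cp <- conservation_profile(fam$truth$alignment)
    t <- segment_regions(cp)
    got <- c(t$regions["dna_binding", "end"], t$regions["variable", "end"],
             t$regions["alpha", "end"], t$regions["linker", "end"])
    expect_true(all(abs(got - true_b) <= 2L),
                info = sprintf("seed %d: boundaries %s", seed,
                               paste(got, collapse = ", ")))
    expect_identical(t$provenance, "inferred")
  }
})

test_that("flat profiles raise a segmentation error carrying the runs", {
  aa <- aa_alphabet()
  flat <- match_alignment(matrix(rep(aa, 60), 20, 60),
                          ids = sprintf("s%02d", 1:20))
  cp <- conservation_profile(flat)
  err <- tryCatch(segment_regions(cp), error = function(e) e)
  expect_s3_class(err, "velvetarch_segmentation_error")
  expect_true(!is.null(err$runs))
  expect_match(conditionMessage(err), "super-blocks")
})

test_that("segmentation is invariant to appending all-gap rows", {
  fam <- sample_family(family_spec(n_sequences = 150, seed = 2))
  a <- fam$truth$alignment
  t1 <- segment_regions(conservation_profile(a))
  n_extra <- 15L
  padded <- match_alignment(rbind(a$match,
                                  matrix("-", n_extra, ncol(a$match))),
                            ids = c(a$ids, sprintf("gap%02d", 1:n_extra)),
                            inserts = a$inserts)
  t2 <- segment_regions(conservation_profile(padded))
  # gap rows scale every column's penalty by the same factor n / (n + k),
  # and the percentile thresholds scale with the track, so the inferred
  # template is exactly unchanged
  expect_identical(t1$regions, t2$regions)
})

test_that("region lengths equal generator truth exactly", {
  fam <- sample_family(family_spec(n_sequences = 100, seed = 3))
  rl <- region_lengths(fam$truth$alignment, fam$truth$template)
  truth <- fam$truth$spans[, c("id", "region", "length")]
  m <- merge(rl, truth, by = c("id", "region"))
  expect_identical(nrow(m), nrow(rl))
  expect_identical(m$length.x, m$length.y)
})

test_that("region lengths partition each sequence's residues", {
  fam <- small_family(n = 40, seed = 47)
  rl <- region_lengths(fam$truth$alignment, fam$truth$template)
  total_by_id <- tapply(rl$length, rl$id, sum)
  seqs <- ungapped_sequences(fam$truth$alignment)
  expect_identical(as.integer(total_by_id[names(seqs)]),
                   unname(nchar(seqs)))
})

test_that("deleted regions yield length zero and inserts count once", {
  # row 2 has the whole variable region deleted; row 1 carries an insert
  m <- rbind(c("A", "C", "G", "L", "V", "W", "A", "C", "G", "L"),
             c("A", "C", "G", "-", "-", "-", "A", "C", "G", "L"))
  tmpl <- architecture_template(
    data.frame(region = c("dna_binding", "variable", "alpha", "linker",
                          "beta"),
               start = c(1, 4, 7, 8, 9), end = c(3, 6, 7, 8, 10)),
    "user-supplied")
  a <- match_alignment(m, ids = c("r1", "r2"),
                       inserts = data.frame(row = 1L, after_col = 4L,
                                            residues = "GG", count = 2L))
  rl <- region_lengths(a, tmpl)
  expect_identical(rl$length[rl$id == "r2" & rl$region == "variable"], 0L)
  expect_identical(rl$length[rl$id == "r1" & rl$region == "variable"], 5L)
  expect_identical(sum(rl$length[rl$id == "r1"]), 12L)
  # insert-free rows: length = non-deleted occupancies per region
  expect_identical(rl$length[rl$id == "r2" & rl$region == "dna_binding"], 3L)
  # column-count mismatch is a validation error
  short <- match_alignment(m[, 1:9], ids = c("r1", "r2"))
  expect_error(region_lengths(short, tmpl), "columns")
})

test_that("length distributions bin and range-count correctly", {
  recs <- data.frame(id = paste0("s", 1:4), region = "linker",
                     length = c(10L, 20L, 30L, 40L))
  ld <- length_distribution(recs, "linker", bin_width = 5,
                            range_of_interest = c(15, 25))
  expect_identical(ld$percent_in_range, 25L)
  expect_equal(ld$fraction_in_range, 0.25)
  expect_identical(sum(ld$bins$count), 4L)
  expect_equal(sum(ld$bins$percent), 100, tolerance = 1e-9)
  # all-equal lengths inside the range -> 100%
  recs50 <- data.frame(id = paste0("s", 1:8), region = "variable",
                       length = rep(50L, 8))
  expect_identical(length_distribution(recs50, "variable",
                                       range_of_interest = c(40, 60))$percent_in_range,
                   100L)
  # widening the range never lowers the percentage
  fam <- small_family(n = 50, seed = 53)
  rl <- region_lengths(fam$truth$alignment, fam$truth$template)
  pct <- vapply(list(c(45, 55), c(40, 60), c(30, 70), c(0, 450)),
                function(r) length_distribution(rl, "variable",
                                                range_of_interest = r)$fraction_in_range,
                numeric(1))
  expect_true(all(diff(pct) >= 0))
  expect_error(length_distribution(recs, "beta"), "no records")
})

test_that("bins are left-closed and right-open", {
  recs <- data.frame(id = paste0("s", 1:3), region = "variable",
                     length = c(39L, 40L, 60L))
  ld <- length_distribution(recs, "variable", bin_width = 20,
                            range_of_interest = c(40, 60))
  b40 <- ld$bins[ld$bins$lower == 40, ]
  b60 <- ld$bins[ld$bins$lower == 60, ]
  expect_identical(b40$count, 1L)   # 40 in [40, 60), 39 below, 60 above
  expect_identical(b60$count, 1L)
  # but the range of interest is inclusive on both ends
  expect_equal(ld$fraction_in_range, 2 / 3, tolerance = 1e-12)
})
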