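# Synthetic velvet-like families with planted architecture: two conserved
# blocks (DNA-binding; dimerization = alpha + linker + beta) joined by a
# poorly conserved variable region whose length varies from 0 to several
# hundred residues. Every downstream stage (alignment bookkeeping,
# conservation scoring, segmentation, length statistics, scan planning) can
# be tested against the exact truth recorded at sampling time.

# ---- length samplers -------------------------------------------------------

#' Probability mass function of a named length sampler
#'
#' Three samplers are available. `"pmf"` is fully explicit (fields
#' `lengths`, `probs`). `"velvet_variable"` is the default variable-region
#' sampler: an atom at length 0 (the variable region can be absent
#' entirely), a discretized log-normal body with mode near 50 aa, and an
#' exponential tail reaching 450 aa; the mixture is calibrated so that the
#' mass on `range` (default `[40, 60]`, inclusive) equals `target_mass`
#' (default 0.47). `"velvet_linker"` is the default linker sampler: a
#' discretized normal body on 5..60 aa centred at 20, calibrated to place
#' `target_mass` (default 0.63) on `[15, 25]`.
#'
#' Calibration reweights the base mixture inside vs outside the target
#' range, so the target mass is met exactly by construction while the shape
#' within each part is preserved.
#'
#' @param sampler A list with a `name` field plus parameters (see above).
#' @return `data.frame` with columns `length` and `prob` (summing to 1).
#' @export
sampler_pmf <- function(sampler) {
  stopifnot(is.list(sampler), !is.null(sampler$name))
  pmf <- switch(
    sampler$name,
    pmf = {
      stopifnot(length(sampler$lengths) == length(sampler$probs))
      data.frame(length = as.integer(sampler$lengths),
                 prob = sampler$probs / sum(sampler$probs))
    },
    velvet_variable = {
      len <- 0:450
      body <- stats::dlnorm(pmax(len, 1), meanlog = log(50), sdlog = 0.35)
      body[len == 0] <- 0
      tail <- ifelse(len >= 20, exp(-len / 120), 0)
      base <- 0.03 * c(1, rep(0, 450)) +
        0.82 * body / sum(body) +
        0.15 * tail / sum(tail)
      calibrate_pmf(len, base,
                    range = sampler$range %||% c(40, 60),
                    target = sampler$target_mass %||% 0.47)
    },
    velvet_linker = {
      len <- 5:60
      base <- stats::dnorm(len, mean = 20, sd = 5)
      calibrate_pmf(len, base / sum(base),
                    range = sampler$range %||% c(15, 25),
                    target = sampler$target_mass %||% 0.63)
    },
    stop("sampler_pmf(): unknown sampler name '", sampler$name, "'")
  )
  pmf$prob <- pmf$prob / sum(pmf$prob)
  pmf
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# reweight a pmf so the (inclusive) range carries exactly `target` mass
calibrate_pmf <- function(len, prob, range, target) {
  inside <- len >= range[1] & len <= range[2]
  m <- sum(prob[inside])
  if (m <= 0 || m >= 1) stop("calibrate_pmf(): base mixture places no mass ",
                             "on one side of the target range")
  prob[inside] <- prob[inside] * target / m
  prob[!inside] <- prob[!inside] * (1 - target) / (1 - m)
  data.frame(length = as.integer(len), prob = prob)
}

# draw n lengths from a sampler (uses the current RNG stream); indexed
# sampling avoids sample()'s scalar-x expansion for one-point supports
draw_lengths <- function(sampler, n) {
  pmf <- sampler_pmf(sampler)
  pmf$length[sample.int(nrow(pmf), n, replace = TRUE, prob = pmf$prob)]
}

#' Empirical summary of a spec's variable-region length sampler
#'
#' Draws `n_draws` lengths from the spec's variable-region sampler (under
#' the spec's seed) and bins them, reporting the fraction landing in the
#' sampler's calibration range. Used to check that a configured generator
#' reproduces the intended length distribution before committing to a large
#' simulation.
#'
#' @param spec A [family_spec()].
#' @param n_draws Number of draws (>= 1).
#' @param bin_width Bin width in residues (left-closed, right-open bins
#'   starting at 0).
#' @return A [length_distribution()] object; its `fraction_in_range` field
#'   can be compared against the sampler's calibration target.
#' @export
length_sampler_summary <- function(spec, n_draws, bin_width = 20L) {
  spec <- validate_family_spec(spec)
  if (n_draws < 1L) stop("length_sampler_summary(): n_draws must be >= 1")
  lens <- with_seed(spec$seed, draw_lengths(spec$variable_length_sampler, n_draws))
  rng <- spec$variable_length_sampler$range %||% c(40, 60)
  recs <- data.frame(id = sprintf("draw%d", seq_len(n_draws)),
                     region = "variable", length = lens,
                     stringsAsFactors = FALSE)
  length_distribution(recs, "variable", bin_width = bin_width,
                      range_of_interest = rng)
}

# ---- family specification --------------------------------------------------

#' Specification of a synthetic velvet-like family
#'
#' Defines the planted architecture and conservation structure. Defaults
#' reproduce the canonical velvet layout: a 30-column DNA-binding block and
#' a 125-column dimerization block (45-column alpha-subunit, 20-column
#' linker, 40-column beta-subunit) separated by 60 variable match columns;
#' variable-region lengths 0-450 aa with 47% of sequences in 40-60 aa;
#' linker lengths mostly 15-25 aa (63% of sequences); and two planted
#' near-invariant sites mirroring the family's hallmark glycine/leucine
#' pair: a G at 98% identity in the alpha-subunit and an L at 95% in the
#' beta-subunit.
#'
#' Conservation classes give per-column Dirichlet concentrations: each
#' column's true residue distribution is drawn once from
#' `Dirichlet(concentration * (dominance * e_r + (1 - dominance) * q))`
#' with a random dominant residue `r` and background `q`; residues are then
#' sampled i.i.d. from it (columns are exchangeable given their class — no
#' phylogeny is simulated). Insertions are placed only inside the variable
#' region and the linker; the conserved blocks are generated insertion-free.
#'
#' @param n_sequences Number of sequences (>= 2).
#' @param block_lengths Named integer vector of match-column counts:
#'   `dna_binding`, `variable`, `alpha`, `linker`, `beta` (all positive).
#' @param variable_length_sampler,linker_length_sampler Named samplers, see
#'   [sampler_pmf()].
#' @param conservation_levels Per-class lists with `dominance` in `[0,1]`
#'   and `concentration > 0`, for classes `conserved` (DNA-binding, alpha,
#'   beta), `linker`, and `variable`.
#' @param invariant_sites `data.frame` with columns `column` (global match
#'   column index), `residue`, `prob` (identity probability in `[0,1]`).
#' @param background Amino-acid background over [aa_alphabet()].
#' @param seed Integer seed; all sampling flows from this single seed.
#' @return Object of class `family_spec`.
#' @export
family_spec <- function(n_sequences = 200L,
                        block_lengths = c(dna_binding = 30L, variable = 60L,
                                          alpha = 45L, linker = 20L, beta = 40L),
                        variable_length_sampler = list(name = "velvet_variable",
                                                       target_mass = 0.47,
                                                       range = c(40, 60)),
                        linker_length_sampler = list(name = "velvet_linker",
                                                     target_mass = 0.63,
                                                     range = c(15, 25)),
                        conservation_levels = list(
                          conserved = list(dominance = 0.90, concentration = 60),
                          linker    = list(dominance = 0.75, concentration = 60),
                          variable  = list(dominance = 0.00, concentration = 60)),
                        invariant_sites = NULL,
                        background = aa_background("uniform"),
                        seed = 42L) {
  spec <- structure(list(n_sequences = as.integer(n_sequences),
                         block_lengths = block_lengths,
                         variable_length_sampler = variable_length_sampler,
                         linker_length_sampler = linker_length_sampler,
                         conservation_levels = conservation_levels,
                         invariant_sites = invariant_sites,
                         background = background,
                         seed = as.integer(seed)),
                    class = "family_spec")
  if (is.null(invariant_sites)) {
    # hallmark G (alpha) and L (beta) sites at the family's canonical
    # identity levels, placed mid-subunit
    b <- region_bounds(spec)
    spec$invariant_sites <- data.frame(
      column = c(b["alpha", "start"] + 9L, b["beta", "start"] + 19L),
      residue = c("G", "L"),
      prob = c(0.98, 0.95),
      stringsAsFactors = FALSE)
  }
  validate_family_spec(spec)
}

# match-column bounds of the planted regions, in architecture order
region_bounds <- function(spec) {
  bl <- spec$block_lengths[c("dna_binding", "variable", "alpha", "linker", "beta")]
  end <- cumsum(as.integer(bl))
  start <- c(1L, head(end, -1) + 1L)
  data.frame(region = names(bl), start = start, end = end,
             row.names = names(bl), stringsAsFactors = FALSE)
}

validate_family_spec <- function(spec) {
  if (!inherits(spec, "family_spec")) stop("not a family_spec")
  if (is.na(spec$n_sequences) || spec$n_sequences < 2L) {
    stop("invalid family_spec: n_sequences must be >= 2")
  }
  need <- c("dna_binding", "variable", "alpha", "linker", "beta")
  if (!all(need %in% names(spec$block_lengths)) ||
      any(spec$block_lengths[need] < 1)) {
    stop("invalid family_spec: block_lengths must name positive counts for ",
         paste(need, collapse = ", "))
  }
  check_distribution(spec$background, "family_spec background")
  for (cl in c("conserved", "linker", "variable")) {
    lv <- spec$conservation_levels[[cl]]
    if (is.null(lv) || lv$dominance < 0 || lv$dominance > 1 ||
        lv$concentration <= 0) {
      stop("invalid family_spec: conservation_levels$", cl,
           " needs dominance in [0,1] and concentration > 0")
    }
  }
  inv <- spec$invariant_sites
  if (!is.null(inv) && nrow(inv) > 0L) {
    M <- sum(spec$block_lengths[need])
    if (any(inv$prob < 0 | inv$prob > 1)) {
      stop("invalid family_spec: invariant_sites prob must lie in [0,1]")
    }
    if (any(inv$column < 1L | inv$column > M)) {
      stop("invalid family_spec: invariant_sites column outside 1..", M)
    }
    if (!all(inv$residue %in% aa_alphabet())) {
      stop("invalid family_spec: invariant_sites residue must be a standard ",
           "amino acid")
    }
  }
  # pmf construction errors surface here, naming the sampler field
  tryCatch(sampler_pmf(spec$variable_length_sampler),
           error = function(e) stop("invalid family_spec: ",
                                    "variable_length_sampler: ",
                                    conditionMessage(e)))
  tryCatch(sampler_pmf(spec$linker_length_sampler),
           error = function(e) stop("invalid family_spec: ",
                                    "linker_length_sampler: ",
                                    conditionMessage(e)))
  spec
}

# run code under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

# ---- the generator ---------------------------------------------------------

#' Sample a synthetic velvet-like family with known truth
#'
#' Draws a family under a [family_spec()]: one true residue distribution per
#' match column (by conservation class), per-sequence variable-region and
#' linker lengths from the spec's samplers, occupancies and insert runs
#' realizing those lengths, and residues from the column distributions.
#' Output is deterministic for a fixed spec and seed.
#'
#' Lengths are realized against the fixed match-column layout: a region
#' whose sampled length falls short of its column count deletes a random
#' subset of its columns; one that exceeds it adds an insert run at a random
#' anchor strictly inside the region. Conserved blocks (DNA-binding, alpha,
#' beta) are fully occupied and insertion-free.
#'
#' @param spec A [family_spec()].
#' @return List with `sequences` (list of [domain_sequence()]) and `truth`,
#'   a `family_truth` object: `alignment` (the true [match_alignment()]),
#'   `template` (true [architecture_template()] over match columns), `spans`
#'   (per-sequence region spans in residue coordinates, partitioning each
#'   sequence exactly), `identity` (per planted invariant site, the realized
#'   identity fraction), and `column_distributions` (the true per-column
#'   residue distributions).
#' @export
sample_family <- function(spec) {
  spec <- validate_family_spec(spec)
  with_seed(spec$seed, {
    aa <- aa_alphabet()
    q <- spec$background
    bounds <- region_bounds(spec)
    M <- bounds$end[nrow(bounds)]
    col_region <- rep(bounds$region, times = bounds$end - bounds$start + 1L)
    class_of <- c(dna_binding = "conserved", variable = "variable",
                  alpha = "conserved", linker = "linker", beta = "conserved")

    # true per-column residue distributions
    P <- matrix(0, nrow = 20L, ncol = M, dimnames = list(aa, NULL))
    for (c in seq_len(M)) {
      lv <- spec$conservation_levels[[class_of[[col_region[c]]]]]
      dom <- sample(aa, 1L, prob = q)
      alpha_vec <- lv$concentration *
        (lv$dominance * (aa == dom) + (1 - lv$dominance) * q)
      P[, c] <- rdirichlet1(alpha_vec)
    }
    inv <- spec$invariant_sites
    if (!is.null(inv)) {
      for (k in seq_len(nrow(inv))) {
        e <- as.numeric(aa == inv$residue[k])
        rest <- q * (1 - e); rest <- rest / sum(rest)
        P[, inv$column[k]] <- inv$prob[k] * e + (1 - inv$prob[k]) * rest
      }
    }

    n <- spec$n_sequences
    var_len <- draw_lengths(spec$variable_length_sampler, n)
    link_len <- draw_lengths(spec$linker_length_sampler, n)

    match_mat <- matrix("-", n, M)
    ins_row <- integer(0); ins_after <- integer(0); ins_res <- character(0)
    full_regions <- c("dna_binding", "alpha", "beta")
    for (r in full_regions) {
      cols <- bounds[r, "start"]:bounds[r, "end"]
      for (c in cols) {
        match_mat[, c] <- sample(aa, n, replace = TRUE, prob = P[, c])
      }
    }
    realize_region <- function(i, region, target_len) {
      cols <- bounds[region, "start"]:bounds[region, "end"]
      ncols <- length(cols)
      occ_n <- min(target_len, ncols)
      if (occ_n > 0L) {
        occ <- sort(sample(cols, occ_n))
        for (c in occ) {
          match_mat[i, c] <<- sample(aa, 1L, prob = P[, c])
        }
      }
      extra <- target_len - ncols
      if (extra > 0L) {
        anchor <- if (ncols > 1L) sample(cols[-length(cols)], 1L) else cols[1] - 1L
        ins_row <<- c(ins_row, i)
        ins_after <<- c(ins_after, anchor)
        ins_res <<- c(ins_res, paste(sample(aa, extra, replace = TRUE, prob = q),
                                     collapse = ""))
      }
    }
    for (i in seq_len(n)) {
      realize_region(i, "variable", var_len[i])
      realize_region(i, "linker", link_len[i])
    }

    ids <- sprintf("seq%04d", seq_len(n))
    aln <- match_alignment(match_mat, ids,
                           data.frame(row = ins_row, after_col = ins_after,
                                      residues = ins_res, count = nchar(ins_res),
                                      stringsAsFactors = FALSE))

    # per-sequence region spans in residue coordinates (1-based inclusive;
    # an absent region gets length 0 and an empty span start > end)
    lens <- cbind(dna_binding = spec$block_lengths[["dna_binding"]],
                  variable = var_len,
                  alpha = spec$block_lengths[["alpha"]],
                  linker = link_len,
                  beta = spec$block_lengths[["beta"]])
    spans <- do.call(rbind, lapply(seq_len(n), function(i) {
      end <- cumsum(lens[i, ])
      start <- c(1L, head(end, -1) + 1L)
      data.frame(id = ids[i], region = colnames(lens),
                 start = as.integer(start), end = as.integer(end),
                 length = as.integer(lens[i, ]), stringsAsFactors = FALSE)
    }))
    rownames(spans) <- NULL

    identity <- NULL
    if (!is.null(inv) && nrow(inv) > 0L) {
      identity <- inv
      identity$realized <- vapply(seq_len(nrow(inv)), function(k) {
        mean(match_mat[, inv$column[k]] == inv$residue[k])
      }, numeric(1))
    }

    template <- architecture_template(bounds[, c("region", "start", "end")],
                                      provenance = "user-supplied")
    seqs_chr <- ungapped_sequences(aln)
    sequences <- lapply(seq_len(n), function(i) {
      domain_sequence(ids[i], seqs_chr[[i]])
    })
    truth <- structure(list(alignment = aln, template = template,
                            spans = spans, identity = identity,
                            column_distributions = P),
                       class = "family_truth")
    list(sequences = sequences, truth = truth)
  })
}

#' @export
print.family_truth <- function(x, ...) {
  cat(sprintf("<family_truth> %d sequences, %d match columns, %d invariant site(s)\n",
              nrow(x$alignment$match), ncol(x$alignment$match),
              if (is.null(x$identity)) 0L else nrow(x$identity)))
  invisible(x)
}

#' Write a sampled family to disk
#'
#' Emits the unaligned sequences as FASTA, the true alignment as Stockholm
#' (with `#=GC RF` match annotation), and a JSON truth sidecar (spans and
#' planted-site identities).
#'
#' @param fam Result of [sample_family()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_family <- function(fam, dir, prefix = "family") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(prefix, ".fasta"))
  lines <- unlist(lapply(fam$sequences, function(s) c(paste0(">", s$id), s$residues)))
  writeLines(lines, fasta)
  sto <- file.path(dir, paste0(prefix, "_truth.sto"))
  write_alignment(fam$truth$alignment, sto, "stockholm")
  truth <- file.path(dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(list(spans = fam$truth$spans,
                            identity = fam$truth$identity,
                            template = fam$truth$template$regions),
                       truth, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fasta, stockholm = sto, truth = truth))
}
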