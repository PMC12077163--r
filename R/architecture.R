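# Segmentation of a conservation profile into the canonical velvet
# architecture — DNA-binding, variable, and dimerization (alpha, linker,
# beta) — plus per-sequence region-length statistics.

REGION_ORDER <- c("dna_binding", "variable", "alpha", "linker", "beta")

#' Construct an architecture template
#'
#' Ordered region boundaries in match-column space. The five regions must
#' appear in canonical order (`dna_binding`, `variable`, `alpha`, `linker`,
#' `beta`), be contiguous and non-overlapping, and jointly cover all match
#' columns; a region may be empty (`end == start - 1`), as the variable
#' region of a compact domain can be.
#'
#' @param regions `data.frame` with columns `region`, `start`, `end`.
#' @param provenance `"inferred"` (from a conservation profile) or
#'   `"user-supplied"`.
#' @return Object of class `architecture_template`.
#' @export
architecture_template <- function(regions,
                                  provenance = c("inferred", "user-supplied")) {
  provenance <- match.arg(provenance)
  stopifnot(all(c("region", "start", "end") %in% names(regions)))
  regions <- regions[, c("region", "start", "end")]
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  if (!identical(regions$region, REGION_ORDER)) {
    stop("architecture_template(): regions must be exactly ",
         paste(REGION_ORDER, collapse = ", "), " in that order")
  }
  if (regions$start[1] != 1L) {
    stop("architecture_template(): first region must start at column 1")
  }
  if (any(regions$end < regions$start - 1L)) {
    stop("architecture_template(): region end before start")
  }
  if (any(regions$start[-1] != head(regions$end, -1) + 1L)) {
    stop("architecture_template(): regions must be contiguous and ",
         "non-overlapping")
  }
  rownames(regions) <- regions$region
  structure(list(regions = regions, provenance = provenance),
            class = "architecture_template")
}

#' @export
print.architecture_template <- function(x, ...) {
  cat(sprintf("<architecture_template> (%s)\n", x$provenance))
  for (i in seq_len(nrow(x$regions))) {
    r <- x$regions[i, ]
    cat(sprintf("  %-12s cols %4d-%4d (%d)\n", r$region, r$start, r$end,
                max(0L, r$end - r$start + 1L)))
  }
  invisible(x)
}

#' Match column count covered by a template
#' @param t An `architecture_template`.
#' @return Integer.
#' @export
template_columns <- function(t) t$regions$end[nrow(t$regions)]

# condition constructor for segmentation failures; carries the run list so
# a caller can inspect what was found and supply a template instead
segmentation_error <- function(msg, runs) {
  stop(structure(class = c("velvetarch_segmentation_error", "error",
                           "condition"),
                 list(message = paste0("segment_regions(): ", msg),
                      call = sys.call(-1), runs = runs)))
}

# maximal runs of TRUE in a logical vector, as a data.frame(start, end)
logical_runs <- function(x) {
  r <- rle(x)
  end <- cumsum(r$lengths)
  start <- c(1L, head(end, -1) + 1L)
  data.frame(start = start[r$values], end = end[r$values])
}

#' Segment a conservation profile into the velvet architecture
#'
#' Thresholds the smoothed, gap-penalized JSD track and reads the region
#' layout off the resulting conserved runs. The rule: columns strictly
#' above `tau` (default: the midpoint between the 20th and 80th percentile
#' of the track) form candidate runs; runs separated by fewer than
#' `merge_gap` columns are merged; runs shorter than `min_block` are
#' dropped. Exactly two super-blocks are expected — the N-terminal one is
#' the DNA-binding region, the C-terminal one the dimerization region, and
#' the span between them the variable region. Within the dimerization
#' block, the lowest-conservation internal valley of width at least
#' `valley_width` (below the midpoint of the block's own 20th/80th
#' percentiles) is the linker, splitting the block into alpha and beta
#' subunits. The DNA-binding region is extended to column 1 and the beta
#' subunit to the last column so the template covers the whole profile.
#'
#' Any other block count, or a dimerization block without an internal
#' valley, raises a condition of class `velvetarch_segmentation_error`
#' carrying the detected run list; callers may then supply an
#' [architecture_template()] by hand.
#'
#' @param cp A [conservation_profile()] over at least 50 columns.
#' @param tau Run threshold; `NULL` for the percentile rule.
#' @param merge_gap Merge runs separated by fewer than this many columns.
#' @param min_block Minimum run length to count as a block.
#' @param valley_width Minimum linker valley width in columns.
#' @return An `architecture_template` with provenance `"inferred"`.
#' @export
segment_regions <- function(cp, tau = NULL, merge_gap = 5L, min_block = 10L,
                            valley_width = 5L) {
  s <- cp$track$jsd_smoothed
  M <- length(s)
  if (M < 50L) stop("segment_regions(): profile has ", M,
                    " columns; need at least 50")
  if (is.null(tau)) {
    qs <- quantile(s, c(0.2, 0.8), names = FALSE)
    tau <- mean(qs)
  }
  runs <- logical_runs(s > tau)
  # merge runs separated by < merge_gap columns
  if (nrow(runs) > 1L) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] - 1L < merge_gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  runs <- runs[runs$end - runs$start + 1L >= min_block, , drop = FALSE]
  if (nrow(runs) != 2L) {
    segmentation_error(paste0("expected exactly 2 conserved super-blocks, ",
                              "found ", nrow(runs)), runs)
  }
  dna_end <- runs$end[1]
  dim_start <- runs$start[2]

  # linker valley inside the dimerization block
  block <- dim_start:M
  sb <- s[block]
  tau2 <- mean(quantile(sb, c(0.2, 0.8), names = FALSE))
  vruns <- logical_runs(sb < tau2)
  if (nrow(vruns) > 0L) {
    internal <- vruns$start > 1L & vruns$end < length(block)
    wide <- vruns$end - vruns$start + 1L >= valley_width
    vruns <- vruns[internal & wide, , drop = FALSE]
  }
  if (nrow(vruns) == 0L) {
    segmentation_error("no internal linker valley of sufficient width in the
 dimerization block", runs)
  }
  depth <- vapply(seq_len(nrow(vruns)),
                  function(i) mean(sb[vruns$start[i]:vruns$end[i]]),
                  numeric(1))
  v <- vruns[which.min(depth), ]
  link_start <- dim_start + v$start - 1L
  link_end <- dim_start + v$end - 1L

  regions <- data.frame(
    region = REGION_ORDER,
    start = c(1L, dna_end + 1L, dim_start, link_start, link_end + 1L),
    end = c(dna_end, dim_start - 1L, link_start - 1L, link_end, M))
  architecture_template(regions, provenance = "inferred")
}

#' Per-sequence region lengths
#'
#' Residue count of each region for each alignment row: non-deleted match
#' occupancies inside the region's columns plus insert-run residues
#' anchored inside it. An insert run after column `k` belongs to the
#' region containing column `k` (runs before the first column belong to
#' the first region); region boundaries fall between match columns, so the
#' generator and aligner never anchor runs across them. Region lengths of
#' a row always sum to its ungapped sequence length.
#'
#' @param a A [match_alignment()] (insert counts suffice; residues may be
#'   stripped).
#' @param template An [architecture_template()] covering `a`'s columns.
#' @return `data.frame` with `id`, `region`, `length`, one row per
#'   sequence x region.
#' @export
region_lengths <- function(a, template) {
  M <- ncol(a$match)
  if (template_columns(template) != M) {
    stop("region_lengths(): template covers ", template_columns(template),
         " columns but alignment has ", M)
  }
  cnt <- insert_count_matrix(a)                # n x (M+1), slot k+1 = after col k
  occ <- a$match != "-"
  n <- nrow(a$match)
  reg <- template$regions
  out <- vector("list", nrow(reg))
  for (r in seq_len(nrow(reg))) {
    cols <- if (reg$end[r] >= reg$start[r]) reg$start[r]:reg$end[r] else integer(0)
    # insert slots owned by this region: after_col in cols, plus after_col=0
    # for the first region
    slots <- cols + 1L
    if (r == 1L) slots <- c(1L, slots)
    len <- (if (length(cols) > 0L) rowSums(occ[, cols, drop = FALSE]) else
              rep(0L, n)) +
           rowSums(cnt[, slots, drop = FALSE])
    out[[r]] <- data.frame(id = a$ids, region = reg$region[r],
                           length = as.integer(len),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$id, a$ids), match(res$region, REGION_ORDER)), ]
  rownames(res) <- NULL
  res
}

#' Binned length distribution of one region
#'
#' Left-closed, right-open bins of width `bin_width` starting at 0, plus
#' the share of sequences whose region length falls in an inclusive range
#' of interest (the convention under which "40-60 aa" includes both
#' endpoints). The percentage is reported rounded to the nearest integer
#' with the raw fraction attached.
#'
#' @param records Output of [region_lengths()] (or any `data.frame` with
#'   `region` and `length`).
#' @param region Region name to summarize.
#' @param bin_width Bin width in residues.
#' @param range_of_interest Inclusive `c(lo, hi)` range.
#' @return Object of class `length_distribution`: list with `region`,
#'   `bins` (`data.frame` of `lower`, `upper`, `count`, `percent`), `n`,
#'   `range`, `fraction_in_range`, and `percent_in_range` (integer).
#' @export
length_distribution <- function(records, region, bin_width = 20L,
                                range_of_interest = c(40, 60)) {
  lens <- records$length[records$region == region]
  if (length(lens) == 0L) {
    stop("length_distribution(): no records for region '", region, "'")
  }
  edges <- seq(0L, max(lens) + bin_width, by = bin_width)
  idx <- findInterval(lens, edges)             # bin i = [edges[i], edges[i+1])
  count <- tabulate(idx, nbins = length(edges) - 1L)
  bins <- data.frame(lower = edges[-length(edges)], upper = edges[-1],
                     count = count, percent = 100 * count / length(lens))
  frac <- mean(lens >= range_of_interest[1] & lens <= range_of_interest[2])
  structure(list(region = region, bins = bins, n = length(lens),
                 range = range_of_interest, fraction_in_range = frac,
                 percent_in_range = as.integer(round(100 * frac))),
            class = "length_distribution")
}

#' @export
print.length_distribution <- function(x, ...) {
  cat(sprintf("<length_distribution> %s region, n = %d\n", x$region, x$n))
  cat(sprintf("  %d%% of sequences in [%g, %g] aa (raw fraction %.4f)\n",
              x$percent_in_range, x$range[1], x$range[2],
              x$fraction_in_range))
  invisible(x)
}

#' Export a template as BED-like TSV over match columns
#' @param t An `architecture_template`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_template <- function(t, path) {
  df <- t$regions
  df$provenance <- t$provenance
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
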