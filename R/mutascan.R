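# From conserved columns to an alanine-scanning plan on a reference
# protein, and residue correspondence tables across several references.

#' Plan an alanine scan over conserved columns
#'
#' Selects the conserved columns (information content strictly above
#' `bits_threshold`) that fall inside the named template regions, maps them
#' to residue numbers of the reference protein, and proposes an alanine
#' substitution for each. Columns where the reference carries a deletion
#' are unmappable and skipped; native alanines are skipped too (there is
#' nothing to substitute), but every other residue — glycines included —
#' is a candidate. A candidate whose reference residue differs from the
#' column consensus is flagged rather than dropped: reference proteins do
#' diverge from consensus at otherwise conserved positions.
#'
#' @param cp A [conservation_profile()].
#' @param rm A [build_reference_map()] result for the reference row.
#' @param template An [architecture_template()] over the same columns.
#' @param regions Region names to scan (default the two dimerization
#'   subunits).
#' @param bits_threshold Conservation call threshold in bits.
#' @return `data.frame` ordered by residue number with columns
#'   `residue_no`, `wt`, `column`, `region`, `bits`, `identity_pct`,
#'   `substitution`, `consensus_mismatch`. Zero rows when nothing is
#'   conserved.
#' @export
plan_alanine_scan <- function(cp, rm, template,
                              regions = c("alpha", "beta"),
                              bits_threshold = 2) {
  stopifnot(all(regions %in% REGION_ORDER))
  cols <- call_conserved(cp, bits_threshold)
  reg <- template$regions
  col_region <- rep(NA_character_, template_columns(template))
  for (r in seq_len(nrow(reg))) {
    if (reg$end[r] >= reg$start[r]) {
      col_region[reg$start[r]:reg$end[r]] <- reg$region[r]
    }
  }
  cols <- cols[col_region[cols] %in% regions]
  hit <- match(cols, rm$table$column)
  mapped <- !is.na(hit)
  cols <- cols[mapped]; hit <- hit[mapped]
  wt <- rm$table$residue[hit]
  keep <- wt != "A"
  cols <- cols[keep]; hit <- hit[keep]; wt <- wt[keep]
  plan <- data.frame(
    residue_no = rm$table$residue_no[hit],
    wt = wt,
    column = cols,
    region = col_region[cols],
    bits = cp$track$bits[cols],
    identity_pct = 100 * cp$track$consensus_identity[cols],
    substitution = if (length(cols)) "A" else character(0),
    consensus_mismatch = wt != cp$track$consensus[cols],
    stringsAsFactors = FALSE)
  plan <- plan[order(plan$residue_no), ]
  rownames(plan) <- NULL
  plan
}

#' Cross-protein residue correspondence at selected columns
#'
#' For each requested match column, reports every reference protein's
#' residue number and residue at that column — the table that turns "this
#' conserved column" into, e.g., VelB G240 / VosA G96 / VeA G83. A
#' reference deleted at a column is reported as `NA`.
#'
#' @param maps List of [build_reference_map()] results over the same
#'   alignment.
#' @param columns Match column indices.
#' @return `data.frame` with `column` plus, per reference,
#'   `<id>_residue_no` and `<id>_residue`.
#' @export
correspondence_table <- function(maps, columns) {
  stopifnot(length(maps) >= 1L)
  ncols <- vapply(maps, function(m) m$n_columns, integer(1))
  if (length(unique(ncols)) != 1L) {
    stop("correspondence_table(): reference maps span different alignments")
  }
  if (any(columns < 1L | columns > ncols[1])) {
    stop("correspondence_table(): column outside alignment (1..", ncols[1], ")")
  }
  out <- data.frame(column = as.integer(columns))
  for (m in maps) {
    cr <- column_to_residue(m, columns)
    out[[paste0(m$reference_id, "_residue_no")]] <- cr$residue_no
    out[[paste0(m$reference_id, "_residue")]] <- cr$residue
  }
  out
}

#' Export an alanine-scan plan as TSV
#' @param plan Output of [plan_alanine_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_plan <- function(plan, path) {
  write.table(plan, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
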