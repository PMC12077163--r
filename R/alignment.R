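#' A single ungapped domain sequence
#'
#' Container for one domain sequence with optional provenance coordinates in
#' its parent protein (1-based inclusive), e.g. a velvet domain excised from
#' positions 22-186 of its parent.
#'
#' @param id Sequence identifier.
#' @param residues Character string over the 20 amino acids plus `X`.
#' @param parent_span Optional integer `c(start, end)`; must satisfy
#'   `end - start + 1 == nchar(residues)`.
#' @return Object of class `domain_sequence`.
#' @export
domain_sequence <- function(id, residues, parent_span = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  if (nchar(residues) == 0L) stop("domain_sequence(): residues must be non-empty")
  chars <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(chars), c(aa_alphabet(), "X"))
  if (length(bad) > 0L) {
    stop("domain_sequence(): invalid residue symbol(s): ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(parent_span)) {
    parent_span <- as.integer(parent_span)
    if (length(parent_span) != 2L ||
        parent_span[2] - parent_span[1] + 1L != nchar(residues)) {
      stop("domain_sequence(): parent_span must be c(start, end) with ",
           "end - start + 1 == number of residues")
    }
  }
  structure(list(id = id, residues = residues, parent_span = parent_span),
            class = "domain_sequence")
}

#' @export
print.domain_sequence <- function(x, ...) {
  span <- if (is.null(x$parent_span)) "" else
    sprintf(" [%d-%d]", x$parent_span[1], x$parent_span[2])
  cat(sprintf("<domain_sequence> %s%s, %d aa\n", x$id, span, nchar(x$residues)))
  invisible(x)
}

#' Construct a match/insert alignment
#'
#' The central alignment container. Match columns are stored as an
#' `n x M` character matrix (`-` marks a deletion); residues that fall in
#' insert states are kept off-matrix as per-row runs anchored between two
#' match columns (`after_col = k` means between match columns `k` and
#' `k + 1`; `k = 0` precedes the first column). This keeps alignments of
#' families with very long inserts compact while remaining lossless:
#' [write_alignment()] re-expands insert runs into explicit insert columns.
#'
#' @param match Character matrix (rows = sequences, columns = match columns);
#'   entries are residue letters, `X`, or `-`.
#' @param ids Character vector of row identifiers (unique).
#' @param inserts `data.frame` with columns `row` (integer row index),
#'   `after_col` (integer in `0..ncol(match)`), `residues` (string, or `NA`
#'   once stripped to counts), `count` (integer run length).
#' @return Object of class `match_alignment`.
#' @export
match_alignment <- function(match, ids, inserts = NULL) {
  stopifnot(is.matrix(match), is.character(match))
  n <- nrow(match); M <- ncol(match)
  if (length(ids) != n || anyDuplicated(ids)) {
    stop("match_alignment(): ids must be unique and match the row count")
  }
  ok <- match %in% c(aa_alphabet(), "X", "-")
  if (!all(ok)) {
    stop("match_alignment(): invalid symbol(s) in match matrix: ",
         paste(unique(match[!ok]), collapse = ", "))
  }
  if (is.null(inserts)) {
    inserts <- data.frame(row = integer(), after_col = integer(),
                          residues = character(), count = integer(),
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("row", "after_col", "count") %in% names(inserts)))
  if (is.null(inserts$residues)) inserts$residues <- NA_character_
  inserts <- inserts[, c("row", "after_col", "residues", "count")]
  if (nrow(inserts) > 0L) {
    if (any(inserts$row < 1L | inserts$row > n) ||
        any(inserts$after_col < 0L | inserts$after_col > M)) {
      stop("match_alignment(): insert anchors out of range")
    }
    has_res <- !is.na(inserts$residues)
    if (any(nchar(inserts$residues[has_res]) != inserts$count[has_res])) {
      stop("match_alignment(): insert residue strings disagree with counts")
    }
    inserts <- inserts[order(inserts$row, inserts$after_col), , drop = FALSE]
    rownames(inserts) <- NULL
  }
  dimnames(match) <- NULL
  structure(list(match = match, ids = as.character(ids), inserts = inserts),
            class = "match_alignment")
}

#' @export
print.match_alignment <- function(x, ...) {
  cat(sprintf("<match_alignment> %d sequences x %d match columns, %d insert run(s)\n",
              nrow(x$match), ncol(x$match), nrow(x$inserts)))
  invisible(x)
}

#' Number of match columns
#' @param a A `match_alignment`.
#' @return Integer column count.
#' @export
n_match_columns <- function(a) ncol(a$match)

# internal: per-row insert counts as an n x (M+1) matrix; slot k+1 holds the
# run between match columns k and k+1
insert_count_matrix <- function(a) {
  n <- nrow(a$match); M <- ncol(a$match)
  cnt <- matrix(0L, n, M + 1L)
  if (nrow(a$inserts) > 0L) {
    idx <- cbind(a$inserts$row, a$inserts$after_col + 1L)
    cnt[idx] <- cnt[idx] + as.integer(a$inserts$count)
  }
  cnt
}

#' Column-to-residue map for one alignment row
#'
#' For a row of a [match_alignment()], returns for every match column the
#' 1-based index of the residue occupying it in the row's ungapped sequence
#' (`NA` at deletions). Insert residues advance the index but occupy no
#' match column, so the map is strictly increasing along columns.
#'
#' @param a A `match_alignment`.
#' @param row Row index or id.
#' @return Integer vector of length `n_match_columns(a)`.
#' @export
row_map <- function(a, row) {
  i <- if (is.character(row)) match(row, a$ids) else as.integer(row)
  if (is.na(i) || i < 1L || i > nrow(a$match)) {
    stop("row_map(): row '", row, "' not found in alignment")
  }
  M <- ncol(a$match)
  ins <- insert_count_matrix(a)[i, ]           # length M + 1
  occ <- a$match[i, ] != "-"
  # residue index before entering column c: inserts in slots 1..c plus
  # occupancies in columns 1..c-1
  out <- rep(NA_integer_, M)
  res <- 0L
  for (c in seq_len(M)) {
    res <- res + ins[c]
    if (occ[c]) {
      res <- res + 1L
      out[c] <- res
    }
  }
  out
}

#' Recover the ungapped sequences of an alignment
#'
#' Concatenates, per row, the match-column occupancies and insert residues
#' in order. Requires insert residues to be present (i.e. the alignment has
#' not been stripped to insert counts).
#'
#' @param a A `match_alignment`.
#' @return Named character vector of ungapped sequences.
#' @export
ungapped_sequences <- function(a) {
  if (nrow(a$inserts) > 0L && anyNA(a$inserts$residues)) {
    stop("ungapped_sequences(): insert residues have been stripped to counts")
  }
  n <- nrow(a$match); M <- ncol(a$match)
  out <- character(n)
  for (i in seq_len(n)) {
    ins <- a$inserts[a$inserts$row == i, , drop = FALSE]
    pieces <- character(0)
    for (c in 0:M) {
      hit <- ins$after_col == c
      if (c > 0L && a$match[i, c] != "-") pieces <- c(pieces, a$match[i, c])
      if (any(hit)) pieces <- c(pieces, ins$residues[hit])
    }
    out[i] <- paste(pieces, collapse = "")
  }
  setNames(out, a$ids)
}

#' Read an alignment with match/insert annotation
#'
#' Two dialects are supported. Stockholm 1.0 requires a `#=GC RF` reference
#' line: `.` marks insert columns, any other symbol a match column.
#' Aligned FASTA follows the Pfam case convention: uppercase and `-` in
#' match columns, lowercase and `.` in insert columns; every column must be
#' consistently one or the other.
#'
#' @param path File path.
#' @param dialect `"stockholm"` or `"aligned_fasta"`.
#' @return A [match_alignment()].
#' @export
read_alignment <- function(path, dialect = c("stockholm", "aligned_fasta")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (dialect == "stockholm") {
    parse_stockholm(lines, path)
  } else {
    parse_aligned_fasta(lines, path)
  }
}

parse_stockholm <- function(lines, path) {
  if (length(lines) == 0L || !grepl("^# STOCKHOLM", lines[1])) {
    stop("read_alignment(): '", path, "' is not a Stockholm 1.0 file")
  }
  rf <- character(0)
  ids <- character(0)
  seqs <- list()
  for (ln in lines[-1]) {
    if (ln == "//" || ln == "" ) next
    if (grepl("^#=GC\\s+RF\\s+", ln)) {
      rf <- c(rf, sub("^#=GC\\s+RF\\s+", "", ln))
    } else if (grepl("^#", ln)) {
      next
    } else {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(parts) != 2L) {
        stop("read_alignment(): malformed sequence line in '", path, "': ", ln)
      }
      if (parts[1] %in% ids) {
        seqs[[parts[1]]] <- paste0(seqs[[parts[1]]], parts[2])
      } else {
        ids <- c(ids, parts[1])
        seqs[[parts[1]]] <- parts[2]
      }
    }
  }
  if (length(rf) == 0L) {
    stop("read_alignment(): Stockholm file '", path,
         "' lacks the required #=GC RF match-column annotation")
  }
  rf <- paste(rf, collapse = "")
  widths <- nchar(unlist(seqs))
  if (length(unique(widths)) != 1L) {
    bad <- ids[widths != nchar(rf)][1]
    stop("read_alignment(): ragged alignment; row '", bad,
         "' length disagrees with the RF line")
  }
  if (widths[1] != nchar(rf)) {
    stop("read_alignment(): RF length (", nchar(rf),
         ") disagrees with row length (", widths[1], ")")
  }
  is_match <- strsplit(rf, "")[[1]] != "."
  build_from_columns(ids, seqs, is_match)
}

parse_aligned_fasta <- function(lines, path) {
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("read_alignment(): no FASTA records in '", path, "'")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- list()
  for (k in seq_along(hdr)) {
    body <- lines[seq(hdr[k] + 1L, ends[k])]
    seqs[[ids[k]]] <- paste(body, collapse = "")
  }
  widths <- nchar(unlist(seqs))
  if (length(unique(widths)) != 1L) {
    bad <- ids[widths != widths[1]][1]
    stop("read_alignment(): ragged alignment; row '", bad, "' has length ",
         nchar(seqs[[bad]]), " but row '", ids[1], "' has ", widths[1])
  }
  mat <- do.call(rbind, strsplit(unlist(seqs), ""))
  upper <- matrix(mat %in% c(LETTERS, "-"), nrow(mat))
  lower <- matrix(mat %in% c(letters, "."), nrow(mat))
  col_match <- apply(upper, 2, all)
  col_ins <- apply(lower, 2, all)
  if (any(!col_match & !col_ins)) {
    stop("read_alignment(): column ", which(!col_match & !col_ins)[1],
         " mixes match (uppercase/-) and insert (lowercase/.) symbols")
  }
  build_from_columns(ids, seqs, col_match)
}

# shared: assemble a match_alignment from full column strings + match labels
build_from_columns <- function(ids, seqs, is_match) {
  mat <- do.call(rbind, strsplit(unlist(seqs[ids]), ""))
  n <- length(ids)
  mcols <- which(is_match)
  match_mat <- toupper(mat[, mcols, drop = FALSE])
  match_mat[match_mat == "."] <- "-"
  # slot index (0..M) for every full column: number of match columns at or
  # before it
  slot <- cumsum(is_match)
  ins_rows <- integer(0); ins_after <- integer(0); ins_res <- character(0)
  icols <- which(!is_match)
  if (length(icols) > 0L) {
    for (i in seq_len(n)) {
      resid <- toupper(mat[i, icols])
      keep <- resid != "." & resid != "-"
      if (!any(keep)) next
      anchors <- slot[icols][keep]
      for (k in unique(anchors)) {
        ins_rows <- c(ins_rows, i)
        ins_after <- c(ins_after, k)
        ins_res <- c(ins_res, paste(resid[keep][anchors == k], collapse = ""))
      }
    }
  }
  inserts <- data.frame(row = ins_rows, after_col = ins_after,
                        residues = ins_res, count = nchar(ins_res),
                        stringsAsFactors = FALSE)
  match_alignment(match_mat, ids, inserts)
}

#' Write an alignment with match/insert annotation
#'
#' Inverse of [read_alignment()]: insert runs are expanded into explicit
#' insert columns (one block per anchor position, padded with `.`), match
#' columns are written uppercase with `-` for deletions. Stockholm output
#' carries a `#=GC RF` line (`x` = match, `.` = insert). An alignment
#' stripped to insert counts can only be written without its insert
#' residues, which [strip_insert_columns()] has discarded; writing one is
#' an error.
#'
#' @param a A `match_alignment` (with insert residues present).
#' @param path Output file path.
#' @param dialect `"stockholm"` or `"aligned_fasta"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(a, path, dialect = c("stockholm", "aligned_fasta")) {
  dialect <- match.arg(dialect)
  if (nrow(a$inserts) > 0L && anyNA(a$inserts$residues)) {
    stop("write_alignment(): alignment has been stripped to insert counts; ",
         "insert residues are no longer available")
  }
  n <- nrow(a$match); M <- ncol(a$match)
  cnt <- insert_count_matrix(a)
  width <- apply(cnt, 2, max)                  # insert block widths, slots 0..M
  rows <- character(n)
  for (i in seq_len(n)) {
    ins <- a$inserts[a$inserts$row == i, , drop = FALSE]
    pieces <- character(0)
    for (c in 0:M) {
      if (c > 0L) pieces <- c(pieces, a$match[i, c])
      if (width[c + 1L] > 0L) {
        hit <- which(ins$after_col == c)
        run <- if (length(hit) == 1L) tolower(ins$residues[hit]) else ""
        pieces <- c(pieces,
                    paste0(run, strrep(".", width[c + 1L] - nchar(run))))
      }
    }
    rows[i] <- paste(pieces, collapse = "")
  }
  rf_pieces <- character(0)
  for (c in 0:M) {
    if (c > 0L) rf_pieces <- c(rf_pieces, "x")
    if (width[c + 1L] > 0L) rf_pieces <- c(rf_pieces, strrep(".", width[c + 1L]))
  }
  rf <- paste(rf_pieces, collapse = "")
  if (dialect == "stockholm") {
    w <- max(nchar(a$ids), nchar("#=GC RF"))
    out <- c("# STOCKHOLM 1.0",
             sprintf("%-*s %s", w, a$ids, rows),
             sprintf("%-*s %s", w, "#=GC RF", rf),
             "//")
  } else {
    out <- as.vector(rbind(paste0(">", a$ids), rows))
  }
  writeLines(out, path)
  invisible(path)
}

#' Remove insert columns, keeping per-row insert counts
#'
#' Reduces an alignment to its match columns. The residues that occupied
#' insert states are discarded, but their counts stay attached between the
#' flanking match columns so that region lengths measured later still
#' account for them (variable regions of real velvet domains owe most of
#' their length to insert-state residues).
#'
#' @param a A `match_alignment`.
#' @return A `match_alignment` whose insert runs carry counts only.
#' @export
strip_insert_columns <- function(a) {
  if (nrow(a$inserts) > 0L) a$inserts$residues <- NA_character_
  a
}

#' Map reference-protein residue numbers to match columns
#'
#' Builds the bijection between a chosen reference row's residue numbering
#' (1-based in its parent protein) and the alignment's match columns, the
#' device that lets conserved columns be read out as residues of, say,
#' VelB (G240, L331) and carried across to VosA or VeA.
#'
#' @param a A `match_alignment`.
#' @param reference_id Row id of the reference sequence.
#' @param parent_offset Parent-protein position of the row's first residue
#'   (so residue index `r` in the row is residue number
#'   `parent_offset + r - 1`).
#' @return Object of class `reference_map`: list with `reference_id` and a
#'   `table` (`data.frame` of `column`, `residue_no`, `residue`) covering
#'   the match-assigned residues of the reference row.
#' @export
build_reference_map <- function(a, reference_id, parent_offset = 1L) {
  i <- match(reference_id, a$ids)
  if (is.na(i)) {
    stop("build_reference_map(): reference id '", reference_id,
         "' not present in alignment")
  }
  if (any(a$match[i, ] == "X")) {
    stop("build_reference_map(): reference row contains X; ",
         "residue numbering would be ambiguous")
  }
  rm_idx <- row_map(a, i)
  keep <- !is.na(rm_idx)
  tab <- data.frame(column = which(keep),
                    residue_no = as.integer(parent_offset) + rm_idx[keep] - 1L,
                    residue = a$match[i, keep],
                    stringsAsFactors = FALSE)
  structure(list(reference_id = reference_id, table = tab,
                 n_columns = ncol(a$match)),
            class = "reference_map")
}

#' @export
print.reference_map <- function(x, ...) {
  cat(sprintf("<reference_map> %s: %d residue <-> column pairs\n",
              x$reference_id, nrow(x$table)))
  invisible(x)
}

#' Look up the match column of a reference residue
#' @param rm A `reference_map`.
#' @param residue_no Residue number in the reference's parent protein.
#' @return Match column index, or `NA` if the residue sits in an insert.
#' @export
residue_to_column <- function(rm, residue_no) {
  hit <- match(residue_no, rm$table$residue_no)
  rm$table$column[hit]
}

#' Look up the reference residue at a match column
#' @param rm A `reference_map`.
#' @param column Match column index.
#' @return One-row `data.frame` (`residue_no`, `residue`); `NA`s when the
#'   reference is deleted at that column.
#' @export
column_to_residue <- function(rm, column) {
  hit <- match(column, rm$table$column)
  data.frame(residue_no = rm$table$residue_no[hit],
             residue = ifelse(is.na(hit), NA_character_, rm$table$residue[hit]),
             stringsAsFactors = FALSE)
}

#' Export a reference map as two-column TSV
#' @param rm A `reference_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_map <- function(rm, path) {
  write.table(rm$table[, c("residue_no", "column")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
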