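# Readers and writers for every external representation the pipeline touches.
#
# Coordinate conventions: everything inside the package is 0-based, half-open,
# in transcript space. The CT and SHAPE formats are 1-based per their
# standards; the conversion happens here and nowhere else.

# ---------------------------------------------------------------------------
# Base count matrix

#' Construct and validate a per-cell per-base count table
#'
#' The central ingestion contract of the pipeline: one row per
#' (cell, transcript, position, condition) with the number of reads covering
#' the base and the number carrying a mutation (mismatches and indels are
#' aggregated into a single count). Positions are 0-based transcript
#' coordinates.
#'
#' @param df data.frame with columns `cell_id`, `transcript_id`, `position`,
#'   `coverage`, `mutated`, `condition` (`"treated"` or `"control"`).
#' @return the validated data.frame with class `base_counts`.
#' @export
base_counts <- function(df) {
  required <- c("cell_id", "transcript_id", "position", "coverage",
                "mutated", "condition")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop_format(sprintf("base count table is missing column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  df <- df[required]
  df$cell_id <- as.character(df$cell_id)
  df$transcript_id <- as.character(df$transcript_id)
  for (col in c("position", "coverage", "mutated")) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v))
      stop_validation(sprintf("column '%s' must be numeric without NA", col))
    bad <- which(v < 0 | v != round(v))
    if (length(bad) > 0)
      stop_validation(sprintf(
        "column '%s' has negative or non-integer value at row %d",
        col, bad[1]))
    df[[col]] <- as.integer(v)
  }
  bad_cond <- which(!df$condition %in% c("treated", "control"))
  if (length(bad_cond) > 0)
    stop_validation(sprintf(
      "condition must be 'treated' or 'control' (row %d)", bad_cond[1]))
  bad <- which(df$mutated > df$coverage)
  if (length(bad) > 0)
    stop_validation(sprintf(
      "mutated > coverage at row %d (mutated=%d, coverage=%d)",
      bad[1], df$mutated[bad[1]], df$coverage[bad[1]]))
  key <- paste(df$cell_id, df$transcript_id, df$position, df$condition,
               sep = "\r")
  if (anyDuplicated(key))
    stop_validation(sprintf(
      "duplicate (cell, transcript, position, condition) record at row %d",
      anyDuplicated(key)))
  class(df) <- c("base_counts", "data.frame")
  df
}

#' Read a per-cell per-base count table
#'
#' Tab-separated with header
#' `cell_id transcript_id position coverage mutated condition`.
#'
#' @param path file path.
#' @return a [base_counts] data.frame.
#' @export
read_base_counts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c(cell_id = "character",
                                         transcript_id = "character"),
                          stringsAsFactors = FALSE)
  base_counts(df)
}

#' Write a per-cell per-base count table
#' @param x a [base_counts] data.frame.
#' @param path output path.
#' @export
write_base_counts <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Reference secondary structures

new_reference_structure <- function(transcript_id, partner_index,
                                    sequence = NULL,
                                    solvent_accessibility = NULL) {
  n <- length(partner_index)
  paired <- partner_index >= 0
  # partner symmetry is a structural invariant, not a user input error
  idx <- which(paired)
  if (any(partner_index[idx] + 1L > n) ||
      any(partner_index[partner_index[idx] + 1L] != idx - 1L))
    stop_format("asymmetric base pairing: partner(partner(i)) != i")
  structure(list(transcript_id = transcript_id,
                 length = n,
                 paired = paired,
                 partner_index = as.integer(partner_index),
                 sequence = sequence,
                 solvent_accessibility = solvent_accessibility),
            class = "reference_structure")
}

#' @export
print.reference_structure <- function(x, ...) {
  cat(sprintf("<reference_structure> %s: %d nt, %d paired, %d unpaired\n",
              x$transcript_id, x$length, sum(x$paired), sum(!x$paired)))
  invisible(x)
}

BRACKET_OPEN  <- c("(", "[", "{", "<")
BRACKET_CLOSE <- c(")", "]", "}", ">")

parse_structure_line <- function(struct, id = "") {
  chars <- strsplit(struct, "")[[1]]
  known <- chars %in% c(BRACKET_OPEN, BRACKET_CLOSE, ".")
  if (!all(known))
    stop_format(sprintf(
      "unknown structure character '%s' at position %d in record '%s'",
      chars[which(!known)[1]], which(!known)[1], id))
  partner <- rep(-1L, length(chars))
  for (tier in seq_along(BRACKET_OPEN)) {
    stack <- integer(0)
    op <- BRACKET_OPEN[tier]; cl <- BRACKET_CLOSE[tier]
    for (i in seq_along(chars)) {
      if (chars[i] == op) {
        stack <- c(stack, i)
      } else if (chars[i] == cl) {
        if (length(stack) == 0)
          stop_format(sprintf(
            "unbalanced '%s' at position %d (bracket tier %d) in record '%s'",
            cl, i, tier, id))
        j <- stack[length(stack)]
        stack <- stack[-length(stack)]
        partner[i] <- j - 1L
        partner[j] <- i - 1L
      }
    }
    if (length(stack) > 0)
      stop_format(sprintf(
        "%d unmatched '%s' (bracket tier %d) in record '%s'",
        length(stack), op, tier, id))
  }
  partner
}

#' Read reference structures from a dot-bracket file
#'
#' FASTA-like records: a `>name` line, a sequence line, and a structure line
#' over the alphabet `().[]{}<>`. Each bracket tier (pseudoknot level) must
#' balance independently. Unknown characters are a hard error because
#' benchmarking labels depend on them.
#'
#' @param path file path.
#' @return a single [reference_structure] when the file holds one record,
#'   otherwise a named list of them.
#' @export
read_dot_bracket <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0)
    stop_format("no '>' record header found in dot-bracket file")
  out <- list()
  for (s in starts) {
    if (s + 2 > length(lines))
      stop_format(sprintf("truncated record '%s'", sub("^>", "", lines[s])))
    id <- trimws(sub("^>", "", lines[s]))
    seq_line <- trimws(lines[s + 1])
    struct_line <- trimws(lines[s + 2])
    if (nchar(seq_line) != nchar(struct_line))
      stop_format(sprintf(
        "sequence (%d nt) and structure (%d) length mismatch in record '%s'",
        nchar(seq_line), nchar(struct_line), id))
    partner <- parse_structure_line(struct_line, id)
    out[[id]] <- new_reference_structure(id, partner, sequence = seq_line)
  }
  if (length(out) == 1) out[[1]] else out
}

#' Write a reference structure as dot-bracket
#'
#' Nested pairs are written with `()`; crossing (pseudoknotted) pairs fall
#' back to `[]`, `{}`, `<>` tiers as needed.
#'
#' @param structure a [reference_structure].
#' @param path output path.
#' @export
write_dot_bracket <- function(structure, path) {
  n <- structure$length
  chars <- rep(".", n)
  assigned <- rep(FALSE, n)
  pairs <- which(structure$partner_index > seq_len(n) - 1L)
  for (tier in seq_along(BRACKET_OPEN)) {
    for (i in pairs) {
      if (assigned[i]) next
      j <- structure$partner_index[i] + 1L
      # a pair fits this tier if it crosses no pair already assigned to it
      tier_pairs <- which(chars == BRACKET_OPEN[tier])
      crosses <- any(vapply(tier_pairs, function(a) {
        b <- structure$partner_index[a] + 1L
        (a < i && i < b && b < j) || (i < a && a < j && j < b)
      }, TRUE))
      if (!crosses) {
        chars[i] <- BRACKET_OPEN[tier]
        chars[j] <- BRACKET_CLOSE[tier]
        assigned[i] <- assigned[j] <- TRUE
      }
    }
    if (all(assigned[pairs])) break
  }
  if (!all(assigned[pairs]))
    stop_validation("structure needs more than 4 pseudoknot tiers")
  seq_line <- structure$sequence %||% strrep("N", n)
  writeLines(c(paste0(">", structure$transcript_id), seq_line,
               paste(chars, collapse = "")), path)
  invisible(path)
}

#' Read a reference structure from a CT file
#'
#' Standard connectivity-table layout: a header line whose first field is the
#' base count, then six columns (index, base, previous, next, pairing
#' partner, natural index), all 1-based; partner 0 means unpaired. Converted
#' to the package's 0-based `partner_index` (-1 when unpaired).
#'
#' @param path file path.
#' @return a [reference_structure].
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(header[1]))
  if (is.na(n)) stop_format("CT header does not start with a base count")
  id <- if (length(header) > 1) paste(header[-1], collapse = " ") else "ct"
  if (length(lines) < n + 1)
    stop_format(sprintf("CT file has %d base lines, header promises %d",
                        length(lines) - 1, n))
  fields <- strsplit(trimws(lines[2:(n + 1)]), "\\s+")
  mat <- t(vapply(fields, function(f) {
    if (length(f) < 6) stop_format("CT base line with fewer than 6 columns")
    c(as.integer(f[1]), as.integer(f[5]))
  }, integer(2)))
  base <- vapply(fields, `[`, "", 2)
  if (any(mat[, 1] != seq_len(n)))
    stop_format("CT index column is not 1..n")
  pair <- mat[, 2]
  if (any(pair < 0 | pair > n))
    stop_format("CT pair column out of range")
  idx <- which(pair > 0)
  bad <- idx[pair[pair[idx]] != idx]
  if (length(bad) > 0)
    stop_format(sprintf(
      "asymmetric CT pair assignment between positions %d and %d (1-based)",
      bad[1], pair[bad[1]]))
  partner <- ifelse(pair == 0, -1L, pair - 1L)
  new_reference_structure(id, partner, sequence = paste(base, collapse = ""))
}

#' Write a reference structure as a CT file
#' @param structure a [reference_structure].
#' @param path output path.
#' @export
write_ct <- function(structure, path) {
  n <- structure$length
  base <- if (is.null(structure$sequence)) rep("N", n)
          else strsplit(structure$sequence, "")[[1]]
  pair <- ifelse(structure$partner_index < 0, 0L,
                 structure$partner_index + 1L)
  lines <- c(paste(n, structure$transcript_id),
             sprintf("%d %s %d %d %d %d", seq_len(n), base,
                     seq_len(n) - 1L, c(seq_len(n - 1) + 1L, 0L), pair,
                     seq_len(n)))
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Feature intervals (BED in transcript space)

#' Read feature/RBP binding intervals from a BED file
#'
#' BED3+1 in transcript coordinates: the chrom column holds the transcript
#' id, the fourth column the feature (e.g. RBP) name; 0-based half-open.
#' Extra columns beyond the fourth are ignored.
#'
#' @param path file path.
#' @return data.frame (class `interval_set`) with columns `transcript_id`,
#'   `start`, `end`, `feature_name`.
#' @export
read_intervals_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0) return(interval_set(data.frame(
    transcript_id = character(0), start = integer(0), end = integer(0),
    feature_name = character(0), stringsAsFactors = FALSE)))
  fields <- strsplit(lines, "\t| +")
  df <- data.frame(
    transcript_id = vapply(fields, `[`, "", 1),
    start = as.integer(vapply(fields, `[`, "", 2)),
    end = as.integer(vapply(fields, `[`, "", 3)),
    feature_name = vapply(fields, function(f)
      if (length(f) >= 4) f[4] else ".", ""),
    stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end))
  if (length(bad) > 0)
    stop_format(sprintf("non-numeric BED coordinates at line %d", bad[1]))
  bad <- which(df$start >= df$end)
  if (length(bad) > 0)
    stop_validation(sprintf("start >= end at BED line %d", bad[1]))
  interval_set(df)
}

#' Validate an interval set
#' @param df data.frame with transcript_id, start, end, feature_name.
#' @return the data.frame with class `interval_set`.
#' @export
interval_set <- function(df) {
  if (any(df$start >= df$end))
    stop_validation("interval with start >= end")
  if (any(!nzchar(df$feature_name)))
    stop_validation("empty feature name")
  class(df) <- c("interval_set", "data.frame")
  df
}

#' Write intervals as BED (transcript space)
#' @param x an `interval_set` data.frame.
#' @param path output path.
#' @export
write_intervals_bed <- function(x, path) {
  utils::write.table(
    data.frame(x$transcript_id, x$start, x$end, x$feature_name),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# SHAPE reactivity files

#' Write a reactivity profile in SHAPE two-column format
#'
#' One line per position: 1-based position and reactivity; masked
#' (no-coverage) positions are written as -999 per the SHAPE convention.
#'
#' @param profile a [reactivity_profile] or numeric vector with NA at masked
#'   positions.
#' @param path output path.
#' @export
write_shape <- function(profile, path) {
  r <- if (inherits(profile, "reactivity_profile")) profile$reactivity
       else profile
  n <- length(r)
  vals <- ifelse(is.na(r), "-999", sprintf("%.15g", r))
  if (n == 0) {
    writeLines(character(0), path)
  } else {
    writeLines(paste(seq_len(n), vals), path)
  }
  invisible(path)
}

#' Read a SHAPE two-column reactivity file
#' @param path file path.
#' @param transcript_id transcript label to attach.
#' @return a [reactivity_profile] with -999 entries mapped to masked.
#' @export
read_shape <- function(path, transcript_id = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(reactivity_profile(numeric(0), transcript_id = transcript_id))
  fields <- strsplit(trimws(lines), "\\s+")
  pos <- as.integer(vapply(fields, `[`, "", 1))
  val <- as.numeric(vapply(fields, `[`, "", 2))
  if (anyNA(pos) || anyNA(val))
    stop_format("malformed SHAPE line (expected: position value)")
  n <- max(pos)
  r <- rep(NA_real_, n)
  r[pos] <- ifelse(val == -999, NA_real_, val)
  reactivity_profile(r, transcript_id = transcript_id)
}

# ---------------------------------------------------------------------------
# Expression, region annotation, accessibility

#' Read a per-cell expression table
#'
#' TSV with header `cell_id gene_id expression`; expression values are
#' non-negative and each (cell, gene) pair appears at most once.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  expression_table(df)
}

#' Validate an expression table
#' @param df data.frame with cell_id, gene_id, expression.
#' @return the data.frame with class `expression_table`.
#' @export
expression_table <- function(df) {
  required <- c("cell_id", "gene_id", "expression")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop_format(sprintf("expression table missing column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  df$cell_id <- as.character(df$cell_id)
  df$gene_id <- as.character(df$gene_id)
  if (!is.numeric(df$expression) || anyNA(df$expression))
    stop_validation("expression must be numeric without NA")
  bad <- which(df$expression < 0)
  if (length(bad) > 0)
    stop_validation(sprintf("negative expression at row %d", bad[1]))
  key <- paste(df$cell_id, df$gene_id, sep = "\r")
  if (anyDuplicated(key))
    stop_validation(sprintf("duplicate (cell, gene) entry at row %d",
                            anyDuplicated(key)))
  class(df) <- c("expression_table", "data.frame")
  df
}

#' Write an expression table
#' @param x an `expression_table`.
#' @param path output path.
#' @export
write_expression_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read transcript region annotation
#'
#' TSV with header `transcript_id transcript_length cds_start cds_end`,
#' 0-based half-open CDS in transcript coordinates.
#'
#' @param path file path.
#' @return validated data.frame (class `region_annotation`).
#' @export
read_region_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  region_annotation(df)
}

#' Validate a region annotation table
#' @param df data.frame with transcript_id, transcript_length, cds_start,
#'   cds_end.
#' @return the data.frame with class `region_annotation`.
#' @export
region_annotation <- function(df) {
  required <- c("transcript_id", "transcript_length", "cds_start", "cds_end")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop_format(sprintf("region annotation missing column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  df$transcript_id <- as.character(df$transcript_id)
  ok <- df$cds_start >= 0 & df$cds_start < df$cds_end &
    df$cds_end <= df$transcript_length
  if (!all(ok))
    stop_validation(sprintf(
      "invalid CDS bounds for transcript '%s' (need 0 <= cds_start < cds_end <= length)",
      df$transcript_id[which(!ok)[1]]))
  class(df) <- c("region_annotation", "data.frame")
  df
}

#' Write a region annotation table
#' @param x a `region_annotation`.
#' @param path output path.
#' @export
write_region_annotation <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a solvent accessibility table
#'
#' TSV with two columns: 1-based position and 2'-OH solvent accessibility
#' (square Angstroms). Returns a numeric vector indexed by position (NA where
#' absent).
#'
#' @param path file path.
#' @return numeric vector.
#' @export
read_accessibility <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  pos <- as.integer(df[[1]]); val <- as.numeric(df[[2]])
  if (anyNA(pos) || anyNA(val) || any(pos < 1))
    stop_format("accessibility table must be '1-based-position<TAB>value'")
  if (any(val < 0)) stop_validation("negative solvent accessibility")
  out <- rep(NA_real_, max(pos))
  out[pos] <- val
  out
}

#' Read a transcript sequence table
#'
#' TSV with header `transcript_id sequence` (one row per transcript).
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_sequences <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "sequence") %in% names(df)))
    stop_format("sequence table needs columns transcript_id, sequence")
  stats::setNames(toupper(df$sequence), df$transcript_id)
}

#' Write a transcript sequence table
#' @param sequences named character vector.
#' @param path output path.
#' @export
write_sequences <- function(sequences, path) {
  utils::write.table(
    data.frame(transcript_id = names(sequences), sequence = unname(sequences)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
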