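#' @import data.table
#' @importFrom stats setNames
NULL

# FAERS quarterly ASCII dialect: one "$"-delimited header line, one "$"-
# delimited row per report entry, no quoting or escaping. Field names changed
# case across years, so they are normalized to lower case on read.

.faers_kinds <- c("DEMO", "DRUG", "REAC", "THER", "OUTC", "INDI", "RPSR")

# Mandatory columns per table kind (lower case). Extra columns are preserved.
.faers_schema <- list(
  DEMO = c("primaryid", "caseid", "fda_dt"),
  DRUG = c("primaryid", "drug_seq", "role_cod", "drugname"),
  REAC = c("primaryid", "pt"),
  THER = c("primaryid", "start_dt"),
  OUTC = c("primaryid", "outc_cod"),
  INDI = c("primaryid", "indi_pt"),
  RPSR = c("primaryid", "rpsr_cod")
)

.match_kind <- function(table_kind) {
  match.arg(toupper(table_kind), .faers_kinds)
}

#' Construct a FAERS table object
#'
#' Wraps a `data.table` of character columns as a typed FAERS quarterly table,
#' validating the mandatory columns for its kind and the presence of a
#' non-empty `primaryid` on every row.
#'
#' @param rows a `data.frame`/`data.table` of character fields (lower-case
#'   names), one row per table entry.
#' @param table_kind one of `"DEMO"`, `"DRUG"`, `"REAC"`, `"THER"`, `"OUTC"`,
#'   `"INDI"`, `"RPSR"`.
#' @param quarter_label free-text quarter tag, e.g. `"2018Q3"`.
#' @return a `faers_table`: a `data.table` with attributes `table_kind` and
#'   `quarter_label`.
#' @export
faers_table <- function(rows, table_kind, quarter_label = NA_character_) {
  table_kind <- .match_kind(table_kind)
  dt <- as.data.table(rows)
  setnames(dt, tolower(names(dt)))
  need <- .faers_schema[[table_kind]]
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop(sprintf("%s table is missing mandatory column(s): %s",
                 table_kind, paste(miss, collapse = ", ")), call. = FALSE)
  }
  for (j in names(dt)) {
    if (!is.character(dt[[j]])) set(dt, j = j, value = as.character(dt[[j]]))
  }
  pid <- dt$primaryid
  if (anyNA(pid) || any(!nzchar(pid))) {
    stop(sprintf("%s table has rows with empty PRIMARYID", table_kind),
         call. = FALSE)
  }
  setattr(dt, "table_kind", table_kind)
  setattr(dt, "quarter_label", quarter_label)
  setattr(dt, "class", c("faers_table", class(dt)))
  dt[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.faers_table <- function(x, ...) {
  cat(sprintf("<faers_table %s%s: %d rows, %d fields>\n",
              attr(x, "table_kind"),
              if (is.na(attr(x, "quarter_label"))) ""
              else paste0(" ", attr(x, "quarter_label")),
              nrow(x), ncol(x)))
  NextMethod()
}

#' Read a FAERS-style "$"-delimited quarterly table
#'
#' Parses the public FAERS ASCII dialect: a `"$"`-delimited header followed by
#' one delimited line per entry, with no quoting. Empty fields become `NA`.
#' A trailing delimiter (and the short lines it produces under `strsplit`
#' semantics) is tolerated by right-padding with missing values. Lines with
#' more fields than the header are kept only when the surplus fields are all
#' empty; otherwise the line is skipped and recorded. Input is decoded as
#' UTF-8; undecodable bytes are replaced and counted.
#'
#' @param path path to the `.txt` file.
#' @param table_kind the table's kind (see [faers_table()]).
#' @param quarter_label optional quarter tag stored on the result.
#' @return a `faers_table`. Parse anomalies (skipped lines, replaced bytes)
#'   are attached as attribute `"anomalies"`, a list suitable for JSON
#'   logging.
#' @export
read_faers_table <- function(path, table_kind, quarter_label = NA_character_) {
  table_kind <- .match_kind(table_kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw_lines <- readLines(path, warn = FALSE)
  lines <- iconv(raw_lines, from = "UTF-8", to = "UTF-8", sub = "�")
  n_replaced <- sum(lines != raw_lines, na.rm = TRUE)
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  header <- tolower(strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]])
  header <- trimws(header)
  need <- .faers_schema[[table_kind]]
  miss <- setdiff(need, header)
  if (length(miss)) {
    stop(sprintf("%s header at %s lacks mandatory column(s): %s",
                 table_kind, path, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  ncols <- length(header)
  body <- lines[-1L]
  skipped <- integer(0)
  if (length(body)) {
    parts <- strsplit(body, "$", fixed = TRUE)
    nf <- lengths(parts)
    over <- which(nf > ncols)
    if (length(over)) {
      ok_over <- vapply(parts[over], function(p) {
        all(!nzchar(p[-seq_len(ncols)]))
      }, logical(1))
      parts[over[ok_over]] <- lapply(parts[over[ok_over]], `[`, seq_len(ncols))
      skipped <- over[!ok_over] + 1L  # 1-based file line numbers
      keep <- setdiff(seq_along(parts), over[!ok_over])
      parts <- parts[keep]
      nf <- lengths(parts)
    }
    mat <- matrix(NA_character_, nrow = length(parts), ncol = ncols)
    for (j in seq_len(ncols)) {
      has <- nf >= j
      mat[has, j] <- vapply(parts[has], `[[`, character(1), j)
    }
    mat[!is.na(mat) & !nzchar(mat)] <- NA_character_
    dt <- as.data.table(mat)
    setnames(dt, header)
  } else {
    dt <- setnames(as.data.table(matrix(character(0), 0, ncols)), header)
  }
  out <- faers_table(dt, table_kind, quarter_label)
  setattr(out, "anomalies",
          list(skipped_lines = skipped, undecodable_byte_lines = n_replaced))
  out
}

#' Write a FAERS-style "$"-delimited table
#'
#' Inverse of [read_faers_table()]: lossless round-trip for all non-missing
#' fields. Because the dialect has no quoting, a literal `"$"` inside a value
#' cannot be represented and raises an error.
#'
#' @param table a `faers_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(table, path) {
  stopifnot(inherits(table, "faers_table"))
  if (anyNA(table$primaryid) || any(!nzchar(table$primaryid))) {
    stop("row with missing PRIMARYID cannot be written", call. = FALSE)
  }
  for (j in names(table)) {
    if (any(grepl("$", table[[j]], fixed = TRUE))) {
      stop(sprintf("column '%s' contains a literal '$'; not representable in the FAERS dialect", j),
           call. = FALSE)
    }
  }
  mat <- as.matrix(table)
  mat[is.na(mat)] <- ""
  lines <- c(paste(names(table), collapse = "$"),
             if (nrow(mat)) apply(mat, 1L, paste, collapse = "$"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Assemble quarterly tables into a linked bundle
#'
#' Links the tables of one quarter by `PRIMARYID`. Rows in non-DEMO tables
#' whose `primaryid` has no DEMO row are orphans: they are excluded and
#' counted. Each table is keyed by `primaryid`, which serves as the bundle
#' index.
#'
#' @param tables a list of `faers_table`s (any order; kinds inferred). DEMO,
#'   DRUG and REAC are required.
#' @return a `faers_bundle`: list with elements `tables` (named by kind,
#'   keyed data.tables), `orphans` (named integer counts), `quarter_label`.
#' @export
assemble_quarter <- function(tables) {
  if (inherits(tables, "faers_bundle")) tables <- tables$tables
  kinds <- vapply(tables, attr, character(1), which = "table_kind")
  names(tables) <- kinds
  if (!"DEMO" %in% kinds) stop("DEMO table is required", call. = FALSE)
  miss <- setdiff(c("DRUG", "REAC"), kinds)
  if (length(miss)) {
    stop("missing required table(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  demo <- tables[["DEMO"]]
  if (anyDuplicated(demo$primaryid)) {
    stop("DEMO contains duplicated PRIMARYIDs", call. = FALSE)
  }
  ids <- demo$primaryid
  orphans <- setNames(integer(length(tables)), names(tables))
  out <- list()
  for (k in names(tables)) {
    dt <- tables[[k]]
    if (k != "DEMO") {
      drop <- !(dt$primaryid %in% ids)
      orphans[[k]] <- sum(drop)
      if (any(drop)) dt <- dt[!drop]
    }
    dt <- copy(dt)
    setkeyv(dt, "primaryid")
    setattr(dt, "table_kind", k)
    setattr(dt, "class", c("faers_table", class(dt)[!class(dt) %in% "faers_table"]))
    out[[k]] <- dt
  }
  structure(
    list(tables = out, orphans = orphans,
         quarter_label = attr(demo, "quarter_label")),
    class = "faers_bundle"
  )
}

#' @export
print.faers_bundle <- function(x, ...) {
  cat(sprintf("<faers_bundle%s: %d reports>\n",
              if (is.na(x$quarter_label %||% NA)) ""
              else paste0(" ", x$quarter_label),
              nrow(x$tables$DEMO)))
  for (k in names(x$tables)) {
    cat(sprintf("  %s: %d rows (%d orphans excluded)\n",
                k, nrow(x$tables[[k]]), x$orphans[[k]]))
  }
  invisible(x)
}

#' Rows of every table for one report
#'
#' @param bundle a `faers_bundle`.
#' @param primaryid a single report identifier.
#' @return named list of data.tables, one per table kind present.
#' @export
bundle_rows <- function(bundle, primaryid) {
  stopifnot(inherits(bundle, "faers_bundle"), length(primaryid) == 1L)
  wanted_id <- as.character(primaryid)
  lapply(bundle$tables, function(dt) dt[J(wanted_id), nomatch = NULL])
}

#' Write a bundle as a directory of FAERS-style files
#'
#' @param bundle a `faers_bundle`.
#' @param dir output directory (created if absent). One `<kind>.txt` per
#'   table.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "faers_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in names(bundle$tables)) {
    write_faers_table(bundle$tables[[k]], file.path(dir, paste0(k, ".txt")))
  }
  invisible(dir)
}

#' Read a directory of FAERS-style files into a bundle
#'
#' @param dir directory containing `<KIND>.txt` files (at least DEMO, DRUG,
#'   REAC).
#' @param quarter_label optional quarter tag.
#' @return a `faers_bundle`.
#' @export
read_bundle <- function(dir, quarter_label = NA_character_) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  kinds <- toupper(sub("\\.txt$", "", basename(files)))
  keep <- kinds %in% .faers_kinds
  tabs <- Map(read_faers_table, files[keep], kinds[keep],
              MoreArgs = list(quarter_label = quarter_label))
  assemble_quarter(unname(tabs))
}
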