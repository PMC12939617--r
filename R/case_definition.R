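# Case definition (MedDRA PT query sets) and drug-name standardization.

# The six cataract Preferred Terms (broad query); the narrow query is the
# single PT "Cataract". Shipped verbatim: a licensed MedDRA dictionary is
# not required for this analysis.
.cataract_pts <- data.table::data.table(
  pt_code = c("10069649", "10007739", "10007748",
              "10007759", "10044135", "10024214"),
  pt_name = c("Atopic cataract", "Cataract", "Cataract cortical",
              "Cataract nuclear", "Toxic cataract", "Lenticular opacities")
)

#' Cataract Preferred-Term query set
#'
#' @param mode `"broad"` (all six cataract PTs) or `"narrow"` (the single PT
#'   `Cataract`, 10007739, used for sensitivity analysis).
#' @return list with `name`, `pt_codes` (character), `pt_names`.
#' @export
cataract_pt_query <- function(mode = c("broad", "narrow")) {
  mode <- match.arg(mode)
  sel <- if (mode == "broad") seq_len(nrow(.cataract_pts)) else 2L
  list(name = mode,
       pt_codes = .cataract_pts$pt_code[sel],
       pt_names = .cataract_pts$pt_name[sel])
}

#' Is a report a cataract case?
#'
#' A report is a case if any of its reaction PT codes intersects the query
#' set. Because the narrow set is a subset of the broad set, every narrow
#' case is a broad case.
#'
#' @param report_pts character vector of PT codes on one report.
#' @param query a query set from [cataract_pt_query()].
#' @return logical scalar.
#' @export
is_cataract_case <- function(report_pts, query = cataract_pt_query("broad")) {
  any(as.character(report_pts) %in% query$pt_codes)
}

#' Flag case reports from a REAC table
#'
#' @param reac data.frame/data.table of REAC rows (`primaryid`, `pt` holding
#'   PT codes).
#' @param query a query set from [cataract_pt_query()].
#' @return character vector of `primaryid`s that are cases.
#' @export
flag_cataract_cases <- function(reac, query = cataract_pt_query("broad")) {
  dt <- as.data.table(reac)
  unique(dt[as.character(pt) %in% query$pt_codes, primaryid])
}

#' Normalize a verbatim drug name
#'
#' Case-, whitespace- and punctuation-insensitive canonical form: upper-cased,
#' punctuation (other than the combination separator `/`) collapsed to
#' spaces, runs of whitespace squeezed, separators tightened. Idempotent.
#'
#' @param x character vector of verbatim names.
#' @return character vector of normalized names.
#' @export
normalize_drug_name <- function(x) {
  y <- toupper(as.character(x))
  y <- gsub("[\\\\+]", "/", y)          # alternative combination separators
  y <- gsub("[^A-Z0-9/]+", " ", y)      # punctuation -> space
  y <- gsub("[[:space:]]*\\/[[:space:]]*", "/", y)
  y <- gsub("[[:space:]]+", " ", trimws(y))
  y
}

#' Load a drug-name standardization map
#'
#' The map is a plain TSV with columns `verbatim`, `generic`,
#' `is_combination` (0/1) and `drug_class` — editable and auditable. The
#' packaged default covers the study's signal drugs (glucocorticoids, CFTR
#' modulators, monoclonal antibodies, immunosuppressants, antineoplastics,
#' topiramate, filgrastim) plus common brand and salt variants. Salts and
#' esters consolidate to the base ingredient except where an explicit entry
#' keeps them distinct (e.g. prednisolone acetate vs prednisolone);
#' combination products are unique entities distinct from their components.
#'
#' @param path TSV path; default the packaged map.
#' @return a keyed `data.table` with a normalized `key` column.
#' @export
load_drug_map <- function(path = system.file("extdata", "drug_name_map.tsv",
                                             package = "faerssignal")) {
  dt <- fread(path, sep = "\t", colClasses = list(character = c("verbatim", "generic", "drug_class")))
  dt[, key := normalize_drug_name(verbatim)]
  if (anyDuplicated(dt$key)) {
    stop("drug map has duplicate verbatim entries after normalization",
         call. = FALSE)
  }
  setkey(dt, key)
  dt[]
}

#' Standardize verbatim drug names to generic entities
#'
#' Looks up the normalized verbatim in the map. Unmapped names come back as
#' their normalized verbatim with `mapped = FALSE` (and class `"other"`), so
#' the operation is idempotent on its own outputs whenever generics are also
#' present as map keys.
#'
#' @param verbatim character vector of names as reported.
#' @param map a map from [load_drug_map()].
#' @return a `data.table` with columns `verbatim`, `generic`, `mapped`,
#'   `is_combination`, `drug_class`.
#' @export
standardize_drug_name <- function(verbatim, map = load_drug_map()) {
  nkey <- normalize_drug_name(verbatim)
  hit <- map[setnames(data.table(nkey), "key"), on = "key",
             .(generic, is_combination, drug_class)]
  out <- data.table(
    verbatim = as.character(verbatim),
    generic = fifelse(is.na(hit$generic), nkey, hit$generic),
    mapped = !is.na(hit$generic),
    is_combination = fifelse(is.na(hit$is_combination), 0L,
                             as.integer(hit$is_combination)),
    drug_class = fifelse(is.na(hit$drug_class), "other", hit$drug_class)
  )
  out[!nzchar(generic), `:=`(generic = NA_character_, mapped = FALSE)]
  out[]
}
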