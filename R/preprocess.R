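# Preprocessing: deduplication, age standardization, pediatric filter,
# primary-suspect selection, time-to-onset derivation.

#' Standardize FAERS ages to years
#'
#' FAERS demographic ages come with a unit code (`AGE_COD`). Conversions:
#' `YR` passthrough, `MON`/12, `WK`/52, `DY`/365, `DEC`\eqn{\times}10.
#' Any other code (including `HR`), a missing value, or a negative value maps
#' to missing.
#'
#' @param age_value numeric vector (or character coercible to numeric).
#' @param age_code character vector of unit codes, case-insensitive.
#' @return numeric vector of ages in years, `NA` where not convertible.
#' @export
standardize_age <- function(age_value, age_code) {
  v <- suppressWarnings(as.numeric(age_value))
  code <- toupper(trimws(as.character(age_code)))
  fac <- c(YR = 1, MON = 1 / 12, WK = 1 / 52, DY = 1 / 365, DEC = 10)
  out <- v * unname(fac[code])  # unknown code -> NA factor -> NA
  out[!is.na(v) & v < 0] <- NA_real_
  out
}

.num_or <- function(x) {
  # numeric comparison; if any value is non-numeric, fall back to
  # lexicographic ordering for the whole vector (deterministic)
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v) && !all(is.na(x))) {
    v <- as.numeric(factor(x, levels = sort(unique(x))))
  }
  v
}

#' Deduplicate reports by CASEID
#'
#' FDA-recommended rule: among reports sharing a `CASEID`, keep the one with
#' the latest `FDA_DT`; on ties, the largest `PRIMARYID`. `fda_dt` and
#' `primaryid` are compared numerically (lexicographic fallback for
#' non-numeric `primaryid`); `caseid` is compared as a string. Records with a
#' missing `caseid` are excluded and counted, not kept.
#'
#' @param demo a data.frame/data.table with at least `primaryid`, `caseid`,
#'   `fda_dt` columns (character).
#' @return a `data.table`, one row per caseid, sorted by `caseid`, with
#'   attribute `"counts"`: `c(input, kept, duplicates_removed,
#'   missing_caseid)`.
#' @export
deduplicate_reports <- function(demo) {
  dt <- as.data.table(demo)
  n_in <- nrow(dt)
  bad <- is.na(dt$caseid) | !nzchar(dt$caseid)
  n_bad <- sum(bad)
  dt <- dt[!bad]
  if (nrow(dt)) {
    dt[, `:=`(.fda = .num_or(fda_dt), .pid = .num_or(primaryid))]
    setorder(dt, caseid, -.fda, -.pid)
    kept <- dt[, .SD[1L], by = caseid]
    kept[, c(".fda", ".pid") := NULL]
    # restore original column order
    setcolorder(kept, names(demo)[names(demo) %in% names(kept)])
  } else {
    kept <- dt
  }
  setorder(kept, caseid)
  setattr(kept, "counts",
          c(input = n_in, kept = nrow(kept),
            duplicates_removed = n_in - n_bad - nrow(kept),
            missing_caseid = n_bad))
  kept[]
}

#' Restrict to pediatric reports
#'
#' Keeps records with standardized age strictly between `lower` and `upper`
#' years (defaults 0 and 18: "greater than 0 and less than 18"). Missing
#' ages are excluded.
#'
#' @param records data.frame/data.table with an `age_years` column.
#' @param lower,upper exclusive age bounds in years.
#' @return filtered `data.table` with attribute `"counts"`:
#'   `c(input, kept, excluded_age, missing_age)`.
#' @export
filter_pediatric <- function(records, lower = 0, upper = 18) {
  dt <- as.data.table(records)
  n_in <- nrow(dt)
  age <- dt$age_years
  keep <- !is.na(age) & age > lower & age < upper
  out <- dt[keep]
  setattr(out, "counts",
          c(input = n_in, kept = nrow(out),
            excluded_age = sum(!keep & !is.na(age)),
            missing_age = sum(is.na(age))))
  out[]
}

#' Select one primary-suspect drug per report
#'
#' Among DRUG rows with role code `PS`, returns the row with the lowest
#' numeric `drug_seq` for each report; reports without any PS row are
#' omitted (excluded from drug-level analysis). Non-numeric `drug_seq`
#' sorts last (treated as +Inf) and is counted.
#'
#' @param drug a data.frame/data.table of DRUG rows with `primaryid`,
#'   `drug_seq`, `role_cod`, `drugname` (and optionally `route`).
#' @return a `data.table` with one row per `primaryid` (columns of `drug`),
#'   attribute `"n_nonnumeric_seq"` counting unparseable sequence numbers
#'   among PS rows.
#' @export
select_primary_suspect <- function(drug) {
  dt <- as.data.table(drug)
  ps <- dt[toupper(trimws(role_cod)) == "PS"]
  seqn <- suppressWarnings(as.numeric(ps$drug_seq))
  n_bad <- sum(is.na(seqn))
  ps[, .seq := fifelse(is.na(seqn), Inf, seqn)]
  setorder(ps, primaryid, .seq)
  out <- ps[, .SD[1L], by = primaryid]
  out[, .seq := NULL]
  setattr(out, "n_nonnumeric_seq", n_bad)
  out[]
}

.valid_ymd <- function(x) {
  ok <- !is.na(x) & grepl("^[0-9]{8}$", x)
  d <- rep(as.Date(NA), length(x))
  d[ok] <- as.Date(x[ok], format = "%Y%m%d")
  d
}

#' Derive time to onset from therapy start and event dates
#'
#' Returns event minus start in days when both dates are complete, valid,
#' and the difference is at least one day; otherwise categorizes the
#' rejection. Partial dates (fewer than 8 digits) are never imputed.
#'
#' Categories, assigned in order: `missing` (either date absent), `incomplete`
#' (a date present but not a valid 8-digit calendar date), `inconsistent`
#' (event on or before start), `implausible` (difference beyond
#' `max_days`), else `ok`.
#'
#' @param start_dt,event_dt character vectors of `YYYYMMDD` dates (possibly
#'   partial or `NA`).
#' @param max_days upper plausibility bound in days; default 6574 (18 years),
#'   inert for pediatric subjects.
#' @return a `data.table` with columns `tto_days` (integer, `NA` unless
#'   included) and `reason` (factor: `ok`, `missing`, `incomplete`,
#'   `inconsistent`, `implausible`).
#' @export
compute_tto_days <- function(start_dt, event_dt, max_days = 6574) {
  start_dt <- as.character(start_dt)
  event_dt <- as.character(event_dt)
  n <- max(length(start_dt), length(event_dt))
  start_dt <- rep_len(start_dt, n)
  event_dt <- rep_len(event_dt, n)
  blank <- function(x) is.na(x) | !nzchar(trimws(x))
  reason <- rep("ok", n)
  s <- .valid_ymd(start_dt)
  e <- .valid_ymd(event_dt)
  d <- as.integer(e - s)
  reason[is.na(s) | is.na(e)] <- "incomplete"
  reason[blank(start_dt) | blank(event_dt)] <- "missing"
  ok <- reason == "ok"
  reason[ok & d <= 0] <- "inconsistent"
  ok <- reason == "ok"
  reason[ok & d > max_days] <- "implausible"
  out <- data.table(
    tto_days = fifelse(reason == "ok", d, NA_integer_),
    reason = factor(reason, levels = c("ok", "missing", "incomplete",
                                       "inconsistent", "implausible"))
  )
  out
}
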