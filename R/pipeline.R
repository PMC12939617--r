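# End-to-end orchestration: raw quarter bundle -> deduplicated pediatric
# analysis dataset -> signal screen (broad + narrow) -> time-to-onset
# analysis, with flowchart-style count accounting at every stage.

#' Pipeline configuration
#'
#' Validated up front and serialized alongside outputs for provenance.
#'
#' @param age_lower,age_upper exclusive pediatric age bounds (years).
#' @param min_reports minimum case count per screened drug.
#' @param bcpnn_strict BCPNN flag on IC-2SD > 0 instead of E(IC) > 0.
#' @param tto_edges interior bin edges for onset binning (days).
#' @param tto_max_days implausibility bound for onset times.
#' @param age_bands right-closed boundaries for descriptive age bands;
#'   defaults give 0-5, 6-13, 14-17.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(age_lower = 0, age_upper = 18, min_reports = 3,
                            bcpnn_strict = FALSE,
                            tto_edges = c(30, 60, 90, 180, 360),
                            tto_max_days = 6574,
                            age_bands = c(5, 13, 17)) {
  stopifnot(age_lower < age_upper, min_reports >= 0,
            all(diff(tto_edges) > 0), tto_max_days > 0,
            all(diff(age_bands) > 0))
  structure(list(age_lower = age_lower, age_upper = age_upper,
                 min_reports = min_reports, bcpnn_strict = bcpnn_strict,
                 tto_edges = tto_edges, tto_max_days = tto_max_days,
                 age_bands = age_bands),
            class = "pipeline_config")
}

#' Build the per-report analysis dataset from a quarter bundle
#'
#' Applies, in order: CASEID deduplication, age standardization, the
#' pediatric filter, primary-suspect selection with drug-name
#' standardization, case flagging under both PT query sets, and onset-time
#' derivation (therapy start from the THER row of the suspect drug sequence,
#' event date from DEMO). Reports without a primary-suspect drug stay in the
#' background with `generic = NA`.
#'
#' @param bundle a `faers_bundle`.
#' @param config a [pipeline_config()].
#' @param drug_map a map from [load_drug_map()].
#' @return list with `dataset` (one row per retained report) and `flow`
#'   (named counts: raw, missing_caseid, duplicates_removed, deduplicated,
#'   pediatric, ps_assigned, cases_broad, cases_narrow).
#' @export
prepare_analysis_dataset <- function(bundle, config = pipeline_config(),
                                     drug_map = load_drug_map()) {
  stopifnot(inherits(bundle, "faers_bundle"))
  demo <- as.data.table(bundle$tables$DEMO)
  n_raw <- nrow(demo)

  dedup <- deduplicate_reports(demo)
  dcounts <- attr(dedup, "counts")

  dedup[, age_years := standardize_age(age, age_cod)]
  ped <- filter_pediatric(dedup, lower = config$age_lower,
                          upper = config$age_upper)
  pcounts <- attr(ped, "counts")

  drug <- bundle$tables$DRUG[.(ped$primaryid), nomatch = NULL]
  ps <- select_primary_suspect(drug)
  std <- standardize_drug_name(ps$drugname, map = drug_map)
  ps[, `:=`(generic = std$generic, drug_class = std$drug_class,
            mapped = std$mapped)]

  reac <- bundle$tables$REAC[.(ped$primaryid), nomatch = NULL]
  broad_ids <- flag_cataract_cases(reac, cataract_pt_query("broad"))
  narrow_ids <- flag_cataract_cases(reac, cataract_pt_query("narrow"))

  ds <- data.table(
    primaryid = ped$primaryid, caseid = ped$caseid, fda_dt = ped$fda_dt,
    age_years = ped$age_years,
    sex = if ("sex" %in% names(ped)) ped$sex else NA_character_,
    event_dt = if ("event_dt" %in% names(ped)) ped$event_dt else NA_character_)
  ds <- merge(ds, ps[, .(primaryid, generic, drug_class, drug_seq, mapped)],
              by = "primaryid", all.x = TRUE)
  ds[, `:=`(is_case = primaryid %chin% broad_ids,
            is_case_narrow = primaryid %chin% narrow_ids)]

  if (!is.null(bundle$tables$THER)) {
    ther <- as.data.table(bundle$tables$THER)
    seq_col <- if ("dsg_drug_seq" %in% names(ther)) "dsg_drug_seq" else "drug_seq"
    ther_ps <- merge(ds[!is.na(drug_seq), .(primaryid, drug_seq)],
                     ther, by.x = c("primaryid", "drug_seq"),
                     by.y = c("primaryid", seq_col))
    ther_ps <- unique(ther_ps, by = "primaryid")
    ther_min <- ther[, .(start_any = start_dt[which.min(suppressWarnings(as.numeric(start_dt)))[1]]),
                     by = primaryid]
    ds <- merge(ds, ther_ps[, .(primaryid, start_dt)], by = "primaryid",
                all.x = TRUE)
    ds <- merge(ds, ther_min, by = "primaryid", all.x = TRUE)
    ds[is.na(start_dt), start_dt := start_any]
    ds[, start_any := NULL]
  } else {
    ds[, start_dt := NA_character_]
  }
  tto <- compute_tto_days(ds$start_dt, ds$event_dt,
                          max_days = config$tto_max_days)
  ds[, `:=`(tto_days = tto$tto_days, tto_reason = tto$reason)]
  setorder(ds, caseid)

  flow <- c(raw = n_raw,
            missing_caseid = unname(dcounts["missing_caseid"]),
            duplicates_removed = unname(dcounts["duplicates_removed"]),
            deduplicated = unname(dcounts["kept"]),
            pediatric = unname(pcounts["kept"]),
            ps_assigned = sum(!is.na(ds$generic)),
            cases_broad = sum(ds$is_case),
            cases_narrow = sum(ds$is_case_narrow))
  list(dataset = ds[], flow = flow)
}

#' Descriptive summaries of case reports
#'
#' Age bands, sex, reporter occupation, outcome codes, report year and
#' country for the cataract case reports, mirroring the standard
#' characterization of a spontaneous-report case series.
#'
#' @param dataset analysis dataset from [prepare_analysis_dataset()].
#' @param demo the deduplicated DEMO rows (for occupation/country/outcome
#'   fields not carried in the dataset); optional.
#' @param age_bands right-closed band boundaries.
#' @return named list of count `data.table`s.
#' @export
describe_cases <- function(dataset, demo = NULL, age_bands = c(5, 13, 17)) {
  cases <- as.data.table(dataset)[is_case == TRUE]
  brk <- c(0, age_bands, Inf)
  lab <- c(paste0(c(0, head(age_bands, -1) + 1), "-", age_bands),
           paste0(">", age_bands[length(age_bands)]))
  out <- list(
    age_band = cases[, .N, by = .(band = cut(age_years, brk, labels = lab,
                                             right = TRUE))][order(band)],
    sex = cases[, .N, by = sex][order(-N)],
    year = cases[, .N, by = .(year = substr(fda_dt, 1, 4))][order(year)]
  )
  if (!is.null(demo)) {
    dm <- as.data.table(demo)[primaryid %chin% cases$primaryid]
    if ("occp_cod" %in% names(dm)) {
      out$reporter <- dm[, .N, by = occp_cod][order(-N)]
    }
    if ("reporter_country" %in% names(dm)) {
      out$country <- dm[, .N, by = reporter_country][order(-N)]
    }
  }
  out
}

#' Run the full screening pipeline on a quarter bundle
#'
#' Preprocessing, broad and narrow disproportionality screens, and the
#' time-to-onset analysis of case reports (inclusion accounting, binning,
#' Weibull fit when enough onsets are available, glucocorticoid-vs-other
#' log-rank comparison when both groups are non-empty).
#'
#' @param bundle a `faers_bundle`.
#' @param config a [pipeline_config()].
#' @param drug_map drug-name map.
#' @param out_dir optional directory: signal tables (TSV), flow counts and
#'   config (JSON) are written there.
#' @return list: `flow`, `dataset`, `signals` (broad), `signals_narrow`,
#'   `tto` (list: counts, bins, weibull or NULL, group_test or NULL),
#'   `descriptives`.
#' @export
run_pipeline <- function(bundle, config = pipeline_config(),
                         drug_map = load_drug_map(), out_dir = NULL) {
  prep <- prepare_analysis_dataset(bundle, config, drug_map)
  ds <- prep$dataset

  signals <- screen_signals(ds, case_col = "is_case",
                            min_reports = config$min_reports,
                            bcpnn_strict = config$bcpnn_strict)
  signals_narrow <- screen_signals(ds, case_col = "is_case_narrow",
                                   min_reports = config$min_reports,
                                   bcpnn_strict = config$bcpnn_strict)

  cases <- ds[is_case == TRUE]
  inc <- tto_inclusion(cases[, .(primaryid, generic, drug_class,
                                 tto_days, reason = tto_reason)])
  tto_res <- list(counts = inc$counts, bins = NULL, weibull = NULL,
                  group_test = NULL)
  if (nrow(inc$included)) {
    tto_res$bins <- bin_tto(inc$included$tto_days, edges = config$tto_edges)
  }
  if (nrow(inc$included) >= 10 &&
      length(unique(inc$included$tto_days)) >= 2) {
    tto_res$weibull <- fit_weibull(inc$included$tto_days)
  }
  grp <- inc$included[, .(tto_days,
                          group = fifelse(!is.na(drug_class) &
                                            drug_class == "glucocorticoid",
                                          "glucocorticoid", "other"))]
  if (length(unique(grp$group)) == 2) {
    tto_res$group_test <- compare_onset_groups(grp$tto_days, grp$group)
  }

  res <- list(flow = prep$flow, dataset = ds, signals = signals,
              signals_narrow = signals_narrow, tto = tto_res,
              descriptives = describe_cases(ds, demo = bundle$tables$DEMO,
                                            age_bands = config$age_bands),
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fwrite(signals, file.path(out_dir, "signals_broad.tsv"), sep = "\t")
    fwrite(signals_narrow, file.path(out_dir, "signals_narrow.tsv"),
           sep = "\t")
    jsonlite::write_json(
      list(flow = as.list(prep$flow), tto_counts = as.list(inc$counts),
           config = unclass(config)),
      file.path(out_dir, "pipeline_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
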