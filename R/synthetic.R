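# Synthetic FAERS-like world with known ground truth: planted drug-event
# signals, CASEID-versioned duplicates, mixed age units, and date
# pathologies. Every pipeline stage and statistic is testable against the
# generator's bookkeeping, without any download.

#' @importFrom stats runif rweibull rpois
NULL

.default_drug_catalogue <- function() {
  # exposure = marginal probability of being the report's primary suspect.
  # Null filler drugs absorb the remaining mass.
  sig <- data.table(
    generic = c("DIFLUPREDNATE", "PREDNISOLONE ACETATE", "PREDNISOLONE",
                "PREDNISONE", "TRIAMCINOLONE ACETONIDE", "FLUTICASONE FUROATE",
                "IVACAFTOR", "ELEXACAFTOR/IVACAFTOR/TEZACAFTOR",
                "IVACAFTOR/LUMACAFTOR", "ADALIMUMAB", "METHOTREXATE",
                "MYCOPHENOLATE MOFETIL", "MELPHALAN", "TOPOTECAN",
                "CISPLATIN", "TOPIRAMATE", "FILGRASTIM", "RANIBIZUMAB"),
    exposure = c(0.0002, 0.0002, 0.004, 0.004, 0.003, 0.0006,
                 0.001, 0.0025, 0.0025, 0.010, 0.008,
                 0.003, 0.0017, 0.001, 0.001, 0.002, 0.001, 0.0002),
    drug_class = c(rep("glucocorticoid", 6), rep("cftr_modulator", 3),
                   "monoclonal_antibody", "immunosuppressant",
                   "immunosuppressant", "antineoplastic", "antineoplastic",
                   "antineoplastic", "antiepileptic",
                   "colony_stimulating_factor", "monoclonal_antibody")
  )
  nulls <- data.table(
    generic = sprintf("NULLDRUG%02d", 1:30),
    exposure = rep((1 - sum(sig$exposure)) / 30, 30),
    drug_class = "other"
  )
  rbind(sig, nulls)
}

.default_planted_pairs <- function() {
  # reporting-rate ratios for exposed reports, roughly echoing the spread of
  # published pediatric-cataract signals (very strong local-ocular steroids,
  # strong CFTR modulators, moderate systemic agents)
  data.table(
    generic = c("DIFLUPREDNATE", "PREDNISOLONE ACETATE", "RANIBIZUMAB",
                "IVACAFTOR", "ELEXACAFTOR/IVACAFTOR/TEZACAFTOR",
                "IVACAFTOR/LUMACAFTOR", "FLUTICASONE FUROATE", "MELPHALAN",
                "TOPOTECAN", "PREDNISONE", "PREDNISOLONE",
                "TRIAMCINOLONE ACETONIDE", "ADALIMUMAB", "METHOTREXATE",
                "MYCOPHENOLATE MOFETIL", "CISPLATIN", "TOPIRAMATE",
                "FILGRASTIM"),
    rate_ratio = c(400, 70, 45, 30, 16, 13, 27, 14, 16, 9, 8, 10, 6, 6, 8, 7,
                   6, 7)
  )
}

#' Configuration of the synthetic FAERS world
#'
#' Defaults describe the study conditions the generator emulates: a
#' pediatric-dominated reporting stream with a rare-event background
#' (cataract reporting probability 0.001 per unexposed report), versioned
#' duplicates on 36% of caseids (so that removed duplicates are ~26% of raw
#' reports), mixed age units, planted drug-event signals acting only through
#' the primary-suspect drug, and a date model with 70% missing / 10%
#' incomplete / 1% inconsistent dates and a Weibull(0.72, 650 days) onset
#' distribution — the scale that puts 52% of onsets beyond 360 days at
#' shape 0.72.
#'
#' @param n_reports number of distinct caseids to generate.
#' @param seed integer seed; same config + seed gives identical output.
#' @param drug_catalogue `data.table(generic, exposure, drug_class)`;
#'   exposures must sum to 1.
#' @param planted_pairs `data.table(generic, rate_ratio)`; rate_ratio
#'   multiplies the background case probability for reports whose primary
#'   suspect is that drug (1 = null).
#' @param p_case background cataract reporting probability per report.
#' @param cataract_pt_choice `"random"` (uniform over the six cataract PTs)
#'   or `"narrow"` (always PT 10007739, making broad and narrow screens
#'   coincide).
#' @param duplicate_fraction fraction of caseids emitted with one extra,
#'   superseded version.
#' @param pediatric_fraction fraction of reports with true age in (0, 18).
#' @param p_age_missing fraction of reports with no age.
#' @param tto_shape,tto_scale Weibull onset-time parameters (days).
#' @param p_date_missing,p_date_incomplete,p_date_inconsistent,p_date_implausible
#'   probabilities of the date pathologies (remainder is clean).
#' @param quarter_label label stamped on the emitted tables.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_reports = 50000,
                             seed = 1L,
                             drug_catalogue = .default_drug_catalogue(),
                             planted_pairs = .default_planted_pairs(),
                             p_case = 0.001,
                             cataract_pt_choice = c("random", "narrow"),
                             duplicate_fraction = 0.36,
                             pediatric_fraction = 0.85,
                             p_age_missing = 0.05,
                             tto_shape = 0.72,
                             tto_scale = 650,
                             p_date_missing = 0.70,
                             p_date_incomplete = 0.10,
                             p_date_inconsistent = 0.01,
                             p_date_implausible = 0,
                             quarter_label = "SYNTH") {
  cataract_pt_choice <- match.arg(cataract_pt_choice)
  cfg <- list(n_reports = as.integer(n_reports), seed = as.integer(seed),
              drug_catalogue = as.data.table(drug_catalogue),
              planted_pairs = as.data.table(planted_pairs),
              p_case = p_case, cataract_pt_choice = cataract_pt_choice,
              duplicate_fraction = duplicate_fraction,
              pediatric_fraction = pediatric_fraction,
              p_age_missing = p_age_missing,
              tto_shape = tto_shape, tto_scale = tto_scale,
              p_date_missing = p_date_missing,
              p_date_incomplete = p_date_incomplete,
              p_date_inconsistent = p_date_inconsistent,
              p_date_implausible = p_date_implausible,
              quarter_label = quarter_label)
  probs <- c(cfg$p_case, cfg$duplicate_fraction, cfg$pediatric_fraction,
             cfg$p_age_missing, cfg$p_date_missing, cfg$p_date_incomplete,
             cfg$p_date_inconsistent, cfg$p_date_implausible)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$p_date_missing + cfg$p_date_incomplete + cfg$p_date_inconsistent +
      cfg$p_date_implausible > 1) {
    stop("date pathology probabilities sum above 1", call. = FALSE)
  }
  if (abs(sum(cfg$drug_catalogue$exposure) - 1) > 1e-8) {
    stop("drug catalogue exposure probabilities must sum to 1", call. = FALSE)
  }
  if (any(cfg$planted_pairs$rate_ratio < 0)) {
    stop("rate ratios must be non-negative", call. = FALSE)
  }
  rr <- merge(cfg$drug_catalogue, cfg$planted_pairs, by = "generic",
              all.x = TRUE)
  rr[is.na(rate_ratio), rate_ratio := 1]
  if (any(rr$rate_ratio * cfg$p_case > 1)) {
    stop("infeasible planted pair: rate_ratio x p_case exceeds 1", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.fmt_date <- function(d) format(d, "%Y%m%d")

# verbatim-name variants for the signal drugs, drawn from the packaged map
.verbatim_pool <- function(catalogue) {
  map <- load_drug_map()
  pool <- map[generic %in% catalogue$generic, .(verbatim, generic)]
  missing <- setdiff(catalogue$generic, pool$generic)
  rbind(pool, data.table(verbatim = missing, generic = missing))
}

#' Generate a synthetic FAERS quarter with ground truth
#'
#' Emits DEMO/DRUG/REAC/THER/OUTC/INDI tables parseable by the IO module,
#' together with a per-caseid ground-truth table recording the latent values
#' an ideal pipeline should recover: the surviving report version, the true
#' standardized age, the primary-suspect drug, case status and the onset-time
#' category. Planted signals act only through the primary-suspect drug; the
#' case probability of an exposed report is `rate_ratio * p_case`.
#' Duplicate versions are emitted as superseded entries — earlier `FDA_DT`,
#' or (30% of duplicates) equal `FDA_DT` with a smaller `PRIMARYID` — so
#' both deduplication tie rules are exercised.
#'
#' @param config a [generator_config()].
#' @param dir optional directory; when given, the bundle and ground truth
#'   (`ground_truth.tsv`) are written there.
#' @return list with `bundle` (a `faers_bundle`), `truth` (a `data.table`,
#'   one row per caseid) and `config`.
#' @export
generate_faers <- function(config = generator_config(), dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_reports == 0L) {
    empty <- function(...) {
      cols <- c(...)
      setnames(as.data.table(matrix(character(0), 0, length(cols))), cols)
    }
    bundle <- assemble_quarter(list(
      faers_table(empty("primaryid", "caseid", "fda_dt", "age", "age_cod",
                        "sex", "occp_cod", "reporter_country", "event_dt"),
                  "DEMO", config$quarter_label),
      faers_table(empty("primaryid", "drug_seq", "role_cod", "drugname",
                        "route"), "DRUG", config$quarter_label),
      faers_table(empty("primaryid", "pt"), "REAC", config$quarter_label),
      faers_table(empty("primaryid", "dsg_drug_seq", "start_dt", "end_dt"),
                  "THER", config$quarter_label),
      faers_table(empty("primaryid", "outc_cod"), "OUTC",
                  config$quarter_label),
      faers_table(empty("primaryid", "indi_drug_seq", "indi_pt"), "INDI",
                  config$quarter_label)))
    truth <- data.table(caseid = character(), primaryid = character(),
                        n_versions = integer(), fda_dt = character(),
                        age_years = numeric(), pediatric = logical(),
                        sex = character(), ps_generic = character(),
                        ps_class = character(), is_case = logical(),
                        case_pt = character(), tto_category = character(),
                        tto_days = integer(), country = character(),
                        occp_cod = character())
    out <- list(bundle = bundle, truth = truth, config = config)
    if (!is.null(dir)) {
      write_bundle(bundle, dir)
      fwrite(truth, file.path(dir, "ground_truth.tsv"), sep = "\t")
    }
    return(out)
  }
  .with_seed(config$seed, {
    n <- config$n_reports
    cat_pts <- .cataract_pts$pt_code
    bg_pts <- sprintf("1%07d", 1:40)  # non-cataract background PTs

    # --- latent per-caseid truth ----------------------------------------
    caseid <- as.character(seq_len(n) + 10000000L)
    fda <- as.Date("2004-01-01") + sample.int(7900L, n, replace = TRUE)

    pediatric <- runif(n) < config$pediatric_fraction
    true_age <- ifelse(pediatric, runif(n, 0, 18), runif(n, 18, 90))
    age_missing <- runif(n) < config$p_age_missing
    unit <- sample(c("YR", "MON", "WK", "DY", "DEC"), n, replace = TRUE,
                   prob = c(0.55, 0.20, 0.05, 0.15, 0.05))
    div <- c(YR = 1, MON = 1 / 12, WK = 1 / 52, DY = 1 / 365, DEC = 10)
    age_value <- signif(true_age / div[unit], 7)
    age_value[age_missing] <- NA_real_
    age_str <- fifelse(is.na(age_value), NA_character_,
                       formatC(age_value, format = "fg", digits = 7))
    # the age the pipeline will recover from the emitted fields, computed
    # from the emitted string so truth and pipeline agree exactly
    age_seen <- standardize_age(age_str, unit)

    cat_idx <- config$drug_catalogue
    drug_i <- sample.int(nrow(cat_idx), n, replace = TRUE,
                         prob = cat_idx$exposure)
    ps_generic <- cat_idx$generic[drug_i]
    ps_class <- cat_idx$drug_class[drug_i]

    rr <- merge(data.table(generic = ps_generic, ord = seq_len(n)),
                config$planted_pairs, by = "generic", all.x = TRUE)
    setorder(rr, ord)
    rho <- fifelse(is.na(rr$rate_ratio), 1, rr$rate_ratio)
    is_case <- runif(n) < config$p_case * rho
    case_pt <- if (config$cataract_pt_choice == "narrow") {
      rep("10007739", n)
    } else {
      sample(cat_pts, n, replace = TRUE)
    }
    case_pt[!is_case] <- NA_character_

    # date model
    u <- runif(n)
    p1 <- config$p_date_missing
    p2 <- p1 + config$p_date_incomplete
    p3 <- p2 + config$p_date_inconsistent
    p4 <- p3 + config$p_date_implausible
    date_cat <- fifelse(u < p1, "missing",
                 fifelse(u < p2, "incomplete",
                  fifelse(u < p3, "inconsistent",
                   fifelse(u < p4, "implausible", "ok"))))
    start <- as.Date("2004-01-01") + sample.int(7000L, n, replace = TRUE)
    tto_true <- pmax(1L, as.integer(ceiling(
      rweibull(n, shape = config$tto_shape, scale = config$tto_scale))))
    tto_true <- pmin(tto_true, 6574L)       # keep clean draws plausible
    event <- start + tto_true
    start_s <- .fmt_date(start)
    event_s <- .fmt_date(event)
    miss_which <- runif(n) < 0.5
    start_s[date_cat == "missing" & miss_which] <- NA_character_
    event_s[date_cat == "missing" & !miss_which] <- NA_character_
    inc <- date_cat == "incomplete"
    event_s[inc & miss_which] <- substr(event_s[inc & miss_which], 1, 6)
    start_s[inc & !miss_which] <- substr(start_s[inc & !miss_which], 1, 4)
    bad <- date_cat == "inconsistent"
    event_s[bad] <- .fmt_date(start[bad] - sample(0:30, sum(bad), replace = TRUE))
    impl <- date_cat == "implausible"
    event_s[impl] <- .fmt_date(start[impl] + 6575L +
                                 sample.int(2000L, sum(impl), replace = TRUE))

    sex <- sample(c("M", "F", "UNK"), n, replace = TRUE,
                  prob = c(0.48, 0.48, 0.04))
    occp <- sample(c("MD", "PH", "OT", "CN", "LW"), n, replace = TRUE,
                   prob = c(0.30, 0.12, 0.17, 0.39, 0.02))
    country <- sample(c("US", "CA", "GB", "FR", "JP", "DE"), n,
                      replace = TRUE,
                      prob = c(0.5, 0.12, 0.1, 0.1, 0.09, 0.09))
    outc <- sample(c("OT", "HO", "DE", "LT", "DS", ""), n, replace = TRUE,
                   prob = c(0.4, 0.2, 0.02, 0.03, 0.05, 0.3))

    # duplicates: extra superseded versions
    is_dup <- runif(n) < config$duplicate_fraction
    tie_dup <- is_dup & runif(n) < 0.3     # equal FDA_DT, smaller PRIMARYID

    # kept version id is <caseid>2 / superseded gets <caseid>1 so the larger
    # primaryid wins numeric comparison on ties
    pid_keep <- paste0(caseid, "2")
    pid_dup <- paste0(caseid, "1")
    fda_keep <- .fmt_date(fda)
    fda_dup <- fifelse(tie_dup, fda_keep, .fmt_date(fda - 30L))

    truth <- data.table(
      caseid = caseid, primaryid = pid_keep, n_versions = 1L + is_dup,
      fda_dt = fda_keep, age_years = age_seen,
      pediatric = !is.na(age_seen) & age_seen > 0 & age_seen < 18,
      sex = sex, ps_generic = ps_generic, ps_class = ps_class,
      is_case = is_case, case_pt = case_pt,
      tto_category = fifelse(date_cat == "ok", "ok", date_cat),
      tto_days = fifelse(date_cat == "ok", tto_true, NA_integer_),
      country = country, occp_cod = occp
    )

    # --- emitted tables --------------------------------------------------
    demo_keep <- data.table(
      primaryid = pid_keep, caseid = caseid, fda_dt = fda_keep,
      age = age_str, age_cod = fifelse(is.na(age_value),
                                       NA_character_, unit),
      sex = sex, occp_cod = occp, reporter_country = country,
      event_dt = event_s
    )
    d <- which(is_dup)
    demo_dup <- demo_keep[d]
    demo_dup[, `:=`(primaryid = pid_dup[d], fda_dt = fda_dup[d])]
    demo <- rbind(demo_keep, demo_dup)

    pool <- .verbatim_pool(cat_idx)
    verb <- {
      # one uniformly chosen verbatim variant (brand/salt spelling) per report
      gdt <- data.table(generic = ps_generic, row = seq_len(n))
      vmap <- pool[, .(vs = list(verbatim)), by = generic]
      gdt <- vmap[gdt, on = "generic"]
      setorder(gdt, row)
      vapply(gdt$vs, function(v) v[[sample.int(length(v), 1L)]], character(1))
    }

    # primary-suspect row (drug_seq 1) + occasional second PS with higher
    # seq (exercises the min-DRUG_SEQ rule) + Poisson concomitants
    second_ps <- runif(n) < 0.05
    n_con <- rpois(n, 1)
    ps_rows <- data.table(
      primaryid = pid_keep, drug_seq = "1", role_cod = "PS", drugname = verb,
      route = fifelse(ps_generic %chin% c("DIFLUPREDNATE",
                                          "PREDNISOLONE ACETATE"),
                      "OPHTHALMIC", "ORAL"))
    extra_ps <- data.table(
      primaryid = pid_keep[second_ps], drug_seq = "2", role_cod = "PS",
      drugname = sample(cat_idx$generic, sum(second_ps), replace = TRUE,
                        prob = cat_idx$exposure),
      route = "ORAL")
    con_pid <- rep(pid_keep, n_con)
    con_rows <- data.table(
      primaryid = con_pid,
      drug_seq = as.character(unlist(lapply(n_con[n_con > 0],
                                            function(k) seq_len(k) + 2L),
                                     use.names = FALSE)),
      role_cod = sample(c("C", "SS", "I"), length(con_pid), replace = TRUE,
                        prob = c(0.6, 0.3, 0.1)),
      drugname = sample(cat_idx$generic, length(con_pid), replace = TRUE,
                        prob = cat_idx$exposure),
      route = "ORAL")
    drug_keep <- rbind(ps_rows, extra_ps, con_rows)

    # reactions: 1-3 background PTs, plus the cataract PT for cases
    n_bg <- sample(1:3, n, replace = TRUE)
    reac_keep <- rbind(
      data.table(primaryid = rep(pid_keep, n_bg),
                 pt = sample(bg_pts, sum(n_bg), replace = TRUE)),
      data.table(primaryid = pid_keep[is_case], pt = case_pt[is_case]))

    ther_keep <- data.table(primaryid = pid_keep, dsg_drug_seq = "1",
                            start_dt = start_s, end_dt = NA_character_)

    # superseded versions carry the same content under the duplicate
    # primaryid (ends in "1" instead of "2")
    dup_copy <- function(dt) {
      x <- dt[primaryid %chin% pid_keep[d]]
      x[, primaryid := paste0(substr(primaryid, 1, nchar(primaryid) - 1L), "1")]
      x
    }
    drug <- rbind(drug_keep, dup_copy(drug_keep))
    reac <- rbind(reac_keep, dup_copy(reac_keep))
    ther <- rbind(ther_keep, dup_copy(ther_keep))

    outc_dt <- data.table(primaryid = pid_keep, outc_cod = outc)[nzchar(outc)]
    indi <- data.table(primaryid = pid_keep, indi_drug_seq = "1",
                       indi_pt = sample(bg_pts, n, replace = TRUE))

    ql <- config$quarter_label
    bundle <- assemble_quarter(list(
      faers_table(demo, "DEMO", ql), faers_table(drug, "DRUG", ql),
      faers_table(reac, "REAC", ql), faers_table(ther, "THER", ql),
      faers_table(outc_dt, "OUTC", ql), faers_table(indi, "INDI", ql)
    ))
    out <- list(bundle = bundle, truth = truth, config = config)
    if (!is.null(dir)) {
      write_bundle(bundle, dir)
      fwrite(truth, file.path(dir, "ground_truth.tsv"), sep = "\t")
    }
    out
  })
}

#' Expected contingency table from the ground truth
#'
#' Exact recount of the generated reports after ideal preprocessing
#' (deduplication to one row per caseid, strict pediatric filter, primary
#' suspect as planted): the oracle the real pipeline is compared against.
#'
#' @param truth the `truth` table from [generate_faers()].
#' @param drug generic entity.
#' @param mode `"broad"` or `"narrow"` case definition.
#' @return a `contingency_2x2`.
#' @export
expected_contingency <- function(truth, drug, mode = c("broad", "narrow")) {
  mode <- match.arg(mode)
  if (!drug %in% truth$ps_generic) stop("unknown drug: ", drug, call. = FALSE)
  ped <- truth[pediatric == TRUE]
  query <- cataract_pt_query(mode)
  case <- ped$is_case & ped$case_pt %in% query$pt_codes
  tgt <- ped$ps_generic == drug
  structure(list(a = sum(tgt & case), b = sum(tgt & !case),
                 c = sum(!tgt & case), d = sum(!tgt & !case),
                 n = nrow(ped)),
            class = "contingency_2x2")
}
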