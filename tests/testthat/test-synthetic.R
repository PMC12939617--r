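test_that("identical config and seed give identical worlds", {
  g1 <- generate_faers(small_config(n = 500, seed = 42))
  g2 <- generate_faers(small_config(n = 500, seed = 42))
  for (k in names(g1$bundle$tables)) {
    expect_identical(as.data.frame(g1$bundle$tables[[k]]),
                     as.data.frame(g2$bundle$tables[[k]]))
  }
  expect_identical(as.data.frame(g1$truth), as.data.frame(g2$truth))
  g3 <- generate_faers(small_config(n = 500, seed = 43))
  expect_false(identical(as.data.frame(g1$truth), as.data.frame(g3$truth)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_faers(small_config(n = 100, seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("zero reports yield header-only tables", {
  g <- generate_faers(small_config(n = 0, seed = 1))
  expect_equal(nrow(g$bundle$tables$DEMO), 0L)
  expect_equal(nrow(g$truth), 0L)
  dir <- withr::local_tempdir()
  write_bundle(g$bundle, dir)
  expect_length(readLines(file.path(dir, "DEMO.txt")), 1L)
})

test_that("duplicate versions follow both deduplication tie rules", {
  g <- generate_faers(small_config(n = 4000, seed = 8,
                                   duplicate_fraction = 0.3))
  demo <- as.data.frame(g$bundle$tables$DEMO)
  expect_equal(length(unique(demo$caseid)), 4000L)
  expect_gt(nrow(demo), 4000L)
  kept <- deduplicate_reports(demo)
  expect_equal(nrow(kept), 4000L)
  # the surviving version is exactly the ground-truth version
  expect_equal(sort(kept$primaryid), sort(g$truth$primaryid))
  # both tie mechanics are present: some duplicates share fda_dt
  dups <- demo[duplicated(demo$caseid) | duplicated(demo$caseid, fromLast = TRUE), ]
  per_case <- split(dups$fda_dt, dups$caseid)
  expect_true(any(vapply(per_case, function(x) length(unique(x)) == 1, TRUE)))
  expect_true(any(vapply(per_case, function(x) length(unique(x)) > 1, TRUE)))

  # duplicate_fraction = 0: raw rows equal distinct caseids
  g0 <- generate_faers(small_config(n = 1000, seed = 8,
                                    duplicate_fraction = 0))
  expect_equal(nrow(g0$bundle$tables$DEMO), 1000L)
})

test_that("infeasible or invalid configurations are refused", {
  expect_error(planted_config(100, 1, rho = 3000, p_case = 0.001),
               "infeasible")
  expect_error(generator_config(duplicate_fraction = 1.5), "\\[0, 1\\]")
  expect_error(generator_config(p_date_missing = 0.8, p_date_incomplete = 0.5),
               "sum above 1")
  expect_error(
    generator_config(drug_catalogue = data.table::data.table(
      generic = "X", exposure = 0.4, drug_class = "other")),
    "sum to 1")
})

test_that("pipeline recovers the generator's latent truth exactly", {
  g <- generate_faers(small_config(n = 8000, seed = 12))
  prep <- prepare_analysis_dataset(g$bundle)
  ds <- prep$dataset

  # deduplication: one report per caseid, the truth version
  expect_equal(unname(prep$flow["deduplicated"]), 8000)
  expect_equal(sort(ds$caseid), sort(g$truth[pediatric == TRUE, caseid]))

  truth_ped <- g$truth[pediatric == TRUE][order(caseid)]
  setkey(truth_ped, caseid)
  dso <- ds[order(caseid)]

  # ages identical to the generator's bookkeeping
  expect_equal(dso$age_years, truth_ped$age_years)
  # primary-suspect generic matches planted truth
  expect_equal(dso$generic, truth_ped$ps_generic)
  # case status matches
  expect_equal(dso$is_case, truth_ped$is_case)
  # onset categories match injected pathologies exactly
  expect_equal(as.character(dso$tto_reason),
               ifelse(truth_ped$tto_category == "ok", "ok",
                      truth_ped$tto_category))
  expect_equal(dso$tto_days, truth_ped$tto_days)
})

test_that("pediatric retention tracks the configured fraction", {
  g <- generate_faers(small_config(n = 20000, seed = 23,
                                   pediatric_fraction = 0.6,
                                   p_age_missing = 0.1))
  prep <- prepare_analysis_dataset(g$bundle)
  frac <- unname(prep$flow["pediatric"] / prep$flow["deduplicated"])
  expect_lt(abs(frac - 0.6 * 0.9), 0.02)
})

test_that("expected_contingency is an exact oracle for pipeline counts", {
  g <- generate_faers(small_config(n = 10000, seed = 19))
  prep <- prepare_analysis_dataset(g$bundle)
  for (drg in unique(g$truth$ps_generic)[1:12]) {
    oc <- expected_contingency(g$truth, drg)
    pc <- build_contingency(prep$dataset, drg)
    expect_identical(unlist(oc), unlist(pc))
  }
  expect_error(expected_contingency(g$truth, "NO SUCH DRUG"), "unknown")
})

test_that("narrow PT choice makes broad and narrow counts coincide", {
  g <- generate_faers(planted_config(15000, seed = 31, rho = 10,
                                     cataract_pt_choice = "narrow"))
  prep <- prepare_analysis_dataset(g$bundle)
  broad <- build_contingency(prep$dataset, "TARGETDRUG", case_col = "is_case")
  narrow <- build_contingency(prep$dataset, "TARGETDRUG",
                              case_col = "is_case_narrow")
  expect_identical(unlist(broad), unlist(narrow))
})

test_that("a null drug's ROR interval covers 1 at nominal rate", {
  covered <- 0L; usable <- 0L
  for (s in 1:200) {
    g <- generate_faers(planted_config(1200, seed = 1000 + s, rho = 1,
                                       exposure = 0.1, p_case = 0.1,
                                       duplicate_fraction = 0,
                                       p_age_missing = 0))
    tab <- expected_contingency(g$truth, "TARGETDRUG")
    r <- ror(tab)
    if (!is.na(r$ror)) {
      usable <- usable + 1L
      covered <- covered + (r$ci_lower <= 1 && r$ci_upper >= 1)
    }
  }
  expect_gt(usable, 190)
  expect_gt(covered / usable, 0.90)
  expect_lt(covered / usable, 0.99)
})
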