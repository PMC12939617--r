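test_that("deduplication keeps latest FDA_DT, then largest PRIMARYID", {
  demo <- data.frame(primaryid = c("5501", "5502"), caseid = "55",
                     fda_dt = c("20200101", "20210101"))
  expect_equal(deduplicate_reports(demo)$primaryid, "5502")

  tie <- data.frame(primaryid = c("5501", "5502"), caseid = "55",
                    fda_dt = "20200101")
  expect_equal(deduplicate_reports(tie)$primaryid, "5502")

  # numeric, not lexicographic, primaryid comparison
  num <- data.frame(primaryid = c("999", "1000"), caseid = "7",
                    fda_dt = "20200101")
  expect_equal(deduplicate_reports(num)$primaryid, "1000")
})

test_that("records with missing caseid are excluded and counted", {
  demo <- data.frame(primaryid = c("1", "2", "3"),
                     caseid = c("10", NA, ""),
                     fda_dt = "20200101")
  out <- deduplicate_reports(demo)
  expect_equal(nrow(out), 1L)
  expect_equal(unname(attr(out, "counts")["missing_caseid"]), 2L)
})

test_that("deduplication is idempotent and order-insensitive", {
  set.seed(42)
  demo <- data.frame(
    primaryid = as.character(sample(1e6, 300)),
    caseid = as.character(sample(1:80, 300, replace = TRUE)),
    fda_dt = format(as.Date("2015-01-01") + sample(0:3000, 300, TRUE),
                    "%Y%m%d"))
  ref <- deduplicate_reports(demo)
  expect_equal(as.data.frame(deduplicate_reports(ref)), as.data.frame(ref),
               ignore_attr = TRUE)
  for (s in 1:5) {
    set.seed(s)
    perm <- demo[sample(nrow(demo)), ]
    expect_equal(as.data.frame(deduplicate_reports(perm)),
                 as.data.frame(ref), ignore_attr = TRUE)
  }
})

test_that("age codes convert to years as specified", {
  expect_equal(standardize_age(24, "MON"), 2)
  expect_equal(standardize_age(730, "DY"), 2)
  expect_equal(standardize_age(1.2, "DEC"), 12)
  expect_equal(standardize_age(104, "WK"), 2)
  expect_equal(standardize_age(5, "YR"), 5)
  expect_true(is.na(standardize_age(3, "HR")))     # hours not convertible
  expect_true(is.na(standardize_age(-1, "YR")))    # negative -> missing
  expect_true(is.na(standardize_age(NA, "YR")))
  expect_true(is.na(standardize_age(5, NA)))
})

test_that("age conversion is unit-consistent across equivalent encodings", {
  x <- c(0, 0.5, 1, 7.25, 17.99, 40)
  expect_equal(standardize_age(12 * x, "MON"), standardize_age(x, "YR"))
  expect_equal(standardize_age(365 * x, "DY"), standardize_age(x, "YR"))
  expect_equal(standardize_age(52 * x, "WK"), standardize_age(x, "YR"))
  expect_equal(standardize_age(x / 10, "DEC"), standardize_age(x, "YR"))
})

test_that("pediatric filter uses strict bounds and drops missing ages", {
  rec <- data.frame(primaryid = as.character(1:5),
                    age_years = c(0, 0.5, 17.99, 18, NA))
  out <- filter_pediatric(rec)
  expect_equal(out$age_years, c(0.5, 17.99))
  cts <- attr(out, "counts")
  expect_equal(unname(cts["excluded_age"]), 2L)
  expect_equal(unname(cts["missing_age"]), 1L)
  # idempotent
  expect_equal(as.data.frame(filter_pediatric(out)), as.data.frame(out),
               ignore_attr = TRUE)
  # all-missing -> empty
  expect_equal(nrow(filter_pediatric(data.frame(age_years = c(NA_real_, NA)))),
               0L)
})

test_that("primary suspect is the PS row with the lowest drug_seq", {
  drug <- data.frame(primaryid = "1",
                     drug_seq = c("3", "1", "2"),
                     role_cod = "PS",
                     drugname = c("C", "A", "B"))
  expect_equal(select_primary_suspect(drug)$drugname, "A")

  conc <- data.frame(primaryid = "1", drug_seq = c("1", "2"),
                     role_cod = "C", drugname = c("A", "B"))
  expect_equal(nrow(select_primary_suspect(conc)), 0L)

  # non-numeric drug_seq sorts last and is counted
  odd <- data.frame(primaryid = "1", drug_seq = c("x", "5"),
                    role_cod = "PS", drugname = c("BAD", "GOOD"))
  out <- select_primary_suspect(odd)
  expect_equal(out$drugname, "GOOD")
  expect_equal(attr(out, "n_nonnumeric_seq"), 1L)
})

test_that("time-to-onset computes day differences and categorizes rejections", {
  out <- compute_tto_days(
    start_dt = c("20200101", "20200131", "202001",  NA,        "20200101", "20200101", "20200230"),
    event_dt = c("20200131", "20200101", "20200301", "20200301", "20200101", "20590101", "20200301"))
  expect_equal(out$tto_days[1], 30L)
  expect_equal(as.character(out$reason),
               c("ok", "inconsistent", "incomplete", "missing",
                 "inconsistent", "implausible", "incomplete"))
  expect_true(all(is.na(out$tto_days[-1])))
  # equal dates are inconsistent (difference must be >= 1)
  expect_equal(as.character(compute_tto_days("20200101", "20200101")$reason),
               "inconsistent")
  # one day apart is included
  expect_equal(compute_tto_days("20200101", "20200102")$tto_days, 1L)
})
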