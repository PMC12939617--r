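# Frozen expected values below were computed from the closed-form Wald /
# chi-square / information-component expressions evaluated independently of
# the package (see also the inline oracles in helper-fixtures.R).

test_that("ROR matches the closed-form oracle", {
  r <- ror(10, 90, 100, 9800)
  expect_equal(r$ror, 10.888889, tolerance = 1e-6)
  expect_equal(r$ci_lower, 5.503342, tolerance = 1e-6)
  expect_equal(r$ci_upper, 21.544708, tolerance = 1e-6)
  expect_true(r$flag)
  o <- ror_oracle(10, 90, 100, 9800)
  expect_equal(unname(unlist(r[, 1:3])), unname(o), tolerance = 1e-12)

  expect_equal(ror(5, 5, 5, 5)$ror, 1)       # ad = bc
  expect_false(ror(5, 5, 5, 5)$flag)          # CI spans 1
})

test_that("PRR and Yates chi-square match the oracle", {
  p <- prr(10, 90, 100, 9800)
  expect_equal(p$prr, 9.9, tolerance = 1e-12)
  expect_equal(p$chisq, 65.51404, tolerance = 1e-6)
  o <- prr_oracle(10, 90, 100, 9800)
  expect_equal(unname(unlist(p[, 1:3])), unname(o), tolerance = 1e-12)
  expect_true(p$flag)

  hom <- prr(5, 5, 5, 5)
  expect_equal(hom$prr, 1)
  expect_equal(hom$chisq, 0)  # correction clamps at zero
  expect_false(hom$flag)
})

test_that("flag thresholds are strict: a >= 3 and chi-square > 4", {
  # huge association but only 2 joint reports -> never flagged
  expect_false(ror(2, 1, 1, 10000)$flag)
  expect_false(prr(2, 1, 1, 10000)$flag)
  tab <- prr(3, 97, 100, 9800)
  expect_identical(tab$flag, tab$chisq > 4 & !is.na(tab$prr))
})

test_that("BCPNN information component follows the prior structure", {
  # a=b=c=d=1: gamma = 36/9 = 4 and the E(IC) ratio collapses to 1
  ic <- bcpnn_ic(1, 1, 1, 1)
  expect_equal(ic$ic, 0)
  expect_equal(ic$e_ic, 0, tolerance = 1e-12)
  expect_false(ic$flag)

  # no joint reports cannot signal; raw IC undefined but E(IC) finite
  z <- bcpnn_ic(0, 50, 50, 5000)
  expect_true(is.na(z$ic))
  expect_true(is.finite(z$e_ic))
  expect_false(z$flag)

  # variance shrinks as counts grow at fixed proportions
  v1 <- bcpnn_ic(10, 90, 100, 9800)$v_ic
  v2 <- bcpnn_ic(100, 900, 1000, 98000)$v_ic
  expect_lt(v2, v1)

  # strict mode flags on IC-2SD > 0
  big <- bcpnn_ic(50, 50, 100, 98000, strict = TRUE)
  expect_identical(big$flag, big$ic_minus_2sd > 0)
})

test_that("EBGM score and its lower bound match the oracle", {
  e <- ebgm(10, 90, 100, 9800)
  expect_equal(e$ebgm, 9.090909, tolerance = 1e-6)
  expect_equal(e$ebgm05, 4.610651, tolerance = 1e-6)
  expect_true(e$flag)

  # degenerate identity: only joint reports
  expect_equal(ebgm(7, 0, 0, 0)$ebgm, 1)
  # symmetric in b <-> c
  expect_equal(ebgm(10, 90, 100, 9800)$ebgm, ebgm(10, 100, 90, 9800)$ebgm)
  # zero cell -> undefined bound, no flag
  z <- ebgm(3, 0, 10, 1000)
  expect_true(is.na(z$ebgm05))
  expect_false(z$flag)
  expect_equal(z$reason, "zero cell")
})

test_that("zero cells leave estimates undefined rather than corrected", {
  for (f in list(ror, prr)) {
    z <- f(0, 10, 10, 1000)
    expect_true(is.na(z[[1]]))
    expect_false(z$flag)
    expect_equal(z$reason, "zero cell")
  }
})

test_that("Wald intervals are geometrically centred on the point estimate", {
  tabs <- random_tables(400, seed = 9)
  r <- ror(tabs$a, tabs$b, tabs$c, tabs$d)
  expect_equal(exp((log(r$ci_lower) + log(r$ci_upper)) / 2), r$ror,
               tolerance = 1e-12)
  p <- prr(tabs$a, tabs$b, tabs$c, tabs$d)
  expect_equal(exp((log(p$ci_lower) + log(p$ci_upper)) / 2), p$prr,
               tolerance = 1e-12)
})

test_that("ROR is invariant under swapping b and c", {
  tabs <- random_tables(100, seed = 13)
  expect_equal(ror(tabs$a, tabs$b, tabs$c, tabs$d)$ror,
               ror(tabs$a, tabs$c, tabs$b, tabs$d)$ror)
})

test_that("point estimates are monotone in a at fixed margins", {
  # moving one report into the joint cell (a+1, b-1, c-1, d+1) preserves
  # the margins a+b, a+c and N
  set.seed(31)
  for (i in 1:50) {
    a <- sample(1:20, 1); b <- sample(2:500, 1)
    c <- sample(2:100, 1); d <- sample(1000:50000, 1)
    expect_gte(ror(a + 1, b - 1, c - 1, d + 1)$ror, ror(a, b, c, d)$ror)
    expect_gte(prr(a + 1, b - 1, c - 1, d + 1)$prr, prr(a, b, c, d)$prr)
    expect_gte(ebgm(a + 1, b - 1, c - 1, d + 1)$ebgm, ebgm(a, b, c, d)$ebgm)
    expect_gte(bcpnn_ic(a + 1, b - 1, c - 1, d + 1)$e_ic,
               bcpnn_ic(a, b, c, d)$e_ic)
  }
})

test_that("ROR >= PRR >= EBGM on positively associated tables", {
  tabs <- random_tables(400, seed = 17, nmax = 500)
  pos <- with(tabs, a * d >= b * c)   # the ordering flips for inverse signals
  tabs <- tabs[pos, ]
  r <- ror(tabs$a, tabs$b, tabs$c, tabs$d)$ror
  p <- prr(tabs$a, tabs$b, tabs$c, tabs$d)$prr
  e <- ebgm(tabs$a, tabs$b, tabs$c, tabs$d)$ebgm
  expect_gt(nrow(tabs), 50)
  expect_true(all(r >= p - 1e-12))
  expect_true(all(p >= e - 1e-12))
})

test_that("contingency tables enumerate the dataset correctly", {
  ds <- data.table::data.table(
    primaryid = as.character(1:4),
    generic = c("X", "X", "Y", "Z"),
    is_case = c(TRUE, FALSE, TRUE, FALSE))
  tab <- build_contingency(ds, "X")
  expect_equal(unlist(tab[c("a", "b", "c", "d")]),
               c(a = 1L, b = 1L, c = 1L, d = 1L))
  # absent drug: a = b = 0, margins intact
  none <- build_contingency(ds, "NOPE")
  expect_equal(none$a + none$b, 0L)
  expect_equal(none$c, 2L)
  expect_equal(none$n, 4L)
})

test_that("consensus requires all four algorithms", {
  expect_true(evaluate_signal(TRUE, TRUE, TRUE, TRUE))
  expect_false(evaluate_signal(TRUE, FALSE, FALSE, FALSE))
  expect_false(evaluate_signal(TRUE, TRUE, TRUE, NA))  # undefined is FALSE
})

test_that("screening respects the minimum report threshold and sort order", {
  set.seed(77)
  ds <- data.table::data.table(
    primaryid = as.character(1:10000),
    generic = sample(c("A", "B", "RARE", NA), 10000, TRUE,
                     prob = c(0.3, 0.3, 0.001, 0.399)),
    is_case = FALSE)
  ds[generic == "RARE", is_case := TRUE]            # a = 2-ish, huge ROR
  ds[sample(which(ds$generic == "A"), 50), is_case := TRUE]
  ds[sample(which(is.na(ds$generic)), 30), is_case := TRUE]
  out <- screen_signals(ds, min_reports = 3)
  if (sum(ds$generic == "RARE", na.rm = TRUE) < 3) {
    expect_false("RARE" %in% out$generic)
  }
  expect_true(all(out$a >= 3))
  expect_equal(out$ror, sort(out$ror, decreasing = TRUE, na.last = TRUE))
  # empty dataset and case-free dataset
  expect_equal(nrow(screen_signals(ds[is_case == FALSE][generic == "ZZZ"])), 0L)
})
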