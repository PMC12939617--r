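# Shared fixtures: tiny in-code bundles, small generator configs, and the
# independently coded oracles used to cross-check the package's statistics.

tiny_bundle <- function() {
  demo <- faers_table(data.frame(
    primaryid = c("101", "102", "103", "104"),
    caseid = c("1", "2", "3", "4"),
    fda_dt = rep("20200101", 4),
    age = c("5", "10", "15", "2"),
    age_cod = rep("YR", 4),
    sex = c("M", "F", "M", "F"),
    event_dt = rep(NA_character_, 4)), "DEMO")
  drug <- faers_table(data.frame(
    primaryid = c("101", "102", "103", "104"),
    drug_seq = "1", role_cod = "PS",
    drugname = c("DRUG X", "DRUG X", "DRUG Y", "DRUG Z")), "DRUG")
  reac <- faers_table(data.frame(
    primaryid = c("101", "103"),
    pt = c("10007739", "10007748")), "REAC")
  assemble_quarter(list(demo, drug, reac))
}

small_config <- function(n = 2000, seed = 1, ...) {
  generator_config(n_reports = n, seed = seed, ...)
}

# catalogue with one planted drug at a given rate ratio against one filler
planted_config <- function(n, seed, rho, exposure = 0.02, p_case = 0.005,
                           ...) {
  generator_config(
    n_reports = n, seed = seed,
    drug_catalogue = data.table::data.table(
      generic = c("TARGETDRUG", "FILLERDRUG"),
      exposure = c(exposure, 1 - exposure),
      drug_class = c("other", "other")),
    planted_pairs = data.table::data.table(generic = "TARGETDRUG",
                                           rate_ratio = rho),
    p_case = p_case, ...)
}

# independently coded two-sample log-rank statistic: hypergeometric
# observed-minus-expected summed over distinct event times
logrank_oracle <- function(t1, t2) {
  times <- sort(unique(c(t1, t2)))
  o_minus_e <- 0
  v <- 0
  for (tt in times) {
    n1 <- sum(t1 >= tt); n2 <- sum(t2 >= tt); n <- n1 + n2
    d1 <- sum(t1 == tt); d2 <- sum(t2 == tt); d <- d1 + d2
    if (n < 2) next
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

# textbook Wald oracles, coded independently of the package's vectorized path
ror_oracle <- function(a, b, c, d) {
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(est = est, lo = exp(log(est) - 1.96 * se), hi = exp(log(est) + 1.96 * se))
}

prr_oracle <- function(a, b, c, d) {
  est <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  c(est = est, lo = exp(log(est) - 1.96 * se), hi = exp(log(est) + 1.96 * se))
}

random_tables <- function(n, seed, nmax = 2000) {
  set.seed(seed)
  data.frame(a = sample(1:50, n, TRUE), b = sample(1:nmax, n, TRUE),
             c = sample(1:200, n, TRUE), d = sample(100:50000, n, TRUE))
}
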