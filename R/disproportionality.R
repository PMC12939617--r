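# Four-algorithm disproportionality screening on 2x2 contingency tables.
#
# Cell layout, with the deduplicated pediatric dataset as background:
#   a  reports with the target drug (primary suspect) AND a case PT
#   b  reports with the target drug and other reactions
#   c  reports with other drugs and a case PT
#   d  reports with other drugs and other reactions
#   N = a + b + c + d

#' Build the 2x2 contingency table for one drug
#'
#' @param dataset a per-report analysis `data.table` (one row per
#'   deduplicated pediatric report) with columns `generic` (primary-suspect
#'   generic entity, `NA` if none) and a logical case column.
#' @param drug generic entity to tabulate.
#' @param case_col name of the logical case column (default `"is_case"`).
#' @return a `contingency_2x2` list with integer `a`, `b`, `c`, `d`, `n`.
#' @export
build_contingency <- function(dataset, drug, case_col = "is_case") {
  dt <- as.data.table(dataset)
  case <- dt[[case_col]]
  stopifnot(is.logical(case))
  tgt <- !is.na(dt$generic) & dt$generic == drug
  a <- sum(tgt & case)
  b <- sum(tgt & !case)
  cc <- sum(!tgt & case)
  d <- sum(!tgt & !case)
  structure(list(a = a, b = b, c = cc, d = d, n = a + b + cc + d),
            class = "contingency_2x2")
}

.abcd <- function(a, b, c, d) {
  if (inherits(a, "contingency_2x2")) {
    list(a = as.numeric(a$a), b = as.numeric(a$b),
         c = as.numeric(a$c), d = as.numeric(a$d))
  } else {
    # double arithmetic: margin products overflow 32-bit integers
    list(a = as.numeric(a), b = as.numeric(b),
         c = as.numeric(c), d = as.numeric(d))
  }
}

#' Reporting odds ratio
#'
#' ROR = (a d)/(b c) with Wald 95% CI
#' \eqn{\exp(\ln ROR \pm 1.96 \sqrt{1/a + 1/b + 1/c + 1/d})}.
#' Signal criterion: a >= 3 and CI lower bound > 1. No continuity
#' correction: any zero cell leaves the estimate undefined and the flag
#' `FALSE` with reason `"zero cell"`.
#'
#' @param a,b,c,d integer vectors of cell counts, or a single
#'   `contingency_2x2` as `a`.
#' @return `data.table` with `ror`, `ci_lower`, `ci_upper`, `flag`, `reason`.
#' @export
ror <- function(a, b = NULL, c = NULL, d = NULL) {
  x <- .abcd(a, b, c, d)
  ok <- x$a > 0 & x$b > 0 & x$c > 0 & x$d > 0
  est <- lo <- hi <- rep(NA_real_, length(x$a))
  est[ok] <- (x$a[ok] * x$d[ok]) / (x$b[ok] * x$c[ok])
  se <- sqrt(1 / x$a[ok] + 1 / x$b[ok] + 1 / x$c[ok] + 1 / x$d[ok])
  lo[ok] <- exp(log(est[ok]) - 1.96 * se)
  hi[ok] <- exp(log(est[ok]) + 1.96 * se)
  flag <- ok & x$a >= 3 & !is.na(lo) & lo > 1
  data.table(ror = est, ci_lower = lo, ci_upper = hi, flag = flag,
             reason = fifelse(ok, NA_character_, "zero cell"))
}

#' Proportional reporting ratio with Yates chi-square
#'
#' PRR = (a/(a+b)) / (c/(c+d)); 95% CI
#' \eqn{\exp(\ln PRR \pm 1.96\sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)})}.
#' The chi-square is the Yates-corrected statistic
#' \eqn{N(|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))},
#' clamped to 0 when the correction exceeds `|ad - bc|`.
#' Signal criterion: a >= 3 and chi-square > 4 (strict).
#'
#' @inheritParams ror
#' @return `data.table` with `prr`, `ci_lower`, `ci_upper`, `chisq`, `flag`,
#'   `reason`.
#' @export
prr <- function(a, b = NULL, c = NULL, d = NULL) {
  x <- .abcd(a, b, c, d)
  n <- x$a + x$b + x$c + x$d
  ok <- x$a > 0 & x$b > 0 & x$c > 0 & x$d > 0
  est <- lo <- hi <- rep(NA_real_, length(x$a))
  est[ok] <- (x$a[ok] / (x$a[ok] + x$b[ok])) / (x$c[ok] / (x$c[ok] + x$d[ok]))
  se <- sqrt(1 / x$a[ok] - 1 / (x$a[ok] + x$b[ok]) +
             1 / x$c[ok] - 1 / (x$c[ok] + x$d[ok]))
  lo[ok] <- exp(log(est[ok]) - 1.96 * se)
  hi[ok] <- exp(log(est[ok]) + 1.96 * se)
  chisq <- yates_chisq(x$a, x$b, x$c, x$d)
  flag <- ok & x$a >= 3 & !is.na(chisq) & chisq > 4
  data.table(prr = est, ci_lower = lo, ci_upper = hi, chisq = chisq,
             flag = flag, reason = fifelse(ok, NA_character_, "zero cell"))
}

#' Yates-corrected chi-square for a 2x2 table
#'
#' @inheritParams ror
#' @return numeric vector; 0 when the continuity correction N/2 exceeds
#'   `|ad - bc|`, `NA` when any margin is zero.
#' @export
yates_chisq <- function(a, b = NULL, c = NULL, d = NULL) {
  x <- .abcd(a, b, c, d)
  n <- x$a + x$b + x$c + x$d
  denom <- (x$a + x$b) * (x$c + x$d) * (x$a + x$c) * (x$b + x$d)
  num <- pmax(abs(x$a * x$d - x$b * x$c) - n / 2, 0)
  fifelse(denom > 0, n * num^2 / denom, NA_real_)
}

#' BCPNN prior counts
#'
#' Defaults \eqn{\alpha_1=\beta_1=1}, \eqn{\alpha=\beta=2},
#' \eqn{\gamma_{11}=1}; the per-table normalizer \eqn{\gamma} is derived
#' inside [bcpnn_ic()].
#'
#' @param alpha1,beta1,alpha,beta,gamma11 positive prior counts.
#' @return list of priors.
#' @export
bcpnn_priors <- function(alpha1 = 1, beta1 = 1, alpha = 2, beta = 2,
                         gamma11 = 1) {
  stopifnot(alpha1 > 0, beta1 > 0, alpha > 0, beta > 0, gamma11 > 0)
  list(alpha1 = alpha1, beta1 = beta1, alpha = alpha, beta = beta,
       gamma11 = gamma11)
}

#' BCPNN information component
#'
#' Raw IC = log2(a N / ((a+b)(a+c))). The shrunk expectation and variance
#' use Dirichlet-style priors with per-table normalizer
#' \eqn{\gamma = \gamma_{11} (N+\alpha)(N+\beta) /
#' ((a+b+\alpha_1)(a+c+\beta_1))}:
#' \deqn{E(IC) = \log_2 \frac{(a+\gamma_{11})(N+\alpha)(N+\beta)}
#'   {(N+\gamma)(a+b+\alpha_1)(a+c+\beta_1)}}
#' \deqn{V(IC) = \frac{1}{\ln^2 2}\left[
#'   \frac{N-a+\gamma-\gamma_{11}}{(a+\gamma_{11})(1+N+\gamma)} +
#'   \frac{N-(a+b)+\alpha-\alpha_1}{(a+b+\alpha_1)(1+N+\alpha)} +
#'   \frac{N-(a+c)+\beta-\beta_1}{(a+c+\beta_1)(1+N+\beta)}\right]}
#' IC-2SD = E(IC) - 2 sqrt(V(IC)) (the IC025-style lower bound shown in
#' figures). Signal criterion: E(IC) > 0 by default; `strict = TRUE` flags
#' on IC-2SD > 0 instead (the two conventions are both surfaced because the
#' criteria column and figure labels of published screens differ).
#'
#' When a = 0 the raw IC is undefined (`-Inf` observed/expected); E(IC)
#' remains defined through the priors and the raw IC is returned `NA`.
#'
#' @inheritParams ror
#' @param priors from [bcpnn_priors()].
#' @param strict flag on IC-2SD > 0 instead of E(IC) > 0.
#' @return `data.table` with `ic`, `e_ic`, `v_ic`, `ic_minus_2sd`, `flag`.
#' @export
bcpnn_ic <- function(a, b = NULL, c = NULL, d = NULL,
                     priors = bcpnn_priors(), strict = FALSE) {
  x <- .abcd(a, b, c, d)
  n <- x$a + x$b + x$c + x$d
  p <- priors
  ab <- x$a + x$b
  ac <- x$a + x$c
  gamma <- p$gamma11 * (n + p$alpha) * (n + p$beta) /
    ((ab + p$alpha1) * (ac + p$beta1))
  e_ic <- log2((x$a + p$gamma11) * (n + p$alpha) * (n + p$beta) /
                 ((n + gamma) * (ab + p$alpha1) * (ac + p$beta1)))
  v_ic <- (1 / log(2)^2) * (
    (n - x$a + gamma - p$gamma11) / ((x$a + p$gamma11) * (1 + n + gamma)) +
    (n - ab + p$alpha - p$alpha1) / ((ab + p$alpha1) * (1 + n + p$alpha)) +
    (n - ac + p$beta - p$beta1) / ((ac + p$beta1) * (1 + n + p$beta))
  )
  ic <- fifelse(x$a > 0 & ab > 0 & ac > 0,
                log2(x$a * n / (ab * ac)), NA_real_)
  lo <- e_ic - 2 * sqrt(v_ic)
  flag <- if (strict) lo > 0 else e_ic > 0
  data.table(ic = ic, e_ic = e_ic, v_ic = v_ic, ic_minus_2sd = lo,
             flag = flag & x$a > 0)
}

#' Empirical Bayes geometric mean score
#'
#' EBGM = a N / ((a+c)(a+b)) — the relative reporting ratio — with lower
#' bound \eqn{EBGM05 = \exp(\ln EBGM - 1.95 \sqrt{1/a+1/b+1/c+1/d})}; the
#' 1.95 multiplier is deliberate (the convention of the screening criteria
#' implemented here). Signal criterion: a > 0 and EBGM05 > 2.
#'
#' Note this is the unshrunk observed/expected score, not the full
#' gamma-Poisson mixture shrinkage estimator sometimes published under the
#' same name; for screening with the EBGM05 > 2 rule the two agree closely
#' at the counts that matter, but small-count estimates here are not shrunk.
#'
#' @inheritParams ror
#' @return `data.table` with `ebgm`, `ebgm05`, `flag`, `reason`.
#' @export
ebgm <- function(a, b = NULL, c = NULL, d = NULL) {
  x <- .abcd(a, b, c, d)
  n <- x$a + x$b + x$c + x$d
  ab <- x$a + x$b
  ac <- x$a + x$c
  est <- fifelse(x$a > 0 & ab > 0 & ac > 0, x$a * n / (ac * ab), NA_real_)
  ok <- x$a > 0 & x$b > 0 & x$c > 0 & x$d > 0
  lo <- rep(NA_real_, length(x$a))
  se <- sqrt(1 / x$a[ok] + 1 / x$b[ok] + 1 / x$c[ok] + 1 / x$d[ok])
  lo[ok] <- exp(log(est[ok]) - 1.95 * se)
  flag <- x$a > 0 & !is.na(lo) & lo > 2
  data.table(ebgm = est, ebgm05 = lo, flag = flag,
             reason = fifelse(ok, NA_character_, "zero cell"))
}

#' Consensus evaluation of the four algorithm flags
#'
#' A signal is positive only if flagged by all four algorithms; an undefined
#' statistic counts as not flagged.
#'
#' @param ror_flag,prr_flag,bcpnn_flag,mgps_flag logical vectors (NA treated
#'   as FALSE).
#' @return logical vector of consensus flags.
#' @export
evaluate_signal <- function(ror_flag, prr_flag, bcpnn_flag, mgps_flag) {
  f <- function(x) !is.na(x) & x
  f(ror_flag) & f(prr_flag) & f(bcpnn_flag) & f(mgps_flag)
}

#' Screen all drugs for disproportionality signals
#'
#' Builds every per-drug 2x2 table against the full dataset background,
#' computes ROR, PRR + Yates chi-square, BCPNN IC and EBGM with their signal
#' criteria, and the consensus flag. Only drugs with at least `min_reports`
#' case reports (a >= `min_reports`) are returned, sorted by descending ROR
#' (ties: larger a, then name; undefined RORs last).
#'
#' @param dataset per-report analysis `data.table` with `generic` and the
#'   case column.
#' @param case_col logical case column name (`"is_case"`; use the narrow
#'   column for sensitivity screens).
#' @param min_reports minimum case-report count per drug (default 3).
#' @param priors BCPNN priors.
#' @param bcpnn_strict flag BCPNN on IC-2SD > 0 instead of E(IC) > 0.
#' @param drugs optional character vector restricting the screen.
#' @return a `data.table`, one row per drug: counts, all four statistics with
#'   CIs/bounds, `log10_ror`, per-algorithm flags and `consensus_flag`.
#' @export
screen_signals <- function(dataset, case_col = "is_case", min_reports = 3,
                           priors = bcpnn_priors(), bcpnn_strict = FALSE,
                           drugs = NULL) {
  dt <- as.data.table(dataset)
  if (!nrow(dt)) return(data.table())
  case <- dt[[case_col]]
  n <- nrow(dt)
  n_cases <- sum(case)
  per <- data.table(generic = dt$generic, case = case)
  tab <- per[!is.na(generic), .(a = sum(case), exposed = .N), by = generic]
  if (!is.null(drugs)) tab <- tab[generic %in% drugs]
  tab[, `:=`(b = exposed - a, c = n_cases - a, d = n - exposed - (n_cases - a))]
  tab <- tab[a >= min_reports]
  if (!nrow(tab)) return(tab)
  r <- ror(tab$a, tab$b, tab$c, tab$d)
  p <- prr(tab$a, tab$b, tab$c, tab$d)
  ic <- bcpnn_ic(tab$a, tab$b, tab$c, tab$d, priors = priors,
                 strict = bcpnn_strict)
  e <- ebgm(tab$a, tab$b, tab$c, tab$d)
  out <- data.table(
    generic = tab$generic, a = tab$a, b = tab$b, c = tab$c, d = tab$d,
    ror = r$ror, ror_ci_lower = r$ci_lower, ror_ci_upper = r$ci_upper,
    log10_ror = log10(r$ror),
    prr = p$prr, prr_ci_lower = p$ci_lower, prr_ci_upper = p$ci_upper,
    chisq = p$chisq,
    ic = ic$ic, e_ic = ic$e_ic, v_ic = ic$v_ic,
    ic_minus_2sd = ic$ic_minus_2sd,
    ebgm = e$ebgm, ebgm05 = e$ebgm05,
    ror_flag = r$flag, prr_flag = p$flag, bcpnn_flag = ic$flag,
    mgps_flag = e$flag
  )
  out[, consensus_flag := evaluate_signal(ror_flag, prr_flag, bcpnn_flag,
                                          mgps_flag)]
  setorder(out, -ror, -a, generic, na.last = TRUE)
  out[]
}
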