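#' False-positive rate with binomial standard error
#'
#' The false-positive rate is the number of false-positive detections
#' divided by the total number of detections; its uncertainty is the
#' binomial standard error `sqrt(rate * (1 - rate) / n)`. This is the
#' estimator behind the scenario summary table (where the SD column is this
#' standard error) and the per-species rates.
#'
#' @param n_fp Number of false-positive detections (vectorized).
#' @param n_detections Total number of detections (vectorized, > 0).
#' @return data.frame with columns `rate` and `se`.
#' @examples
#' fp_rate(31, 959)   # expert DDO scenario: 0.032 (se 0.006)
#' fp_rate(692, 3111) # overall: 0.222
#' @export
fp_rate <- function(n_fp, n_detections) {
  if (any(n_detections <= 0)) {
    stop("n_detections must be positive (rate undefined for 0 detections)")
  }
  if (any(n_fp < 0) || any(n_fp > n_detections)) {
    stop("need 0 <= n_fp <= n_detections")
  }
  rate <- n_fp / n_detections
  data.frame(rate = rate, se = sqrt(rate * (1 - rate) / n_detections))
}

#' Scenario summary table of false-positive rates
#'
#' Applies [fp_rate()] to each (experience x method) scenario row and
#' appends a pooled `Total` row. The detection-weighted mean of the scenario
#' rates equals the pooled rate exactly (both are ratios of summed counts).
#'
#' @param counts data.frame with columns `experience`, `method`,
#'   `n_surveys` (optional), `n_detections`, `n_fp`.
#' @return `counts` with `rate` and `se` columns added and a final pooled
#'   row (`experience = "Total"`).
#' @export
scenario_rate_table <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("experience", "method", "n_detections", "n_fp")
                %in% names(counts)))
  r <- fp_rate(counts$n_fp, counts$n_detections)
  out <- cbind(counts, r)
  total <- counts[1, , drop = FALSE]
  total$experience <- "Total"
  total$method <- ""
  if ("n_surveys" %in% names(total)) total$n_surveys <- sum(counts$n_surveys)
  total$n_detections <- sum(counts$n_detections)
  total$n_fp <- sum(counts$n_fp)
  total <- cbind(total, fp_rate(total$n_fp, total$n_detections))
  rbind(out, total)
}

cell_odds <- function(n_fp, n_detections) n_fp / (n_detections - n_fp)

#' Saturated logistic regression on a 2 x 2 scenario design
#'
#' Fits the binomial logit of the false-positive indicator on
#' experience x method with the full interaction. Because the design is
#' saturated, the fit is available in closed form from the four cell odds
#' `fp / (detections - fp)`:
#' \itemize{
#'   \item intercept: the odds of the reference cell;
#'   \item each main effect: the odds ratio of the cell differing from the
#'     reference in that factor only;
#'   \item interaction: the ratio of the fourth cell's odds ratio to the
#'     product of the two main-effect odds ratios.
#' }
#' Standard errors follow the classical log-odds-ratio formula
#' `sqrt(sum(1/k))` over the 2, 4 or 8 counts entering each term
#' (reported exponentiated, matching the odds scale of the estimates), with
#' Wald confidence intervals and p values. An iteratively fitted
#' `stats::glm` reproduces these numbers to machine precision; the closed
#' form is used so every reported quantity is an explicit function of the
#' counts.
#'
#' @param cells data.frame with one row per (experience x method) cell and
#'   columns `experience`, `method`, `n_detections`, `n_fp`. Exactly four
#'   cells over two experience levels and two methods.
#' @param reference Length-2 named character vector giving the reference
#'   levels, default `c(experience = "expert", method = "DDO")`.
#' @param conf_level Confidence level for the Wald intervals (default 0.95).
#' @param ci Interval type: `"wald"` (closed form, default) or `"profile"`
#'   (profile likelihood via `stats::glm` + `MASS::confint`, slightly wider
#'   in small cells).
#' @return Object of class `logit_result`: data.frame with one row per term
#'   (`intercept`, the two main effects named after the non-reference
#'   levels, and their interaction) and columns `estimate` (odds scale),
#'   `exp_se` (exponentiated SE of the log estimate), `ci_low`, `ci_high`
#'   (odds scale), and `p_value` (Wald test of log estimate = 0).
#' @examples
#' counts <- reference_scenario_counts()
#' fit_saturated_logit(counts)
#' @export
fit_saturated_logit <- function(cells,
                                reference = c(experience = "expert",
                                              method = "DDO"),
                                conf_level = 0.95,
                                ci = c("wald", "profile")) {
  ci <- match.arg(ci)
  stopifnot(is.data.frame(cells),
            all(c("experience", "method", "n_detections", "n_fp")
                %in% names(cells)))
  if (nrow(cells) != 4L) stop("need exactly the four experience x method cells")
  exps <- unique(cells$experience)
  meths <- unique(cells$method)
  if (length(exps) != 2L || length(meths) != 2L ||
      anyDuplicated(paste(cells$experience, cells$method))) {
    stop("cells must form a complete 2 x 2 experience x method design")
  }
  if (!(reference[["experience"]] %in% exps) ||
      !(reference[["method"]] %in% meths)) {
    stop("reference levels not present in cells")
  }
  k_fp <- cells$n_fp
  k_ok <- cells$n_detections - cells$n_fp
  if (any(k_fp <= 0) || any(k_ok <= 0)) {
    stop(paste("every cell needs at least one false positive and one",
               "correct detection; the saturated odds are undefined",
               "otherwise. Pool cells or apply an explicit continuity",
               "correction before refitting."))
  }
  e0 <- reference[["experience"]]; e1 <- setdiff(exps, e0)
  m0 <- reference[["method"]];     m1 <- setdiff(meths, m0)
  cell <- function(e, m) {
    i <- which(cells$experience == e & cells$method == m)
    c(fp = k_fp[i], ok = k_ok[i])
  }
  c00 <- cell(e0, m0); c10 <- cell(e1, m0)
  c01 <- cell(e0, m1); c11 <- cell(e1, m1)
  odds <- function(x) x[["fp"]] / x[["ok"]]

  est <- c(odds(c00),
           odds(c10) / odds(c00),
           odds(c01) / odds(c00),
           odds(c11) * odds(c00) / (odds(c10) * odds(c01)))
  se_log <- c(sqrt(sum(1 / c00)),
              sqrt(sum(1 / c00) + sum(1 / c10)),
              sqrt(sum(1 / c00) + sum(1 / c01)),
              sqrt(sum(1 / c00) + sum(1 / c10) +
                     sum(1 / c01) + sum(1 / c11)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lo <- est * exp(-z * se_log)
  hi <- est * exp(z * se_log)
  p <- 2 * stats::pnorm(-abs(log(est)) / se_log)

  if (ci == "profile") {
    if (!requireNamespace("MASS", quietly = TRUE)) {
      stop("profile-likelihood intervals need the MASS package")
    }
    fit <- stats::glm(
      cbind(n_fp, n_detections - n_fp) ~ experience * method,
      family = stats::binomial(),
      data = transform(cells,
                       experience = stats::relevel(factor(experience), e0),
                       method = stats::relevel(factor(method), m0)))
    pci <- suppressMessages(exp(stats::confint(fit, level = conf_level)))
    lo <- unname(pci[, 1]); hi <- unname(pci[, 2])
  }

  out <- data.frame(
    term = c("intercept", e1, m1, paste(e1, "x", m1)),
    estimate = est,
    exp_se = exp(se_log),
    ci_low = lo,
    ci_high = hi,
    p_value = p,
    stringsAsFactors = FALSE)
  class(out) <- c("logit_result", "data.frame")
  out
}

#' Percent reduction between two false-positive rates
#'
#' `100 * (rate_iso - rate_ddo) / rate_iso`, computed after rounding both
#' rates to `digits` decimals. Rounding first reproduces headline
#' percentages quoted from printed-precision rates (published summaries are
#' typically computed from the 3-decimal rates they print).
#'
#' @param rate_iso Baseline (single-observer) rate, > 0 after rounding.
#' @param rate_ddo Comparison (double-observer) rate.
#' @param digits Decimals to round the input rates to before comparing
#'   (default 3); use `Inf` for no rounding.
#' @return Percent reduction (positive when `rate_ddo < rate_iso`).
#' @examples
#' percent_reduction(0.095, 0.032) # 66.3% for expert observers
#' @export
percent_reduction <- function(rate_iso, rate_ddo, digits = 3) {
  if (is.finite(digits)) {
    rate_iso <- round(rate_iso, digits)
    rate_ddo <- round(rate_ddo, digits)
  }
  if (any(rate_iso <= 0)) stop("rate_iso must be positive")
  100 * (rate_iso - rate_ddo) / rate_iso
}

#' Per-species false-positive rates with normal-approximation intervals
#'
#' Same estimator as [fp_rate()] applied per species, plus a 95% (or
#' `conf_level`) normal-approximation confidence interval truncated to
#' \[0, 1\]. Species with zero detections get `NA` rates (undefined, not
#' zero). At 0 observed false positives the interval degenerates to
#' \[0, 0\] — a known weakness of the Wald interval near the boundary.
#'
#' @param counts data.frame with columns `species`, `n_fp`, `n_detections`
#'   (plus any grouping columns, carried through).
#' @param conf_level Confidence level (default 0.95).
#' @return `counts` with `rate`, `se`, `ci_low`, `ci_high` added.
#' @export
per_species_rates <- function(counts, conf_level = 0.95) {
  stopifnot(is.data.frame(counts),
            all(c("species", "n_fp", "n_detections") %in% names(counts)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ok <- counts$n_detections > 0
  rate <- se <- rep(NA_real_, nrow(counts))
  if (any(ok)) {
    r <- fp_rate(counts$n_fp[ok], counts$n_detections[ok])
    rate[ok] <- r$rate
    se[ok] <- r$se
  }
  counts$rate <- rate
  counts$se <- se
  counts$ci_low <- pmax(0, rate - z * se)
  counts$ci_high <- pmin(1, rate + z * se)
  counts
}
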