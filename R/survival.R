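#' Median dichotomization of an expression covariate
#'
#' Splits samples into a high and a low expression group at the median of
#' the covariate. The tie rule is declared: values strictly greater than
#' the median go to `"high"`, values less than or equal to the median go to
#' `"low"`.
#'
#' @param table A survival tibble (`sample_id`, `time`, `event`,
#'   `covariate`), see [read_survival_table()].
#' @return The table with an added `group` factor (`"low"`, `"high"`).
#' @export
#' @examples
#' tb <- tibble::tibble(sample_id = letters[1:4], time = 1:4,
#'                      event = c(1L, 1L, 0L, 1L), covariate = c(1, 2, 3, 4))
#' median_split(tb)$group
median_split <- function(table) {
  tb <- validate_survival_table(table)
  x <- tb$covariate
  if (sum(is.finite(x)) < 4) {
    stop("need >= 4 samples with finite covariate values", call. = FALSE)
  }
  med <- stats::median(x[is.finite(x)])
  if (all(x[is.finite(x)] == med)) {
    stop("degenerate split: all covariate values equal the median", call. = FALSE)
  }
  tb$group <- factor(ifelse(x > med, "high", "low"), levels = c("low", "high"))
  tb
}

#' Kaplan-Meier product-limit estimator
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`, where `d_i`
#' counts events and `n_i` the at-risk set at `t_i`. Censored times shrink
#' the risk set without producing a step; a subject censored exactly at an
#' event time is counted at risk for that time (the textbook convention).
#'
#' @param table A survival tibble; a `group` column (from [median_split()])
#'   yields one curve per group.
#' @return A `km_curve` tibble: `group` (if any), `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`.
#' @export
kaplan_meier <- function(table) {
  tb <- tibble::as_tibble(table)
  if (nrow(tb) == 0) stop("empty survival table", call. = FALSE)
  if (any(tb$time < 0, na.rm = TRUE)) stop("negative survival time", call. = FALSE)
  one <- function(d) {
    times <- sort(unique(d$time))
    f <- factor(d$time, levels = times)
    d_i <- as.integer(tapply(d$event == 1L, f, sum, default = 0L))
    c_i <- as.integer(tapply(d$event == 0L, f, sum, default = 0L))
    leaving <- d_i + c_i
    n_risk <- nrow(d) - c(0L, cumsum(leaving)[-length(times)])
    tibble::tibble(time = times, n_risk = n_risk, n_event = d_i,
                   n_censor = c_i, survival = cumprod(1 - d_i / n_risk))
  }
  out <- if ("group" %in% names(tb)) {
    dplyr::bind_rows(lapply(split(tb, tb$group), one), .id = "group")
  } else {
    one(tb)
  }
  class(out) <- c("km_curve", class(out))
  out
}

#' Two-group log-rank test
#'
#' Chi-square(1) test comparing two survival curves. At each distinct event
#' time the observed group-1 events are compared with their hypergeometric
#' expectation given the margins; the statistic is `(O - E)^2 / V` with O,
#' E and the hypergeometric variance V summed over event times, and the
#' p-value is the upper chi-square(1) tail. Tied events are aggregated per
#' distinct time.
#'
#' @param table A survival tibble.
#' @param groups Group labels aligned with `table` rows (two levels), or
#'   NULL to use `table$group` (e.g. from [median_split()]).
#' @return A `logrank_result`: `statistic`, `p_value`, `n_per_group`,
#'   `observed`, `expected` (group-1 totals).
#' @export
logrank_test <- function(table, groups = NULL) {
  tb <- tibble::as_tibble(table)
  g <- groups %||% tb$group
  if (is.null(g)) stop("no group labels supplied", call. = FALSE)
  g <- factor(g)
  if (nlevels(g) != 2) stop("exactly two groups are required", call. = FALSE)
  if (any(table(g) == 0)) stop("both groups must be nonempty", call. = FALSE)
  is1 <- g == levels(g)[1]
  all_times <- sort(unique(tb$time))
  f <- factor(tb$time, levels = all_times)
  d_all <- as.integer(tapply(tb$event == 1L, f, sum, default = 0L))
  d_1 <- as.integer(tapply(tb$event == 1L & is1, f, sum, default = 0L))
  leave_all <- as.integer(tabulate(f, nbins = length(all_times)))
  leave_1 <- as.integer(tapply(is1, f, sum, default = 0L))
  n_all <- nrow(tb) - c(0L, cumsum(leave_all)[-length(all_times)])
  n_1 <- sum(is1) - c(0L, cumsum(leave_1)[-length(all_times)])
  ev <- d_all > 0
  n_j <- n_all[ev]; n1j <- n_1[ev]; d_j <- d_all[ev]; d1j <- d_1[ev]
  O <- sum(d1j)
  E <- sum(d_j * n1j / n_j)
  V <- sum(ifelse(n_j > 1,
                  d_j * (n1j / n_j) * (1 - n1j / n_j) * (n_j - d_j) / (n_j - 1),
                  0))
  if (sum(ev) == 0 || V <= 0) {
    stat <- 0
    p <- 1
  } else {
    stat <- (O - E)^2 / V
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(statistic = stat, p_value = p,
                 n_per_group = as.integer(table(g)),
                 observed = O, expected = E, variance = V,
                 group_levels = levels(g)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f (1 df), p = %.4g\n",
              x$statistic, x$p_value))
  cat(sprintf("  groups %s/%s: n = %d/%d; O = %.0f, E = %.2f\n",
              x$group_levels[1], x$group_levels[2],
              x$n_per_group[1], x$n_per_group[2], x$observed, x$expected))
  invisible(x)
}

#' @method tidy logrank_result
#' @export
tidy.logrank_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 observed = x$observed, expected = x$expected,
                 variance = x$variance,
                 n_group1 = x$n_per_group[1], n_group2 = x$n_per_group[2])
}

#' @method glance logrank_result
#' @export
glance.logrank_result <- function(x, ...) tidy(x)

#' Median-split survival validation of a candidate driver
#'
#' The validation applied to each candidate key driver: dichotomize
#' subjects at the median of the driver's expression, estimate the two
#' Kaplan-Meier curves, and compare them with the log-rank test.
#'
#' @param table A survival tibble whose `covariate` column holds the
#'   driver's expression.
#' @return A list with `table` (grouped), `km` (the two curves) and
#'   `logrank` (the test result).
#' @export
survival_validation <- function(table) {
  tb <- median_split(table)
  list(table = tb, km = kaplan_meier(tb), logrank = logrank_test(tb))
}
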