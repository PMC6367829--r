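#' Weighted Pearson correlation coefficient
#'
#' Frequency-weight semantics (weights act as replication counts, e.g. the
#' number of repeated motion measurements per patient): weighted means are
#' subtracted, and the weighted covariance is divided by the product of
#' weighted standard deviations.
#'
#' @param x,y numeric vectors (>= 3 observations).
#' @param w positive weights (equal weights reduce to plain Pearson).
#' @return correlation in `[-1, 1]`.
#' @export
weighted_pearson <- function(x, y, w = rep(1, length(x))) {
  stopifnot(length(x) == length(y), length(x) == length(w))
  if (length(x) < 3) stop("at least 3 observations are required", call. = FALSE)
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  mx <- sum(w * x) / sum(w)
  my <- sum(w * y) / sum(w)
  cov <- sum(w * (x - mx) * (y - my))
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) {
    stop("zero weighted variance: correlation undefined", call. = FALSE)
  }
  cov / sqrt(vx * vy)
}

#' t-statistic for a correlation coefficient
#'
#' Small-sample significance statistic `t = rho * sqrt((N - 2) / (1 - rho^2))`
#' for a correlation over N observations. For negative correlations the
#' magnitude `|t|` is what is compared against the one-sided critical value.
#'
#' @param rho correlation coefficient, `|rho| < 1`.
#' @param n number of observations (>= 3).
#' @return list with `t` (signed) and `t_abs`.
#' @export
t_statistic <- function(rho, n) {
  stopifnot(n >= 3)
  if (abs(rho) >= 1) {
    warning("|rho| = 1: t-statistic is infinite")
    t <- sign(rho) * Inf
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
  }
  list(t = t, t_abs = abs(t))
}

#' One-sided critical t value
#'
#' Student-t quantile for a one-sided test at the given confidence level.
#' The default degrees of freedom is 9 (reproducing the tabulated 1.833 for
#' a 9-patient cohort); `df = n - 2` (the regression convention matching the
#' t formula) is the natural alternative and can be requested explicitly.
#'
#' @param df degrees of freedom.
#' @param level one-sided confidence level.
#' @return the critical value t_crit.
#' @export
t_critical <- function(df = 9, level = 0.95) stats::qt(level, df)

#' Significance decision for a correlation t-statistic
#'
#' Significant iff `t > t_crit` (strict inequality); for negative
#' correlations pass the magnitude.
#'
#' @param t the t-statistic (or magnitude).
#' @param t_crit critical value (see [t_critical()]).
#' @return logical.
#' @export
significance <- function(t, t_crit = t_critical()) t > t_crit

#' Inter-patient correlation suite
#'
#' The four study correlations over per-patient observations: CTV motion
#' amplitude vs single-fraction interplay (d5/d95), breathing period vs
#' amplitude, and period vs d5/d95 — all weighted by the number of repeated
#' motion measurements per patient — plus CTV volume vs d5/d95, unweighted
#' (volumes are constant over fractions, so measurement counts carry no
#' information there).
#'
#' @param observations data frame with one row per patient and columns
#'   `amplitude_mm` (mean CTV motion amplitude), `period_s` (mean breathing
#'   period), `d5d95` (mean single-fraction interplay), `volume_cc` (CTV
#'   volume) and `weight` (number of repeated measurements, >= 1 integer).
#' @param df degrees of freedom for the critical value (default 9).
#' @param level one-sided confidence level.
#' @return an `interplay_cor` object; see [tidy.interplay_cor()].
#' @export
correlation_suite <- function(observations, df = 9, level = 0.95) {
  obs <- tibble::as_tibble(observations)
  need <- c("amplitude_mm", "period_s", "d5d95", "volume_cc", "weight")
  if (!all(need %in% names(obs))) {
    stop("observations must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(obs$weight < 1)) stop("weights must be >= 1", call. = FALSE)
  n <- nrow(obs)
  tc <- t_critical(df, level)
  row <- function(pair, x, y, w) {
    rho <- weighted_pearson(obs[[x]], obs[[y]], w)
    ts <- t_statistic(rho, n)
    tibble::tibble(pair = pair, weighted = !all(w == 1), rho = rho,
                   t = ts$t, t_abs = ts$t_abs,
                   t_crit = tc, significant = significance(ts$t_abs, tc))
  }
  tab <- dplyr::bind_rows(
    row("amplitude ~ d5/d95", "amplitude_mm", "d5d95", obs$weight),
    row("period ~ amplitude", "period_s", "amplitude_mm", obs$weight),
    row("period ~ d5/d95", "period_s", "d5d95", obs$weight),
    row("volume ~ d5/d95", "volume_cc", "d5d95", rep(1, n))
  )
  structure(list(table = tab, n = n, df = df, level = level,
                 observations = obs),
            class = "interplay_cor")
}

#' @export
print.interplay_cor <- function(x, ...) {
  cat(sprintf("<interplay_cor> N = %d patients, t_crit = %.3f (df = %g)\n",
              x$n, x$table$t_crit[1], x$df))
  print(x$table)
  invisible(x)
}

#' Tidy the correlation suite
#' @param x an `interplay_cor`.
#' @param ... unused.
#' @return tibble with one row per correlation pair: `pair`, `weighted`,
#'   `rho`, `t`, `t_abs`, `t_crit`, `significant`.
#' @export
tidy.interplay_cor <- function(x, ...) x$table

#' One-row summary of the correlation suite
#' @param x an `interplay_cor`.
#' @param ... unused.
#' @return tibble with `n_patients`, `df`, `t_crit`, `n_significant`.
#' @export
glance.interplay_cor <- function(x, ...) {
  tibble::tibble(n_patients = x$n, df = x$df, t_crit = x$table$t_crit[1],
                 n_significant = sum(x$table$significant))
}

#' @export
autoplot.interplay_cor <- function(object, ...) {
  obs <- object$observations
  dat <- dplyr::bind_rows(
    tibble::tibble(pair = "amplitude ~ d5/d95", x = obs$amplitude_mm, y = obs$d5d95,
                   w = obs$weight),
    tibble::tibble(pair = "period ~ amplitude", x = obs$period_s, y = obs$amplitude_mm,
                   w = obs$weight),
    tibble::tibble(pair = "period ~ d5/d95", x = obs$period_s, y = obs$d5d95,
                   w = obs$weight),
    tibble::tibble(pair = "volume ~ d5/d95", x = obs$volume_cc, y = obs$d5d95,
                   w = 1)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y, size = .data$w)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~pair, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, size = "weight") +
    ggplot2::theme_minimal()
}
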