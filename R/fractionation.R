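#' Simulate one fractionated treatment
#'
#' Draws, independently for every fraction, a motion input (uniform over the
#' available patterns) and a pair of starting phases `(i, k)` (uniform over
#' the 20 phases, independent per field), accumulates the fraction doses and
#' evaluates CTV metrics after every fraction count. Cumulative dose after
#' `n` fractions is reported in % of the prescription delivered so far, i.e.
#' the mean of the first `n` fraction doses.
#'
#' @param tab an `interplay_table` (see [interplay_table()]).
#' @param n_fractions number of fractions (default 28).
#' @param seed integer seed; the realization is deterministic given it.
#' @param motion_ids motion patterns to sample from (default: all in `tab`).
#' @return a `treatment_realization`: list with `draws` (tibble of
#'   per-fraction `m`, `i`, `k`), `per_n` (tibble of cumulative CTV metrics
#'   after each fraction count) and `final_dose` (point dose vector at
#'   n = `n_fractions`).
#' @export
simulate_treatment <- function(tab, n_fractions = 28, seed = 1L,
                               motion_ids = NULL) {
  if (is.null(motion_ids)) motion_ids <- tab$motion_ids
  stopifnot(length(motion_ids) >= 1)
  np <- tab$n_phases
  rng <- local_rng(seed)
  on.exit(restore_rng(rng), add = TRUE)
  draws <- tibble::tibble(
    fraction = seq_len(n_fractions),
    m = sample(motion_ids, n_fractions, replace = TRUE),
    i = sample.int(np, n_fractions, replace = TRUE) - 1L,
    k = sample.int(np, n_fractions, replace = TRUE) - 1L
  )
  ctv <- tab$point_structure == "CTV"
  acc <- 0
  per_n <- vector("list", n_fractions)
  for (n in seq_len(n_fractions)) {
    acc <- acc + fraction_dose_points(tab, draws$m[n], draws$i[n], draws$k[n])
    cum <- acc / n
    met <- ctv_metrics(cum[ctv])
    per_n[[n]] <- tibble::tibble(n = n, !!!met)
  }
  structure(
    list(draws = draws, per_n = dplyr::bind_rows(per_n),
         final_dose = acc / n_fractions, seed = seed),
    class = "treatment_realization"
  )
}

#' @export
print.treatment_realization <- function(x, ...) {
  last <- x$per_n[nrow(x$per_n), ]
  cat(sprintf(
    "<treatment_realization> %d fractions (seed %d): d5/d95 %.3f, v95 %.1f%%\n",
    nrow(x$per_n), x$seed, last$d5d95, last$v95))
  invisible(x)
}

#' @export
tidy.treatment_realization <- function(x, ...) x$per_n

#' Metric distributions as a function of fraction number
#'
#' Pools a set of treatment realizations into per-fraction-count
#' distributions of the CTV metrics (median and central quantile band), and
#' records for each realization the first fraction count at which full
#' coverage (`v95 = 100`) and no overdose (`v107 = 0`) are reached.
#'
#' @param realizations list of `treatment_realization` objects.
#' @return a `fractionation_curve`: list of tibbles `curve` (per `n` and
#'   metric: median, q5, q95) and `coverage` (per realization: first `n`
#'   with `v95 = 100`, first `n` with `v107 = 0`; NA if never reached).
#' @export
fractionation_curve <- function(realizations) {
  stopifnot(length(realizations) >= 1)
  per_n <- purrr::imap_dfr(realizations, function(r, idx) {
    dplyr::mutate(r$per_n, realization = idx, .before = 1)
  })
  curve <- per_n |>
    tidyr::pivot_longer(cols = c("d5d95", "v95", "v107", "d2", "dmean"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$n, .data$metric) |>
    dplyr::summarise(
      median = stats::median(.data$value),
      q5 = stats::quantile(.data$value, 0.05, names = FALSE),
      q95 = stats::quantile(.data$value, 0.95, names = FALSE),
      .groups = "drop"
    )
  coverage <- per_n |>
    dplyr::group_by(.data$realization) |>
    dplyr::summarise(
      first_n_v95_full = if (any(.data$v95 >= 100)) min(.data$n[.data$v95 >= 100]) else NA_integer_,
      first_n_v107_zero = if (any(.data$v107 <= 0)) min(.data$n[.data$v107 <= 0]) else NA_integer_,
      .groups = "drop"
    )
  structure(list(curve = curve, coverage = coverage, per_n = per_n),
            class = "fractionation_curve")
}

#' @export
autoplot.fractionation_curve <- function(object, metric = "d5d95", ...) {
  dat <- dplyr::filter(object$curve, .data$metric == !!metric)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$n, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q5, ymax = .data$q95),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "number of fractions", y = metric,
                  title = "Interplay mitigation by fractionation (5-95% band)") +
    ggplot2::theme_minimal()
}

#' Single- vs multi-measurement longitudinal comparison
#'
#' Simulates `n_sim` full fractionated treatments twice: once sampling the
#' per-fraction motion only from the first motion pattern (a single
#' pre-treatment acquisition) and once from all available patterns. Reports
#' the paired mean d5/d95 curves and their absolute difference per fraction
#' count.
#'
#' @param tab an `interplay_table` built from a scenario with >= 2 motion
#'   inputs.
#' @param n_sim simulated treatments per arm (default 30).
#' @param n_fractions fractions per treatment (default 28).
#' @param seed base seed; realization `r` of each arm uses `seed + r` offset
#'   by arm.
#' @return a `longitudinal_comparison`: tibble `curves` (per `n`: arm means
#'   of d5/d95), tibble `difference` (per `n`: absolute mean difference),
#'   and the two realization lists.
#' @export
longitudinal_comparison <- function(tab, n_sim = 30, n_fractions = 28,
                                    seed = 1L) {
  if (length(tab$motion_ids) < 2) {
    stop("longitudinal comparison needs >= 2 motion inputs", call. = FALSE)
  }
  single <- lapply(seq_len(n_sim), function(r) {
    simulate_treatment(tab, n_fractions, seed = seed + r,
                       motion_ids = tab$motion_ids[1])
  })
  multi <- lapply(seq_len(n_sim), function(r) {
    simulate_treatment(tab, n_fractions, seed = seed + 10000L + r)
  })
  arm_mean <- function(rs, arm) {
    purrr::map_dfr(rs, function(r) r$per_n) |>
      dplyr::group_by(.data$n) |>
      dplyr::summarise(mean_d5d95 = mean(.data$d5d95), .groups = "drop") |>
      dplyr::mutate(arm = arm, .before = 1)
  }
  curves <- dplyr::bind_rows(arm_mean(single, "single-m"), arm_mean(multi, "all-m"))
  difference <- curves |>
    tidyr::pivot_wider(names_from = "arm", values_from = "mean_d5d95") |>
    dplyr::mutate(abs_diff = abs(.data$`single-m` - .data$`all-m`))
  structure(
    list(curves = curves, difference = difference,
         single = single, multi = multi),
    class = "longitudinal_comparison"
  )
}

#' @export
autoplot.longitudinal_comparison <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$n, y = .data$mean_d5d95,
                               colour = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "number of fractions", y = "mean d5/d95", colour = NULL,
                  title = "Single vs multiple motion measurements") +
    ggplot2::theme_minimal()
}
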