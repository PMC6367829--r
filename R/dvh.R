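#' Dose at volume percentile (dN)
#'
#' `dose_percentile(dose, N)` is the dose received by at least N% of the
#' voxels: on the descending-sorted voxel doses `s_1 >= ... >= s_M`, the
#' cumulative curve passes through `(i/M, s_i)`; the query interpolates
#' linearly between adjacent voxels. This sorted-voxel-list convention is
#' used consistently for every dN metric so that d5/d95 is reproducible
#' bit-for-bit from a dose grid.
#'
#' @param dose numeric vector of voxel doses within the structure.
#' @param p volume percentage in (0, 100].
#' @return the dose dN, same units as `dose`.
#' @export
dose_percentile <- function(dose, p) {
  stopifnot(p > 0, p <= 100, length(dose) > 0)
  s <- sort(dose, decreasing = TRUE)
  M <- length(s)
  f <- p / 100 * M # voxel count covering p% of the volume
  if (f <= 1) return(s[1])
  i <- floor(f)
  if (i >= M) return(s[M])
  s[i] + (f - i) * (s[i + 1] - s[i])
}

#' Volume receiving at least a dose level (vL)
#' @param dose numeric vector of voxel doses within the structure.
#' @param level dose level (same units as `dose`).
#' @return percentage of the structure volume with `dose >= level`.
#' @export
volume_at_dose <- function(dose, level) {
  stopifnot(length(dose) > 0)
  100 * mean(dose >= level)
}

#' Cumulative dose-volume histogram
#'
#' Exact voxel-counting cumulative DVH: volume fraction receiving at least
#' each dose level, on a dense regular grid of dose bins (0.1% of
#' prescription wide by default). Percentile queries should use
#' [dose_percentile()], which interpolates on the unbinned voxel list.
#'
#' @param dose a `voxel_grid` of dose or a numeric vector of voxel doses.
#' @param mask logical mask selecting the structure (required for grids).
#' @param structure structure name carried into the output.
#' @param bin_width dose bin width (% of prescription).
#' @return a `dvh_curve` tibble with columns `structure`, `dose`,
#'   `volume_fraction` (monotone non-increasing from 1).
#' @export
compute_dvh <- function(dose, mask = NULL, structure = "structure",
                        bin_width = 0.1) {
  if (inherits(dose, "voxel_grid")) {
    if (is.null(mask)) stop("a structure mask is required", call. = FALSE)
    if (!any(mask)) stop("structure mask is empty", call. = FALSE)
    dose <- dose$values[mask]
  }
  if (length(dose) == 0) stop("structure mask is empty", call. = FALSE)
  grid <- seq(0, max(dose) + bin_width, by = bin_width)
  vf <- 1 - (findInterval(grid, sort(dose), left.open = TRUE) / length(dose))
  out <- tibble::tibble(structure = structure, dose = grid, volume_fraction = vf)
  class(out) <- c("dvh_curve", class(out))
  out
}

#' @export
autoplot.dvh_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$dose, y = 100 * .data$volume_fraction,
                               colour = .data$structure)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(x = "dose [% of prescription]", y = "volume [%]",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Scalar dose metrics per structure
#'
#' Computes the study's metric set — `dmean`, `d2`, `d5`, `d95`, the
#' homogeneity index `d5/d95`, `v95`, `v107` and `v30` — for each structure
#' of a structure set on a dose grid (doses in % of prescription).
#'
#' @param dose a `voxel_grid` of dose (% of prescription).
#' @param structures a `structure_set` (or named list of logical masks).
#' @param which structure names (default: all).
#' @return tibble with one row per structure.
#' @export
dose_report <- function(dose, structures, which = NULL) {
  if (is.null(which)) which <- names(structures)
  purrr::map_dfr(which, function(nm) {
    dv <- dose$values[structures[[nm]]]
    tibble::tibble(
      structure = nm,
      dmean = mean(dv),
      d2 = dose_percentile(dv, 2),
      d5 = dose_percentile(dv, 5),
      d95 = dose_percentile(dv, 95),
      d5d95 = dose_percentile(dv, 5) / dose_percentile(dv, 95),
      v95 = volume_at_dose(dv, 95),
      v107 = volume_at_dose(dv, 107),
      v30 = volume_at_dose(dv, 30)
    )
  })
}

#' One-sided rank-sum comparison of metric samples
#'
#' Wilcoxon rank-sum test between two scenario metric samples (e.g. d5/d95
#' under 4Dx1 vs 4Dx28): exact null distribution when the combined sample
#' size is at most 20 and there are no ties, normal approximation with tie
#' correction otherwise. Decision at alpha = 0.05. Fully tied samples give
#' the p = 0.5 convention, flagged.
#'
#' @param a,b numeric metric samples.
#' @param alternative "greater" tests a shifted-up A, "less" the reverse.
#' @param alpha significance level.
#' @return tibble with `p_value`, `significant`, `method`, `flag`.
#' @export
compare_scenarios <- function(a, b, alternative = c("greater", "less"),
                              alpha = 0.05) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) > 0, length(b) > 0)
  if (length(unique(c(a, b))) == 1L) {
    return(tibble::tibble(p_value = 0.5, significant = FALSE,
                          method = "degenerate", flag = "all values tied"))
  }
  ties <- any(duplicated(c(a, b)))
  exact <- (length(a) + length(b) <= 20) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative,
                       exact = exact, correct = TRUE)
  )
  tibble::tibble(
    p_value = wt$p.value,
    significant = wt$p.value < alpha,
    method = if (exact) "exact" else "normal approximation",
    flag = if (ties) "ties present" else NA_character_
  )
}
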