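#' CTV motion distribution of a motion input
#'
#' Applies the binary CTV mask to the deformation fields, giving the
#' distribution of per-voxel displacements inside the CTV per axis —
#' at end-inhalation by default, optionally for every phase. Displacements
#' are signed (left/anterior/superior positive); absolute summaries are
#' reported alongside. Whiskers of the matching boxplot figure are the 95%
#' central range.
#'
#' @param motion a `motion_input`.
#' @param ctv logical CTV mask (non-empty).
#' @param phases integer phase indices to extract (default: EIN only).
#' @return a `motion_summary`: tibble with columns `motion`, `phase`,
#'   `axis`, `mean`, `mean_abs`, `max_abs`, `q2.5`, `q97.5`, `min`, `max`;
#'   the per-voxel samples are attached as attribute `"samples"` (tibble
#'   with `phase`, `axis`, `displacement_mm`).
#' @export
ctv_motion_distribution <- function(motion, ctv, phases = NULL) {
  if (!any(ctv)) stop("CTV mask is empty", call. = FALSE)
  if (is.null(phases)) phases <- ein_phase(motion)
  axes <- c("LR", "AP", "IS")
  idx <- which(ctv)
  samples <- purrr::map_dfr(phases, function(j) {
    f <- phase_field(motion, j)
    purrr::map_dfr(1:3, function(a) {
      tibble::tibble(
        phase = j, axis = axes[a],
        displacement_mm = f$u[, , , a][idx]
      )
    })
  })
  summ <- samples |>
    dplyr::group_by(.data$phase, .data$axis) |>
    dplyr::summarise(
      mean = mean(.data$displacement_mm),
      mean_abs = mean(abs(.data$displacement_mm)),
      max_abs = max(abs(.data$displacement_mm)),
      q2.5 = stats::quantile(.data$displacement_mm, 0.025, names = FALSE),
      q97.5 = stats::quantile(.data$displacement_mm, 0.975, names = FALSE),
      min = min(.data$displacement_mm),
      max = max(.data$displacement_mm),
      .groups = "drop"
    ) |>
    dplyr::mutate(motion = motion$id, .before = 1)
  attr(summ, "samples") <- samples
  class(summ) <- c("motion_summary", class(summ))
  summ
}

#' Day-to-day motion variation across measurements
#'
#' Largest pairwise absolute difference of the mean and maximum absolute
#' CTV motion amplitudes per axis across a set of motion summaries
#' (one per repeated measurement).
#'
#' @param summaries list of `motion_summary` objects (>= 2), EIN rows.
#' @return tibble with columns `axis`, `delta_mean_mm`, `delta_max_mm`.
#' @export
day_to_day_variation <- function(summaries) {
  if (length(summaries) < 2) {
    stop("at least two motion summaries are required", call. = FALSE)
  }
  purrr::map_dfr(summaries, function(s) {
    s <- tibble::as_tibble(s)
    ein <- s$phase[which.max(s$max_abs)] # EIN row when several phases present
    s |>
      dplyr::filter(.data$phase == ein) |>
      dplyr::select("motion", "axis", "mean_abs", "max_abs")
  }) |>
    dplyr::group_by(.data$axis) |>
    dplyr::summarise(
      delta_mean_mm = max(.data$mean_abs) - min(.data$mean_abs),
      delta_max_mm = max(.data$max_abs) - min(.data$max_abs),
      .groups = "drop"
    )
}

#' @export
autoplot.motion_summary <- function(object, ...) {
  samples <- attr(object, "samples")
  ggplot2::ggplot(samples,
                  ggplot2::aes(x = factor(.data$phase), y = .data$displacement_mm)) +
    ggplot2::geom_boxplot(outlier.shape = NA, coef = 0) +
    ggplot2::stat_summary(
      fun.min = function(x) stats::quantile(x, 0.025),
      fun.max = function(x) stats::quantile(x, 0.975),
      geom = "errorbar", width = 0.3
    ) +
    ggplot2::facet_wrap(~axis, scales = "free_y") +
    ggplot2::labs(x = "breathing phase", y = "CTV voxel displacement [mm]",
                  title = "CTV motion distribution (whiskers: 95% range)") +
    ggplot2::theme_minimal()
}
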