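#' Default multi-patient study configuration
#'
#' Nine pseudo-patients spanning the study conditions: CTV volumes and beam
#' angles follow the reference cohort (33-195 cc; posterior 160/210 or
#' anterior 20/340 field pairs), dominant IS amplitudes span 2-15 mm with
#' AP/LR amplitudes of at most ~3 mm, breathing periods lie in [2.8, 10] s,
#' and each patient carries as many repeated motion measurements as their
#' weight; additional periods are emulated by period-rescaled copies of the
#' first measurement. Day-to-day amplitude variation across repeated
#' measurements is a seeded +/-15% rescaling.
#'
#' @param grid_n voxels per axis of the phantom grid.
#' @param spacing_mm voxel spacing (mm).
#' @param n_patients number of pseudo-patients (<= 9).
#' @param n_fractions,n_sim fractionation scheme and simulated treatments.
#' @param seed study seed.
#' @return a `study_config` list.
#' @export
study_config <- function(grid_n = 64, spacing_mm = 3.75, n_patients = 9,
                         n_fractions = 28, n_sim = 30, seed = 20190207) {
  patients <- list(
    list(id = "P1", ctv_volume_cc = 51.9, angles = c(160, 210), weight = 2,
         amplitude_is = 10, periods = c(7.1, 3.0, 5.5)),
    list(id = "P2", ctv_volume_cc = 33.0, angles = c(160, 210), weight = 6,
         amplitude_is = 8, periods = c(3.8, 2.8, 3.7)),
    list(id = "P3", ctv_volume_cc = 95.1, angles = c(160, 210), weight = 5,
         amplitude_is = 12, periods = c(9.7, 8.2, 8.8)),
    list(id = "P4", ctv_volume_cc = 87.8, angles = c(20, 340), weight = 2,
         amplitude_is = 6, periods = c(3.7, 3.0, 5.5)),
    list(id = "P5", ctv_volume_cc = 194.8, angles = c(20, 340), weight = 1,
         amplitude_is = 5, periods = c(3.7, 3.0, 8.0)),
    list(id = "P6", ctv_volume_cc = 115.1, angles = c(20, 340), weight = 1,
         amplitude_is = 2, periods = c(5.6, 3.0, 10.0)),
    list(id = "P7", ctv_volume_cc = 112.0, angles = c(160, 200), weight = 1,
         amplitude_is = 4, periods = c(3.0, 5.0, 10.0)),
    list(id = "P8", ctv_volume_cc = 62.4, angles = c(20, 340), weight = 3,
         amplitude_is = 15, periods = c(4.7, 3.0, 10.0)),
    list(id = "P9", ctv_volume_cc = 46.0, angles = c(20, 340), weight = 2,
         amplitude_is = 7, periods = c(3.7, 2.9, 5.5))
  )[seq_len(n_patients)]
  structure(
    list(grid_n = grid_n, spacing_mm = spacing_mm, patients = patients,
         n_fractions = n_fractions, n_sim = n_sim, seed = seed,
         ap_lr_ratio = c(ap = 0.35, lr = 0.25)),
    class = "study_config"
  )
}

#' Read a study configuration from YAML
#' @param path a YAML file with the fields of [study_config()].
#' @return a `study_config` list.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- study_config()
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  base
}

#' Write a study configuration to YAML
#' @param config a `study_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# build the motion-input list for one pseudo-patient
build_patient_motions <- function(reference, ctv, p, ap_lr_ratio, seed) {
  amp_scale <- if (p$weight >= 2) {
    seq(0.85, 1.15, length.out = p$weight)
  } else 1
  motions <- list()
  for (w in seq_len(p$weight)) {
    amp <- c(p$amplitude_is * ap_lr_ratio[["lr"]],
             p$amplitude_is * ap_lr_ratio[["ap"]],
             p$amplitude_is) * amp_scale[w]
    period <- p$periods[(w - 1) %% length(p$periods) + 1]
    motions[[w]] <- generate_motion_input(
      reference, ctv, amplitude_mm = amp, period_s = period,
      id = sprintf("m%d", w), seed = seed + w
    )
  }
  extra <- setdiff(p$periods, vapply(motions, function(m) m$period_s, numeric(1)))
  for (tt in extra) {
    motions[[length(motions) + 1]] <-
      rescale_period(motions[[1]], tt,
                     id = sprintf("m%d", length(motions) + 1))
  }
  motions
}

#' Run the full interplay study
#'
#' Orchestrates the pipeline for every pseudo-patient of a configuration:
#' phantom and motion generation, deformation QA, SFUD planning, static
#' (3DDC) dose, single-fraction 4D ensemble (4Dx1), fractionated simulation
#' (4Dx28), and finally the inter-patient correlation suite weighted by the
#' number of repeated measurements. When `out_dir` is given, all tables are
#' written as CSV along with the resolved configuration as YAML.
#'
#' @param config a `study_config`.
#' @param out_dir optional output directory.
#' @param verbose print per-stage progress.
#' @return a `study_result`: `summary` (per-patient static/4Dx1/4Dx28 CTV
#'   metrics), `qa` (deformation QA rows), `single_fraction` (4Dx1 ensemble
#'   members), `fractionation` (per-n metric curves), `correlations`
#'   (an `interplay_cor`) and `observations`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- Sys.time()
  summaries <- list(); qa_rows <- list(); ens_rows <- list()
  frac_rows <- list(); obs_rows <- list()
  for (pi in seq_along(config$patients)) {
    p <- config$patients[[pi]]
    say("[%s] phantom + motion", p$id)
    ph <- build_phantom(phantom_config(config$grid_n, config$spacing_mm,
                                       ctv_volume_cc = p$ctv_volume_cc))
    motions <- build_patient_motions(ph$ct, ph$structures$CTV, p,
                                     config$ap_lr_ratio,
                                     seed = config$seed + 100 * pi)
    scen <- patient_scenario(ph$ct, ph$structures, motions,
                             angles_deg = p$angles)
    say("[%s] QA", p$id)
    qa <- qa_report(scen)
    qa_rows[[pi]] <- dplyr::mutate(qa, patient = p$id, .before = 1)
    say("[%s] SFUD plan + 3DDC", p$id)
    plan <- plan_sfud(scen)
    static <- compute_static_dose(plan, scen$ct)
    rep_static <- dose_report(static, scen$structures, which = "CTV")
    say("[%s] 4Dx1 ensemble + 4Dx%d simulation", p$id, config$n_fractions)
    tab <- interplay_table(plan, scen)
    ens <- enumerate_single_fraction(tab)
    ens_rows[[pi]] <- dplyr::mutate(ens, patient = p$id, .before = 1)
    sims <- lapply(seq_len(config$n_sim), function(r) {
      simulate_treatment(tab, config$n_fractions, seed = config$seed + 1000 * pi + r)
    })
    fc <- fractionation_curve(sims)
    frac_rows[[pi]] <- dplyr::mutate(fc$curve, patient = p$id, .before = 1)
    final <- purrr::map_dfr(sims, function(s) s$per_n[nrow(s$per_n), ])
    amp <- mean(vapply(motions, function(m) {
      max(abs(m$temporal)) * sqrt(sum(sample_dvf(
        m$spatial, rbind(mask_centroid(scen$ct, scen$structures$CTV)))^2))
    }, numeric(1)))
    summaries[[pi]] <- tibble::tibble(
      patient = p$id,
      static_d5d95 = rep_static$d5d95, static_v95 = rep_static$v95,
      static_v107 = rep_static$v107, static_dmean = rep_static$dmean,
      fx1_d5d95 = mean(ens$d5d95), fx1_v95 = mean(ens$v95),
      fx1_v107 = mean(ens$v107), fx1_dmean = mean(ens$dmean),
      fx28_d5d95 = mean(final$d5d95), fx28_v95 = mean(final$v95),
      fx28_v107 = mean(final$v107), fx28_dmean = mean(final$dmean),
      mean_first_n_v95 = mean(fc$coverage$first_n_v95_full, na.rm = TRUE)
    )
    obs_rows[[pi]] <- tibble::tibble(
      patient = p$id, amplitude_mm = amp,
      period_s = mean(vapply(motions, function(m) m$period_s, numeric(1))),
      d5d95 = mean(ens$d5d95), volume_cc = p$ctv_volume_cc,
      weight = p$weight
    )
  }
  observations <- dplyr::bind_rows(obs_rows)
  correlations <- if (nrow(observations) >= 3) {
    correlation_suite(observations)
  } else NULL
  result <- structure(
    list(summary = dplyr::bind_rows(summaries),
         qa = dplyr::bind_rows(qa_rows),
         single_fraction = dplyr::bind_rows(ens_rows),
         fractionation = dplyr::bind_rows(frac_rows),
         observations = observations,
         correlations = correlations,
         config = config,
         runtime_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
    class = "study_result"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_csv(result$summary, file.path(out_dir, "summary.csv"))
    write_table_csv(result$qa, file.path(out_dir, "qa.csv"))
    write_table_csv(result$single_fraction, file.path(out_dir, "single_fraction.csv"))
    write_table_csv(result$fractionation, file.path(out_dir, "fractionation.csv"))
    write_table_csv(result$observations, file.path(out_dir, "observations.csv"))
    if (!is.null(correlations)) {
      write_table_csv(tidy(correlations), file.path(out_dir, "correlations.csv"))
    }
    write_study_config(config, file.path(out_dir, "config_resolved.yaml"))
  }
  say("study finished in %.1f s", result$runtime_s)
  result
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d pseudo-patients, %.1f s\n",
              nrow(x$summary), x$runtime_s))
  print(x$summary)
  if (!is.null(x$correlations)) print(x$correlations)
  invisible(x)
}
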