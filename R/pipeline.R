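#' Configuration for the end-to-end analysis pipeline
#'
#' All tunable defaults of the pipeline in one object; unknown keys are
#' rejected (they simply do not exist as arguments).
#'
#' @param seed master integer seed; every stage derives its own sub-seed
#'   from it, so a fixed seed makes the whole report reproducible.
#' @param r_eff_true generative effective Forster radius, nm.
#' @param geometry a [ruler_geometry()].
#' @param ruler_bp dsDNA ruler lengths, bp.
#' @param trend_params named list of generative per-condition trend
#'   coefficients \code{c(a, b)} (nm, nm/nt).
#' @param scatter_sd between-molecule scatter about the trend, nm.
#' @param lengths_nt RNA lengths, nt.
#' @param sigma_link per-axis fluorophore-linker jitter of the RNA
#'   simulations, nm (broadens histograms beyond shot noise).
#' @param trace_length,burst_rate,burst_brightness,background_rate trace
#'   simulation settings shared by the calibration and RNA stages
#'   (background rate applies to each channel).
#' @param threshold burst threshold in counts/bin, or \code{NULL} for the
#'   default rule of [select_bursts()].
#' @param n_bins,hist_range histogram settings.
#' @param polymer a [polymer_params()].
#' @param measurements optional: a measurement data.frame (or CSV path as
#'   written by [write_measurements()]) to analyse instead of simulating;
#'   the calibration and burst stages are then skipped.
#' @return Object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(seed = 1L,
                            r_eff_true = 8.5,
                            geometry = ruler_geometry(),
                            ruler_bp = ruler_lengths_bp,
                            trend_params = list(TM = c(a = 6.8, b = 7.2e-4),
                                                TE = c(a = 7.2, b = 7.6e-4)),
                            scatter_sd = 1.2,
                            lengths_nt = rna_lengths_nt,
                            sigma_link = 0.5,
                            trace_length = 20000L,
                            burst_rate = 5,
                            burst_brightness = 100,
                            background_rate = 1,
                            threshold = NULL,
                            n_bins = 40L,
                            hist_range = c(-0.1, 1.1),
                            polymer = polymer_params(),
                            measurements = NULL) {
  stopifnot(inherits(geometry, "ruler_geometry"),
            inherits(polymer, "polymer_params"))
  check_pos(r_eff_true, "r_eff_true")
  check_nonneg(scatter_sd, "scatter_sd")
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

# analyse one simulated trace: burst selection, efficiency histogram,
# distance inversion, width excess
.analyse_trace <- function(trace, calib, cfg) {
  bins <- select_bursts(trace, cfg$threshold)
  eff <- suppressMessages(compute_efficiencies(trace, bins))
  h <- fit_histogram(eff, n_bins = cfg$n_bins, range = cfg$hist_range)
  n_burst <- nrow(eff)
  se_mean <- h$sigma_E / sqrt(n_burst)
  N_bar <- mean(eff$I_A + eff$I_D)
  mean_E <- min(max(h$mean_E, 1e-6), 1 - 1e-6)
  inv <- distance_from_efficiency(mean_E, se_mean, calib)
  shot_fwhm <- sigma_to_fwhm(shot_noise_sigma(mean_E, N_bar))
  list(mean_E = h$mean_E, sigma_E_fit = h$sigma_E, fwhm = h$fwhm,
       n_bursts = n_burst, N_bar = N_bar,
       distance_nm = inv$R_nm, sigma_nm = inv$sigma_R_nm,
       width_excess = width_excess(h$fwhm, shot_fwhm))
}

#' Run the full synthetic smFRET analysis pipeline
#'
#' Chains every stage on seeded synthetic data: photon-trace simulation of
#' the ten dsDNA rulers, burst analysis and Gaussian histogram fits,
#' calibration of the effective Forster radius, simulation and burst
#' analysis of the RNA samples under both buffer conditions, inversion of
#' mean efficiencies to inter-dye distances, linker correction, per-condition
#' length-trend fits with 1-sigma errors, the fractional separation change
#' over the measured length span, residual scatter, rigid-rod and
#' worm-like-chain exterior-loop contour estimates, and the
#' histogram-width (shot-noise excess) analysis.
#'
#' When \code{config$measurements} is supplied, the simulation/burst/
#' calibration stages are skipped and the given distance table is analysed.
#'
#' @param config a [pipeline_config()].
#' @return Object of class \code{"fret_report"}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  sub_seeds <- with_seed(cfg$seed, sample.int(.Machine$integer.max - 1L, 4L))

  calib <- NULL
  if (is.null(cfg$measurements)) {
    ## stage 1: dsDNA ruler calibration from simulated traces
    R_true <- ruler_separation(cfg$ruler_bp, cfg$geometry)
    cal_rows <- lapply(seq_along(cfg$ruler_bp), function(i) {
      tr <- simulate_trace(sim_config(
        trace_length = cfg$trace_length,
        background_rate_donor = cfg$background_rate,
        background_rate_acceptor = cfg$background_rate,
        burst_rate = cfg$burst_rate,
        burst_brightness = cfg$burst_brightness,
        distance_model = distance_fixed(R_true[i]),
        r_eff = cfg$r_eff_true,
        sample_id = sprintf("ruler_%02dbp", cfg$ruler_bp[i]),
        condition = "TE",
        seed = sub_seeds[1] %% 100000L * 100L + i))
      bins <- select_bursts(tr, cfg$threshold)
      eff <- suppressMessages(compute_efficiencies(tr, bins))
      h <- fit_histogram(eff, n_bins = cfg$n_bins, range = cfg$hist_range)
      data.frame(bp = cfg$ruler_bp[i], R_nm = R_true[i], E = h$mean_E,
                 sigma_E = h$sigma_E / sqrt(nrow(eff)))
    })
    cal_points <- do.call(rbind, cal_rows)
    calib <- fit_calibration(cal_points, cfg$geometry)

    ## stage 2: RNA samples, both buffer conditions
    rows <- list()
    k <- 0L
    for (cond in names(cfg$trend_params)) {
      ab <- cfg$trend_params[[cond]]
      truth <- simulate_rna_dataset(a = ab[["a"]], b = ab[["b"]],
                                    lengths_nt = cfg$lengths_nt,
                                    scatter_sd = cfg$scatter_sd,
                                    condition = cond,
                                    seed = sub_seeds[2] + k)
      for (j in seq_len(nrow(truth))) {
        tr <- simulate_trace(sim_config(
          trace_length = cfg$trace_length,
          background_rate_donor = cfg$background_rate,
          background_rate_acceptor = cfg$background_rate,
          burst_rate = cfg$burst_rate,
          burst_brightness = cfg$burst_brightness,
          distance_model = distance_linker(truth$distance_nm[j], cfg$sigma_link),
          r_eff = cfg$r_eff_true,
          sample_id = truth$sample_id[j],
          condition = cond,
          seed = sub_seeds[3] %% 1000000L * 100L + k * 30L + j))
        res <- .analyse_trace(tr, calib, cfg)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = truth$sample_id[j],
          length_nt = truth$length_nt[j],
          condition = cond,
          cistron_class = truth$cistron_class[j],
          true_distance_nm = truth$distance_nm[j],
          distance_nm = res$distance_nm,
          sigma_nm = res$sigma_nm,
          mean_E = res$mean_E,
          fwhm = res$fwhm,
          n_bursts = res$n_bursts,
          N_bar = res$N_bar,
          width_excess = res$width_excess)
      }
      k <- k + 1L
    }
    measurements <- do.call(rbind, rows)
  } else {
    measurements <- cfg$measurements
    if (is.character(measurements)) measurements <- read_measurements(measurements)
    if (!"width_excess" %in% names(measurements)) measurements$width_excess <- NA_real_
  }

  ## stage 3: linker correction
  measurements$end_to_end_nm <- linker_correct(measurements$distance_nm,
                                               cfg$geometry$linker_total)

  ## stage 4: trend fits per condition (on fluorophore separations).
  ## Ordinary LS: the between-molecule scatter dominates the per-point
  ## inversion error, so residual-based parameter errors are the honest ones
  conditions <- unique(measurements$condition)
  trend_data <- measurements[setdiff(names(measurements), "sigma_nm")]
  trends <- lapply(conditions, function(cond) {
    fit_length_trend(trend_data, condition = cond)
  })
  names(trends) <- conditions

  n_lo <- min(measurements$length_nt)
  n_hi <- max(measurements$length_nt)
  frac_change <- vapply(trends, fractional_change, numeric(1),
                        n_low = n_lo, n_high = n_hi)
  scatter <- vapply(conditions, function(cond) {
    residual_sd(measurements[measurements$condition == cond, , drop = FALSE],
                trends[[cond]])
  }, numeric(1))

  ## stage 5: contour-length back-calculation at the observed range
  sep_range <- range(measurements$distance_nm)
  e2e_range <- linker_correct(sep_range, cfg$geometry$linker_total)
  contour_rigid <- rigid_contour_nt(e2e_range, cfg$polymer)
  contour_wlc <- lapply(e2e_range, invert_contour_length,
                        lp = cfg$polymer$lp, params = cfg$polymer)

  structure(
    list(config = cfg, seed = cfg$seed, sub_seeds = sub_seeds,
         calibration = calib,
         measurements = measurements,
         trends = trends,
         fractional_change_pct = frac_change,
         residual_sd_nm = scatter,
         separation_range_nm = sep_range,
         end_to_end_range_nm = e2e_range,
         contour_rigid = contour_rigid,
         contour_wlc = contour_wlc,
         mean_width_excess = mean(measurements$width_excess, na.rm = TRUE)),
    class = "fret_report"
  )
}

#' @export
print.fret_report <- function(x, ...) {
  cat("smFRET end-to-end distance analysis report\n")
  cat(sprintf("  seed: %d\n", x$seed))
  if (!is.null(x$calibration)) {
    cat(sprintf("  calibration: R_eff = %.3g +/- %.2g nm (%d rulers)\n",
                x$calibration$r_eff, x$calibration$sigma_r_eff,
                nrow(x$calibration$points)))
  }
  cat(sprintf("  samples analysed: %d (%s)\n", nrow(x$measurements),
              paste(sprintf("%s: %d", names(table(x$measurements$condition)),
                            table(x$measurements$condition)), collapse = ", ")))
  for (cond in names(x$trends)) {
    tr <- x$trends[[cond]]
    cat(sprintf("  trend [%s]: a = %.3g +/- %.2g nm, b = %.3g +/- %.2g nm/nt; residual sd %.3g nm\n",
                cond, tr$a, tr$sigma_a, tr$b, tr$sigma_b,
                x$residual_sd_nm[[cond]]))
  }
  cat(sprintf("  fractional separation change over %d-%d nt: %s\n",
              min(x$measurements$length_nt), max(x$measurements$length_nt),
              paste(sprintf("%s %.1f%%", names(x$fractional_change_pct),
                            x$fractional_change_pct), collapse = ", ")))
  cat(sprintf("  separations %.3g-%.3g nm -> end-to-end %.3g-%.3g nm after linker correction\n",
              x$separation_range_nm[1], x$separation_range_nm[2],
              x$end_to_end_range_nm[1], x$end_to_end_range_nm[2]))
  cat(sprintf("  exterior loop: rigid %d-%d nt; WLC (lp = %g nm) %d-%d nt\n",
              x$contour_rigid$L_nt[1], x$contour_rigid$L_nt[2],
              x$config$polymer$lp,
              x$contour_wlc[[1]]$L_nt, x$contour_wlc[[2]]$L_nt))
  if (is.finite(x$mean_width_excess)) {
    cat(sprintf("  mean histogram width excess over shot noise: %.2f\n",
                x$mean_width_excess))
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits a JSON summary (calibration, trends, ranges, contours, seeds) and a
#' CSV of the per-sample measurement table.
#'
#' @param report a \code{"fret_report"}.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "fret_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(
    seed = report$seed,
    sub_seeds = report$sub_seeds,
    r_eff = if (is.null(report$calibration)) NULL else report$calibration$r_eff,
    sigma_r_eff = if (is.null(report$calibration)) NULL else report$calibration$sigma_r_eff,
    trends = lapply(report$trends, function(tr) {
      list(a = tr$a, sigma_a = tr$sigma_a, b = tr$b, sigma_b = tr$sigma_b,
           n = tr$n)
    }),
    fractional_change_pct = as.list(report$fractional_change_pct),
    residual_sd_nm = as.list(report$residual_sd_nm),
    separation_range_nm = report$separation_range_nm,
    end_to_end_range_nm = report$end_to_end_range_nm,
    contour_rigid_nt = report$contour_rigid$L_nt,
    contour_wlc_nt = c(report$contour_wlc[[1]]$L_nt, report$contour_wlc[[2]]$L_nt),
    mean_width_excess = report$mean_width_excess)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$measurements, file.path(dir, "measurements.csv"),
                   row.names = FALSE)
  invisible(dir)
}
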