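# End-to-end runner: executes the requested analysis stages over replicate
# inputs (CSV files or seeded simulations), summarizes replicate estimates
# as mean +/- SEM, and emits a machine-readable JSON report.

summary_row <- function(values) {
  s <- summarize_replicates(values)
  list(n = s$n, mean = s$mean, sem = s$sem)
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages — `geometry` (shape set, swelling
#' transform, depth-band volume fractions), `swelling` (per-replicate
#' pseudo-second-order fits), `absorption` (transport parameters per
#' record) and `release` (aliquot correction, ultra-fast release fits,
#' burst rate) — and returns a report list with per-replicate values and
#' mean +/- SEM summaries. Replicate inputs are either CSV file paths or a
#' `simulate` block (truth + noise + base seed; replicate i uses
#' `seed + i - 1`).
#'
#' Configuration is a named list (or a path to a JSON file with the same
#' structure):
#' \describe{
#'   \item{stages}{character vector; any of `"geometry"`, `"swelling"`,
#'     `"absorption"`, `"release"`. Empty -> metadata-only report.}
#'   \item{seed}{base RNG seed, recorded in the report.}
#'   \item{geometry}{list: `band` (`top_depth`, `bottom_depth`,
#'     `uninserted_offset`), `swell` (`delta_height`,
#'     `delta_base_diameter`).}
#'   \item{swelling}{list: either `files` + `m0` (recycled), or `simulate`
#'     (`S_inf`, `k_s`, `m0`, `noise_cv`, `n_reps`).}
#'   \item{absorption}{list: `records`, a list of argument lists for
#'     [absorption_record()].}
#'   \item{release}{list: either `files` (+ `V_reservoir`, `V_aliquot`),
#'     or `simulate` (`k`, `a`, `C_max`, `noise_cv`, `n_reps`).}
#' }
#'
#' @param config named list or path to a JSON config file.
#' @param out optional path; when given the report is written there as JSON.
#' @return the report, invisibly when `out` is given.
#' @export
run_pipeline <- function(config, out = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) {
    abort("`config` must be a named list or a JSON file path",
          "mnswell_validation_error")
  }
  stages <- config$stages %||% character()
  seed <- config$seed %||% 1L
  report <- list(
    meta = list(
      package = "mnswell",
      version = as.character(utils::packageVersion("mnswell")),
      seed = seed,
      stages = stages,
      generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  )
  if ("geometry" %in% stages) {
    report$geometry <- stage_geometry(config$geometry)
  }
  if ("swelling" %in% stages) {
    report$swelling <- stage_swelling(config$swelling, seed)
  }
  if ("absorption" %in% stages) {
    report$absorption <- stage_absorption(config$absorption)
  }
  if ("release" %in% stages) {
    report$release <- stage_release(config$release, seed)
  }
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_geometry <- function(cfg) {
  cfg <- cfg %||% list()
  band_cfg <- cfg$band %||% list()
  band <- depth_band(
    top_depth = band_cfg$top_depth %||% 450,
    bottom_depth = band_cfg$bottom_depth %||% 550,
    uninserted_offset = band_cfg$uninserted_offset %||% 100
  )
  swell_cfg <- cfg$swell %||% list()
  inc <- swell_increment(
    delta_height = swell_cfg$delta_height %||% 150,
    delta_base_diameter = swell_cfg$delta_base_diameter %||% 75
  )
  shapes <- default_shapes()
  res <- lapply(names(shapes), function(nm) {
    prof <- shape_profile(shapes[[nm]])
    swollen <- apply_swell(prof, inc)
    v0 <- revolve_volume(prof)
    vt <- revolve_volume(swollen)
    list(
      shape = nm,
      volume_um3 = v0,
      volume_swollen_um3 = vt,
      volume_change_percent = percent_volume_change(v0, vt),
      band_fraction = band_volume_fraction(prof, band),
      band_fraction_swollen = band_volume_fraction(swollen, band)
    )
  })
  names(res) <- names(shapes)
  list(band = unclass(band),
       swell = unclass(inc),
       shapes = res)
}

fit_one_swelling <- function(series) {
  sp <- swelling_percent_series(series)
  fit <- suppressMessages(pso_fit(sp$t, sp$S))
  list(S_inf = fit$S_inf, k_s = fit$k_s, r2 = fit$r2,
       m_inf = m_inf_from_fit(series$m0, fit),
       S_final = sp$S[nrow(sp)])
}

stage_swelling <- function(cfg, seed) {
  if (is.null(cfg)) {
    abort("swelling stage requested without a `swelling` config block",
          "mnswell_validation_error")
  }
  series_list <- if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    n <- sim$n_reps %||% 3L
    lapply(seq_len(n), function(i) {
      gen_swelling_series(S_inf = sim$S_inf, k_s = sim$k_s, m0 = sim$m0,
                          noise_cv = sim$noise_cv %||% 0,
                          seed = seed + i - 1L)
    })
  } else if (!is.null(cfg$files)) {
    m0 <- rep_len(cfg$m0, length(cfg$files))
    lapply(seq_along(cfg$files), function(i) {
      read_swelling_csv(cfg$files[[i]], m0 = m0[[i]])
    })
  } else {
    abort("swelling config needs `files` or `simulate`",
          "mnswell_validation_error")
  }
  fits <- lapply(series_list, fit_one_swelling)
  list(
    replicates = fits,
    summary = lapply(
      stats::setNames(nm = c("S_inf", "k_s", "r2", "S_final")),
      function(f) summary_row(vapply(fits, `[[`, numeric(1), f))
    )
  )
}

stage_absorption <- function(cfg) {
  if (is.null(cfg) || is.null(cfg$records)) {
    abort("absorption stage needs a `records` list",
          "mnswell_validation_error")
  }
  fits <- lapply(cfg$records, function(args) {
    rec <- do.call(absorption_record, args)
    tp <- transport_params(rec)
    out <- list(P = tp$P, Kd = tp$Kd, D = tp$D)
    if (!is.na(rec$Mx)) {
      out$absorbed_ug_per_mg <- absorbed_amount(
        C_measured = rec$Ct, V_res = rec$V_res, Mx = rec$Mx)
    }
    out
  })
  keys <- c("P", "Kd", "D")
  list(
    replicates = fits,
    summary = lapply(stats::setNames(nm = keys), function(f) {
      summary_row(vapply(fits, `[[`, numeric(1), f))
    })
  )
}

fit_one_release <- function(series) {
  C_cum <- cumulative_correct(series)
  C_max <- C_cum[length(C_cum)]
  Cp <- cumulative_percent(C_cum, C_max)
  fit <- taolu_fit(series$t, C_cum / C_max)
  list(k = fit$k, a = fit$a, r2 = fit$r2, plateau = fit$plateau,
       rate_120min = release_rate(c(0, Cp), c(0, series$t),
                                  window_end = 120))
}

stage_release <- function(cfg, seed) {
  if (is.null(cfg)) {
    abort("release stage requested without a `release` config block",
          "mnswell_validation_error")
  }
  series_list <- if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    n <- sim$n_reps %||% 3L
    lapply(seq_len(n), function(i) {
      gen_release_series(k = sim$k, a = sim$a, C_max = sim$C_max %||% 1,
                         V_reservoir = sim$V_reservoir %||% 14,
                         V_aliquot = sim$V_aliquot %||% 1,
                         noise_cv = sim$noise_cv %||% 0,
                         seed = seed + i - 1L)
    })
  } else if (!is.null(cfg$files)) {
    lapply(cfg$files, function(f) {
      read_release_csv(f, V_reservoir = cfg$V_reservoir %||% 14,
                       V_aliquot = cfg$V_aliquot %||% 1)
    })
  } else {
    abort("release config needs `files` or `simulate`",
          "mnswell_validation_error")
  }
  fits <- lapply(series_list, fit_one_release)
  keys <- c("k", "a", "r2", "plateau", "rate_120min")
  list(
    replicates = fits,
    summary = lapply(stats::setNames(nm = keys), function(f) {
      summary_row(vapply(fits, `[[`, numeric(1), f))
    })
  )
}
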