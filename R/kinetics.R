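#' Parameters of the fed-batch culture kinetics
#'
#' Defines the minimal difference-equation system used to emulate a fed-batch
#' CHO culture: logistic biomass growth to a plateau, first-order cell death
#' that accelerates under glucose starvation, cell-specific (per viable cell)
#' nutrient uptake and product formation with Monod saturation at low
#' substrate, lactate production from glycolytic overflow followed by
#' late-culture consumption, and once-daily bolus glucose feeding that tops
#' the reactor back up to a target concentration.
#'
#' Cell densities are expressed in 1e6 cells/mL; "per-cell" rates are per
#' unit of that density. Defaults are tuned to the standard phenomenology of
#' 10 L fed-batch IgG runs: inoculation at 0.6e6 viable cells/mL, a viable
#' plateau of ~20e6 cells/mL around day 8, daily glucose swings from ~5 g/L
#' post-feed down to ~1-2 g/L pre-feed once uptake peaks, lactate rising to
#' ~2 g/L then consumed, glutamine exhausted from ~4.8 mM, glutamate
#' accumulating to ~11 mM, and IgG titer reaching ~4.5 g/L.
#'
#' @param seed_density Viable cell density at inoculation (1e6 cells/mL).
#' @param growth_rate Specific growth rate (1/h).
#' @param carrying_capacity Total-cell density at which growth stops
#'   (1e6 cells/mL).
#' @param death_rate_baseline,death_rate_starved First-order death rates
#'   (1/h) under normal and glucose-starved conditions.
#' @param starvation_threshold_glc Glucose level (g/L) below which the
#'   starved death rate applies.
#' @param glc_uptake_per_cell Glucose uptake, g/L per hour per 1e6 viable
#'   cells/mL.
#' @param km_glc,km_gln Monod half-saturation constants (g/L, mM).
#' @param lac_yield_from_glc Grams of lactate produced per gram of glucose
#'   consumed before the metabolic shift.
#' @param lac_consumption_switch_time Culture time (h) at which net lactate
#'   production switches to consumption.
#' @param lac_uptake_per_cell Lactate consumption after the switch, g/L per
#'   hour per 1e6 viable cells/mL.
#' @param gln_uptake_per_cell Glutamine uptake, mM per hour per 1e6 viable
#'   cells/mL.
#' @param glu_production_per_cell Glutamate accumulation, mM per hour per
#'   1e6 viable cells/mL.
#' @param igg_specific_productivity IgG production, g/L per hour per 1e6
#'   viable cells/mL.
#' @param init_glc,init_lac,init_gln,init_glu,init_igg Initial
#'   concentrations (g/L, g/L, mM, mM, g/L).
#' @param feed_target_glc Post-feed glucose target (g/L); the daily bolus
#'   restores glucose up to this level (never removes glucose).
#' @param feed_start_day First feeding day (feeds occur at 24 h * day).
#' @param feed_stop_day If set, feeding stops on this day (no feed from this
#'   day onward), inducing starvation and cell death.
#' @param duration_days Culture duration (days).
#' @param dt Integration step (h), at most 1 h.
#' @return An object of class `kinetics_params` (a validated list).
#' @seealso [simulate_batch_kinetics()]
#' @export
kinetics_params <- function(seed_density = 0.6,
                            growth_rate = 0.042,
                            carrying_capacity = 24,
                            death_rate_baseline = 0.0015,
                            death_rate_starved = 0.03,
                            starvation_threshold_glc = 0.15,
                            glc_uptake_per_cell = 0.0095,
                            km_glc = 0.4,
                            km_gln = 0.3,
                            lac_yield_from_glc = 0.16,
                            lac_consumption_switch_time = 168,
                            lac_uptake_per_cell = 0.0007,
                            gln_uptake_per_cell = 0.0016,
                            glu_production_per_cell = 0.0038,
                            igg_specific_productivity = 0.00095,
                            init_glc = 5.5,
                            init_lac = 0.05,
                            init_gln = 4.8,
                            init_glu = 0.8,
                            init_igg = 0,
                            feed_target_glc = 5,
                            feed_start_day = 2,
                            feed_stop_day = NA,
                            duration_days = 14,
                            dt = 1 / 3) {
  p <- as.list(environment())
  rates <- c("seed_density", "growth_rate", "carrying_capacity",
             "death_rate_baseline", "death_rate_starved",
             "starvation_threshold_glc", "glc_uptake_per_cell", "km_glc",
             "km_gln", "lac_yield_from_glc", "lac_uptake_per_cell",
             "gln_uptake_per_cell", "glu_production_per_cell",
             "igg_specific_productivity", "init_glc", "init_lac", "init_gln",
             "init_glu", "init_igg", "feed_target_glc")
  for (nm in rates) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] < 0) {
      abort(paste0("`", nm, "` must be a single non-negative finite number."))
    }
  }
  if (!(p$dt > 0 && p$dt <= 1)) abort("`dt` must satisfy 0 < dt <= 1 h.")
  if (p$duration_days <= 0) abort("`duration_days` must be positive.")
  if (p$feed_start_day >= p$duration_days) {
    abort("`feed_start_day` must be smaller than `duration_days`.")
  }
  if (!is.na(p$feed_stop_day) &&
      !(p$feed_start_day < p$feed_stop_day &&
        p$feed_stop_day <= p$duration_days)) {
    abort("`feed_stop_day` must lie in (feed_start_day, duration_days].")
  }
  structure(p, class = "kinetics_params")
}

#' @export
print.kinetics_params <- function(x, ...) {
  cat("<kinetics_params>\n")
  scen <- if (is.na(x$feed_stop_day)) "normal feeding" else
    paste0("feeding stopped on day ", x$feed_stop_day, " (induced death)")
  cat("  ", x$duration_days, "-day fed-batch, feeds from day ",
      x$feed_start_day, " to ", x$feed_target_glc, " g/L glucose; ", scen,
      "\n", sep = "")
  invisible(x)
}

feed_days <- function(params) {
  last <- if (is.na(params$feed_stop_day)) params$duration_days else
    params$feed_stop_day - 1
  days <- seq(params$feed_start_day, floor(params$duration_days))
  ## no feed at the harvest instant itself
  days[days <= last & days * 24 < params$duration_days * 24]
}

#' Simulate fed-batch culture kinetics
#'
#' Integrates the culture model of [kinetics_params()] by forward Euler and
#' applies the once-daily glucose bolus (glucose is restored up to
#' `feed_target_glc` at each feed time; nothing is removed when glucose sits
#' above the target). The run is deterministic: the `seed` argument is kept
#' for interface symmetry with the stochastic generators and recorded as an
#' attribute.
#'
#' @param params A [kinetics_params()] object.
#' @param seed Integer, recorded in the output.
#' @return A tibble with columns `time_h`, `glc`, `lac`, `gln`, `glu`,
#'   `igg` , `vcd`, `tcd`, with attributes `feed_times_h` (feed event times)
#'   and `params`.
#' @examples
#' k <- simulate_batch_kinetics(kinetics_params(duration_days = 6))
#' dplyr::slice_tail(k, n = 2)
#' @export
simulate_batch_kinetics <- function(params = kinetics_params(), seed = 1L) {
  stopifnot(inherits(params, "kinetics_params"))
  p <- params
  times <- seq(0, p$duration_days * 24, by = p$dt)
  n <- length(times)
  feeds <- feed_days(p) * 24

  out <- matrix(NA_real_, n, 7,
                dimnames = list(NULL, c("glc", "lac", "gln", "glu", "igg",
                                        "vcd", "tcd")))
  st <- c(glc = p$init_glc, lac = p$init_lac, gln = p$init_gln,
          glu = p$init_glu, igg = p$init_igg, vcd = p$seed_density,
          tcd = p$seed_density)
  out[1, ] <- st
  fed <- logical(length(feeds))

  for (i in seq_len(n - 1)) {
    t <- times[i]
    monod_glc <- st[["glc"]] / (st[["glc"]] + p$km_glc)
    monod_gln <- st[["gln"]] / (st[["gln"]] + p$km_gln)
    room <- max(0, 1 - st[["tcd"]] / max(p$carrying_capacity, 1e-12))
    growth <- p$growth_rate * st[["vcd"]] * room * monod_glc
    kd <- if (st[["glc"]] < p$starvation_threshold_glc)
      p$death_rate_starved else p$death_rate_baseline

    glc_up <- p$glc_uptake_per_cell * st[["vcd"]] * monod_glc
    gln_up <- p$gln_uptake_per_cell * st[["vcd"]] * monod_gln
    lac_rate <- if (t < p$lac_consumption_switch_time)
      p$lac_yield_from_glc * glc_up
    else
      -p$lac_uptake_per_cell * st[["vcd"]] *
        st[["lac"]] / (st[["lac"]] + 0.2)

    st[["vcd"]] <- st[["vcd"]] + p$dt * (growth - kd * st[["vcd"]])
    st[["tcd"]] <- st[["tcd"]] + p$dt * growth
    st[["glc"]] <- max(0, st[["glc"]] - p$dt * glc_up)
    st[["gln"]] <- max(0, st[["gln"]] - p$dt * gln_up)
    st[["lac"]] <- max(0, st[["lac"]] + p$dt * lac_rate)
    st[["glu"]] <- st[["glu"]] + p$dt * p$glu_production_per_cell *
      st[["vcd"]] * monod_gln
    st[["igg"]] <- st[["igg"]] + p$dt * p$igg_specific_productivity *
      st[["vcd"]]

    if (any(!is.finite(st))) {
      abort(paste0("Kinetics diverged (non-finite ",
                   paste(names(st)[!is.finite(st)], collapse = ", "),
                   ") at t = ", round(times[i + 1], 2),
                   " h; check the rate parameters."))
    }

    ## bolus feed: first step at or past each feed time
    due <- which(!fed & feeds <= times[i + 1] + 1e-9)
    if (length(due)) {
      st[["glc"]] <- max(st[["glc"]], p$feed_target_glc)
      fed[due] <- TRUE
    }
    out[i + 1, ] <- st
  }

  res <- dplyr::bind_cols(tibble::tibble(time_h = times),
                          tibble::as_tibble(out))
  attr(res, "feed_times_h") <- feeds
  attr(res, "params") <- p
  attr(res, "seed") <- seed
  res
}

## Linear interpolation of every kinetics column at arbitrary times; shared
## by the spectral forward model and the off-line sampler so both see the
## same state.
kinetics_at <- function(kinetics, times) {
  cols <- setdiff(names(kinetics), "time_h")
  vals <- purrr::map(cols, function(cl) {
    approx(kinetics$time_h, kinetics[[cl]], xout = times, rule = 2)$y
  })
  names(vals) <- cols
  dplyr::bind_cols(tibble::tibble(time_h = times), tibble::as_tibble(vals))
}

#' Schedule and draw noisy off-line reference samples
#'
#' Emulates the bench-assay sampling plan: one sample at inoculation, then
#' two per day from `feed_start_day` on — immediately before and after the
#' daily feed (offsets `pre_offset_h`/`post_offset_h` around each 24 h * day
#' mark, also used on days after feeding has stopped). Measured values are
#' the true kinetics multiplied by lognormal noise with unit mean and
#' relative standard deviation `assay_cv`, emulating the 10-15% standard
#' error typical of off-line substrate/metabolite and cell-count assays.
#'
#' @param kinetics Output of [simulate_batch_kinetics()].
#' @param assay_cv Fractional relative standard deviation in `[0, 0.5]`.
#' @param seed Integer seed; draws are deterministic given it.
#' @param pre_offset_h,post_offset_h Sampling offsets (h) before/after the
#'   feed clock time. The 1 h default keeps each sample's paired (averaged)
#'   spectrum entirely on one side of the feed bolus at 20-30 min cadences,
#'   so pre- and post-feed states are both observable.
#' @param batch_id Batch label attached to the samples.
#' @return A tibble with columns `batch_id`, `timestamp_h`, `analyte`,
#'   `value`, `units`, `true_value`, `assay_cv`.
#' @export
schedule_offline_samples <- function(kinetics, assay_cv = 0.12, seed = 1L,
                                     pre_offset_h = 1,
                                     post_offset_h = 1,
                                     batch_id = "B1") {
  if (!is.numeric(assay_cv) || assay_cv < 0 || assay_cv > 0.5) {
    abort("`assay_cv` must lie in [0, 0.5].")
  }
  if (nrow(kinetics) == 0L) abort("`kinetics` is empty.")
  params <- attr(kinetics, "params")
  start_day <- if (!is.null(params)) params$feed_start_day else 2
  duration <- max(kinetics$time_h)
  days <- seq(start_day, floor(duration / 24))
  times <- sort(unique(c(0, pmax(0, days * 24 - pre_offset_h),
                         pmin(duration, days * 24 + post_offset_h))))

  state <- kinetics_at(kinetics, times)
  long <- tidyr::pivot_longer(state, -dplyr::all_of("time_h"),
                              names_to = "analyte",
                              values_to = "true_value")
  sdlog <- sqrt(log(1 + assay_cv^2))
  noise <- local({
    set.seed(seed)
    exp(rnorm(nrow(long), mean = -sdlog^2 / 2, sd = sdlog))
  })
  tibble::tibble(
    batch_id = batch_id,
    timestamp_h = long$time_h,
    analyte = long$analyte,
    value = long$true_value * noise,
    units = analyte_units(long$analyte),
    true_value = long$true_value,
    assay_cv = assay_cv
  )
}
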