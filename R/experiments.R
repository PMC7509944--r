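#' Scripted reproductions of the model experiments
#'
#' `run_experiment` executes a named experiment from the registry with a
#' validated configuration, writes its tabular outputs (CSV) and a
#' machine-readable summary (JSON, containing every headline number the
#' experiment produces) into the output directory, and returns the summary.
#' All randomness flows from `config$seed`, so runs are reproducible.
#'
#' Registry: `steady_state`, `eht_distribution`, `trp_sweep`, `meals`,
#' `male_female`, `snr_responses`, `variability`, `ssri_mao`, `aadc_b6`.
#'
#' @param config list with fields `name` (registry entry), and optionally
#'   `overrides` (parameter overrides), `n` (population size), `seed`,
#'   `out_dir` (default: no files written).
#' @return the summary list, invisibly also written to
#'   `<out_dir>/<name>_summary.json`.
#' @examples
#' s <- run_experiment(list(name = "steady_state"))
#' s$eht_nM
#' @export
run_experiment <- function(config) {
  if (is.null(config$name) || !config$name %in% names(experiment_registry))
    stop("unknown experiment: ", config$name)
  config$seed <- config$seed %||% 1L
  config$overrides <- config$overrides %||% list()
  config$params <- do.call(sero_params, config$overrides)
  t0 <- proc.time()[3]
  summary <- experiment_registry[[config$name]](config)
  summary$experiment <- config$name
  summary$seed <- config$seed
  summary$overrides <- config$overrides
  summary$wall_time_s <- unname(proc.time()[3] - t0)
  summary$package_version <- as.character(utils::packageVersion("serosim"))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary,
                         file.path(config$out_dir,
                                   paste0(config$name, "_summary.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_if <- function(df, config, file) {
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(df, file.path(config$out_dir, file), row.names = FALSE)
  }
}

experiment_registry <- list(

  # the normal steady state and its flux table
  steady_state = function(config) {
    eq <- compute_equilibrium(config$params)
    write_if(flux_table(eq), config, "steady_state.csv")
    list(eht_nM = 1000 * eq$state[["eht"]], vht_uM = eq$state[["vht"]],
         fluxes = as.list(eq$fluxes), residual_norm = eq$residual_norm,
         sert_recapture_fraction =
           eq$fluxes[["v_sert"]] / eq$fluxes[["release"]])
  },

  # eht distributions under three autoreceptor strengths
  eht_distribution = function(config) {
    n <- config$n %||% 1000
    base <- config$params
    cases <- list(
      standard = base,
      none = do.call(sero_params,
                     utils::modifyList(unclass(base),
                                       list(s_rel = 0, s_syn = 0))),
      doubled = do.call(sero_params,
                        utils::modifyList(unclass(base),
                                          list(s_rel = 2 * base$s_rel,
                                               s_syn = 2 * base$s_syn))))
    anchors <- compute_equilibrium(base)$anchors
    out <- list(n = n)
    for (nm in names(cases)) {
      db <- build_population(n, variation_spec("fig2"), cases[[nm]],
                             seed = config$seed, anchors = anchors)
      s <- summarize_population(db, "eht_nM")
      out[[nm]] <- list(mean_nM = s$mean, sd_nM = s$sd, range_nM = s$range)
      write_if(db$individuals, config, paste0("eht_distribution_", nm, ".csv"))
    }
    out
  },

  # steady-state eht and vht over a blood-tryptophan range, with and
  # without the autoreceptor effect
  trp_sweep = function(config) {
    btrps <- config$btrp_grid %||% seq(30, 150, by = 10)
    anchors <- compute_equilibrium(config$params)$anchors
    sweep1 <- function(p) {
      t(vapply(btrps, function(bt) {
        p$btrp <- bt
        eq <- compute_equilibrium(p, anchors = anchors)
        c(btrp = bt, eht_nM = 1000 * eq$state[["eht"]],
          vht_uM = eq$state[["vht"]])
      }, numeric(3)))
    }
    p_off <- do.call(sero_params,
                     utils::modifyList(unclass(config$params),
                                       list(s_rel = 0, s_syn = 0)))
    on <- as.data.frame(sweep1(config$params))
    off <- as.data.frame(sweep1(p_off))
    write_if(cbind(on, autoreceptors = "on"), config, "trp_sweep_on.csv")
    write_if(cbind(off, autoreceptors = "off"), config, "trp_sweep_off.csv")
    list(btrp_grid = btrps,
         eht_range_on_nM = range(on$eht_nM),
         eht_range_off_nM = range(off$eht_nM),
         vht_range_on_uM = range(on$vht_uM),
         vht_range_off_uM = range(off$vht_uM))
  },

  # 48 h meal simulation; day 1 is burn-in, day 2 is reported
  meals = function(config) {
    run1 <- function(p) {
      eq <- compute_equilibrium(p)
      f <- sero_forcings(p, btrp_of_t = meal_btrp(mean_btrp = p$btrp,
                                                  days = 2))
      tr <- sero_simulate(eq$state, p, eq$anchors, f,
                          times = seq(0, 48, by = 0.02))
      day2 <- tr[tr$time_h >= 24, ]
      list(trajectory = tr, min_nM = 1000 * min(day2$eht),
           max_nM = 1000 * max(day2$eht), mean_nM = 1000 * mean(day2$eht))
    }
    p_off <- do.call(sero_params,
                     utils::modifyList(unclass(config$params),
                                       list(s_rel = 0, s_syn = 0)))
    on <- run1(config$params)
    off <- run1(p_off)
    write_if(on$trajectory, config, "meals_on.csv")
    write_if(off$trajectory, config, "meals_off.csv")
    fb <- meal_btrp(mean_btrp = config$params$btrp)
    tt <- seq(0, 24, by = 1 / 240)[-1]
    list(on = on[c("min_nM", "max_nM", "mean_nM")],
         off = off[c("min_nM", "max_nM", "mean_nM")],
         btrp_mean_24h = mean(fb(tt)),
         btrp_levels = as.list(attr(fb, "levels")))
  },

  # fitted male and female average hippocampal responses
  male_female = function(config) {
    out <- list()
    for (nm in c("male", "female")) {
      resp <- simulate_response(sero_preset(nm), params = config$params)
      write_if(resp, config, paste0("response_", nm, ".csv"))
      out[[nm]] <- list(baseline_eht_nM = attr(resp, "baseline_eht_nM"),
                        peak_delta_nM = max(resp$delta_eht_nM),
                        min_delta_nM = min(resp$delta_eht_nM))
    }
    out
  },

  # fast / hybrid / slow SNr presets (histamine forcing constant unless a
  # pulse is configured; qualitative shape analysis only)
  snr_responses = function(config) {
    out <- list()
    for (nm in c("fast", "hybrid", "slow")) {
      resp <- simulate_response(sero_preset(nm), params = config$params)
      write_if(resp, config, paste0("response_", nm, ".csv"))
      out[[nm]] <- list(baseline_eht_nM = attr(resp, "baseline_eht_nM"),
                        peak_delta_nM = max(resp$delta_eht_nM),
                        peak_abs_nM = attr(resp, "baseline_eht_nM") +
                          max(resp$delta_eht_nM))
    }
    out
  },

  # response-curve variability in a virtual population
  variability = function(config) {
    n <- config$n %||% 1000
    rp <- response_population(n, variation_spec("fig6ab"),
                              base_params = config$params,
                              seed = config$seed)
    write_if(data.frame(t_s = rp$t_s, mean = rp$mean_curve,
                        sd = rp$sd_curve), config, "variability_curves.csv")
    top7 <- attribute_variation(rp, t_query_s = 7)
    list(n = nrow(rp$curves),
         peak_mean_nM = max(rp$mean_curve),
         max_sd_nM = max(rp$sd_curve),
         top_drivers_at_7s = as.list(top7$parameter[1:3]),
         r_squared_at_7s = attr(top7, "r_squared"))
  },

  # SSRI efficacy stratified by MAO expression
  ssri_mao = function(config) {
    n <- config$n %||% 500
    db <- build_population(n, variation_spec("ssri_mao"), config$params,
                           seed = config$seed)
    sc <- two_factor_scan(db)
    write_if(sc, config, "ssri_mao.csv")
    terc <- stats::quantile(sc$m_vmax_catab, c(1 / 3, 2 / 3))
    slope_in <- function(rows)
      stats::coef(stats::lm(eht_nM ~ m_vmax_sert, data = rows))[2]
    list(n = n,
         sert_slope_high_mao = unname(slope_in(sc[sc$m_vmax_catab >= terc[2], ])),
         sert_slope_low_mao = unname(slope_in(sc[sc$m_vmax_catab <= terc[1], ])))
  },

  # vitamin-B6 question: eht is insensitive to AADC expression
  aadc_b6 = function(config) {
    n <- config$n %||% 500
    db <- build_population(n, variation_spec("aadc_b6"), config$params,
                           seed = config$seed)
    sc <- two_factor_scan(db)
    write_if(sc, config, "aadc_b6.csv")
    list(n = n,
         cor_eht_aadc = stats::cor(sc$m_vmax_aadc, sc$eht_nM),
         cv_aadc_flux = stats::sd(sc$v_aadc) / mean(sc$v_aadc),
         cv_aadc_multiplier = stats::sd(sc$m_vmax_aadc) /
           mean(sc$m_vmax_aadc))
  }
)

#' Compare two experiment summaries field by field
#'
#' Regression-testing aid: recursively diffs the numeric fields of two
#' summaries (as returned by [run_experiment()] or read back from their
#' JSON files) against per-field or global tolerances.
#'
#' @param a,b summary lists.
#' @param tol global relative tolerance for numeric fields; must be > 0 for
#'   stochastic fields (a zero tolerance on anything non-deterministic is
#'   flagged as a misconfiguration via `stochastic_fields`).
#' @param stochastic_fields character vector of field names that are
#'   sampling-dependent.
#' @return data.frame of differing fields (`field`, `a`, `b`, `rel_diff`);
#'   zero rows means the runs agree.  Attribute `pass` gives the overall
#'   verdict.
#' @export
compare_runs <- function(a, b, tol = 1e-8, stochastic_fields = character()) {
  if (tol == 0 && length(stochastic_fields))
    stop("tolerance 0 on stochastic fields is a misconfiguration")
  flat <- function(x, prefix = "") {
    out <- list()
    for (nm in names(x)) {
      v <- x[[nm]]
      key <- if (prefix == "") nm else paste0(prefix, ".", nm)
      if (is.list(v)) out <- c(out, flat(v, key))
      else if (is.numeric(v)) out[[key]] <- v
    }
    out
  }
  fa <- flat(a); fb <- flat(b)
  keys <- intersect(names(fa), names(fb))
  keys <- keys[!keys %in% c("wall_time_s", "seed")]
  rows <- list()
  for (k in keys) {
    va <- fa[[k]]; vb <- fb[[k]]
    if (length(va) != length(vb)) next
    rd <- max(abs(va - vb) / pmax(abs(va), abs(vb), 1e-12))
    if (rd > tol)
      rows[[k]] <- data.frame(field = k, a = va[1], b = vb[1], rel_diff = rd)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(field = character(), a = numeric(), b = numeric(),
               rel_diff = numeric())
  rownames(out) <- NULL
  attr(out, "pass") <- nrow(out) == 0
  out
}
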