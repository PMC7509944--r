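#' Expression-variation specifications for virtual populations
#'
#' A variation spec lists parameter keys together with the lower and upper
#' bounds of the uniform multiplier applied to each: a virtual individual is
#' drawn by multiplying every listed parameter by an independent
#' `Uniform(lower, upper)` factor.  Named presets:
#'
#' * `"fig2"` — the steady-state population design: Vmax of TRPin, TPH,
#'   AADC, MAT, MAO (catabolism), Uptake 2 and SERT, plus the basal firing
#'   strength and the release-inhibition slope, each 75-125% of normal.
#' * `"fig6ab"` — the stimulation-response design: Vmax of AADC, MAO, MAT,
#'   SERT, TPH and Uptake 2, both autoreceptor slopes, extracellular
#'   histamine, and the joint receptor speed `beta`, each 60-140%;
#'   stimulation strength `r` 75-125%; SBP rate `b_sbp_protocol`
#'   (which sets the timing of the release-kernel peak) 80-120%.
#' * `"ssri_mao"` — SERT and MAO expression each 25-175%.
#' * `"aadc_b6"` — blood tryptophan and AADC expression each 25-175%.
#'
#' @param preset one of `"fig2"`, `"fig6ab"`, `"ssri_mao"`, `"aadc_b6"`, or
#'   `"custom"` with an explicit `table`.
#' @param table data.frame with columns `key`, `lower`, `upper` (custom).
#' @return data.frame of class `variation_spec`.
#' @export
variation_spec <- function(preset = c("fig2", "fig6ab", "ssri_mao",
                                      "aadc_b6", "custom"), table = NULL) {
  preset <- match.arg(preset)
  tab <- switch(preset,
    fig2 = data.frame(
      key = c("vmax_trpin", "vmax_tph", "vmax_aadc", "vmax_mat",
              "vmax_catab", "vmax_u2", "vmax_sert", "f_basal", "s_rel"),
      lower = 0.75, upper = 1.25),
    fig6ab = rbind(
      data.frame(key = c("vmax_aadc", "vmax_catab", "vmax_mat", "vmax_sert",
                         "vmax_tph", "vmax_u2", "s_rel", "s_syn", "eha",
                         "beta"),
                 lower = 0.6, upper = 1.4),
      data.frame(key = "r", lower = 0.75, upper = 1.25),
      data.frame(key = "b_sbp_protocol", lower = 0.8, upper = 1.2)),
    ssri_mao = data.frame(key = c("vmax_sert", "vmax_catab"),
                          lower = 0.25, upper = 1.75),
    aadc_b6 = data.frame(key = c("btrp", "vmax_aadc"),
                         lower = 0.25, upper = 1.75),
    custom = {
      if (is.null(table)) stop("custom spec needs a 'table'")
      stopifnot(all(c("key", "lower", "upper") %in% names(table)))
      table[c("key", "lower", "upper")]
    })
  if (any(tab$lower <= 0) || any(tab$lower > tab$upper))
    stop("need 0 < lower <= upper for every key")
  structure(tab, class = c("variation_spec", "data.frame"),
            preset = preset)
}

#' Draw the multipliers of one virtual individual
#'
#' @param spec a [variation_spec()].
#' @return named numeric vector of multipliers (relies on the current RNG
#'   state; callers seed per individual for order-independence).
#' @export
sample_multipliers <- function(spec) {
  stats::setNames(stats::runif(nrow(spec), spec$lower, spec$upper),
                  spec$key)
}

#' Sample one virtual individual's parameter set
#'
#' @param spec a [variation_spec()].
#' @param base_params the reference parameter set.
#' @return list with `multipliers` and the rescaled `params` (protocol-level
#'   keys `r` / `b_sbp_protocol` are left to the caller).
#' @export
sample_individual <- function(spec, base_params = sero_params()) {
  m <- sample_multipliers(spec)
  list(multipliers = m, params = apply_multipliers(base_params, m))
}

# one child seed per individual from a master seed, so populations are
# order-independent and extensible
child_seeds <- function(n, seed) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

#' Build a steady-state virtual population
#'
#' Draws `n` virtual individuals from `spec`, solves each one's equilibrium
#' with the autoreceptor feedback anchored at the reference model's
#' equilibrium (the reference operating point the receptors defend), and
#' collects multipliers, steady-state concentrations and fluxes into a
#' database.  Individuals whose steady state fails to converge are excluded
#' (never resampled) and counted; more than 1% failures aborts.
#'
#' @param n number of individuals.
#' @param spec a [variation_spec()].
#' @param base_params reference parameter set.
#' @param seed master RNG seed; the same `(seed, spec, n)` reproduces the
#'   database exactly, independently of evaluation order.
#' @param anchors reference anchors; default: the self-anchored equilibrium
#'   of `base_params`.
#' @return object of class `sero_population`: list with `individuals` (one
#'   row per converged individual: `id`, multiplier columns prefixed `m_`,
#'   state columns, flux columns, `eht_nM`), `spec`, `seed`, `n_requested`,
#'   `n_failed`, `anchors`.
#' @examples
#' \donttest{
#' db <- build_population(50, variation_spec("fig2"), seed = 1)
#' summarize_population(db, "eht_nM")
#' }
#' @export
build_population <- function(n, spec, base_params = sero_params(), seed = 1,
                             anchors = NULL) {
  if (n < 1) stop("n must be at least 1")
  if (is.null(anchors)) anchors <- compute_equilibrium(base_params)$anchors
  seeds <- child_seeds(n, seed)
  rows <- vector("list", n)
  n_failed <- 0L
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    ind <- sample_individual(spec, base_params)
    eq <- tryCatch(compute_equilibrium(ind$params, anchors = anchors),
                   error = function(e) NULL)
    if (is.null(eq)) { n_failed <- n_failed + 1L; next }
    rows[[i]] <- c(id = i, stats::setNames(ind$multipliers,
                                           paste0("m_", names(ind$multipliers))),
                   eq$state, eq$fluxes, eht_nM = 1000 * eq$state[["eht"]])
  }
  if (n_failed > 0.01 * n)
    stop(n_failed, " of ", n, " individuals failed to converge (> 1%)")
  if (n_failed > 0)
    message(n_failed, " individual(s) failed to converge and were excluded")
  individuals <- as.data.frame(do.call(rbind, rows[!vapply(rows, is.null,
                                                           logical(1))]))
  structure(list(individuals = individuals, spec = spec, seed = seed,
                 n_requested = n, n_failed = n_failed, anchors = anchors,
                 base_params = base_params),
            class = "sero_population")
}

#' @export
print.sero_population <- function(x, ...) {
  cat("<sero_population> ", nrow(x$individuals), " individuals (",
      x$n_failed, " failed), spec '", attr(x$spec, "preset"),
      "', seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Summarize a population field
#'
#' Moments, range, and a fixed-bin histogram (2.5 nM bins for `eht_nM`,
#' matching the granularity the extracellular-serotonin distributions are
#' conventionally displayed at; statistics are computed on raw values, not
#' bins).
#'
#' @param db a `sero_population` (or its `individuals` data.frame).
#' @param field column to summarize (default `"eht_nM"`).
#' @param binwidth histogram bin width (field units).
#' @return list with `mean`, `sd`, `range`, `n`, `histogram` (data.frame
#'   `mid`, `count`).
#' @export
summarize_population <- function(db, field = "eht_nM",
                                 binwidth = if (field == "eht_nM") 2.5 else NULL) {
  x <- if (inherits(db, "sero_population")) db$individuals[[field]]
       else db[[field]]
  if (is.null(x)) stop("field '", field, "' not found")
  out <- list(mean = mean(x), sd = stats::sd(x), range = range(x),
              n = length(x))
  if (!is.null(binwidth)) {
    lo <- floor(min(x) / binwidth) * binwidth
    brk <- seq(lo, max(x) + binwidth, by = binwidth)
    h <- graphics::hist(x, breaks = brk, plot = FALSE)
    out$histogram <- data.frame(mid = h$mids, count = h$counts)
  }
  out
}

#' Stimulation-response virtual population
#'
#' Draws `n` individuals from a variation spec (typically `"fig6ab"`),
#' equilibrates each under its own parameters, stimulates with its own
#' protocol (the `r` and `b_sbp_protocol` multipliers scale the protocol),
#' and records each response curve on a shared time grid, together with the
#' pointwise mean and standard-deviation curves.
#'
#' @param n number of individuals.
#' @param spec a [variation_spec()].
#' @param protocol reference [stim_protocol()].
#' @param base_params reference parameter set.
#' @param seed master RNG seed.
#' @param record_window_s,dt_s recording window and resolution (s).
#' @return list of class `sero_response_population`: `t_s`, `curves`
#'   (matrix, individuals in rows), `mean_curve`, `sd_curve`,
#'   `multipliers` (data.frame), `n_failed`, `seed`, `spec`.
#' @export
response_population <- function(n, spec = variation_spec("fig6ab"),
                                protocol = stim_protocol(r = 18),
                                base_params = sero_params(), seed = 1,
                                record_window_s = 30, dt_s = 0.25) {
  seeds <- child_seeds(n, seed)
  t_s <- seq(0, record_window_s, by = dt_s)
  curves <- matrix(NA_real_, n, length(t_s))
  mults <- vector("list", n)
  n_failed <- 0L
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    m <- sample_multipliers(spec)
    p <- apply_multipliers(base_params, m)
    proto <- protocol
    if ("r" %in% names(m)) proto$r <- proto$r * m[["r"]]
    if ("b_sbp_protocol" %in% names(m)) proto$b <- proto$b * m[["b_sbp_protocol"]]
    resp <- tryCatch(
      simulate_response(sero_preset("custom"), proto, params = p,
                        record_window_s = record_window_s, dt_s = dt_s),
      error = function(e) NULL)
    if (is.null(resp)) { n_failed <- n_failed + 1L; next }
    curves[i, ] <- resp$delta_eht_nM
    mults[[i]] <- m
  }
  if (n_failed > 0.01 * n)
    stop(n_failed, " of ", n, " response simulations failed (> 1%)")
  ok <- !is.na(curves[, 1])
  curves <- curves[ok, , drop = FALSE]
  structure(list(t_s = t_s, curves = curves,
                 mean_curve = colMeans(curves),
                 sd_curve = apply(curves, 2, stats::sd),
                 multipliers = as.data.frame(do.call(rbind, mults[ok])),
                 n_failed = n_failed, seed = seed, spec = spec),
            class = "sero_response_population")
}

#' Attribute response variation to sampled parameters
#'
#' Ordinary least squares of a response summary (by default the
#' baseline-relative extracellular serotonin at a query time) on the
#' standardized sampled multipliers; coefficients are returned ranked by
#' absolute standardized size, with the fit's R-squared.
#'
#' @param multipliers data.frame of sampled multipliers (one individual per
#'   row), e.g. `rp$multipliers` from [response_population()].
#' @param response numeric response vector, one value per individual;
#'   alternatively pass a `sero_response_population` as `multipliers` and a
#'   query time `t_query_s`.
#' @param t_query_s query time (s) when a response population is given.
#' @return data.frame `parameter`, `beta_std`, `rank`; attribute
#'   `r_squared`.
#' @export
attribute_variation <- function(multipliers, response = NULL,
                                t_query_s = NULL) {
  if (inherits(multipliers, "sero_response_population")) {
    rp <- multipliers
    if (is.null(t_query_s)) stop("t_query_s required")
    j <- which.min(abs(rp$t_s - t_query_s))
    response <- rp$curves[, j]
    multipliers <- rp$multipliers
  }
  X <- as.matrix(multipliers)
  if (nrow(X) < ncol(X) + 2)
    stop("need at least #parameters + 2 individuals for the regression")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0) || stats::sd(response) == 0)
    stop("degenerate (zero-variance) input; standardization undefined")
  Xs <- scale(X)
  ys <- as.vector(scale(response))
  fit <- stats::lm(ys ~ Xs)
  beta <- stats::coef(fit)[-1]
  names(beta) <- colnames(X)
  out <- data.frame(parameter = names(beta), beta_std = unname(beta))
  out <- out[order(-abs(out$beta_std)), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "r_squared") <- summary(fit)$r.squared
  out
}

#' Two-factor population scan
#'
#' Convenience extraction of the per-individual records of a two-factor
#' population (e.g. the SERT-by-MAO or tryptophan-by-AADC designs):
#' the two multipliers together with extracellular serotonin and, where
#' relevant, the AADC substrate and flux.
#'
#' @param db a `sero_population` built from a two-factor [variation_spec()].
#' @return data.frame with the multiplier columns, `eht_nM`, `htp`, and
#'   `v_aadc`.
#' @export
two_factor_scan <- function(db) {
  ind <- db$individuals
  mcols <- grep("^m_", names(ind), value = TRUE)
  if (length(mcols) != 2)
    stop("two_factor_scan expects a population varying exactly two factors")
  out <- ind[c(mcols, "eht_nM", "htp", "v_aadc")]
  rownames(out) <- NULL
  out
}
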