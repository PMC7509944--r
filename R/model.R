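#' Names of the 16 dynamical variables, in canonical order
#'
#' Concentrations in uM (`eht` reported in nM where conventional); the six
#' receptor species are in arbitrary receptor units.
#' @export
STATE_NAMES <- c("bh2", "bh4", "trp", "htp", "cht", "vht", "eht", "hiaa",
                 "pool", "ght", "g_ht_star", "t_ht_star", "b_ht",
                 "g_ha_star", "t_ha_star", "b_ha")

#' Construct a model state vector
#'
#' Defaults are the reported normal steady-state concentrations, which also
#' serve as the root-finding seed in [compute_equilibrium()].
#'
#' @param ... named overrides of individual state components.
#' @return named numeric vector of length 16.
#' @examples
#' s <- sero_state(eht = 0.09)
#' @export
sero_state <- function(...) {
  s <- c(bh2 = 0.1, bh4 = 0.9, trp = 20.2, htp = 1.61, cht = 0.04,
         vht = 67.5, eht = 0.060, hiaa = 0.87, pool = 113, ght = 0,
         g_ht_star = 0.86, t_ht_star = 1.01, b_ht = 0.97,
         g_ha_star = 0.69, t_ha_star = 12.69, b_ha = 2.94)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(s))
    if (length(bad)) stop("unknown state variable(s): ",
                          paste(bad, collapse = ", "))
    s[names(dots)] <- unlist(dots)
  }
  if (any(s < 0)) stop("state components must be non-negative")
  s
}

#' Constant or time-varying forcings
#'
#' Blood tryptophan and extracellular histamine have no differential
#' equations; their time courses are supplied as functions of time in
#' hours.  The default holds both at the baseline values in `params`.
#'
#' @param params a [sero_params()] list (supplies the constant baselines).
#' @param btrp_of_t,eha_of_t functions mapping time (h) to concentration
#'   (uM); `NULL` means constant at the baseline.
#' @return list with elements `btrp` and `eha` (functions of time in hours),
#'   carrying a `breaks` attribute with known discontinuity times (h) used
#'   to split stiff integrations.
#' @export
sero_forcings <- function(params = sero_params(),
                          btrp_of_t = NULL, eha_of_t = NULL) {
  btrp0 <- params$btrp
  eha0 <- params$eha
  f <- list(
    btrp = if (is.null(btrp_of_t)) function(t) rep(btrp0, length(t)) else btrp_of_t,
    eha = if (is.null(eha_of_t)) function(t) rep(eha0, length(t)) else eha_of_t
  )
  brk <- sort(unique(c(attr(f$btrp, "breaks"), attr(f$eha, "breaks"))))
  attr(f, "breaks") <- brk
  f
}

#' Right-hand side of the 16-ODE varicosity model
#'
#' Computes d(state)/dt in uM/h (receptor components in receptor units/h).
#' Release is `inhib_release * inhib_ha * fire * vht`; the cytosolic and
#' glial leaks enter the extracellular balance as inflows, matching their
#' outflow terms in the `cht` and `ght` equations; the receptor ODEs are
#' scaled by `beta1..beta3`.
#'
#' @param t time in hours.
#' @param state named numeric state vector (see [sero_state()]).
#' @param params a [sero_params()] list.
#' @param anchors equilibrium anchors (list with `g_ht_star_eq`,
#'   `g_ha_star_eq`) defining the operating points of the inhibition
#'   multipliers.  Ignored when `multipliers` is given.
#' @param forcings a [sero_forcings()] list.
#' @param fire_value instantaneous firing rate (/h), `f_basal` at rest.
#' @param multipliers optional named vector `c(rel=, syn=, ha=)` freezing
#'   the three inhibition multipliers at constant values (used by the
#'   first anchoring pass of the steady-state solver).
#' @return named numeric vector of derivatives.
#' @export
sero_rhs <- function(t, state, params, anchors = NULL,
                     forcings = sero_forcings(params),
                     fire_value = params$f_basal, multipliers = NULL) {
  if (any(!is.finite(state))) stop("non-finite state passed to sero_rhs")
  s <- as.list(state)
  if (is.null(multipliers)) {
    if (is.null(anchors))
      stop("either 'anchors' or fixed 'multipliers' must be supplied")
    m_rel <- inhib_release(s$g_ht_star, anchors, params)
    m_syn <- inhibsyn(s$g_ht_star, anchors, params)
    m_ha <- inhib_ha(s$g_ha_star, anchors, params)
  } else {
    m_rel <- multipliers[["rel"]]
    m_syn <- multipliers[["syn"]]
    m_ha <- multipliers[["ha"]]
  }
  btrp <- forcings$btrp(t)
  eha <- forcings$eha(t)

  vtph <- params$vmax_tph * s$trp * s$bh4 /
    ((params$km_tph_trp + s$trp + s$trp^2 / params$ki_tph) *
       (params$km_tph_bh4 + s$bh4)) * m_syn
  vdrr <- v_drr(s$bh2, s$bh4, params)
  vaadc <- v_aadc(s$htp, params)
  vmat <- v_mat(s$cht, s$vht, params)
  vsert <- v_sert(s$eht, params)
  vcat_c <- v_catab(s$cht, params)
  vcat_g <- v_catab(s$ght, params)
  vu2 <- v_u2(s$eht, params)
  vpool <- v_pool(s$trp, s$pool, params)
  release <- m_rel * m_ha * fire_value * s$vht
  bind <- params$k5 * s$eht * (params$b_ht_tot - s$b_ht) -
    params$k6 * s$b_ht

  c(bh2 = vtph - vdrr,
    bh4 = vdrr - vtph,
    trp = v_trpin(btrp, params) - vtph - vpool - params$k_catab_trp * s$trp,
    htp = vtph - vaadc,
    cht = vaadc - vmat + vsert - vcat_c - params$k_leak_cht * s$cht,
    vht = vmat - release,
    eht = release - vsert - vu2 - params$k_rem_eht * s$eht +
      params$k_leak_ght * s$ght + params$k_leak_cht * s$cht - bind,
    hiaa = vcat_c + vcat_g - params$k_catab_hiaa * s$hiaa,
    pool = vpool - params$k_catab_pool * s$pool,
    ght = vu2 - vcat_g - params$k_leak_ght * s$ght,
    g_ht_star = params$beta1 *
      (params$k1 * s$b_ht^2 * (params$g_ht_tot - s$g_ht_star) -
         params$k2 * s$t_ht_star * s$g_ht_star),
    t_ht_star = params$beta2 *
      (params$k3 * s$g_ht_star^2 * (params$t_ht_tot - s$t_ht_star) -
         params$k4 * s$t_ht_star),
    b_ht = params$beta3 * bind,
    g_ha_star = params$k7 * s$b_ha^2 * (params$g_ha_tot - s$g_ha_star) -
      params$k8 * s$t_ha_star * s$g_ha_star,
    t_ha_star = params$k9 * s$g_ha_star^2 * (params$t_ha_tot - s$t_ha_star) -
      params$k10 * s$t_ha_star,
    b_ha = params$k11 * eha * (params$b_ha_tot - s$b_ha) -
      params$k12 * s$b_ha)
}

#' Integrate the model over time
#'
#' Stiff integration (the receptor binding constants are of order 1e4/h) of
#' the full system with `deSolve::ode` (lsoda).  Known discontinuities of
#' the forcings (e.g. meal steps) split the integration into segments so
#' the step-size control never straddles a jump.
#'
#' @param state initial state vector ([sero_state()]).
#' @param params a [sero_params()] list.
#' @param anchors equilibrium anchors (or `NULL` with `multipliers`).
#' @param forcings a [sero_forcings()] list.
#' @param fire_fun function of time (h) returning the firing rate (/h);
#'   `NULL` means constant basal firing.
#' @param times output time grid in hours.
#' @param multipliers optional fixed inhibition multipliers, see
#'   [sero_rhs()].
#' @param rtol,atol solver tolerances.
#' @return a data.frame with column `time_h` followed by the 16 state
#'   variables.
#' @examples
#' eq <- compute_equilibrium()
#' tr <- sero_simulate(eq$state, eq$params, eq$anchors,
#'                     times = seq(0, 1, by = 0.1))
#' @export
sero_simulate <- function(state, params = sero_params(), anchors = NULL,
                          forcings = sero_forcings(params), fire_fun = NULL,
                          times = seq(0, 1, by = 1 / 360),
                          multipliers = NULL, rtol = 1e-8, atol = 1e-10) {
  if (any(!is.finite(times)) || length(times) < 2)
    stop("'times' must be a finite grid with at least two points")
  if (any(state < 0)) stop("initial state must be non-negative")
  f_basal <- params$f_basal
  deriv <- function(t, y, parms) {
    fv <- if (is.null(fire_fun)) f_basal else fire_fun(t)
    list(sero_rhs(t, y, params, anchors, forcings, fv, multipliers))
  }
  brk <- attr(forcings, "breaks")
  brk <- brk[brk > min(times) & brk < max(times)]
  segs <- sort(unique(c(min(times), brk, max(times))))
  out <- NULL
  y0 <- state
  for (i in seq_len(length(segs) - 1)) {
    tt <- times[times >= segs[i] & times <= segs[i + 1]]
    tt <- sort(unique(c(segs[i], tt, segs[i + 1])))
    sol <- deSolve::ode(y = y0, times = tt, func = deriv, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("ODE integration failed (istate = ", attr(sol, "istate")[1], ")")
    if (any(!is.finite(sol)))
      stop("ODE integration produced non-finite values")
    y0 <- sol[nrow(sol), STATE_NAMES]
    keep <- sol[, "time"] %in% times
    sol <- sol[keep, , drop = FALSE]
    if (!is.null(out) && nrow(sol) && sol[1, "time"] == out[nrow(out), "time"])
      sol <- sol[-1, , drop = FALSE]
    out <- rbind(out, sol)
  }
  out <- as.data.frame(out)
  names(out)[1] <- "time_h"
  out
}
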