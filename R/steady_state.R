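#' Closed-form receptor equilibria
#'
#' For a fixed ligand concentration the three receptor ODEs (bound receptor
#' B, activated G-protein G*, activated RGS T*) have a closed-form/1-D-root
#' equilibrium: `B_eq = k_on * L * B_tot / (k_on * L + k_off)`, and G* solves
#' `k_a * B^2 * (G_tot - G*) = k_d * T*(G*) * G*` with
#' `T*(G) = k_c * G^2 * T_tot / (k_c * G^2 + k_e)`.  The left side is
#' decreasing and the right side increasing in G*, so the root in
#' `[0, G_tot]` is unique.  Used both as the anchor generator and as an
#' independent oracle for the ODE limit.
#'
#' @param ligand ligand concentration (uM): `eht` for the serotonin 5HT1B
#'   autoreceptor, `eha` for the histamine H3 receptor.
#' @param params a [sero_params()] list.
#' @param which `"serotonin"` or `"histamine"`.
#' @return list with `b_eq`, `g_star_eq`, `t_star_eq`.
#' @examples
#' receptor_equilibrium(0.060, sero_params(), "serotonin")$b_eq  # ~0.97
#' @export
receptor_equilibrium <- function(ligand, params,
                                 which = c("serotonin", "histamine")) {
  which <- match.arg(which)
  if (ligand < 0) stop("ligand concentration must be non-negative")
  k <- if (which == "serotonin") {
    list(ka = params$k1, kd = params$k2, kc = params$k3, ke = params$k4,
         kon = params$k5, koff = params$k6, g_tot = params$g_ht_tot,
         t_tot = params$t_ht_tot, b_tot = params$b_ht_tot)
  } else {
    list(ka = params$k7, kd = params$k8, kc = params$k9, ke = params$k10,
         kon = params$k11, koff = params$k12, g_tot = params$g_ha_tot,
         t_tot = params$t_ha_tot, b_tot = params$b_ha_tot)
  }
  b <- k$kon * ligand * k$b_tot / (k$kon * ligand + k$koff)
  if (b == 0)
    return(list(b_eq = 0, g_star_eq = 0, t_star_eq = 0))
  tstar <- function(g) k$kc * g^2 * k$t_tot / (k$kc * g^2 + k$ke)
  f <- function(g) k$ka * b^2 * (k$g_tot - g) - k$kd * tstar(g) * g
  if (f(k$g_tot) > 0)
    stop("no receptor equilibrium in [0, G_tot]; corrupt parameters?")
  g <- stats::uniroot(f, c(0, k$g_tot), tol = 1e-13)$root
  list(b_eq = b, g_star_eq = g, t_star_eq = tstar(g))
}

# steady-state glial serotonin given the Uptake 2 influx:
# vu2 = Vmax*g/(Km+g) + k_leak*g  has the positive quadratic root below.
ght_equilibrium <- function(vu2, params) {
  if (vu2 <= 0) return(0)
  kl <- params$k_leak_ght
  # kl*g^2 + (Vmax + kl*Km - vu2)*g - Km*vu2 = 0
  a <- kl
  b <- params$vmax_catab + kl * params$km_catab - vu2
  cc <- -params$km_catab * vu2
  (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
}

# residuals of the reduced 5-variable metabolic system at equilibrium;
# x = (bh2, trp, cht, vht, eht), receptor species at closed-form equilibrium
metabolic_residual <- function(x, params, anchors, ptot, m_ha) {
  bh2 <- x[1]; trp <- x[2]; cht <- x[3]; vht <- x[4]; eht <- x[5]
  bh4 <- ptot - bh2
  if (is.null(anchors)) {
    m_rel <- params$c_rel
    m_syn <- 1
  } else {
    g <- receptor_equilibrium(max(eht, 0), params, "serotonin")$g_star_eq
    m_rel <- inhib_release(g, anchors, params)
    m_syn <- inhibsyn(g, anchors, params)
  }
  vtph <- params$vmax_tph * trp * bh4 /
    ((params$km_tph_trp + trp + trp^2 / params$ki_tph) *
       (params$km_tph_bh4 + bh4)) * m_syn
  pool <- params$k_topool * trp / (params$k_frompool + params$k_catab_pool)
  vu2 <- v_u2(max(eht, 0), params)
  ght <- ght_equilibrium(vu2, params)
  vsert <- v_sert(eht, params)
  vmat <- v_mat(cht, vht, params)
  release <- m_rel * m_ha * params$f_basal * vht
  c(v_drr(bh2, bh4, params) - vtph,
    v_trpin(params$btrp, params) - vtph - v_pool(trp, pool, params) -
      params$k_catab_trp * trp,
    vtph + vsert - vmat - v_catab(cht, params) - params$k_leak_cht * cht,
    vmat - release,
    release - vsert - vu2 - params$k_rem_eht * eht +
      params$k_leak_ght * ght + params$k_leak_cht * cht)
}

# damped Newton with finite-difference Jacobian on the reduced system
newton_metabolic <- function(x0, params, anchors, ptot, m_ha,
                             tol = 1e-11, maxit = 60) {
  x <- x0
  f <- metabolic_residual(x, params, anchors, ptot, m_ha)
  for (it in seq_len(maxit)) {
    if (any(!is.finite(f))) return(NULL)
    if (max(abs(f)) < tol) return(x)
    J <- matrix(0, 5, 5)
    for (j in 1:5) {
      h <- max(1e-7 * abs(x[j]), 1e-10)
      xh <- x; xh[j] <- xh[j] + h
      J[, j] <- (metabolic_residual(xh, params, anchors, ptot, m_ha) - f) / h
    }
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      fn <- suppressWarnings(
        metabolic_residual(xn, params, anchors, ptot, m_ha))
      ok <- all(is.finite(fn)) && all(xn[-5] > 0) && xn[5] >= 0 &&
        sum(fn^2) < sum(f^2)
      if (ok || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    if (!ok) return(NULL)
    x <- xn; f <- fn
  }
  if (max(abs(f)) < 1e-8) x else NULL
}

assemble_state <- function(x, params, anchors, ptot, m_ha) {
  bh2 <- x[1]; trp <- x[2]; cht <- x[3]; vht <- x[4]; eht <- x[5]
  bh4 <- ptot - bh2
  if (is.null(anchors)) {
    m_syn <- 1
  } else {
    g <- receptor_equilibrium(eht, params, "serotonin")$g_star_eq
    m_syn <- inhibsyn(g, anchors, params)
  }
  vtph <- params$vmax_tph * trp * bh4 /
    ((params$km_tph_trp + trp + trp^2 / params$ki_tph) *
       (params$km_tph_bh4 + bh4)) * m_syn
  htp <- params$km_aadc * vtph / (params$vmax_aadc - vtph)
  vu2 <- v_u2(eht, params)
  ght <- ght_equilibrium(vu2, params)
  pool <- params$k_topool * trp / (params$k_frompool + params$k_catab_pool)
  hiaa <- (v_catab(cht, params) + v_catab(ght, params)) / params$k_catab_hiaa
  re_ht <- receptor_equilibrium(eht, params, "serotonin")
  re_ha <- receptor_equilibrium(params$eha, params, "histamine")
  sero_state(bh2 = bh2, bh4 = bh4, trp = trp, htp = htp, cht = cht,
             vht = vht, eht = eht, hiaa = hiaa, pool = pool, ght = ght,
             g_ht_star = re_ht$g_star_eq, t_ht_star = re_ht$t_star_eq,
             b_ht = re_ht$b_eq, g_ha_star = re_ha$g_star_eq,
             t_ha_star = re_ha$t_star_eq, b_ha = re_ha$b_eq)
}

#' Self-consistent steady state of the varicosity model
#'
#' The inhibition multipliers reference the equilibrium they help define:
#' at the model's own steady state `inhib = c_rel`, `inhibsyn = 1` and
#' `inhib_ha = 1`.  Two modes:
#'
#' * `anchors = NULL` (self-anchoring, the default): pass 1 freezes the
#'   three multipliers at their anchored equilibrium values (`c_rel`, 1, 1)
#'   and solves the metabolic system (receptor species substituted by their
#'   closed-form equilibria) by damped Newton iteration seeded from the
#'   normal steady state, falling back to long-time stiff integration; pass
#'   2 sets the anchors from the solved receptor state and verifies that
#'   the full right-hand side vanishes under the live inhibition functions.
#' * `anchors` given: the equilibrium is solved with the autoreceptor
#'   feedback *live* relative to the supplied anchors (the operating points
#'   of a reference model).  This is the mode used for virtual-population
#'   individuals and parameter sweeps, where the feedback buffers
#'   deviations of the individual from the reference equilibrium.
#'
#' @param params a [sero_params()] list.
#' @param anchors `NULL` for self-anchoring, or a reference anchor list
#'   (fields `g_ht_star_eq`, `g_ha_star_eq`).
#' @param ptot total pterin pool bh2 + bh4 (uM); conserved by the dynamics,
#'   so it is a datum of the problem, not an unknown.
#' @param seed_state root-finding seed, defaulting to [sero_state()].
#' @param tol acceptable residual norm (uM/h) of the full right-hand side.
#' @return object of class `sero_equilibrium`: list with `state` (named
#'   16-vector), `fluxes` (named rates in uM/h), `anchors`,
#'   `residual_norm`, `multipliers`, and `params`.
#' @examples
#' eq <- compute_equilibrium()
#' eq$state[["eht"]] * 1000  # extracellular serotonin in nM, ~60
#' @export
compute_equilibrium <- function(params = sero_params(), anchors = NULL,
                                ptot = 1, seed_state = sero_state(),
                                tol = 1e-6) {
  m_ha <- if (is.null(anchors)) 1 else {
    inhib_ha(receptor_equilibrium(params$eha, params, "histamine")$g_star_eq,
             anchors, params)
  }
  x0 <- unname(seed_state[c("bh2", "trp", "cht", "vht", "eht")])
  x <- newton_metabolic(x0, params, anchors, ptot, m_ha)
  if (is.null(x)) {
    # fallback: integrate the stiff system for 200 h from the seed, then
    # polish from the trajectory endpoint
    mults <- if (is.null(anchors)) c(rel = params$c_rel, syn = 1, ha = 1)
             else NULL
    tr <- sero_simulate(seed_state, params, anchors,
                        times = c(0, 50, 100, 200), multipliers = mults)
    xe <- unlist(tr[nrow(tr), c("bh2", "trp", "cht", "vht", "eht")])
    x <- newton_metabolic(unname(xe), params, anchors, ptot, m_ha)
    if (is.null(x))
      stop("steady-state solver failed to converge")
    if (max(abs(x - xe) / pmax(abs(xe), 1e-6)) > 0.05 &&
        max(abs(x - xe)) > 1e-4)
      stop("root-finder and integration limit disagree; no reliable ",
           "steady state found")
  }
  state <- assemble_state(x, params, anchors, ptot, m_ha)
  if (is.null(anchors))
    anchors <- list(g_ht_star_eq = state[["g_ht_star"]],
                    g_ha_star_eq = state[["g_ha_star"]],
                    t_ht_star_eq = state[["t_ht_star"]],
                    b_ht_eq = state[["b_ht"]],
                    t_ha_star_eq = state[["t_ha_star"]],
                    b_ha_eq = state[["b_ha"]])
  resid <- sero_rhs(0, state, params, anchors)
  residual_norm <- max(abs(resid))
  if (residual_norm > tol)
    stop("steady-state residual ", format(residual_norm),
         " uM/h exceeds tolerance ", format(tol))
  if (any(state < 0))
    stop("steady state has negative concentrations")
  mults <- c(rel = inhib_release(state[["g_ht_star"]], anchors, params),
             syn = inhibsyn(state[["g_ht_star"]], anchors, params),
             ha = inhib_ha(state[["g_ha_star"]], anchors, params))
  structure(list(state = state,
                 fluxes = equilibrium_fluxes(state, params, mults),
                 anchors = anchors, residual_norm = residual_norm,
                 multipliers = mults, params = params),
            class = "sero_equilibrium")
}

equilibrium_fluxes <- function(state, params, mults) {
  s <- as.list(state)
  vtph <- params$vmax_tph * s$trp * s$bh4 /
    ((params$km_tph_trp + s$trp + s$trp^2 / params$ki_tph) *
       (params$km_tph_bh4 + s$bh4)) * mults[["syn"]]
  c(v_trpin = v_trpin(params$btrp, params),
    v_tph = vtph,
    v_aadc = v_aadc(s$htp, params),
    v_catab = v_catab(s$cht, params),
    v_mat = v_mat(s$cht, s$vht, params),
    release = mults[["rel"]] * mults[["ha"]] * params$f_basal * s$vht,
    v_sert = v_sert(s$eht, params),
    removal = params$k_rem_eht * s$eht,
    v_u2 = v_u2(s$eht, params))
}

#' @export
print.sero_equilibrium <- function(x, ...) {
  cat("<sero_equilibrium>  residual ", format(x$residual_norm, digits = 3),
      " uM/h\n", sep = "")
  cat("  eht = ", round(1000 * x$state[["eht"]], 2), " nM,  vht = ",
      round(x$state[["vht"]], 2), " uM,  V_TPH = ",
      round(x$fluxes[["v_tph"]], 3), " uM/h\n", sep = "")
  invisible(x)
}

#' Tabulate a steady state
#'
#' Renders an equilibrium as a two-part table: concentrations (uM, with
#' `eht` also in nM) and the nine principal fluxes (uM/h).
#'
#' @param eq a `sero_equilibrium` from [compute_equilibrium()].
#' @param path optional CSV path; when given the table is also written out.
#' @return data.frame with columns `quantity`, `value`, `units`.
#' @export
flux_table <- function(eq, path = NULL) {
  st <- eq$state
  conc <- data.frame(quantity = names(st), value = unname(st),
                     units = c(rep("uM", 10), rep("receptor units", 6)))
  conc <- rbind(conc, data.frame(quantity = "eht_nM",
                                 value = 1000 * st[["eht"]], units = "nM"))
  fl <- data.frame(quantity = names(eq$fluxes), value = unname(eq$fluxes),
                   units = "uM/h")
  out <- rbind(conc, fl)
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
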