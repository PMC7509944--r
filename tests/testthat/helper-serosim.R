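# shared fixtures: the baseline equilibrium is used by many tests and is
# deterministic, so compute it once per test run
baseline_eq <- compute_equilibrium()

params_off <- function(...) sero_params(s_rel = 0, s_syn = 0, ...)

# independent oracle for the receptor equilibria: integrate the three
# receptor ODEs alone (ligand fixed) to their long-time limit
receptor_ode_limit <- function(ligand, params, which) {
  k <- if (which == "serotonin")
    with(params, list(ka = k1, kd = k2, kc = k3, ke = k4, kon = k5,
                      koff = k6, g_tot = g_ht_tot, t_tot = t_ht_tot,
                      b_tot = b_ht_tot))
  else
    with(params, list(ka = k7, kd = k8, kc = k9, ke = k10, kon = k11,
                      koff = k12, g_tot = g_ha_tot, t_tot = t_ha_tot,
                      b_tot = b_ha_tot))
  rhs <- function(t, y, parms) {
    list(c(k$kon * ligand * (k$b_tot - y[1]) - k$koff * y[1],
           k$ka * y[1]^2 * (k$g_tot - y[2]) - k$kd * y[3] * y[2],
           k$kc * y[2]^2 * (k$t_tot - y[3]) - k$ke * y[3]))
  }
  out <- deSolve::ode(c(b = 0.5, g = 0.5, t = 0.5), c(0, 1000), rhs, NULL,
                      method = "lsoda", rtol = 1e-11, atol = 1e-12)
  as.list(out[nrow(out), c("b", "g", "t")])
}
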