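#' Rate laws of the serotonin varicosity model
#'
#' Each velocity is a plain function of the relevant concentrations and the
#' parameter set; all are vectorized over their concentration arguments.
#' Units are uM and uM/h throughout (the Uptake 2 gate works on the nM
#' scale internally).
#'
#' @name rate-laws
#' @param trp,bh4,bh2,htp,cht,vht,eht,ght,x,pool,btrp concentrations (uM).
#' @param params a [sero_params()] list.
#' @param g_ht_star,g_ha_star activated G-protein levels (receptor units).
#' @param anchors equilibrium anchors, see [receptor_equilibrium()] and
#'   [compute_equilibrium()]; a list with `g_ht_star_eq` and `g_ha_star_eq`.
NULL

#' @describeIn rate-laws Tryptophan hydroxylase with substrate inhibition in
#'   trp and synthesis inhibition by the 5HT1B autoreceptor G-protein.
#' @export
v_tph <- function(trp, bh4, g_ht_star, anchors, params) {
  base <- params$vmax_tph * trp * bh4 /
    ((params$km_tph_trp + trp + trp^2 / params$ki_tph) *
       (params$km_tph_bh4 + bh4))
  base * inhibsyn(g_ht_star, anchors, params)
}

#' @describeIn rate-laws Release-inhibition multiplier of the 5HT1B
#'   autoreceptor: `c_rel - s_rel * (G* - G*_eq)`, clamped below at zero
#'   (a negative release rate is unphysical).  Equals `c_rel` at the anchor.
#' @export
inhib_release <- function(g_ht_star, anchors, params) {
  pmax(0, params$c_rel - params$s_rel * (g_ht_star - anchors$g_ht_star_eq))
}

#' @describeIn rate-laws Synthesis-inhibition multiplier of the 5HT1B
#'   autoreceptor: `1 - s_syn * (G* - G*_eq)`, clamped below at zero.
#' @export
inhibsyn <- function(g_ht_star, anchors, params) {
  pmax(0, 1 - params$s_syn * (g_ht_star - anchors$g_ht_star_eq))
}

#' @describeIn rate-laws Release-inhibition multiplier of the histamine H3
#'   receptor: `1 - s_ha * (G*_ha - G*_ha_eq)`, clamped below at zero.
#' @export
inhib_ha <- function(g_ha_star, anchors, params) {
  pmax(0, 1 - params$s_ha * (g_ha_star - anchors$g_ha_star_eq))
}

#' @describeIn rate-laws Uptake 2 gate: 0 at or below `gate_lo` nM, rising
#'   linearly to 1 at `gate_hi` nM.  `eht_nm` is in nM.
#' @param eht_nm extracellular serotonin in nM.
#' @export
u2_gate <- function(eht_nm, params) {
  pmin(1, pmax(0, (eht_nm - params$gate_lo) / (params$gate_hi - params$gate_lo)))
}

#' @describeIn rate-laws Glial Uptake 2: gated Michaelis-Menten uptake of
#'   extracellular serotonin, identically zero at or below the gate.
#' @export
v_u2 <- function(eht, params) {
  u2_gate(1000 * eht, params) * params$vmax_u2 * eht / (params$km_u2 + eht)
}

#' @describeIn rate-laws SERT reuptake of extracellular serotonin.
#' @export
v_sert <- function(eht, params) {
  params$vmax_sert * eht / (params$km_sert + eht)
}

#' @describeIn rate-laws Aromatic amino acid decarboxylase.
#' @export
v_aadc <- function(htp, params) {
  params$vmax_aadc * htp / (params$km_aadc + htp)
}

#' @describeIn rate-laws Monoamine-oxidase catabolism of serotonin; applied
#'   to cytosolic and to glial serotonin.
#' @export
v_catab <- function(x, params) {
  params$vmax_catab * x / (params$km_catab + x)
}

#' @describeIn rate-laws Neutral amino acid transporter importing blood
#'   tryptophan.
#' @export
v_trpin <- function(btrp, params) {
  params$vmax_trpin * btrp / (params$km_trpin + btrp)
}

#' @describeIn rate-laws Vesicular monoamine transporter: Michaelis-Menten
#'   packaging minus a linear back-leak from the vesicles (may be negative).
#' @export
v_mat <- function(cht, vht, params) {
  params$vmax_mat * cht / (params$km_mat + cht) - params$k_back_vht * vht
}

#' @describeIn rate-laws Dihydropteridine reductase, reversible two-substrate
#'   Michaelis-Menten with NADPH/NADP held at fixed concentrations.
#' @export
v_drr <- function(bh2, bh4, params) {
  fwd <- params$vmax_drr_f * bh2 * params$nadph /
    ((params$km_drr_bh2 + bh2) * (params$km_drr_nadph + params$nadph))
  bck <- params$vmax_drr_b * bh4 * params$nadp /
    ((params$km_drr_bh4 + bh4) * (params$km_drr_nadp + params$nadp))
  fwd - bck
}

#' @describeIn rate-laws Linear exchange between cytosolic tryptophan and
#'   the cellular tryptophan pool (signed).
#' @export
v_pool <- function(trp, pool, params) {
  params$k_topool * trp - params$k_frompool * pool
}
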