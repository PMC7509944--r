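#' Baseline kinetic parameters for the serotonin varicosity model
#'
#' Returns the full parameter set of the model: Michaelis-Menten constants
#' for every enzyme and transporter, linear leak/catabolism rate constants,
#' the 5HT1B autoreceptor and histamine H3 receptor rate constants, the
#' inhibition-function slopes, the Uptake 2 gate thresholds, and the fixed
#' concentrations held constant during simulation (NADP, NADPH, blood
#' tryptophan, extracellular histamine).
#'
#' Units: concentrations in uM, Vmax in uM/h, first-order constants in /h,
#' except the serotonin-binding-protein dissociation rate `b_sbp` which is
#' in /s (the stimulation clock runs in seconds).  The Uptake 2 gate
#' thresholds `gate_lo`/`gate_hi` are in nM because the gate is defined on
#' the nM scale of extracellular serotonin.  Receptor species are in
#' arbitrary receptor units.
#'
#' @param ... named overrides of individual parameters, e.g.
#'   `sero_params(vmax_sert = 433)`.  Unknown names are an error.
#' @return A named list of class `sero_params`.
#' @examples
#' p <- sero_params()
#' p$vmax_sert
#' p2 <- sero_params(vmax_sert = 433)
#' @export
sero_params <- function(...) {
  p <- list(
    # neutral amino acid transporter (tryptophan import from blood)
    vmax_trpin = 700, km_trpin = 330,
    # tryptophan hydroxylase (substrate inhibition in trp)
    vmax_tph = 278, km_tph_trp = 40, km_tph_bh4 = 20, ki_tph = 1000,
    # aromatic amino acid decarboxylase
    vmax_aadc = 400, km_aadc = 160,
    # vesicular monoamine transporter; linear back-leak from vesicles
    vmax_mat = 1230, km_mat = 0.2, k_back_vht = 1,
    # serotonin reuptake transporter
    vmax_sert = 250, km_sert = 0.060,
    # monoamine-oxidase catabolism of serotonin (cytosol and glia)
    vmax_catab = 4000, km_catab = 95,
    # glial Uptake 2, gated on the nM scale of eht
    vmax_u2 = 14, km_u2 = 0.17, gate_lo = 60.5, gate_hi = 80.5,
    # dihydropteridine reductase (reversible, NADPH/NADP fixed)
    vmax_drr_f = 5000, km_drr_bh2 = 100, km_drr_nadph = 75,
    vmax_drr_b = 3, km_drr_bh4 = 10, km_drr_nadp = 75,
    nadph = 330, nadp = 26,
    # linear exchange between trp and the cellular tryptophan pool
    k_topool = 9, k_frompool = 0.6,
    # first-order diffusion / catabolism
    k_catab_trp = 2, k_leak_cht = 1, k_leak_ght = 1,
    k_catab_hiaa = 1.82, k_catab_pool = 1, k_rem_eht = 40,
    # 5HT1B autoreceptor: B (bound receptor), G* (active G-protein),
    # T* (active RGS); beta's rescale the speed of the three ODEs
    k1 = 20, k2 = 200, k3 = 30, k4 = 200, k5 = 36000, k6 = 20000,
    beta1 = 1, beta2 = 1, beta3 = 1,
    g_ht_tot = 10, t_ht_tot = 10, b_ht_tot = 10,
    # histamine H3 receptor on the serotonin varicosity
    k7 = 4.32, k8 = 1.296, k9 = 14.4, k10 = 25.92, k11 = 432, k12 = 1440,
    g_ha_tot = 1, t_ha_tot = 60, b_ha_tot = 10,
    # inhibition multipliers: release, synthesis, histamine; offsets/slopes
    c_rel = 1.89, s_rel = 12.5, s_syn = 2.5, s_ha = 5,
    # basal firing rate (/h) and SBP dissociation rate (/s)
    f_basal = 1, b_sbp = 1,
    # constant forcings at baseline
    btrp = 96, eha = 1.39
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("parameter overrides must be named")
    bad <- setdiff(names(dots), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  class(p) <- "sero_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks positivity of rate constants and capacities, the ordering of the
#' Uptake 2 gate thresholds, and non-negativity of receptor totals.
#'
#' @param p a `sero_params` list.
#' @return `p`, invisibly; signals an error on violation.
#' @export
validate_params <- function(p) {
  pos <- c("vmax_trpin", "km_trpin", "vmax_tph", "km_tph_trp", "km_tph_bh4",
           "ki_tph", "vmax_aadc", "km_aadc", "vmax_mat", "km_mat",
           "vmax_sert", "km_sert", "vmax_catab", "km_catab", "vmax_u2",
           "km_u2", "vmax_drr_f", "km_drr_bh2", "km_drr_nadph", "vmax_drr_b",
           "km_drr_bh4", "km_drr_nadp", "nadph", "nadp",
           "k1", "k2", "k3", "k4", "k5", "k6",
           "k7", "k8", "k9", "k10", "k11", "k12",
           "beta1", "beta2", "beta3", "b_sbp")
  for (nm in pos)
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("parameter '", nm, "' must be strictly positive")
  nonneg <- c("k_topool", "k_frompool", "k_catab_trp", "k_leak_cht",
              "k_leak_ght", "k_catab_hiaa", "k_catab_pool", "k_rem_eht",
              "k_back_vht", "g_ht_tot", "t_ht_tot", "b_ht_tot",
              "g_ha_tot", "t_ha_tot", "b_ha_tot",
              "s_rel", "s_syn", "s_ha", "c_rel", "f_basal", "btrp", "eha")
  for (nm in nonneg)
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop("parameter '", nm, "' must be non-negative")
  if (p$gate_lo >= p$gate_hi)
    stop("gate_lo must be strictly below gate_hi")
  invisible(p)
}

#' Apply named multipliers to a parameter set
#'
#' Multiplies selected parameters by scale factors, the mechanism used by
#' the population sampler to model expression-level variation.  The special
#' key `"beta"` scales `beta1`, `beta2` and `beta3` jointly (the joint speed
#' of the autoreceptor machinery); keys `"r"` and `"b_sbp"` belong to the
#' stimulation protocol and are ignored here (the caller applies them to the
#' protocol).
#'
#' @param params a `sero_params` list.
#' @param multipliers named numeric vector of scale factors.
#' @return the rescaled `sero_params` list.
#' @export
apply_multipliers <- function(params, multipliers) {
  for (key in names(multipliers)) {
    m <- multipliers[[key]]
    if (key == "beta") {
      params$beta1 <- params$beta1 * m
      params$beta2 <- params$beta2 * m
      params$beta3 <- params$beta3 * m
    } else if (key %in% c("r", "b_sbp_protocol")) {
      # protocol-level keys, applied by the caller
    } else if (key %in% names(params)) {
      params[[key]] <- params[[key]] * m
    } else {
      stop("multiplier key '", key, "' is not a model parameter")
    }
  }
  validate_params(params)
  params
}

#' @export
print.sero_params <- function(x, ...) {
  cat("<sero_params> ", length(unclass(x)), " parameters\n", sep = "")
  cat("  key values: vmax_sert=", x$vmax_sert, ", vmax_u2=", x$vmax_u2,
      ", gate=[", x$gate_lo, ",", x$gate_hi, "] nM, s_rel=", x$s_rel,
      ", s_syn=", x$s_syn, ", btrp=", x$btrp, " uM\n", sep = "")
  invisible(x)
}

#' Read or write a parameter set as JSON
#'
#' Parameter files are flat JSON objects whose keys match the names in
#' [sero_params()]; missing keys take their baseline values.
#'
#' @param path file path.
#' @param params a `sero_params` list (for writing).
#' @return `read_params_json` returns a `sero_params` list.
#' @export
read_params_json <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sero_params, as.list(vals))
}

#' @rdname read_params_json
#' @export
write_params_json <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
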