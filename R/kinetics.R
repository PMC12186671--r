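#' Context-resolved kinetic parameter set
#'
#' All rate and strength constants of the FdeR biosensor reporter model,
#' resolved to scalars for one experimental context. Scopes in the full
#' library are: global (`vmax_PROM`, `k_deg`, `k_FDER`, `K_NFDER`,
#' `k_deg_FDER`, `vmax_NAR`, `k_deg_GFP`, `R_basal`), promoter-dependent
#' (`K_Pk`), medium-dependent (`K_mRNAp`, `K_mRNAdeg`, `K_P`, `K_lysis`) and
#' fully context-dependent (`RBS_strength`). The Hill half-saturation is
#' fixed at 0.5 (no FdeR concentration data exist to estimate it) and the
#' Hill exponent at 2.
#'
#' @param vmax_PROM Maximum promoter activity (global).
#' @param K_Pk Transcriptional strength of the promoter (reference promoter
#'   P1 has `K_Pk = 1`).
#' @param K_mRNAp mRNA production rate constant for the medium.
#' @param k_deg Base mRNA degradation constant (global).
#' @param K_mRNAdeg Medium multiplier on mRNA degradation (reference medium
#'   M0 has multiplier 1).
#' @param K_P Protein (GFP) production rate constant for the medium.
#' @param K_lysis Proteolysis rate constant for the medium.
#' @param RBS_strength Translational strength of the RBS in this context.
#' @param k_FDER FdeR translation rate (global).
#' @param K_NFDER Michaelis constant for FdeR translation (global).
#' @param k_deg_FDER FdeR degradation constant (global).
#' @param vmax_NAR Maximum GFP production rate at the saturating 400 uM
#'   naringenin reference induction (global).
#' @param k_deg_GFP GFP degradation constant (global).
#' @param R_basal Baseline ribosome availability in `[0, 1]`.
#' @param hill_half,hill_exp Hill half-saturation and exponent; fixed, not
#'   estimated.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(vmax_PROM, K_Pk = 1, K_mRNAp = 1, k_deg,
                           K_mRNAdeg = 1, K_P = 1, K_lysis = 1,
                           RBS_strength = 1, k_FDER, K_NFDER, k_deg_FDER,
                           vmax_NAR, k_deg_GFP, R_basal,
                           hill_half = 0.5, hill_exp = 2) {
  kp <- list(vmax_PROM = vmax_PROM, K_Pk = K_Pk, K_mRNAp = K_mRNAp,
             k_deg = k_deg, K_mRNAdeg = K_mRNAdeg, K_P = K_P,
             K_lysis = K_lysis, RBS_strength = RBS_strength,
             k_FDER = k_FDER, K_NFDER = K_NFDER, k_deg_FDER = k_deg_FDER,
             vmax_NAR = vmax_NAR, k_deg_GFP = k_deg_GFP, R_basal = R_basal,
             hill_half = hill_half, hill_exp = hill_exp)
  vals <- unlist(kp)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("kinetic parameters must be finite and non-negative")
  if (R_basal > 1) stop("R_basal must lie in [0, 1]")
  structure(kp, class = "kinetic_params")
}

#' Update a kinetic parameter set by (possibly scoped) name
#'
#' Accepts plain parameter names (`"vmax_NAR"`) or the scoped names used by
#' calibration problems (`"RBS_strength.M0_S0_P1_R1"`, `"K_P.M2"`); the
#' scope suffix is ignored because the set is already context-resolved.
#'
#' @param kp A [kinetic_params()] object.
#' @param ... Named replacement values, or a single named vector/list.
#' @return A revalidated [kinetic_params()] object.
#' @export
update_k <- function(kp, ...) {
  values <- c(...)
  if (is.list(values)) values <- unlist(values)
  for (nm in names(values)) {
    base <- strsplit(nm, ".", fixed = TRUE)[[1]][1]
    if (!base %in% names(kp)) stop("unknown kinetic parameter '", base, "'")
    kp[[base]] <- unname(values[[nm]])
  }
  do.call(kinetic_params, unclass(kp))
}
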