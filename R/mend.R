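#' Calibrated parameters of the microbial-enzyme decomposition model
#'
#' The eleven process parameters adjusted during calibration plus the
#' temperature-CUE pair and its reference temperature. All pools are in
#' mg C per g soil; rates are per day.
#'
#' @param f_INP Fraction of external soil C input routed to the particulate
#'   pools (remainder to dissolved organic C), in `[0, 1]`.
#' @param r_E Enzyme turnover rate (1/d).
#' @param p_EP Enzyme production rate coefficient (fraction of active
#'   biomass per day, split equally between the two exo-enzyme classes).
#' @param fp_EM Production ratio of the mineral-associated-pool enzyme
#'   relative to `p_EP`.
#' @param f_D Fraction of decomposed particulate C routed to dissolved
#'   organic C (remainder to the mineral-associated pool).
#' @param g_D Fraction of dead biomass and turned-over enzyme C routed to
#'   dissolved organic C.
#' @param V_g Maximum specific uptake rate of dissolved organic C by active
#'   biomass (1/d).
#' @param alpha Maintenance respiration coefficient (1/d) on active
#'   biomass.
#' @param K_D Half-saturation constant for D uptake (mg C/g).
#' @param beta Dormancy transition rate coefficient (1/d).
#' @param psi_A2D Moisture-scalar threshold below which active biomass
#'   drifts dormant, in `[0, 1]`.
#' @param Yg_ref Intrinsic carbon use efficiency at `T_ref`, in (0, 1).
#' @param k_Yg Slope of intrinsic CUE against temperature (1/degC);
#'   negative for the usual efficiency loss with warming.
#' @param T_ref Reference temperature (degC).
#' @return A named numeric vector of class `mend_params`.
#' @export
mend_params <- function(f_INP = 0.70, r_E = 0.010, p_EP = 0.005,
                        fp_EM = 0.20, f_D = 0.50, g_D = 0.50,
                        V_g = 0.20, alpha = 0.008, K_D = 0.25,
                        beta = 0.02, psi_A2D = 0.35,
                        Yg_ref = 0.43, k_Yg = -0.004, T_ref = 15) {
  p <- c(f_INP = f_INP, r_E = r_E, p_EP = p_EP, fp_EM = fp_EM, f_D = f_D,
         g_D = g_D, V_g = V_g, alpha = alpha, K_D = K_D, beta = beta,
         psi_A2D = psi_A2D, Yg_ref = Yg_ref, k_Yg = k_Yg, T_ref = T_ref)
  validate_mend_params(p)
  structure(p, class = "mend_params")
}

validate_mend_params <- function(p) {
  fr <- c("f_INP", "fp_EM", "f_D", "g_D", "psi_A2D")
  if (any(p[fr] < 0 | p[fr] > 1))
    stop("fractions must lie in [0, 1]: ",
         paste(fr[p[fr] < 0 | p[fr] > 1], collapse = ", "), call. = FALSE)
  rt <- c("r_E", "p_EP", "V_g", "alpha", "K_D", "beta")
  if (any(p[rt] < 0)) stop("rates must be >= 0", call. = FALSE)
  if (p["Yg_ref"] <= 0 || p["Yg_ref"] >= 1)
    stop("Yg_ref must lie in (0, 1)", call. = FALSE)
  invisible(p)
}

#' Frozen kinetic constants of the decomposition model
#'
#' Constants held fixed during calibration: maximum enzyme-specific
#' decomposition rates and half-saturation constants, sorption exchange
#' rates, Arrhenius activation energies (J/mol) for decomposition, uptake
#' and maintenance, mortality rates, the dormant maintenance fraction, the
#' moisture scalar shape, and the GPP-to-soil C input coefficient
#' (mg C g-1 per g C m-2 d-1, folding in belowground allocation and soil
#' mass).
#'
#' @param ... Named overrides of individual constants.
#' @return Named numeric vector of class `mend_constants`.
#' @export
mend_constants <- function(...) {
  cs <- c(V_P = 2.0, V_M = 0.6, K_P = 50, K_M = 250,
          k_ads = 0.02, k_des = 0.002, Q_max = 1.7,
          Ea_dec = 47000, Ea_up = 47000, Ea_m = 20000,
          k_mortA = 0.008, k_mortD = 0.0008, dorm_maint_frac = 0.02,
          W_ref = 25, w_exp = 0.75, c_gpp = 0.003)
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cs))
    if (length(bad)) stop("unknown constant: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    cs[names(over)] <- over
  }
  structure(cs, class = "mend_constants")
}

#' Default initial carbon pools (mg C/g soil)
#'
#' @return Named numeric vector over the ten model pools.
#' @export
mend_initial_pools <- function() {
  c(P_O = 4, P_H = 6, M = 20, Q = 0.5, D = 0.15,
    B_A = 0.4, B_D = 0.4, EP_O = 0.050, EP_H = 0.050, EM = 0.020)
}

#' Intrinsic carbon use efficiency at a temperature
#'
#' `Yg(T) = Yg_ref + k_Yg (T - T_ref)`, clamped to `[0.01, 0.99]`.
#' Clamping is flagged through the `clamped` attribute.
#'
#' @param temperature Temperature(s), degC.
#' @param params A [mend_params()] vector.
#' @return CUE value(s) in (0, 1), attribute `clamped` TRUE if any input
#'   hit a bound.
#' @examples
#' cue_at(25, mend_params(Yg_ref = 0.45, k_Yg = -0.01, T_ref = 15)) # 0.35
#' @export
cue_at <- function(temperature, params) {
  raw <- params[["Yg_ref"]] + params[["k_Yg"]] *
    (temperature - params[["T_ref"]])
  out <- pmin(0.99, pmax(0.01, raw))
  attr(out, "clamped") <- any(raw < 0.01 | raw > 0.99)
  out
}

# Arrhenius temperature scalar relative to T_ref (== 1 at T_ref)
arrhenius_scalar <- function(temperature, ea, t_ref) {
  exp((ea / 8.314) * (1 / (t_ref + 273.15) - 1 / (temperature + 273.15)))
}

# saturating moisture scalar on volumetric moisture (%)
moisture_scalar <- function(moisture, consts = mend_constants()) {
  ifelse(moisture <= 0, 0,
         pmin(1, moisture / consts[["W_ref"]])^consts[["w_exp"]])
}

#' Instantaneous fluxes of the decomposition model
#'
#' Evaluates every component flux at a given state and environment; the
#' reference implementation the compiled integrator is tested against.
#'
#' @param state Named pool vector (see [mend_initial_pools()]).
#' @param params A [mend_params()] vector.
#' @param temperature Soil temperature, degC.
#' @param moisture Volumetric soil moisture, % (0-100).
#' @param gpp GPP (g C m-2 d-1) supplying external input.
#' @param consts A [mend_constants()] vector.
#' @return List with `fluxes` (named), `derivatives` (named, per pool),
#'   `rh` (respiration rate) and `input`.
#' @export
mend_fluxes <- function(state, params, temperature, moisture, gpp = 0,
                        consts = mend_constants()) {
  if (any(state < 0)) stop("negative pool", call. = FALSE)
  if (moisture < 0 || moisture > 100)
    stop("moisture must lie in [0, 100]", call. = FALSE)
  p <- params; cs <- consts
  fT_dec <- arrhenius_scalar(temperature, cs[["Ea_dec"]], p[["T_ref"]])
  fT_up <- arrhenius_scalar(temperature, cs[["Ea_up"]], p[["T_ref"]])
  fT_m <- arrhenius_scalar(temperature, cs[["Ea_m"]], p[["T_ref"]])
  fW <- moisture_scalar(moisture, cs)
  Yg <- as.numeric(cue_at(temperature, p))

  dec_PO <- cs[["V_P"]] * fT_dec * fW * state[["EP_O"]] *
    state[["P_O"]] / (cs[["K_P"]] + state[["P_O"]])
  dec_PH <- cs[["V_P"]] * fT_dec * fW * state[["EP_H"]] *
    state[["P_H"]] / (cs[["K_P"]] + state[["P_H"]])
  dec_M <- cs[["V_M"]] * fT_dec * fW * state[["EM"]] *
    state[["M"]] / (cs[["K_M"]] + state[["M"]])
  ads <- cs[["k_ads"]] * state[["D"]] * (1 - state[["Q"]] / cs[["Q_max"]])
  des <- cs[["k_des"]] * state[["Q"]]
  uptake <- p[["V_g"]] * fT_up * fW * state[["B_A"]] *
    state[["D"]] / (p[["K_D"]] + state[["D"]])
  growth <- Yg * uptake
  growth_resp <- (1 - Yg) * uptake
  maint <- p[["alpha"]] * fT_m * state[["B_A"]]
  maint_dorm <- cs[["dorm_maint_frac"]] * p[["alpha"]] * fT_m * state[["B_D"]]
  prod_EPO <- 0.5 * p[["p_EP"]] * state[["B_A"]]
  prod_EPH <- 0.5 * p[["p_EP"]] * state[["B_A"]]
  prod_EM <- p[["fp_EM"]] * p[["p_EP"]] * state[["B_A"]]
  turn_EPO <- p[["r_E"]] * state[["EP_O"]]
  turn_EPH <- p[["r_E"]] * state[["EP_H"]]
  turn_EM <- p[["r_E"]] * state[["EM"]]
  enz_turn <- turn_EPO + turn_EPH + turn_EM
  mort_A <- cs[["k_mortA"]] * state[["B_A"]]
  mort_D <- cs[["k_mortD"]] * state[["B_D"]]
  mort <- mort_A + mort_D
  a2d <- if (fW < p[["psi_A2D"]])
    p[["beta"]] * (p[["psi_A2D"]] - fW) * state[["B_A"]] else 0
  d2a <- if (fW >= p[["psi_A2D"]])
    p[["beta"]] * (fW - p[["psi_A2D"]]) * state[["B_D"]] else 0
  input <- cs[["c_gpp"]] * max(0, gpp)

  d <- c(
    P_O = 0.5 * p[["f_INP"]] * input - dec_PO,
    P_H = 0.5 * p[["f_INP"]] * input - dec_PH + (1 - p[["g_D"]]) * mort,
    M = (1 - p[["f_D"]]) * (dec_PO + dec_PH) - dec_M +
      (1 - p[["g_D"]]) * enz_turn,
    Q = ads - des,
    D = (1 - p[["f_INP"]]) * input + p[["f_D"]] * (dec_PO + dec_PH) +
      dec_M + p[["g_D"]] * (mort + enz_turn) - ads + des - uptake,
    B_A = growth - maint - (prod_EPO + prod_EPH + prod_EM) - mort_A -
      a2d + d2a,
    B_D = a2d - d2a - maint_dorm - mort_D,
    EP_O = prod_EPO - turn_EPO,
    EP_H = prod_EPH - turn_EPH,
    EM = prod_EM - turn_EM)

  list(
    fluxes = c(dec_PO = dec_PO, dec_PH = dec_PH, dec_M = dec_M, ads = ads,
               des = des, uptake = uptake, growth = growth,
               growth_resp = growth_resp, maint = maint,
               maint_dorm = maint_dorm, enz_production = prod_EPO +
                 prod_EPH + prod_EM, enz_turnover = enz_turn,
               mortality = mort, a2d = a2d, d2a = d2a),
    derivatives = d,
    rh = growth_resp + maint + maint_dorm,
    input = input)
}

# mg C g-1 soil d-1  ->  umol CO2 m-2 s-1 (0-15 cm, bulk density 1.3)
rh_unit_conversion <- function(soil_mass_g_m2 = 195000) {
  soil_mass_g_m2 * 1000 / (12.011 * 86400)
}

#' Forward-simulate the microbial-enzyme decomposition model
#'
#' Daily explicit time stepping (with adaptive sub-stepping whenever a pool
#' would be driven negative) over a forcing series, producing daily
#' heterotrophic respiration, pool trajectories, enzyme concentrations and
#' intrinsic CUE. Mass balance (change in total C = inputs - cumulative
#' Rh) holds to floating-point accuracy by construction and is recorded.
#'
#' @param params A [mend_params()] vector.
#' @param forcing Tibble with daily `temperature`, `moisture`, `gpp` (one
#'   treatment; see [gen_forcing()]), optionally `date` and `month`.
#' @param initial Named initial pool vector.
#' @param substeps Base sub-steps per day (default 4).
#' @param consts A [mend_constants()] vector.
#' @return A `mend_sim` object: tibble with daily `rh` (mg C/g/d),
#'   `rh_umol` (umol CO2 m-2 s-1), the ten pools, `enzco`/`enzch` aliases,
#'   `cue` and `input`; attributes carry the parameters and the mass
#'   balance summary.
#' @export
mend_simulate <- function(params, forcing, initial = mend_initial_pools(),
                          substeps = 4, consts = mend_constants()) {
  validate_mend_params(params)
  stopifnot(all(c("temperature", "moisture", "gpp") %in% names(forcing)))
  if (anyNA(forcing[c("temperature", "moisture", "gpp")]))
    stop("forcing series contains missing values", call. = FALSE)
  res <- mend_simulate_cpp(unclass(params)[1:14], unclass(consts)[1:16],
                           unname(initial[c("P_O", "P_H", "M", "Q", "D",
                                            "B_A", "B_D", "EP_O", "EP_H",
                                            "EM")]),
                           forcing$temperature, forcing$moisture,
                           forcing$gpp, as.integer(substeps))
  pools <- tibble::as_tibble(res$pools, .name_repair = "minimal")
  names(pools) <- c("P_O", "P_H", "M", "Q", "D", "B_A", "B_D",
                    "EP_O", "EP_H", "EM")
  out <- dplyr::bind_cols(
    tibble::tibble(
      day = seq_len(nrow(pools)),
      date = if ("date" %in% names(forcing)) forcing$date else NA,
      month = if ("month" %in% names(forcing)) forcing$month else NA,
      temperature = forcing$temperature,
      rh = res$rh,
      rh_umol = res$rh * rh_unit_conversion(),
      cue = res$cue,
      input = res$input),
    pools) |>
    dplyr::mutate(enzco = .data$EP_O, enzch = .data$EP_H)
  total0 <- sum(initial)
  total1 <- sum(res$pools[nrow(pools), ])
  attr(out, "params") <- params
  attr(out, "mass_balance") <- c(
    delta_total = total1 - total0,
    inputs = sum(res$input), cumulative_rh = sum(res$rh),
    residual = (total1 - total0) - (sum(res$input) - sum(res$rh)),
    throughput = sum(res$input) + sum(res$rh))
  class(out) <- c("mend_sim", class(out))
  out
}

#' Monthly aggregation of a daily simulation
#'
#' Calendar-month means of daily Rh (in observation units) and enzyme
#' pools, the scale at which observations constrain the model.
#'
#' @param sim A `mend_sim` tibble with a `month` column.
#' @return Tibble `month`, `rh_umol`, `enzco`, `enzch`.
#' @export
monthly_mend <- function(sim) {
  sim |>
    dplyr::group_by(month = .data$month) |>
    dplyr::summarise(rh_umol = mean(.data$rh_umol),
                     enzco = mean(.data$enzco),
                     enzch = mean(.data$enzch), .groups = "drop")
}

#' Generate monthly flux observations from a known parameter set
#'
#' Forward-simulates the decomposition model on a forcing series and emits
#' monthly heterotrophic respiration with additive Gaussian noise
#' (truncated at zero), together with noisy gene-abundance proxies for the
#' oxidative and hydrolytic enzyme pools (arbitrary scale: only their
#' monthly log-scale covariation is informative) and companion soil and
#' autotrophic respiration columns satisfying `r_a = r_s - r_h`.
#'
#' @param params True [mend_params()].
#' @param forcing A single-treatment daily forcing tibble.
#' @param noise_sd Gaussian noise SD on monthly Rh, in umol CO2 m-2 s-1
#'   (>= 0). Enzyme proxies receive multiplicative lognormal noise of the
#'   same relative magnitude.
#' @param seed Seed for the noise draws.
#' @param gene_scale Arbitrary multiplier mapping enzyme pools to
#'   gene-abundance signal units.
#' @inheritParams mend_simulate
#' @return Tibble `month`, `treatment` (copied from forcing if present),
#'   `r_h`, `r_s`, `r_a`, `enzco_obs`, `enzch_obs`, plus the noiseless
#'   truth columns `r_h_true`, `enzco_true`, `enzch_true`.
#' @export
gen_rh_observations <- function(params, forcing, noise_sd, seed,
                                gene_scale = 100,
                                initial = mend_initial_pools(),
                                substeps = 4, consts = mend_constants()) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  sim <- mend_simulate(params, forcing, initial = initial,
                       substeps = substeps, consts = consts)
  m <- monthly_mend(sim)
  rel <- if (mean(m$rh_umol) > 0) noise_sd / mean(m$rh_umol) else 0
  gpp_m <- tapply(forcing$gpp, forcing$month, mean)
  with_seed(derive_seed(seed, "rh-observations"), {
    r_h <- pmax(0, m$rh_umol + rnorm(nrow(m), 0, noise_sd))
    enzco_obs <- gene_scale * m$enzco * exp(rnorm(nrow(m), 0, rel))
    enzch_obs <- gene_scale * m$enzch * exp(rnorm(nrow(m), 0, rel))
    r_a <- pmax(0, 0.35 * 0.9637 * as.numeric(gpp_m[as.character(m$month)]) +
                  rnorm(nrow(m), 0, noise_sd))
  })
  tibble::tibble(
    month = m$month,
    treatment = if ("treatment" %in% names(forcing))
      forcing$treatment[match(m$month, forcing$month)] else NA_character_,
    r_h = r_h, r_a = r_a, r_s = r_h + r_a,
    enzco_obs = enzco_obs, enzch_obs = enzch_obs,
    r_h_true = m$rh_umol, enzco_true = m$enzco, enzch_true = m$enzch)
}
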