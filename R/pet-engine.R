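# Physiologically Equivalent Temperature (PET) from afternoon meteorology.
#
# The chain is: wind reduced to body height -> global radiation and mean
# radiant temperature estimated from cloud cover -> steady-state two-node
# (core/skin) human energy balance -> PET as the reference-environment air
# temperature reproducing the same body temperatures.
#
# The reference environment is the conventional one: Tmrt = Ta, wind
# 0.1 m/s, vapour pressure 12 hPa, standard person.

# ---------------------------------------------------------------------------
# Model constants. All tunables of the body model live here.
.memi_const <- list(
  sigma      = 5.67e-8, # Stefan-Boltzmann, W/m2K4
  eps_body   = 0.97,    # longwave emissivity of the clothed body
  f_eff      = 0.725,   # effective radiation area factor, standing
  f_proj     = 0.3,     # projected area factor for shortwave on the body
  alpha_sw   = 0.7,     # shortwave absorption coefficient of the body
  lewis_hpa  = 1.65,    # Lewis ratio, K/hPa
  i_m        = 0.38,    # moisture permeation index of clothing
  tsk_set    = 33.7,    # skin setpoint, degC (thermoregulatory control)
  tcr_set    = 36.8,    # core setpoint, degC
  skbf_base  = 6.3,     # basal skin blood flow, L/m2h
  skbf_dil   = 200,     # vasodilation gain, L/m2h per K core warm signal
  skbf_con   = 0.5,     # vasoconstriction gain per K skin cold signal
  skbf_min   = 0.5,     # clamp, L/m2h
  skbf_max   = 90,
  k_min      = 5.28,    # minimal core-skin conductance, W/m2K
  k_blood    = 1.163,   # conductance per unit skin blood flow, Wh/LK
  sweat_gain = 170,     # regulatory sweating, g/m2h per K body warm signal
  sweat_exp  = 10.7,    # local skin-temperature amplification, K
  sweat_max  = 500,     # g/m2h
  h_vap      = 0.68,    # evaporative heat, Wh/g
  w_dif      = 0.06,    # skin diffusion fraction of max evaporation
  ref_vp     = 12,      # reference-environment vapour pressure, hPa
  ref_wind   = 0.1,     # reference-environment wind, m/s
  pet_range  = c(-50, 80)
)

#' Standard person for PET calculations
#'
#' The fixed reference subject of the thermal index: male, 35 years, 75 kg,
#' 1.75 m, light activity (80 W above basal metabolism), clothing 0.9 clo.
#'
#' @param sex `"male"` or `"female"` (Harris-Benedict basal metabolism).
#' @param age Years.
#' @param mass Body mass, kg.
#' @param height Body height, m.
#' @param activity Metabolic heat of activity above basal, W.
#' @param clo Clothing insulation, clo (1 clo = 0.155 m2K/W).
#' @return A list of class `standard_person` with the inputs plus derived
#'   quantities: Du Bois surface area `area` (m2), basal metabolic rate
#'   `basal` (W) and total internal heat production `metabolism` (W).
#' @examples
#' standard_person()$area # about 1.91 m2
#' @export
standard_person <- function(sex = "male", age = 35, mass = 75, height = 1.75,
                            activity = 80, clo = 0.9) {
  sex <- match.arg(sex, c("male", "female"))
  area <- 0.203 * mass^0.425 * height^0.725 # Du Bois
  kcal_day <- if (sex == "male") {
    66.473 + 13.752 * mass + 5.003 * height * 100 - 6.755 * age
  } else {
    655.096 + 9.563 * mass + 1.850 * height * 100 - 4.676 * age
  }
  basal <- kcal_day * 4184 / 86400
  p <- list(sex = sex, age = age, mass = mass, height = height,
            activity = activity, clo = clo,
            area = area, basal = basal, metabolism = basal + activity)
  class(p) <- "standard_person"
  p
}

#' Reduce wind speed from measurement height to body height
#'
#' Power-law wind profile from the standard 10 m anemometer height down to
#' 1.1 m, the height of the centre of gravity of a standing person.
#'
#' @param v10 Wind speed at `z_ref`, m/s. Vectorised.
#' @param z_target Target height, m (default 1.1).
#' @param z_ref Measurement height, m (default 10).
#' @param alpha Power-law exponent (default 0.25, urban surroundings).
#' @return Wind speed at `z_target`, m/s.
#' @examples
#' reduce_wind(3) # about 1.73 m/s
#' @export
reduce_wind <- function(v10, z_target = 1.1, z_ref = 10, alpha = 0.25) {
  if (any(v10 < 0, na.rm = TRUE)) stop("wind speed must be non-negative")
  v10 * (z_target / z_ref)^alpha
}

#' Lapse-rate correction of air temperature for an altitude offset
#'
#' Adjusts model air temperature for the altitude difference between a
#' climate-model grid cell and the station, at a fixed vertical gradient.
#'
#' @param ta Air temperature, degC. Vectorised.
#' @param dz Altitude difference (model minus station), m. A model level
#'   above the station (`dz > 0`) yields a warming correction.
#' @param rate Lapse rate, K per 100 m (default 0.65).
#' @return Corrected air temperature, degC.
#' @examples
#' lapse_correct(20, 30) # 20.195
#' @export
lapse_correct <- function(ta, dz, rate = 0.65) {
  ta + rate * dz / 100
}

# Solar position: sine of solar elevation for date/hour/coordinates.
# `hour` is local clock time; `tz_offset` hours east of UTC of that clock.
solar_elevation_sin <- function(dates, hour, lat, lon, tz_offset = 1) {
  doy <- as.POSIXlt(dates)$yday + 1
  gamma <- 2 * pi * (doy - 1) / 365
  decl <- 0.006918 - 0.399912 * cos(gamma) + 0.070257 * sin(gamma) -
    0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma) -
    0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(gamma) - 0.032077 * sin(gamma) -
    0.014615 * cos(2 * gamma) - 0.040849 * sin(2 * gamma)) # minutes
  solar_time <- hour + (lon / 15 - tz_offset) + eqtime / 60
  ha <- (solar_time - 12) * 15 * pi / 180
  lat_r <- lat * pi / 180
  sin(lat_r) * sin(decl) + cos(lat_r) * cos(decl) * cos(ha)
}

#' Estimate global radiation and mean radiant temperature from cloud cover
#'
#' Clear-sky global radiation from solar geometry (Kasten-Czeplak form
#' `910 sin(h) - 30` W/m2) attenuated by the cloud factor
#' `1 - 0.75 (N/8)^3.4`; mean radiant temperature from the short- and
#' long-wave balance on the standard person over a flat, unobstructed
#' surface (isotropic sky and ground half-spaces, ground at air
#' temperature, clear-sky atmospheric emissivity after Idso with a
#' quadratic cloud enhancement, shortwave absorption 0.7).
#'
#' @param ta Air temperature, degC. Vectorised.
#' @param vp Vapour pressure, hPa.
#' @param cloud Cloud cover, octas in `[0, 8]`.
#' @param dates Dates (anything `as.POSIXlt` accepts).
#' @param hour Local hour of the day (default 14).
#' @param lat,lon Station coordinates, degrees.
#' @param tz_offset Clock offset from UTC in hours (default 1, CET).
#' @return A data frame with columns `grad` (global radiation, W/m2) and
#'   `tmrt` (mean radiant temperature, degC).
#' @examples
#' estimate_radiation(28, 20, 2, as.Date("2000-07-01"),
#'                    hour = 14, lat = 48.25, lon = 16.36)
#' @export
estimate_radiation <- function(ta, vp, cloud, dates, hour = 14,
                               lat = 48.25, lon = 16.36, tz_offset = 1) {
  if (any(cloud < 0 | cloud > 8, na.rm = TRUE)) {
    stop("cloud cover must be in octas [0, 8]")
  }
  cc <- .memi_const
  sin_h <- solar_elevation_sin(dates, hour, lat, lon, tz_offset)
  g_clear <- pmax(0, 910 * sin_h - 30)
  grad <- g_clear * (1 - 0.75 * (cloud / 8)^3.4)
  ta_k <- ta + 273.15
  eps_clear <- pmin(1, 0.70 + 5.95e-5 * vp * exp(1500 / ta_k))
  eps_sky <- eps_clear + (1 - eps_clear) * (cloud / 8)^2
  l_down <- eps_sky * cc$sigma * ta_k^4
  # ground: emission at air temperature plus reflected sky longwave
  l_up <- cc$eps_body * cc$sigma * ta_k^4 + (1 - cc$eps_body) * l_down
  tmrt4 <- (0.5 * l_down + 0.5 * l_up +
    cc$alpha_sw * cc$f_proj * grad / cc$eps_body) / cc$sigma
  data.frame(grad = grad, tmrt = tmrt4^0.25 - 273.15)
}

# ---------------------------------------------------------------------------
# Two-node energy balance (vectorised over days).

# Clothing surface temperature: balance of conduction through clothing
# against convection + longwave exchange, exact Stefan-Boltzmann with an
# iterated linearisation of the radiative coefficient.
clothing_temperature <- function(tskin, ta, tmrt, hc, person) {
  cc <- .memi_const
  icl <- 0.155 * person$clo
  fcl <- 1 + 0.31 * person$clo
  tcl <- (tskin + ta) / 2
  for (i in 1:8) {
    tcl_k <- tcl + 273.15
    tmrt_k <- tmrt + 273.15
    hr <- cc$f_eff * cc$eps_body * cc$sigma *
      (tcl_k^2 + tmrt_k^2) * (tcl_k + tmrt_k)
    tcl <- (tskin / icl + fcl * hc * ta + fcl * hr * tmrt) /
      (1 / icl + fcl * hc + fcl * hr)
  }
  tcl
}

# Core-node residual only (metabolism - respiration - core-to-skin
# transport); cheap, used by the inner bisection which never needs the
# clothing solution.
memi_core_residual <- function(tcore, tskin, ta, vp, person) {
  cc <- .memi_const
  area <- person$area
  m_area <- person$metabolism / area
  q_res <- 0.0014 * m_area * (34 - ta) + 0.0173 * m_area * (5.87 - vp / 10)
  wsig_cr <- pmax(tcore - cc$tcr_set, 0)
  csig_sk <- pmax(cc$tsk_set - tskin, 0)
  skbf <- clamp((cc$skbf_base + cc$skbf_dil * wsig_cr) /
                  (1 + cc$skbf_con * csig_sk),
                cc$skbf_min, cc$skbf_max)
  q_cs <- (cc$k_min + cc$k_blood * skbf) * (tcore - tskin)
  person$metabolism - area * q_res - area * q_cs
}

# All energy fluxes (W, whole body) at prescribed core and skin
# temperatures. Returns the two node residuals plus diagnostic fluxes.
#' Energy-balance residuals of the two-node body model
#'
#' Evaluates every heat flux of the clothed two-node (core/skin) model at
#' prescribed body temperatures and returns the core and skin node
#' residuals in W (whole body). Exposed so that solver output can be
#' verified independently, e.g. by grid search.
#'
#' @param tcore,tskin Core and skin temperature, degC. Vectorised.
#' @param ta Air temperature, degC.
#' @param vp Vapour pressure, hPa.
#' @param v Wind speed at body height, m/s.
#' @param tmrt Mean radiant temperature, degC.
#' @param person A [standard_person()].
#' @return A list with `core` and `skin` residuals (W; zero at the steady
#'   state), and fluxes `dry` (convective + radiative through clothing),
#'   `evap` (skin evaporation), `resp` (respiratory), `sweat`
#'   (regulatory sweat evaporation), all W, plus `tcl` (degC).
#' @export
memi_residuals <- function(tcore, tskin, ta, vp, v, tmrt,
                           person = standard_person()) {
  cc <- .memi_const
  area <- person$area
  m_area <- person$metabolism / area

  # respiration (PMV form, vapour pressure in hPa)
  q_res <- 0.0014 * m_area * (34 - ta) +
    0.0173 * m_area * (5.87 - vp / 10)

  # dry heat loss through clothing
  hc <- 2.67 + 6.5 * v^0.67
  icl <- 0.155 * person$clo
  tcl <- clothing_temperature(tskin, ta, tmrt, hc, person)
  q_dry <- (tskin - tcl) / icl

  # evaporation: regulatory sweat + skin diffusion, capped by the maximum
  # wet-skin evaporation through clothing and boundary layer
  fcl <- 1 + 0.31 * person$clo
  re_cl <- icl / (cc$lewis_hpa * cc$i_m)
  re_air <- 1 / (fcl * cc$lewis_hpa * hc)
  e_max <- (saturation_vp(tskin) - vp) / (re_cl + re_air)
  tb <- 0.1 * tskin + 0.9 * tcore
  tb_set <- 0.1 * cc$tsk_set + 0.9 * cc$tcr_set
  wsig_b <- pmax(tb - tb_set, 0)
  wsig_sk <- pmax(tskin - cc$tsk_set, 0)
  regsw <- pmin(cc$sweat_gain * wsig_b * exp(wsig_sk / cc$sweat_exp),
                cc$sweat_max)
  e_rsw <- cc$h_vap * regsw
  frac <- ifelse(e_max > 0, pmin(e_rsw / e_max, 1), 1)
  e_sk <- ifelse(e_max > 0,
                 pmin(e_rsw + cc$w_dif * (1 - frac) * e_max, e_max),
                 e_max)

  # core-to-skin transport via conduction + skin blood flow
  wsig_cr <- pmax(tcore - cc$tcr_set, 0)
  csig_sk <- pmax(cc$tsk_set - tskin, 0)
  skbf <- clamp((cc$skbf_base + cc$skbf_dil * wsig_cr) /
                  (1 + cc$skbf_con * csig_sk),
                cc$skbf_min, cc$skbf_max)
  q_cs <- (cc$k_min + cc$k_blood * skbf) * (tcore - tskin)

  list(core = person$metabolism - area * q_res - area * q_cs,
       skin = area * q_cs - area * q_dry - area * e_sk,
       dry = area * q_dry, evap = area * e_sk, resp = area * q_res,
       sweat = area * pmin(e_rsw, pmax(e_max, 0)), tcl = tcl)
}

#' Solve the steady-state two-node energy balance
#'
#' Finds core and skin temperature at which both body nodes are in
#' balance: metabolic heat minus respiratory losses equals the core-to-skin
#' transport, and that transport equals the dry plus evaporative loss from
#' the skin through clothing. Solved by nested bisection, exploiting that
#' the core residual is monotone in core temperature and the skin residual
#' monotone in skin temperature; this converges unconditionally and is
#' fully deterministic.
#'
#' @inheritParams memi_residuals
#' @param tol Residual tolerance, W (default 0.01).
#' @return A data frame with columns `tcore`, `tskin`, `tcl` (degC),
#'   `sweat` (regulatory sweat evaporation, W) and `residual`
#'   (`|core| + |skin|`, W).
#' @examples
#' solve_memi(ta = 23, vp = 12, v = 0.1, tmrt = 23)
#' @export
solve_memi <- function(ta, vp, v, tmrt, person = standard_person(),
                       tol = 0.01) {
  n <- max(length(ta), length(vp), length(v), length(tmrt))
  ta <- rep_len(ta, n); vp <- rep_len(vp, n)
  v <- rep_len(v, n); tmrt <- rep_len(tmrt, n)

  core_for_skin <- function(tskin) {
    lo <- tskin + 1e-4
    hi <- tskin + 18
    for (i in 1:36) {
      mid <- (lo + hi) / 2
      r <- memi_core_residual(mid, tskin, ta, vp, person)
      hi <- ifelse(r <= 0, mid, hi) # residual decreasing in tcore
      lo <- ifelse(r > 0, mid, lo)
    }
    (lo + hi) / 2
  }

  lo <- rep(0, n); hi <- rep(48, n)
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    tc <- core_for_skin(mid)
    r <- memi_residuals(tc, mid, ta, vp, v, tmrt, person)$skin
    hi <- ifelse(r <= 0, mid, hi) # skin residual decreasing in tskin
    lo <- ifelse(r > 0, mid, lo)
  }
  tskin <- (lo + hi) / 2
  tcore <- core_for_skin(tskin)
  res <- memi_residuals(tcore, tskin, ta, vp, v, tmrt, person)
  residual <- abs(res$core) + abs(res$skin)
  if (any(residual > tol)) {
    warning(sum(residual > tol),
            " day(s) did not reach the energy-balance tolerance; ",
            "max residual ", format(max(residual), digits = 3), " W")
  }
  data.frame(tcore = tcore, tskin = tskin, tcl = res$tcl,
             sweat = res$sweat, residual = residual)
}

#' PET: reference-environment temperature for a solved body state
#'
#' Given the core and skin temperatures reached outdoors, finds the air
#' temperature of the standard indoor reference environment (Tmrt equal to
#' air temperature, wind 0.1 m/s, vapour pressure 12 hPa) at which the
#' body, held at those temperatures, has a closed energy budget. Root
#' located by bisection on `[-50, 80]` degC.
#'
#' @param state Data frame from [solve_memi()] (columns `tcore`, `tskin`).
#' @param person A [standard_person()].
#' @param tol Bisection half-width at termination, degC (default 0.001).
#' @return PET, degC (vector).
#' @examples
#' st <- solve_memi(ta = 30, vp = 15, v = 1, tmrt = 50)
#' compute_pet(st)
#' @export
compute_pet <- function(state, person = standard_person(), tol = 0.001) {
  cc <- .memi_const
  n <- nrow(state)
  budget <- function(ta_ref) {
    r <- memi_residuals(state$tcore, state$tskin, ta_ref, cc$ref_vp,
                        cc$ref_wind, ta_ref, person)
    # total budget; core-to-skin transport cancels between the two nodes
    r$core + r$skin
  }
  lo <- rep(cc$pet_range[1], n)
  hi <- rep(cc$pet_range[2], n)
  bad <- budget(lo) > 0 | budget(hi) < 0
  if (any(bad)) stop("no PET root in [-50, 80] degC for ", sum(bad), " day(s)")
  while (max(hi - lo) > 2 * tol) {
    mid <- (lo + hi) / 2
    b <- budget(mid)
    lo <- ifelse(b <= 0, mid, lo) # budget increasing in ta_ref
    hi <- ifelse(b > 0, mid, hi)
  }
  (lo + hi) / 2
}

#' Daily PET series from a meteorological series
#'
#' Runs the full chain for each day of a met series: vapour pressure from
#' relative humidity (unless a `vp` column is present), wind reduction to
#' 1.1 m, radiation and mean radiant temperature from cloud cover, energy
#' balance and PET.
#'
#' @param met Data frame with columns `date`, `ta`, `rh` (or `vp`),
#'   `wind`, `cloud`, as returned by [generate_met_series()] or
#'   [read_met_csv()]. If a `pet` column is already present it is returned
#'   unchanged (precomputed-PET bypass).
#' @param hour Reference hour (default 14 local).
#' @param lat,lon,tz_offset Passed to [estimate_radiation()].
#' @param person A [standard_person()].
#' @return Data frame `date`, `pet` (degC) plus intermediate columns
#'   `tmrt`, `grad`, `vp`, `v11`.
#' @export
pet_series <- function(met, hour = 14, lat = 48.25, lon = 16.36,
                       tz_offset = 1, person = standard_person()) {
  stopifnot(is.data.frame(met), "date" %in% names(met), "ta" %in% names(met))
  if ("pet" %in% names(met)) {
    return(data.frame(date = met$date, pet = met$pet))
  }
  vp <- if ("vp" %in% names(met)) met$vp else vapour_pressure(met$ta, met$rh)
  v11 <- reduce_wind(met$wind)
  rad <- estimate_radiation(met$ta, vp, met$cloud, met$date, hour = hour,
                            lat = lat, lon = lon, tz_offset = tz_offset)
  state <- solve_memi(met$ta, vp, v11, rad$tmrt, person)
  data.frame(date = met$date, pet = compute_pet(state, person),
             tmrt = rad$tmrt, grad = rad$grad, vp = vp, v11 = v11)
}
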