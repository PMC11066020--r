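# Subject-specific RCR Windkessel outlet boundary conditions. Total
# peripheral resistance comes from MAP over mean flow, total capacitance
# from stroke volume over pulse pressure; outflow is split across outlets
# by Murray's law (exponent 2.1) and each outlet's RCR triple is checked by
# a 0D pressure-response integration.

#' Mean arterial pressure
#'
#' MAP = DBP + (SBP - DBP)/3 = (SBP + 2 DBP)/3, the standard diastole-
#' weighted estimate.
#'
#' @param systolic Systolic pressure, mmHg.
#' @param diastolic Diastolic pressure, mmHg; must be below systolic.
#' @return MAP, mmHg. Linear in both inputs, so group-mean pressures give
#'   the group-mean MAP.
#' @examples
#' mean_arterial_pressure(126.9, 73.6)  # 91.4
#' mean_arterial_pressure(135.4, 72.3)  # 93.3
#' @export
mean_arterial_pressure <- function(systolic, diastolic) {
  if (any(systolic <= diastolic))
    stop("systolic pressure must exceed diastolic", call. = FALSE)
  diastolic + (systolic - diastolic) / 3
}

#' RCR Windkessel configuration
#'
#' @param murray_coefficient Murray's-law exponent on outlet diameter
#'   (default 2.1).
#' @param proximal_fraction Rp / (Rp + Rd) split (default 0.09, a
#'   conventional carotid choice).
#' @param reference_pressure Distal (venous) reference pressure, mmHg
#'   (default 0).
#' @return A list of class `rcr_config`.
#' @export
rcr_config <- function(murray_coefficient = 2.1, proximal_fraction = 0.09,
                       reference_pressure = 0) {
  stopifnot(murray_coefficient > 0,
            proximal_fraction > 0, proximal_fraction < 1)
  structure(list(murray_coefficient = murray_coefficient,
                 proximal_fraction = proximal_fraction,
                 reference_pressure = reference_pressure),
            class = "rcr_config")
}

#' RCR parameter triple
#'
#' All values in CGS: resistances in dyn s cm^-5, capacitance in
#' cm^5 dyn^-1, reference pressure in dyn/cm^2.
#' @param Rp Proximal resistance.
#' @param C Capacitance.
#' @param Rd Distal resistance.
#' @param P_ref Reference pressure (dyn/cm^2), default 0.
#' @return A list of class `rcr_parameters`.
#' @export
rcr_parameters <- function(Rp, C, Rd, P_ref = 0) {
  stopifnot(Rp > 0, C > 0, Rd > 0)
  structure(list(Rp = Rp, C = C, Rd = Rd, P_ref = P_ref),
            class = "rcr_parameters")
}

#' @export
print.rcr_parameters <- function(x, ...) {
  cat(sprintf("RCR: Rp = %.4g, Rd = %.4g dyn s cm^-5; C = %.4g cm^5/dyn; P_ref = %.4g dyn/cm^2\n",
              x$Rp, x$Rd, x$C, x$P_ref))
  invisible(x)
}

#' Estimate total RCR parameters from vitals and mean flow
#'
#' R_total = MAP / mean_flow and C_total = stroke_volume / pulse_pressure,
#' converted to CGS; the proximal/distal split follows
#' `config$proximal_fraction`.
#'
#' @param map Mean arterial pressure, mmHg.
#' @param mean_flow Time-averaged inlet flow, mL/s.
#' @param stroke_volume Stroke volume, mL.
#' @param pulse_pressure Pulse pressure, mmHg.
#' @param config An [rcr_config()].
#' @return An [rcr_parameters()] object holding the totals.
#' @export
estimate_total_rcr <- function(map, mean_flow, stroke_volume, pulse_pressure,
                               config = rcr_config()) {
  if (mean_flow <= 0) stop("mean flow must be positive", call. = FALSE)
  stopifnot(map > 0, stroke_volume > 0, pulse_pressure > 0)
  R_total <- mmHg_to_cgs(map / mean_flow)           # mmHg s/mL -> dyn s cm^-5
  C_total <- stroke_volume / mmHg_to_cgs(pulse_pressure)  # mL/mmHg -> cm^5/dyn
  rcr_parameters(Rp = config$proximal_fraction * R_total,
                 C = C_total,
                 Rd = (1 - config$proximal_fraction) * R_total,
                 P_ref = mmHg_to_cgs(config$reference_pressure))
}

#' Distribute total RCR parameters across outlets by Murray's law
#'
#' Flow fractions f_i = d_i^k / sum d_j^k; per-outlet resistances
#' R_i = R_total / f_i so that the parallel combination recovers the total;
#' capacitances C_i = f_i C_total so they sum to the total.
#'
#' @param totals An [rcr_parameters()] with total values.
#' @param outlet_diameters Outlet diameters, cm.
#' @param config An [rcr_config()].
#' @return A list of [rcr_parameters()], one per outlet, with the flow
#'   fractions in attribute `"fractions"`.
#' @export
distribute_outlets <- function(totals, outlet_diameters, config = rcr_config()) {
  stopifnot(inherits(totals, "rcr_parameters"))
  if (!length(outlet_diameters)) stop("need at least one outlet", call. = FALSE)
  f <- murray_fractions(outlet_diameters, config$murray_coefficient)
  R_total <- totals$Rp + totals$Rd
  out <- lapply(f, function(fi) {
    Ri <- R_total / fi
    rcr_parameters(Rp = config$proximal_fraction * Ri,
                   C = fi * totals$C,
                   Rd = (1 - config$proximal_fraction) * Ri,
                   P_ref = totals$P_ref)
  })
  attr(out, "fractions") <- f
  out
}

#' 0D pressure response of an RCR outlet
#'
#' Integrates C dPd/dt = Q(t) - (Pd - P_ref)/Rd with
#' P_in = Pd + Rp Q(t), starting from Pd(0) = P_ref + Rd Qbar, by classical
#' 4th-order Runge-Kutta over `n_cycles` cardiac cycles; returns the final
#' cycle (the transient has decayed by then for physiological RC times).
#'
#' @param waveform A [flow_waveform()] (mL/s).
#' @param rcr An [rcr_parameters()] (CGS).
#' @param n_cycles Number of cycles to integrate (default 5).
#' @param dt Time step, s; must be at most period/100 (default period/200).
#' @return A data frame with columns `time` (s, final cycle, starting at 0),
#'   `P_in` and `P_d` (dyn/cm^2), `Q` (mL/s).
#' @export
rcr_pressure_response <- function(waveform, rcr, n_cycles = 5, dt = NULL) {
  stopifnot(inherits(waveform, "flow_waveform"), inherits(rcr, "rcr_parameters"))
  Tp <- waveform$period
  if (is.null(dt)) dt <- Tp / 200
  if (dt > Tp / 100 + 1e-12)
    stop("dt must be at most period/100", call. = FALSE)
  Qfun <- waveform_function(waveform)
  Qbar <- waveform_mean_flow(waveform)
  times <- seq(0, n_cycles * Tp, by = dt)
  deriv <- function(t, y, parms) {
    list((Qfun(t) - (y - rcr$P_ref) / rcr$Rd) / rcr$C)
  }
  sol <- deSolve::rk4(y = rcr$P_ref + rcr$Rd * Qbar, times = times,
                      func = deriv, parms = NULL)
  Pd <- sol[, 2L]
  if (any(!is.finite(Pd)))
    stop("0D integration diverged (non-finite pressure)", call. = FALSE)
  tfin <- times >= (n_cycles - 1) * Tp - 1e-12
  tt <- times[tfin] - (n_cycles - 1) * Tp
  Q <- Qfun(times[tfin])
  data.frame(time = tt, P_in = Pd[tfin] + rcr$Rp * Q, P_d = Pd[tfin], Q = Q)
}
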