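#' Sample reservoir geometry for depletion runs
#'
#' Models the sample reservoir as a liquid column of constant free-surface
#' cross-section `area` whose surface recedes radially outward as the sample
#' drains through `n_channels` identical parallel microchannels. The nozzle
#' radius `nozzle_radius = R1 + R2` is fixed by the chip; the split between
#' R1 (centre to surface) and R2 (surface to nozzles, the column height)
#' evolves with the remaining volume as `R2 = V / area`.
#'
#' @param area Free-surface cross-sectional area (m^2), > 0.
#' @param volume Initial aqueous volume V0 (m^3), > 0; the column must fit
#'   between the rotational centre and the nozzles (`volume/area <=
#'   nozzle_radius`).
#' @param n_channels Number of parallel microchannels (>= 0; 0 is a
#'   degenerate guard yielding a constant trace).
#' @param nozzle_radius Radial position of the nozzles (m), > 0.
#' @return An object of class `reservoir_geometry`.
#' @export
reservoir_geometry <- function(area, volume, n_channels, nozzle_radius) {
  .check_num(area, "area", positive = TRUE)
  .check_num(volume, "volume", positive = TRUE)
  .check_num(nozzle_radius, "nozzle_radius", positive = TRUE)
  if (!is.numeric(n_channels) || length(n_channels) != 1L ||
      n_channels < 0 || n_channels != round(n_channels)) {
    stop("`n_channels` must be a non-negative integer", call. = FALSE)
  }
  if (volume / area > nozzle_radius) {
    stop("liquid column does not fit: volume/area exceeds `nozzle_radius`",
         call. = FALSE)
  }
  structure(list(area = area, volume = volume, n_channels = n_channels,
                 nozzle_radius = nozzle_radius),
            class = "reservoir_geometry")
}

#' Simulate the decline of inlet velocity as the reservoir drains
#'
#' During no-dead-volume emulsification the aqueous surface recedes, the
#' driving pressure drops, and the inlet velocity V_in declines. This
#' integrates the volume balance `dV/dt = -n w h V_in(V)` with
#' `R2(V) = V/A_res` and `R1(V) = R_noz - R2(V)` using a classical
#' fixed-step fourth-order Runge-Kutta scheme. The step count is doubled
#' until the end-of-run velocity changes by less than `summary_tol`
#' (Richardson-style self-consistency). Integration stops when the
#' remaining volume falls below `v_floor * V0` or the channels stop flowing.
#' For hydrophobic channels the no-flow state (total pressure <= 0) is an
#' asymptote of the volume balance, so the run is also terminated once the
#' instantaneous flux falls below 1e-6 of its initial value; a small
#' residual volume then legitimately remains undispensed.
#'
#' @param reservoir A [reservoir_geometry()].
#' @param channel A [channel_geometry()].
#' @param fluids A [fluid_system()].
#' @param omega Angular velocity (rad s^-1).
#' @param n_steps Initial number of steps per characteristic drain time
#'   (default 2000).
#' @param summary_tol Relative change in end velocity accepted between
#'   refinements (default 1e-3, i.e. 0.1 percent).
#' @param max_refinements Maximum number of step-halvings.
#' @param v_floor Terminal volume fraction of V0 (default 1e-4); avoids
#'   division noise at the empty limit.
#' @return An object of class `depletion_trace`: a list with `trace` (a
#'   data frame with columns `time`, `volume`, `r1`, `r2`, `v_in`),
#'   `v_begin`, `v_end`, `decline_pct`, `dispensed` (flux integral, m^3),
#'   `no_flow_end`, and `n_steps_used`.
#' @export
simulate_depletion <- function(reservoir, channel, fluids, omega,
                               n_steps = 2000, summary_tol = 1e-3,
                               max_refinements = 5, v_floor = 1e-4) {
  stopifnot(inherits(reservoir, "reservoir_geometry"),
            inherits(channel, "channel_geometry"),
            inherits(fluids, "fluid_system"))
  .check_num(omega, "omega")

  # The capillary pressure and hydraulic resistance are constants of the
  # run; only the driving pressure varies with the receding surface, so the
  # velocity map reduces to a cheap closed form in V.
  pcap <- capillary_pressure(channel, fluids)
  rwh <- hydraulic_resistance(channel, fluids) * channel$width * channel$height
  rnoz <- reservoir$nozzle_radius
  area <- reservoir$area
  half_rho_om2 <- 0.5 * fluids$density * omega^2
  vin_of <- function(V) {
    r1 <- rnoz - max(V, 0) / area
    p <- half_rho_om2 * (rnoz^2 - r1^2) + pcap
    if (p <= 0) 0 else p / rwh
  }
  v0 <- vin_of(reservoir$volume)
  if (v0 <= 0) {
    stop("condition does not emulsify: no flow at the initial volume",
         call. = FALSE)
  }

  xsec <- channel$width * channel$height
  if (reservoir$n_channels == 0) {
    # Degenerate guard: nothing drains, V_in stays at its initial value.
    tr <- data.frame(time = c(0, 1), volume = reservoir$volume,
                     r1 = rnoz - reservoir$volume / area,
                     r2 = reservoir$volume / area,
                     v_in = v0)
    return(structure(list(trace = tr, v_begin = v0, v_end = v0,
                          decline_pct = 0, dispensed = 0,
                          no_flow_end = FALSE, n_steps_used = 0L),
                     class = "depletion_trace"))
  }

  flux_of <- function(V) {
    if (V <= 0) return(0)
    reservoir$n_channels * xsec * vin_of(V)
  }
  flux0 <- flux_of(reservoir$volume)

  run <- function(nst) {
    dt <- reservoir$volume / flux0 / nst
    vmin <- v_floor * reservoir$volume
    cap <- 100L * nst
    tt <- numeric(cap + 1L); vv <- numeric(cap + 1L)
    tt[1L] <- 0; vv[1L] <- reservoir$volume
    V <- reservoir$volume
    i <- 1L
    no_flow_end <- FALSE
    while (i <= cap) {
      k1 <- -flux_of(V)
      k2 <- -flux_of(V + dt / 2 * k1)
      k3 <- -flux_of(V + dt / 2 * k2)
      k4 <- -flux_of(V + dt * k3)
      V <- V + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      i <- i + 1L
      tt[i] <- tt[i - 1L] + dt
      vv[i] <- V
      if (V <= vmin) {
        # pin the end point to the terminal volume itself so the summary
        # does not depend on the size of the final overshoot
        frac <- (vv[i - 1L] - vmin) / (vv[i - 1L] - V)
        tt[i] <- tt[i - 1L] + frac * dt
        vv[i] <- vmin
        break
      }
      q <- flux_of(V)
      # For hydrophobic channels the no-flow state is an asymptote of the
      # ODE; stop once the flux is a negligible fraction of its start value,
      # pinning the end point to the crossing so it is step-size independent.
      if (q <= 0 || q <= 1e-6 * flux0) {
        q_prev <- flux_of(vv[i - 1L])
        if (q_prev > q) {
          frac <- (q_prev - 1e-6 * flux0) / (q_prev - q)
          frac <- min(max(frac, 0), 1)
          tt[i] <- tt[i - 1L] + frac * dt
          vv[i] <- vv[i - 1L] + frac * (V - vv[i - 1L])
        }
        no_flow_end <- TRUE
        break
      }
    }
    tt <- tt[seq_len(i)]; vv <- pmax(vv[seq_len(i)], 0)
    r1 <- rnoz - vv / area
    p <- half_rho_om2 * (rnoz^2 - r1^2) + pcap
    vin <- ifelse(p > 0, p / rwh, 0)
    q <- reservoir$n_channels * xsec * vin
    dispensed <- sum(diff(tt) * (q[-1L] + q[-length(q)]) / 2)
    list(trace = data.frame(time = tt, volume = vv, r1 = r1,
                            r2 = vv / area, v_in = vin),
         v_begin = vin[1L], v_end = vin[length(vin)],
         dispensed = dispensed, no_flow_end = no_flow_end, n_steps = nst)
  }

  res <- run(n_steps)
  for (k in seq_len(max_refinements)) {
    res2 <- run(2L * res$n_steps)
    converged <- abs(res2$v_end - res$v_end) <=
      summary_tol * max(abs(res$v_end), 1e-6 * res$v_begin)
    res <- res2
    if (converged) break
  }

  structure(list(trace = res$trace, v_begin = res$v_begin, v_end = res$v_end,
                 decline_pct = 100 * (res$v_begin - res$v_end) / res$v_begin,
                 dispensed = res$dispensed, no_flow_end = res$no_flow_end,
                 n_steps_used = res$n_steps),
            class = "depletion_trace")
}

#' Begin/end velocities and relative decline of a depletion trace
#'
#' @param trace A `depletion_trace` from [simulate_depletion()].
#' @return Named numeric vector `c(v_begin, v_end, decline_pct)`; the
#'   decline is `100 (v_begin - v_end) / v_begin` and lies in \[0, 100\] for
#'   a physical (non-increasing) trace.
#' @export
decline_summary <- function(trace) {
  stopifnot(inherits(trace, "depletion_trace"))
  v <- trace$trace$v_in
  if (length(v) == 0L) stop("empty depletion trace", call. = FALSE)
  vb <- v[1L]
  ve <- v[length(v)]
  c(v_begin = vb, v_end = ve, decline_pct = 100 * (vb - ve) / vb)
}

#' @export
print.depletion_trace <- function(x, ...) {
  cat(sprintf(
    "Depletion trace: %d points, V_in %.4g -> %.4g m/s (decline %.2f%%)%s\n",
    nrow(x$trace), x$v_begin, x$v_end, x$decline_pct,
    if (x$no_flow_end) ", ended at no-flow" else ""))
  invisible(x)
}
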