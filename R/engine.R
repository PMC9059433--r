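# Time integration of the coupled valve-tube-lung system. Each breath phase
# is integrated as its own segment (so no integrator step straddles a valve
# switching discontinuity), with the volume cutoff of the VCV controller
# located by root-finding inside the inspiration segment.

.wf_cols <- c(
  "time_s", "phase", "p_tube_cmH2O", "p_lung_cmH2O",
  "flow_insp_L_min", "flow_exh_L_min", "v_lung_mL"
)

# Signed orifice flow with a linear blending band near pressure equality.
# The subsonic law goes like sqrt(1 - r) near r = 1, which is non-Lipschitz
# at equalization and makes the contact point numerically stiff; below
# `dp_lin` (Pa) the flow is taken linear in the pressure difference,
# continuous at the band edge. 5 Pa (~0.05 cmH2O) is far below any feature
# the model resolves.
.signed_orifice <- function(area, p_from, p_to, gas, dp_lin = 5) {
  dp <- p_from - p_to
  adp <- abs(dp)
  hi <- max(p_from, p_to)
  lo <- min(p_from, p_to)
  if (adp >= dp_lin) {
    return(sign(dp) * orifice_mass_flow(area, hi, lo, gas))
  }
  f_edge <- orifice_mass_flow(area, hi, hi - dp_lin, gas)
  sign(dp) * f_edge * adp / dp_lin
}

#' Simulate a ventilation scenario
#'
#' Integrates the tube and lung pressure equations under the VCV controller
#' and the valve connectivity of the scenario, phase by phase. During
#' inspiration the ventilator acts as a flow source at the set flow Q_T,
#' bounded by the compressible-flow capacity of the supply orifice at the
#' regulated source pressure (if the bound binds, the breath is flow-limited
#' and the run log says so). The tube-to-lung path is always open; the
#' exhalation valve is open during expiration only. Switching instants are
#' segment boundaries; the tidal-volume cutoff is an integration root.
#'
#' @param scenario A [vent_scenario()].
#' @return An object of class `vcv_sim` with elements `waveform` (tibble with
#'   columns `time_s`, `cycle`, `phase`, `p_tube_cmH2O`, `p_lung_cmH2O`,
#'   `flow_insp_L_min`, `flow_exh_L_min`, `v_lung_mL`), `scenario`, `mass`
#'   (boundary-mass bookkeeping incl. the conservation residual), and `log`.
#' @examples
#' \donttest{
#' sim <- simulate_vcv(vent_scenario(n_cycles = 1))
#' breath_metrics(sim)
#' }
#' @export
simulate_vcv <- function(scenario) {
  stopifnot(inherits(scenario, "vent_scenario"))
  gas <- scenario$gas
  lung <- scenario$lung
  tube <- scenario$tube
  vcv <- scenario$vcv
  eng <- scenario$engine
  rho <- reference_density(gas)
  q_set <- target_flow(vcv)
  a_sup <- scenario$valve$spec$supply_area
  a_rt <- scenario$valve$insp_area
  a_ev <- scenario$valve$spec$exhaust_area
  cushion <- scenario$valve$cushion
  ctau <- scenario$valve$cushion_tau
  p_src <- vcv$source_pressure

  flows_at <- function(t_seg, p_t, p_l, delivered, phase) {
    mdot_in <- 0
    capped <- FALSE
    if (phase == "INSPIRATION" && delivered < vcv$tidal_volume) {
      cmd <- rho * q_set
      cap <- if (p_src > p_t) orifice_mass_flow(a_sup, p_src, p_t, gas) else 0
      capped <- cap < cmd
      mdot_in <- min(cmd, cap)
    }
    mdot_tl <- .signed_orifice(a_rt, p_t, p_l, gas)
    mdot_ex <- 0
    if (phase == "EXPIRATION") {
      a_eff <- a_ev * (if (cushion) 1 - exp(-t_seg / ctau) else 1)
      mdot_ex <- .signed_orifice(a_eff, p_t, gas$p_atm, gas)
    }
    list(mdot_in = mdot_in, mdot_tl = mdot_tl, mdot_ex = mdot_ex, capped = capped)
  }

  rhs <- function(t, y, parms) {
    f <- flows_at(t - parms$t0, y[1], y[2], y[3], parms$phase)
    dp <- pressure_derivatives(
      y[1], y[2], f$mdot_in, f$mdot_tl, f$mdot_ex,
      tube, lung, gas
    )
    list(c(dp[[1]], dp[[2]], f$mdot_in / rho, f$mdot_in, f$mdot_ex))
  }
  cutoff_root <- function(t, y, parms) y[3] - vcv$tidal_volume

  integrate_segment <- function(y, t0, t1, phase, use_root = FALSE) {
    times <- seq(t0, t1, by = eng$dt_out)
    if (times[length(times)] < t1 - 1e-12) times <- c(times, t1)
    if (length(times) < 2) times <- c(t0, t1)
    args <- list(
      y = y, times = times, func = rhs,
      parms = list(phase = phase, t0 = t0),
      method = "lsodar", rtol = eng$rtol, atol = eng$atol
    )
    if (use_root) args$rootfunc <- cutoff_root
    out <- tryCatch(
      suppressWarnings(do.call(deSolve::ode, args)),
      error = function(e) {
        stop(sprintf(
          "integration failed in %s segment starting at t = %.4f s: %s",
          phase, t0, conditionMessage(e)
        ), call. = FALSE)
      }
    )
    m <- as.matrix(out)
    if (any(!is.finite(m[, 2:3])) || any(m[, 2:3] <= 0)) {
      bad <- which(!is.finite(m[, 2]) | m[, 2] <= 0 | !is.finite(m[, 3]) | m[, 3] <= 0)[1]
      stop(sprintf(
        "nonphysical pressure excursion at t = %.4f s (p_t = %g Pa, p_l = %g Pa)",
        m[bad, 1], m[bad, 2], m[bad, 3]
      ), call. = FALSE)
    }
    m
  }

  y <- c(
    p_t = gas$p_atm, p_l = gas$p_atm,
    delivered = 0, m_in = 0, m_ex = 0
  )
  m0 <- sum(stored_mass(y[1], y[2], tube, lung, gas))
  ti <- vcv$inspiratory_time
  tvo <- ti - vcv$plateau_time
  te <- vcv$exhaust_time
  seg_rows <- list()
  flow_limited <- FALSE

  for (cyc in seq_len(eng$n_cycles)) {
    tc0 <- (cyc - 1) * vcv$cycle_period
    y["delivered"] <- 0
    # inspiration, ended early if the volume cutoff roots first
    m <- integrate_segment(y, tc0, tc0 + tvo, "INSPIRATION", use_root = TRUE)
    t_cut <- m[nrow(m), 1]
    seg_rows[[length(seg_rows) + 1]] <- list(m = m, phase = "INSPIRATION", cycle = cyc, t0 = tc0)
    y <- m[nrow(m), 2:6]
    segs <- list(
      list(t0 = t_cut, t1 = tc0 + ti, phase = "PLATEAU"),
      list(t0 = tc0 + ti, t1 = tc0 + ti + te, phase = "EXPIRATION"),
      list(t0 = tc0 + ti + te, t1 = tc0 + vcv$cycle_period, phase = "REST")
    )
    for (s in segs) {
      if (s$t1 - s$t0 < 1e-9) next
      m <- integrate_segment(y, s$t0, s$t1, s$phase)
      seg_rows[[length(seg_rows) + 1]] <- list(m = m, phase = s$phase, cycle = cyc, t0 = s$t0)
      y <- m[nrow(m), 2:6]
    }
  }

  # assemble the waveform: half-open segments (boundary sample belongs to the
  # next segment), endpoint of the run kept
  n_seg <- length(seg_rows)
  pieces <- vector("list", n_seg)
  for (i in seq_len(n_seg)) {
    s <- seg_rows[[i]]
    m <- s$m
    keep <- if (i < n_seg) seq_len(max(nrow(m) - 1, 1)) else seq_len(nrow(m))
    mm <- m[keep, , drop = FALSE]
    t_seg <- mm[, 1] - s$t0
    f <- lapply(seq_len(nrow(mm)), function(j) {
      flows_at(t_seg[j], mm[j, 2], mm[j, 3], mm[j, 4], s$phase)
    })
    mdot_in <- vapply(f, `[[`, numeric(1), "mdot_in")
    mdot_ex <- vapply(f, `[[`, numeric(1), "mdot_ex")
    if (any(vapply(f, `[[`, logical(1), "capped"))) flow_limited <- TRUE
    pieces[[i]] <- tibble::tibble(
      time_s = mm[, 1],
      cycle = s$cycle,
      phase = s$phase,
      p_tube_cmH2O = convert_pressure(mm[, 2] - gas$p_atm, "Pa", "cmH2O"),
      p_lung_cmH2O = convert_pressure(mm[, 3] - gas$p_atm, "Pa", "cmH2O"),
      flow_insp_L_min = convert_flow(mdot_in / rho, "m3/s", "L/min"),
      flow_exh_L_min = convert_flow(mdot_ex / rho, "m3/s", "L/min"),
      v_lung_mL = convert_volume(lung_volume(mm[, 3], lung, gas), "m3", "mL")
    )
  }
  waveform <- dplyr::bind_rows(pieces)

  m1 <- sum(stored_mass(y[1], y[2], tube, lung, gas))
  net_in <- unname(y["m_in"] - y["m_ex"])
  throughput <- unname(y["m_in"] + y["m_ex"])
  residual_pct <- 100 * abs((m1 - m0) - net_in) / max(throughput, .Machine$double.eps)
  log <- c(
    sprintf(
      "mass balance: stored %+.6e kg, boundary net %+.6e kg, residual %.4f%% of throughput",
      m1 - m0, net_in, residual_pct
    ),
    if (flow_limited) "WARN flow-limited breath: supply orifice saturated below the set flow"
  )

  structure(
    list(
      waveform = waveform,
      scenario = scenario,
      mass = list(
        mass_in_kg = unname(y["m_in"]), mass_out_kg = unname(y["m_ex"]),
        stored_change_kg = m1 - m0, residual_pct = residual_pct
      ),
      flow_limited = flow_limited,
      log = log
    ),
    class = "vcv_sim"
  )
}

#' @export
print.vcv_sim <- function(x, ...) {
  cfg <- x$scenario$config
  cat(sprintf(
    "<vcv_sim: %d cycles of %g s, %d samples>\n",
    cfg$n_cycles, cfg$cycle_period, nrow(x$waveform)
  ))
  cat(" ", x$log[1], "\n")
  if (x$flow_limited) cat("  NOTE: flow-limited (supply orifice saturated)\n")
  invisible(x)
}

#' Locate a pressure plateau in a trace
#'
#' Finds the earliest maximal interval where the pressure slope stays within
#' `eps` for at least `tau` seconds. Absence is a valid result (zero-row
#' return); this is the "pressure platform" detector of the bench literature.
#'
#' @param time Sample times (s), strictly increasing.
#' @param pressure Pressure samples (any single unit; `eps` is in that unit
#'   per second).
#' @param eps Slope tolerance (pressure unit / s).
#' @param tau Minimum duration (s).
#' @return A tibble with zero rows (no plateau) or one row: `start`, `end`
#'   (s) and `pressure` (mean over the interval).
#' @export
detect_plateau <- function(time, pressure, eps = 0.5, tau = 0.2) {
  stopifnot(
    length(time) == length(pressure), length(time) >= 2,
    all(diff(time) > 0), eps > 0, tau > 0
  )
  empty <- tibble::tibble(start = numeric(), end = numeric(), pressure = numeric())
  slope <- diff(pressure) / diff(time)
  flat <- abs(slope) < eps
  r <- rle(flat)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    i0 <- idx_start[i]
    i1 <- idx_end[i] + 1 # interval i covers samples i..i+1
    if (time[i1] - time[i0] >= tau) {
      return(tibble::tibble(
        start = time[i0], end = time[i1],
        pressure = mean(pressure[i0:i1])
      ))
    }
  }
  empty
}

#' Per-breath ventilation metrics
#'
#' Segments the waveform by breath cycle and reports, per breath: peak and
#' plateau tube pressure (plateau via [detect_plateau()] over the
#' inspiration-to-expiration span, rest excluded since a closed circuit holds
#' pressure trivially constant), PEEP (tube pressure at end-expiration),
#' delivered volume (trapezoidal re-integration of the inspiratory flow
#' trace), and peak inspiratory/expiratory flows.
#'
#' @param x A `vcv_sim` or a waveform tibble with the columns produced by
#'   [simulate_vcv()] (including `cycle`).
#' @param eps,tau Plateau detector settings (cmH2O/s, s).
#' @return A tibble, one row per complete breath: `breath`, `peak_cmH2O`,
#'   `plateau_cmH2O` (NA when absent), `plateau_detected`, `peep_cmH2O`,
#'   `delivered_mL`, `peak_insp_flow_L_min`, `peak_exp_flow_L_min`.
#' @export
breath_metrics <- function(x, eps = 0.5, tau = 0.2) {
  wf <- if (inherits(x, "vcv_sim")) x$waveform else tibble::as_tibble(x)
  need <- c("time_s", "cycle", "phase", "p_tube_cmH2O", "flow_insp_L_min", "flow_exh_L_min")
  if (!all(need %in% names(wf))) {
    stop(
      "waveform lacks required columns: ",
      paste(setdiff(need, names(wf)), collapse = ", "),
      call. = FALSE
    )
  }
  complete <- wf |>
    dplyr::group_by(.data$cycle) |>
    dplyr::summarise(done = any(.data$phase == "EXPIRATION"), .groups = "drop") |>
    dplyr::filter(.data$done) |>
    dplyr::pull(.data$cycle)
  # a cycle is complete once its expiration has been simulated in full, i.e.
  # a later sample exists past the last expiratory sample of that cycle
  if (length(complete) > 0) {
    last_ok <- vapply(complete, function(cc) {
      t_exp_end <- max(wf$time_s[wf$cycle == cc & wf$phase == "EXPIRATION"])
      any(wf$time_s > t_exp_end)
    }, logical(1))
    complete <- complete[last_ok | complete < max(wf$cycle)]
  }
  if (length(complete) == 0) {
    stop(sprintf(
      "waveform contains no complete breath cycle (%d complete found)",
      length(complete)
    ), call. = FALSE)
  }
  trapz <- function(t, f) sum(diff(t) * (utils::head(f, -1) + utils::tail(f, -1)) / 2)
  purrr::map_dfr(complete, function(cc) {
    b <- wf[wf$cycle == cc, ]
    act <- b[b$phase != "REST", ]
    det <- detect_plateau(act$time_s, act$p_tube_cmH2O, eps = eps, tau = tau)
    exp_rows <- b[b$phase == "EXPIRATION", ]
    tibble::tibble(
      breath = cc,
      peak_cmH2O = max(b$p_tube_cmH2O),
      plateau_cmH2O = if (nrow(det) == 1) det$pressure else NA_real_,
      plateau_detected = nrow(det) == 1,
      peep_cmH2O = exp_rows$p_tube_cmH2O[nrow(exp_rows)],
      delivered_mL = trapz(b$time_s, b$flow_insp_L_min) * 1000 / 60,
      peak_insp_flow_L_min = max(b$flow_insp_L_min),
      peak_exp_flow_L_min = max(b$flow_exh_L_min)
    )
  })
}

#' Steady-state breath metrics after washout
#'
#' @param sim A `vcv_sim`.
#' @param washout Breaths to discard; defaults to the scenario's setting.
#' @inheritParams breath_metrics
#' @return One-row tibble: the metrics of the last complete breath after
#'   washout.
#' @export
steady_state_metrics <- function(sim, washout = NULL, eps = 0.5, tau = 0.2) {
  stopifnot(inherits(sim, "vcv_sim"))
  if (is.null(washout)) washout <- sim$scenario$engine$washout
  bm <- breath_metrics(sim, eps = eps, tau = tau)
  bm <- bm[bm$breath > washout, , drop = FALSE]
  if (nrow(bm) == 0) {
    stop("no complete breath after the washout period", call. = FALSE)
  }
  bm[nrow(bm), , drop = FALSE]
}

#' Write / read a waveform CSV
#'
#' Fixed column set and header:
#' `time_s,phase,p_tube_cmH2O,p_lung_cmH2O,flow_insp_L_min,flow_exh_L_min,v_lung_mL`.
#'
#' @param x A `vcv_sim` or waveform tibble.
#' @param path Output file.
#' @return The path (write) or a waveform tibble with a reconstructed `cycle`
#'   column (read).
#' @export
write_waveform_csv <- function(x, path) {
  wf <- if (inherits(x, "vcv_sim")) x$waveform else tibble::as_tibble(x)
  utils::write.csv(wf[, .wf_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @param cycle_period Cycle period (s) used to rebuild the `cycle` column.
#' @export
read_waveform_csv <- function(path, cycle_period = NULL) {
  wf <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!is.null(cycle_period)) {
    wf$cycle <- floor(wf$time_s / cycle_period + 1e-9) + 1
  } else {
    # new cycle wherever the phase steps back to inspiration
    insp_start <- wf$phase == "INSPIRATION" &
      c(TRUE, wf$phase[-nrow(wf)] != "INSPIRATION")
    wf$cycle <- cumsum(insp_start)
  }
  wf
}
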