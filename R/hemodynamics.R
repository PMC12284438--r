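#' Boundary layer thickness of oscillatory flow
#'
#' `delta = sqrt(nu T / 2 pi)`: the Stokes-layer scale used by the
#' friction term of the 1D momentum balance.
#'
#' @param nu Kinematic viscosity (cm^2/s).
#' @param T_cycle Cardiac cycle period (s).
#' @return Boundary layer thickness (cm).
#' @examples
#' boundary_layer_thickness(0.049, 0.5)  # 0.06245 cm
#' @export
boundary_layer_thickness <- function(nu, T_cycle) {
  stopifnot(nu >= 0, T_cycle > 0)
  sqrt(nu * T_cycle / (2 * pi))
}

#' Three-element Windkessel (RCR) outlet parameters
#'
#' @param R1 Proximal resistance (mmHg s/mL).
#' @param R2 Distal resistance (mmHg s/mL); defaults to `R1` (the two
#'   resistances are taken equal unless overridden).
#' @param Cd Distal compliance (mL/mmHg). The distal stiffness is
#'   `Sd = 1/Cd`. `Cd = Inf` (or `R2 = 0`) degenerates to a pure
#'   resistance.
#' @return Object of class `windkessel_params`.
#' @export
windkessel_params <- function(R1, R2 = R1, Cd) {
  stopifnot(R1 >= 0, R2 >= 0, Cd > 0)
  structure(list(R1 = R1, R2 = R2, Cd = Cd, Sd = 1 / Cd),
            class = "windkessel_params")
}

#' Lumped Windkessel pressure response to a flow waveform
#'
#' Integrates the RCR outlet ODE
#' `dP/dt = R1 dQ/dt + Q (R1 + R2)/(R2 Cd) - P/(R2 Cd)`
#' by implicit Euler over repeated cycles of the flow waveform and
#' returns the final cycle of pressure. This is the lumped model on its
#' own, without a vessel attached; it is used to initialize and to
#' cross-check the coupled simulation.
#'
#' @param flow A flow [waveform()] (mL/s).
#' @param wk A [windkessel_params()].
#' @param n_cycles Cycles to integrate (the transient decays with time
#'   constant `R2 Cd`).
#' @param P0 Initial pressure (mmHg).
#' @return A pressure [waveform()] (mmHg).
#' @export
windkessel_response <- function(flow, wk, n_cycles = 50, P0 = 0) {
  stopifnot(inherits(flow, "waveform"), inherits(wk, "windkessel_params"))
  n <- length(flow$time)
  dt <- flow$period / n
  q <- flow$values
  P <- P0
  k <- if (is.finite(wk$Cd) && wk$R2 > 0) dt / (wk$R2 * wk$Cd) else NA
  out <- numeric(n)
  for (cyc in seq_len(n_cycles)) {
    for (i in seq_len(n)) {
      qi <- q[i]
      qprev <- if (i == 1) q[n] else q[i - 1]
      if (is.na(k)) {
        P <- (wk$R1 + wk$R2) * qi
      } else {
        P <- (P + wk$R1 * (qi - qprev) + k * (wk$R1 + wk$R2) * qi) / (1 + k)
      }
      out[i] <- P
    }
  }
  waveform(flow$time, out, flow$period)
}

#' Simulation configuration for the 1D flow solver
#'
#' @param rho Blood density (g/cm^3).
#' @param nu Kinematic viscosity (cm^2/s).
#' @param cfl Courant number in (0, 1\] used to pick the time step.
#' @param dx_cm Target spatial step (cm); every segment gets at least
#'   `n_grid_min` points.
#' @param n_grid_min Minimum grid points per segment (>= 3).
#' @param n_out Output samples per cycle (sets the Nyquist limit of the
#'   impedance analysis; 512 samples of a 0.2 s cycle resolve 1280 Hz).
#' @param periodicity_tol Relative L2 change of the pressure field
#'   between successive cycles below which the run is periodic.
#' @param n_cycles_max Maximum cardiac cycles.
#' @param lambda_z Axial stretch of every vessel wall during the run.
#' @param tension_only Fiber tension-only switch of the wall model.
#' @param table_m,table_range Tube-law lookup resolution and area range
#'   (as multiples of the reference area).
#' @param eps_filter Strength of the conservative 2nd-difference filter
#'   that suppresses the odd-even grid mode (0 disables).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(rho = 1.055, nu = 0.046, cfl = 0.5, dx_cm = 0.1,
                       n_grid_min = 3, n_out = 512,
                       periodicity_tol = 1e-4, n_cycles_max = 60,
                       lambda_z = 1, tension_only = TRUE,
                       table_m = 400, table_range = c(0.2, 4),
                       eps_filter = 0) {
  stopifnot(rho > 0, nu > 0, cfl > 0, cfl <= 1, n_grid_min >= 3,
            periodicity_tol > 0, table_m >= 50,
            table_range[1] > 0, table_range[2] > table_range[1])
  structure(list(rho = rho, nu = nu, cfl = cfl, dx_cm = dx_cm,
                 n_grid_min = n_grid_min, n_out = n_out,
                 periodicity_tol = periodicity_tol,
                 n_cycles_max = n_cycles_max, lambda_z = lambda_z,
                 tension_only = tension_only, table_m = table_m,
                 table_range = table_range, eps_filter = eps_filter),
            class = "sim_config")
}

# cumulative trapezoid
.cumtrapz <- function(x, y) {
  c(0, cumsum(0.5 * (y[-1] + y[-length(y)]) * diff(x)))
}

# build SI lookup tables (P, dP/dA, B, I) for one segment. The table
# grid is aligned so the reference area is exactly a node (the fiber
# tension-only switch kinks the law there), and all derived quantities
# come from an 8x finer internal grid so the linear-interpolation slopes
# of P and B stay mutually consistent even where the law is strongly
# curved.
.tube_tables <- function(r0_cm, wall_ratio, params, config) {
  A0_cm2 <- pi * r0_cm^2
  m <- config$table_m
  dA_rel <- (config$table_range[2] - config$table_range[1]) / (m - 1)
  lo <- 1 - round((1 - config$table_range[1]) / dA_rel) * dA_rel
  a_rel <- lo + (seq_len(m) - 1L) * dA_rel
  refine <- 8L
  af_rel <- lo + (seq_len(refine * (m - 1L) + 1L) - 1L) * (dA_rel / refine)
  geom <- wall_geometry(r0_cm, wall_ratio * r0_cm)
  Pf <- transmural_pressure(af_rel * A0_cm2, geom, params,
                            lambda_z = config$lambda_z,
                            tension_only = config$tension_only) * .MMHG_PA
  Af <- af_rel * A0_cm2 * .CM2_M2             # m^2
  nf <- length(Af)
  dPf <- numeric(nf)
  dPf[-c(1, nf)] <- (Pf[-(1:2)] - Pf[1:(nf - 2)]) /
    (Af[-(1:2)] - Af[1:(nf - 2)])
  dPf[1] <- (Pf[2] - Pf[1]) / (Af[2] - Af[1])
  dPf[nf] <- (Pf[nf] - Pf[nf - 1]) / (Af[nf] - Af[nf - 1])
  if (any(dPf <= 0))
    stop("tube law is not monotone over the tabulated range")
  rho <- config$rho * 1000                    # g/cm^3 -> kg/m^3
  cwf <- sqrt(Af * dPf / rho)
  # B = (1/rho) int A dP, by parts: A P - int P dA. This uses only the
  # pressure values themselves, so the slope discontinuity at the
  # reference area (fiber tension-only switch) does not bias it.
  Bf <- (Af * Pf - Af[1] * Pf[1] - .cumtrapz(Af, Pf)) / rho
  If <- .cumtrapz(Af, cwf / Af)
  i0 <- which.min(abs(af_rel - 1))
  Bf <- Bf - Bf[i0]; If <- If - If[i0]        # arbitrary constants
  sel <- seq(1L, nf, by = refine)
  list(A = Af[sel], P = Pf[sel], dP = dPf[sel], B = Bf[sel], I = If[sel],
       Amin = Af[1], dA = Af[1 + refine] - Af[1], cmax = max(cwf))
}

#' Simulate pulsatile flow on a vascular tree
#'
#' Runs the 1D fluid--structure-interaction model to a periodic state:
#' mass and momentum conservation on every segment (two-step
#' Lax--Wendroff), continuity of pressure and flow at bifurcations,
#' a prescribed periodic inflow at the root, and three-element
#' Windkessel outlets at the terminals. Cycles repeat until the pressure
#' field changes by less than `periodicity_tol` (relative L2) between
#' cycles.
#'
#' @param tree A [vascular_tree()].
#' @param params An [ho_params()] for the vessel walls (apply
#'   [apply_stiffness_scaling()] beforehand to stiffen them).
#' @param inflow A flow [waveform()] (mL/s) imposed at the root.
#' @param wk Either a single [windkessel_params()] applied to every
#'   terminal, or a data.frame with columns
#'   `terminal_id, R1, R2, Cd` (mmHg s/mL, mL/mmHg).
#' @param config A [sim_config()].
#' @return Object of class `pa_simulation`: list with `time` (s, one
#'   cycle), per-segment fields `A` (cm^2), `Q` (mL/s), `P` (mmHg)
#'   (matrices grid x time), `converged`, `diagnostics`, `tree`,
#'   `period`.
#' @export
simulate_tree <- function(tree, params, inflow, wk, config = sim_config()) {
  stopifnot(inherits(tree, "vascular_tree"), inherits(params, "ho_params"),
            inherits(inflow, "waveform"), inherits(config, "sim_config"))
  seg <- tree$segments
  n_seg <- nrow(seg)
  idx <- stats::setNames(seq_len(n_seg), seg$id)

  # windkessel map
  R1 <- R2 <- Cd <- rep(-1, n_seg)
  if (inherits(wk, "windkessel_params")) {
    for (id in tree$terminals) {
      R1[idx[id]] <- wk$R1; R2[idx[id]] <- wk$R2; Cd[idx[id]] <- wk$Cd
    }
  } else {
    stopifnot(all(c("terminal_id", "R1", "R2", "Cd") %in% names(wk)))
    if (!setequal(wk$terminal_id, tree$terminals))
      stop("windkessel map must cover exactly the terminal segments")
    for (i in seq_len(nrow(wk))) {
      j <- idx[as.character(wk$terminal_id[i])]
      R1[j] <- wk$R1[i]; R2[j] <- wk$R2[i]; Cd[j] <- wk$Cd[i]
    }
  }
  # unit conversion (infinite compliance -> resistive flag Cd = -1)
  R1si <- ifelse(R1 >= 0, R1 * .R_SI, -1)
  R2si <- ifelse(R2 >= 0, R2 * .R_SI, -1)
  Cdsi <- ifelse(is.finite(Cd) & Cd > 0, Cd * .C_SI, -1)

  # children (exactly 2 or none)
  child1 <- child2 <- rep(-1L, n_seg)
  for (id in seg$id) {
    ch <- tree$children[[id]]
    if (length(ch) == 2) {
      child1[idx[id]] <- idx[ch[1]] - 1L
      child2[idx[id]] <- idx[ch[2]] - 1L
    }
  }

  # grids
  nn <- if (!is.null(seg$n_grid)) pmax(as.integer(seg$n_grid), config$n_grid_min)
        else pmax(config$n_grid_min,
                  as.integer(ceiling(seg$length_cm / config$dx_cm)) + 1L)
  dx <- seg$length_cm * .CM_M / (nn - 1)

  # tube-law tables
  tabs <- lapply(seq_len(n_seg), function(i)
    .tube_tables(seg$radius_cm[i], seg$wall_ratio[i], params, config))
  m <- config$table_m
  tab_P <- vapply(tabs, `[[`, numeric(m), "P")
  tab_dP <- vapply(tabs, `[[`, numeric(m), "dP")
  tab_B <- vapply(tabs, `[[`, numeric(m), "B")
  tab_I <- vapply(tabs, `[[`, numeric(m), "I")
  tab_Amin <- vapply(tabs, `[[`, numeric(1), "Amin")
  tab_dA <- vapply(tabs, `[[`, numeric(1), "dA")
  A0 <- pi * seg$radius_cm^2 * .CM2_M2

  T_ <- inflow$period
  qin <- inflow$values * .ML_M3                      # m^3/s
  rho <- config$rho * 1000                           # kg/m^3
  nu <- config$nu * 1e-4                             # m^2/s
  delta <- sqrt(nu * T_ / (2 * pi))
  fric0 <- 2 * pi * nu / delta

  # time step from the CFL bound: wave speed from the tables over the
  # expected working range, advective velocity from splitting the peak
  # inflow down the tree in proportion to lumen area
  q_est <- stats::setNames(rep(NA_real_, n_seg), seg$id)
  q_est[tree$root] <- max(abs(qin))
  for (id in seg$id[order(seg$generation)]) {
    ch <- tree$children[[id]]
    if (length(ch) == 2) {
      a12 <- A0[idx[ch]]
      q_est[ch] <- 1.3 * q_est[id] * a12 / sum(a12)
    }
  }
  speed <- vapply(seq_len(n_seg), function(i) {
    sel <- tabs[[i]]$A >= 0.7 * A0[i] & tabs[[i]]$A <= 1.8 * A0[i]
    max(sqrt(tabs[[i]]$A[sel] * tabs[[i]]$dP[sel] / rho)) +
      q_est[i] / (0.8 * A0[i])
  }, numeric(1))
  dt_req <- config$cfl * min(dx / speed)
  n_steps <- as.integer(config$n_out *
                          ceiling(T_ / (dt_req * config$n_out)))

  run <- function(n_steps) .solve_tree_cpp(
    nn = as.integer(nn), dx = dx,
    child1 = as.integer(child1), child2 = as.integer(child2),
    root = idx[tree$root] - 1L,
    tab_Amin = tab_Amin, tab_dA = tab_dA,
    tab_P = tab_P, tab_dP = tab_dP, tab_B = tab_B, tab_I = tab_I,
    A0 = A0, qin = qin, T = T_,
    R1 = R1si, R2 = R2si, Cd = Cdsi,
    rho = rho, fric0 = fric0,
    n_steps = n_steps, n_out = config$n_out,
    n_cycles_max = config$n_cycles_max, tol = config$periodicity_tol,
    eps_filter = config$eps_filter)
  res <- NULL
  for (try in 1:3) {
    res <- tryCatch(run(n_steps), error = function(e) {
      if (grepl("CFL", conditionMessage(e)) && try < 3) NULL else stop(e)
    })
    if (!is.null(res)) break
    n_steps <- 2L * n_steps      # halve dt and retry
  }

  if (isTRUE(res$table_clamped))
    warning("tube-law table range was clamped during the run; ",
            "consider widening table_range")

  off <- res$offsets
  n_out <- config$n_out
  # recorded sample k is at t = k * T/n_out for k = 1..n_out; rotate so
  # the returned grid starts at t = 0 (= t = T by periodicity)
  rot <- c(n_out, seq_len(n_out - 1L))
  fields <- lapply(seq_len(n_seg), function(i) {
    rows <- (off[i] + 1L):off[i + 1L]
    list(A = res$A[rows, rot, drop = FALSE] / .CM2_M2,
         Q = res$Q[rows, rot, drop = FALSE] / .ML_M3,
         P = res$P[rows, rot, drop = FALSE] / .MMHG_PA)
  })
  names(fields) <- seg$id
  structure(list(
    time = seq(0, T_, length.out = n_out + 1L)[seq_len(n_out)],
    period = T_, fields = fields, converged = res$converged,
    diagnostics = list(n_cycles = res$n_cycles,
                       cycle_resid = res$cycle_resid,
                       max_mass_defect_ml_s = res$max_mass_defect / .ML_M3,
                       max_cfl = res$max_cfl, n_steps = n_steps),
    tree = tree, config = config),
    class = "pa_simulation")
}

#' @export
print.pa_simulation <- function(x, ...) {
  root <- x$tree$root
  P <- x$fields[[root]]$P[1, ]
  cat(sprintf(
    "1D FSI simulation: %d segments, %d cycles (%s), MPA %.1f/%.1f mmHg\n",
    length(x$fields), x$diagnostics$n_cycles,
    if (x$converged) "periodic" else "NOT periodic",
    max(P), min(P)))
  invisible(x)
}

#' Extract pressure and flow waveforms at a station
#'
#' @param result A `pa_simulation` from [simulate_tree()].
#' @param segment_id Segment to sample (default: the root, i.e. the MPA).
#' @param position `"proximal"`, `"mid"` or `"distal"` station along the
#'   segment.
#' @return List with `P` (mmHg) and `Q` (mL/s) [waveform()]s.
#' @export
extract_waveforms <- function(result, segment_id = result$tree$root,
                              position = c("proximal", "mid", "distal")) {
  position <- match.arg(position)
  segment_id <- as.character(segment_id)
  if (!segment_id %in% names(result$fields))
    stop("unknown segment id: ", segment_id)
  f <- result$fields[[segment_id]]
  n <- nrow(f$P)
  j <- switch(position, proximal = 1L, mid = as.integer(ceiling(n / 2)),
              distal = n)
  list(P = waveform(result$time, f$P[j, ], result$period),
       Q = waveform(result$time, f$Q[j, ], result$period))
}

#' Read / write a Windkessel terminal map as CSV
#'
#' Columns: `terminal_id,R1,R2,Cd` (mmHg s/mL and mL/mmHg).
#' @param path File path.
#' @return data.frame.
#' @export
read_windkessel_csv <- function(path) {
  d <- utils::read.csv(path, colClasses = c(terminal_id = "character"))
  stopifnot(all(c("terminal_id", "R1", "R2", "Cd") %in% names(d)))
  d
}

#' @rdname read_windkessel_csv
#' @param wk_map data.frame with `terminal_id,R1,R2,Cd`.
#' @export
write_windkessel_csv <- function(wk_map, path) {
  utils::write.csv(wk_map[, c("terminal_id", "R1", "R2", "Cd")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Export the station waveforms of a simulation as a flat CSV
#'
#' One row per (segment, station, time): columns `segment_id`,
#' `position`, `time_s`, `P_mmHg`, `Q_ml_s`, `A_cm2`.
#' @param result A `pa_simulation`.
#' @param path Output path.
#' @param positions Stations to export.
#' @export
write_simulation_csv <- function(result, path,
                                 positions = c("proximal", "mid", "distal")) {
  rows <- list()
  for (id in names(result$fields)) {
    f <- result$fields[[id]]
    n <- nrow(f$P)
    for (pos in positions) {
      j <- switch(pos, proximal = 1L, mid = as.integer(ceiling(n / 2)),
                  distal = n)
      rows[[length(rows) + 1L]] <- data.frame(
        segment_id = id, position = pos, time_s = result$time,
        P_mmHg = f$P[j, ], Q_ml_s = f$Q[j, ], A_cm2 = f$A[j, ])
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
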