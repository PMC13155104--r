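#' Zero-order oxygen depletion time
#'
#' Closed-form time for a water parcel to go anoxic when respiration is
#' zero-order and diffusion is ignored:
#' `t = 1000 * initial_o2 / respiration` (the factor converts uM to nmol/L).
#'
#' @param initial_o2 Initial dissolved O2, uM.
#' @param respiration Volumetric respiration rate, nmol O2 L^-1 h^-1.
#' @return Hours to anoxia; `Inf` when `respiration = 0` (never).
#' @examples
#' depletion_time(14, 400)   # 35 h
#' @export
depletion_time <- function(initial_o2, respiration) {
  stopifnot(initial_o2 >= 0, respiration >= 0)
  if (respiration == 0) return(Inf)
  1000 * initial_o2 / respiration
}

#' Incubation-bottle oxygen diffusion-respiration model
#'
#' Solves the 1-D reaction-diffusion equation
#' `dC/dt = D d2C/dz2 - R` on an unstirred water column beneath an air
#' headspace: Dirichlet air-equilibrium boundary at the surface
#' (`C(0, t) = surface_o2` for t > 0), no-flux bottom, and zero-order
#' respiration that switches off where the water is anoxic (C clamped at 0).
#' Explicit finite differences with the time step chosen to satisfy
#' `D dt / dz^2 <= 0.5`; a user-requested unstable `dt` is refined with a
#' warning. A per-step mass budget (boundary flux minus integrated
#' respiration) is accumulated as a diagnostic.
#'
#' @param column_height Water column depth, cm.
#' @param initial_o2 Initial O2 throughout the column, uM.
#' @param surface_o2 Air-equilibrium O2 at the headspace interface, uM.
#' @param diffusivity Molecular O2 diffusivity, cm^2/s.
#' @param respiration Zero-order respiration, nmol O2 L^-1 h^-1
#'   (sane band 0--1e4).
#' @param hypoxia_threshold Hypoxia threshold, uM (63 uM is the conventional
#'   definition).
#' @param duration Simulated time, h.
#' @param grid_dz Spatial step, cm (must be < column_height / 10).
#' @param dt Optional time step, h; default auto from the stability limit.
#' @param save_every Snapshot interval, h.
#' @param headspace_ml Headspace volume, mL (documentation only; the
#'   headspace is treated as an infinite air reservoir).
#'
#' @return Object of class `bottle_o2`: list with `times` (h), `depths`
#'   (cm, 0 = interface), `conc` (time x depth matrix, uM), `params`, and
#'   mass-budget diagnostics (`mass_error`, `clamped`).
#' @seealso [hypoxic_volume_fraction()], [depletion_time()]
#' @export
bottle_o2 <- function(column_height = 12, initial_o2 = 14, surface_o2 = 350,
                      diffusivity = 1.3e-5, respiration = 400,
                      hypoxia_threshold = 63, duration = 48,
                      grid_dz = 0.1, dt = NULL, save_every = 0.25,
                      headspace_ml = 160) {
  if (any(c(column_height, initial_o2, surface_o2, diffusivity, respiration,
            hypoxia_threshold, duration, grid_dz) < 0))
    stop("all parameters must be non-negative")
  if (respiration > 1e4) stop("respiration outside the sane band [0, 1e4]")
  if (grid_dz >= column_height / 10)
    stop("grid_dz must be < column_height / 10")

  Dh <- diffusivity * 3600        # cm^2/h
  Rh <- respiration / 1000        # uM/h
  nz <- as.integer(round(column_height / grid_dz)) + 1L
  depths <- seq(0, column_height, length.out = nz)
  dz <- depths[2L] - depths[1L]

  dt_stable <- if (Dh > 0) 0.4 * dz^2 / Dh else save_every
  if (is.null(dt)) {
    dt <- dt_stable
  } else if (Dh > 0 && Dh * dt / dz^2 > 0.5) {
    warning(sprintf("requested dt = %g h is unstable; refined to %g h",
                    dt, dt_stable))
    dt <- dt_stable
  }
  nsteps <- max(1L, ceiling(duration / dt))
  dt <- duration / nsteps
  lam <- Dh * dt / dz^2

  save_times <- unique(c(seq(0, duration, by = save_every), duration))
  conc <- matrix(NA_real_, length(save_times), nz,
                 dimnames = list(NULL, NULL))
  C <- rep(initial_o2, nz)
  conc[1L, ] <- C

  mass_err_max <- 0
  clamped <- FALSE
  t_now <- 0
  save_i <- 2L
  for (s in seq_len(nsteps)) {
    Cb <- C
    Cb[1L] <- surface_o2                    # Dirichlet top from t > 0
    lap <- c(0,
             Cb[3L:nz] - 2 * Cb[2L:(nz - 1L)] + Cb[1L:(nz - 2L)],
             2 * (Cb[nz - 1L] - Cb[nz]))    # no-flux bottom (mirror)
    resp <- dt * Rh * (Cb > 0)
    Cn <- Cb + lam * lap - resp
    if (any(Cn < 0)) { clamped <- TRUE; Cn[Cn < 0] <- 0 }
    Cn[1L] <- surface_o2

    # mass budget over interior+bottom nodes (trapezoid weights)
    w <- c(0.5, rep(1, nz - 2L), 0.5) * dz
    flux_in <- Dh * (Cb[1L] - Cb[2L]) / dz * dt     # through the interface
    dmass <- sum(w[-1L] * (Cn[-1L] - Cb[-1L]))
    budget <- flux_in - sum(w[-1L] * resp[-1L])
    if (!clamped && abs(budget) > 1e-12) {
      rel <- abs(dmass - budget) / max(abs(budget), 1e-9)
      mass_err_max <- max(mass_err_max, rel)
    }
    C <- Cn
    t_now <- t_now + dt
    while (save_i <= length(save_times) &&
           save_times[save_i] <= t_now + 1e-9) {
      conc[save_i, ] <- C
      save_i <- save_i + 1L
    }
  }

  structure(
    list(times = save_times, depths = depths, conc = conc,
         params = list(column_height = column_height, initial_o2 = initial_o2,
                       surface_o2 = surface_o2, diffusivity = diffusivity,
                       respiration = respiration,
                       hypoxia_threshold = hypoxia_threshold,
                       duration = duration, grid_dz = dz, dt = dt,
                       headspace_ml = headspace_ml),
         mass_error = mass_err_max, clamped = clamped),
    class = "bottle_o2")
}

#' Fraction of the water column below an oxygen threshold
#'
#' Trapezoidal depth integration of the indicator `C(z, t) < threshold`
#' over the column (uniform cross-section), i.e. the volume fraction of
#' hypoxic water at time `t`.
#'
#' @param profile A [bottle_o2()] result.
#' @param t Time, h; must lie within the simulated range (nearest saved
#'   snapshot is used).
#' @param threshold O2 threshold, uM; defaults to the model's
#'   `hypoxia_threshold`.
#' @return Volume fraction in \[0, 1\].
#' @export
hypoxic_volume_fraction <- function(profile, t,
                                    threshold = profile$params$hypoxia_threshold) {
  stopifnot(inherits(profile, "bottle_o2"))
  if (t < min(profile$times) - 1e-9 || t > max(profile$times) + 1e-9)
    stop("t outside the simulated time range")
  i <- which.min(abs(profile$times - t))
  ind <- as.numeric(profile$conc[i, ] < threshold)
  nz <- length(ind)
  w <- c(0.5, rep(1, nz - 2L), 0.5)
  sum(w * ind) / sum(w)
}

#' @export
print.bottle_o2 <- function(x, ...) {
  p <- x$params
  cat(sprintf("Bottle O2 model: %g cm column, D = %g cm2/s, R = %g nmol/L/h\n",
              p$column_height, p$diffusivity, p$respiration))
  cat(sprintf("  initial %g uM, surface %g uM, %g h simulated (dz = %g cm)\n",
              p$initial_o2, p$surface_o2, p$duration, p$grid_dz))
  frac <- hypoxic_volume_fraction(x, p$duration)
  cat(sprintf("  hypoxic (< %g uM) volume fraction at %g h: %.3f\n",
              p$hypoxia_threshold, p$duration, frac))
  if (x$clamped) cat("  note: anoxia reached somewhere in the column\n")
  invisible(x)
}

#' Plot oxygen depth profiles over time
#'
#' @param x A [bottle_o2()] result.
#' @param times Times (h) at which to draw profiles.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.bottle_o2 <- function(x, times = pretty(x$times, 5), ...) {
  idx <- unique(vapply(times, function(t) which.min(abs(x$times - t)), 1L))
  graphics::matplot(t(x$conc[idx, , drop = FALSE]), -x$depths, type = "l",
                    lty = 1, xlab = expression(O[2] ~ (mu * M)),
                    ylab = "depth below interface (cm)", ...)
  graphics::abline(v = x$params$hypoxia_threshold, lty = 2)
  graphics::legend("bottomright", legend = sprintf("%g h", x$times[idx]),
                   lty = 1, col = seq_along(idx), cex = 0.8)
  invisible(x)
}
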