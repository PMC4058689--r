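# R-level driver for the axisymmetric steady Navier-Stokes core: domain
# padding, spline wall representation, Reynolds guard, field container,
# recirculation metrics and field export.

#' Solve steady axisymmetric flow through a (possibly stenosed) tube
#'
#' Streamfunction-vorticity finite-difference solution of the steady
#' incompressible Navier-Stokes equations in an axisymmetric tube whose
#' wall radius follows the supplied diameter profile. The inflow is a
#' prescribed parabolic profile carrying `Q`; the wall is rigid with
#' no-slip; the outflow is zero-gradient with the outlet pressure pinned
#' at zero. The domain is padded with straight tube upstream and
#' downstream (defaults 3 and 10 local diameters) so the outflow boundary
#' does not clip the recirculation zone. Cross-sectional flux is conserved
#' identically by the streamfunction formulation.
#'
#' @param profile two-column matrix of `(s_mm, d_mm)` samples (or a
#'   [vessel_segment()]), interpolated with a natural cubic spline (the
#'   wall must be smooth for the mapped metric terms).
#' @param Q_m3s volumetric flow (m^3/s, > 0).
#' @param fluid a [fluid_properties()].
#' @param grid list overriding `nr` (radial intervals, default 32; >= 8),
#'   `nz` (axial intervals, default 256; >= 8), `pad_up`, `pad_down`
#'   (padding lengths in local diameters, defaults 3 and 10).
#' @param numerics list overriding `tol` (scaled residual, default 1e-6),
#'   `max_outer` (default 20000), `beta_omega`, `beta_wall` (vorticity and
#'   wall-vorticity underrelaxation, defaults 0.7 / 0.3), `sor_psi`
#'   (streamfunction SOR factor, default 1.6), `psi_sweeps` (default 4),
#'   `central_weight` (deferred-correction weight toward central
#'   convection, default 0.9), `re_max` (laminar Reynolds cap on the throat
#'   diameter, default 2000).
#' @return Object of class `axisym_field`: grid vectors (`z_m`, `eta`,
#'   `radius_m`), node fields (`psi`, `omega`, `uz`, `ur`), `p_axis_pa`,
#'   `wall_shear_pa`, the inlet-to-outlet pressure drop `dp` (Pa),
#'   `converged`, `iterations`, `residual`, `residual_history` and the
#'   mapping offset `s0_mm` back to profile arclength. A non-converged
#'   solve is returned flagged, never silently.
#' @export
solve_axisym <- function(profile, Q_m3s, fluid = fluid_properties(),
                         grid = list(), numerics = list()) {
  if (inherits(profile, "vessel_segment")) profile <- profile$profile
  profile <- as.matrix(profile)
  if (Q_m3s <= 0) stop("Q must be > 0", call. = FALSE)
  g <- utils::modifyList(list(nr = 32L, nz = 256L, pad_up = 3, pad_down = 10),
                         grid)
  nm <- utils::modifyList(list(tol = 1e-6, max_outer = 20000L,
                               beta_omega = 0.7, beta_wall = 0.3,
                               sor_psi = 1.6, psi_sweeps = 4L,
                               central_weight = 0.9, re_max = 2000),
                          numerics)
  if (g$nr < 8L || g$nz < 8L) stop("nz and nr must be >= 8", call. = FALSE)
  d_min <- min(profile[, 2L])
  re <- 4 * fluid$rho * Q_m3s / (pi * fluid$mu * mm_to_m(d_min))
  if (re > nm$re_max) {
    stop(sprintf("throat Reynolds number %.0f exceeds the laminar cap %.0f",
                 re, nm$re_max), call. = FALSE)
  }
  s <- profile[, 1L]
  d0 <- profile[1L, 2L]; dL <- profile[nrow(profile), 2L]
  pad_up <- g$pad_up * d0
  pad_down <- g$pad_down * dL
  s_aug <- c(s[1L] - pad_up, s[1L] - pad_up / 2, s,
             s[length(s)] + pad_down / 2, s[length(s)] + pad_down)
  d_aug <- c(d0, d0, profile[, 2L], dL, dL)
  rfun <- splinefun(mm_to_m(s_aug), mm_to_m(d_aug) / 2, method = "natural")
  z <- seq(mm_to_m(s[1L] - pad_up), mm_to_m(s[length(s)] + pad_down),
           length.out = g$nz + 1L)
  Rw <- rfun(z); Rp <- rfun(z, deriv = 1); Rpp <- rfun(z, deriv = 2)
  if (any(Rw <= 0)) stop("wall radius must be positive everywhere", call. = FALSE)
  core <- axisym_core(z, Rw, Rp, Rpp, as.integer(g$nr), Q_m3s,
                      fluid$rho, fluid$mu, nm$tol, as.integer(nm$max_outer),
                      nm$beta_omega, nm$beta_wall, nm$sor_psi,
                      as.integer(nm$psi_sweeps), nm$central_weight)
  structure(list(z_m = z, eta = seq(0, 1, length.out = g$nr + 1L),
                 radius_m = Rw, s0_mm = s[1L] - pad_up,
                 psi = core$psi, omega = core$omega,
                 uz = core$uz, ur = core$ur,
                 p_axis_pa = core$p_axis, wall_shear_pa = core$wall_shear,
                 dp = core$dp, converged = core$converged,
                 iterations = core$iterations, residual = core$residual,
                 residual_history = core$residual_history,
                 Q_m3s = Q_m3s, reynolds = re, fluid = fluid),
            class = "axisym_field")
}

#' @export
print.axisym_field <- function(x, ...) {
  cat(sprintf("<axisym_field> %d x %d nodes, Re = %.0f, %s (%d iterations)\n",
              length(x$z_m), length(x$eta), x$reynolds,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat(sprintf("  dP = %.4g Pa (%.3f mmHg) over %.1f mm\n",
              x$dp, pa_to_mmhg(x$dp), m_to_mm(diff(range(x$z_m)))))
  invisible(x)
}

# volumetric flux 2 pi int u_z r dr through axial station i (Simpson on the
# uniform eta grid; falls back to trapezoid for an odd interval count)
axisym_flux <- function(field, i) {
  r <- field$eta * field$radius_m[i]
  f <- field$uz[i, ] * r
  n <- length(r) - 1L
  h <- r[2L] - r[1L]
  if (n %% 2L == 0L) {
    s <- f[1L] + f[n + 1L] + 4 * sum(f[seq(2L, n, by = 2L)]) +
      2 * sum(f[seq(3L, n - 1L, by = 2L)])
    2 * pi * s * h / 3
  } else {
    2 * pi * sum(diff(r) * (head(f, -1) + tail(f, -1)) / 2)
  }
}

#' Recirculation metrics of an axisymmetric field
#'
#' The reattachment point is the first wall location downstream of the
#' throat where the wall shear changes sign from negative to positive; the
#' reattachment length is its distance from the throat. The reversed-flow
#' area is the meridional-plane area where the axial velocity is negative.
#' Both metrics are zero when no reversed flow exists (e.g. a straight
#' tube).
#'
#' @param field a converged [solve_axisym()] result.
#' @return Named numeric vector `c(reattachment_mm, reversed_area_mm2)`.
#' @export
recirculation_metrics <- function(field) {
  stopifnot(inherits(field, "axisym_field"))
  if (!field$converged) {
    stop("recirculation metrics require a converged field", call. = FALSE)
  }
  i_throat <- which.min(field$radius_m)
  tau <- field$wall_shear_pa
  z <- field$z_m
  reatt <- 0
  down <- seq(i_throat, length(z) - 1L)
  neg <- down[tau[down] < 0]
  if (length(neg)) {
    k <- neg[1L]
    m <- k
    while (m < length(z) && tau[m + 1L] < 0) m <- m + 1L
    if (m < length(z)) {
      frac <- tau[m] / (tau[m] - tau[m + 1L])
      z_re <- z[m] + frac * (z[m + 1L] - z[m])
    } else {
      z_re <- z[m]
    }
    reatt <- m_to_mm(z_re - z[i_throat])
  }
  dz <- diff(z)[1L]
  deta <- diff(field$eta)[1L]
  cell <- outer(rep(dz, length(z)), rep(deta, length(field$eta))) *
    field$radius_m
  area <- sum(cell[field$uz < 0]) * 1e6
  c(reattachment_mm = reatt, reversed_area_mm2 = area)
}

#' Export an axisymmetric field
#'
#' `format = "vtk"` writes a legacy-VTK structured grid with `uz`, `ur`,
#' `psi` and `vorticity` point arrays; `format = "wall_shear_csv"` writes
#' the wall shear versus axial position.
#'
#' @param field an `axisym_field`.
#' @param path output path.
#' @param format `"vtk"` or `"wall_shear_csv"`.
#' @return `path`, invisibly.
#' @export
export_axisym_field <- function(field, path,
                                format = c("vtk", "wall_shear_csv")) {
  format <- match.arg(format)
  if (format == "wall_shear_csv") {
    write.csv(data.frame(z_mm = m_to_mm(field$z_m),
                         wall_shear_pa = field$wall_shear_pa),
              path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  nz1 <- length(field$z_m); nr1 <- length(field$eta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "axisymmetric field", "ASCII",
               "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", nz1, nr1),
               sprintf("POINTS %d float", nz1 * nr1)), con)
  for (j in seq_len(nr1)) {
    writeLines(sprintf("%.9g %.9g 0", field$z_m,
                       field$eta[j] * field$radius_m), con)
  }
  writeLines(sprintf("POINT_DATA %d", nz1 * nr1), con)
  for (nmfield in c("uz", "ur", "psi", "omega")) {
    writeLines(c(sprintf("SCALARS %s float 1", nmfield),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", as.vector(field[[nmfield]])), con)
  }
  invisible(path)
}
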