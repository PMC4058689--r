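# Algebraic pressure-drop laws for vessel segments. A law is
# dP(Q) = a_v * Q + a_t * Q * |Q| with a_v the integrated Poiseuille
# coefficient and a_t a separation/expansion-loss coefficient that is zero
# for stenosis-free segments.

#' Blood fluid properties
#'
#' @param rho density (kg/m^3); default 1060, typical of blood in large
#'   epicardial arteries.
#' @param mu dynamic viscosity (Pa s); default 4.5e-3 (Newtonian
#'   approximation, justified for vessels above 1 mm diameter).
#' @return List of class `fluid_properties`.
#' @export
fluid_properties <- function(rho = 1060, mu = 4.5e-3) {
  if (rho <= 0 || mu <= 0) stop("fluid properties must be positive", call. = FALSE)
  structure(list(rho = rho, mu = mu), class = "fluid_properties")
}

#' Construct a segment pressure-drop law
#'
#' @param a_v linear (viscous) coefficient, Pa s/m^3 (> 0).
#' @param a_t quadratic (expansion-loss) coefficient, Pa s^2/m^6 (>= 0).
#' @param provenance one of `"poiseuille"`, `"stenosis_algebraic"`,
#'   `"axisym_tabulated"`.
#' @return Object of class `segment_law`.
#' @export
segment_law <- function(a_v, a_t = 0,
                        provenance = c("poiseuille", "stenosis_algebraic",
                                       "axisym_tabulated")) {
  provenance <- match.arg(provenance)
  if (a_v <= 0) stop("a_v must be > 0", call. = FALSE)
  if (a_t < 0) stop("a_t must be >= 0", call. = FALSE)
  if (provenance == "poiseuille" && a_t != 0) {
    stop("a_t must be 0 for stenosis-free (poiseuille) segments", call. = FALSE)
  }
  structure(list(a_v = a_v, a_t = a_t, provenance = provenance),
            class = "segment_law")
}

#' @export
print.segment_law <- function(x, ...) {
  cat(sprintf("<segment_law> %s: a_v = %.4g Pa s/m^3, a_t = %.4g Pa s^2/m^6\n",
              x$provenance, x$a_v, x$a_t))
  invisible(x)
}

#' Evaluate or invert a segment law
#'
#' `law_dp` gives the signed pressure drop `a_v Q + a_t Q |Q|` (Pa) for a
#' signed flow (m^3/s); `law_flow` inverts it in closed form. Both are odd
#' functions, so reverse flow is handled consistently.
#'
#' @param law a [segment_law()].
#' @param Q signed flow, m^3/s.
#' @param dp signed pressure drop, Pa.
#' @return Numeric vector (Pa for `law_dp`, m^3/s for `law_flow`).
#' @export
law_dp <- function(law, Q) law$a_v * Q + law$a_t * Q * abs(Q)

#' @rdname law_dp
#' @export
law_flow <- function(law, dp) {
  if (law$a_t == 0) return(dp / law$a_v)
  sign(dp) * (-law$a_v + sqrt(law$a_v^2 + 4 * law$a_t * abs(dp))) /
    (2 * law$a_t)
}

# dQ/d(dp): used by the network Newton iteration
law_dq_ddp <- function(law, Q) 1 / (law$a_v + 2 * law$a_t * abs(Q))

# composite-trapezoid integral of 128 mu / (pi d(s)^4) over a (sub)profile.
# The throat dominates through d^-4, so the profile is refined to at least
# `min_points` samples before quadrature.
poiseuille_coefficient <- function(profile, fluid, s_from = NULL, s_to = NULL,
                                   min_points = 400L) {
  s <- profile[, 1L]; d <- profile[, 2L]
  if (is.null(s_from)) s_from <- s[1L]
  if (is.null(s_to)) s_to <- s[length(s)]
  if (s_to <= s_from) return(0)
  grid <- sort(unique(c(s[s >= s_from & s <= s_to],
                        seq(s_from, s_to, length.out = min_points))))
  dg <- approx(s, d, xout = grid, rule = 2)$y
  integrand <- 128 * fluid$mu / (pi * mm_to_m(dg)^4)
  sum(diff(mm_to_m(grid)) * (head(integrand, -1) + tail(integrand, -1)) / 2)
}

#' Integrated Poiseuille law for a vessel segment
#'
#' `a_v = integral over s of 128 mu / (pi d(s)^4)` by composite trapezoid on
#' the (refined) sampled profile; `a_t = 0`.
#'
#' @param segment a [vessel_segment()].
#' @param fluid a [fluid_properties()].
#' @return A [segment_law()] with provenance `"poiseuille"`.
#' @examples
#' seg <- vessel_segment("tube", 10, c(3, 3))
#' poiseuille_law(seg, fluid_properties())  # a_v ~ 2.26e7 Pa s/m^3
#' @export
poiseuille_law <- function(segment, fluid = fluid_properties()) {
  segment_law(poiseuille_coefficient(segment$profile, fluid),
              0, "poiseuille")
}

#' Algebraic viscous + expansion-loss law for a stenosed segment
#'
#' The viscous coefficient integrates Poiseuille resistance over the
#' narrowed profile; the quadratic coefficient models the separation /
#' expansion loss downstream of the throat as
#' `a_t = Kt * (rho/2) * (1/A_throat - 1/A_normal)^2`
#' (an empirical loss form in the Young--Tsai family), so
#' `dP(Q) = a_v Q + a_t Q |Q|`.
#'
#' @param segment the narrowed [vessel_segment()] (i.e. the trunk after
#'   [insert_stenosis()]).
#' @param spec the [stenosis_spec()] that produced it.
#' @param fluid a [fluid_properties()].
#' @param Kt expansion-loss coefficient (> 0); default 1.52.
#' @return A [segment_law()]; for `ds = 0` the quadratic term vanishes and
#'   the law reduces exactly to [poiseuille_law()].
#' @export
stenosis_law <- function(segment, spec, fluid = fluid_properties(), Kt = 1.52) {
  stopifnot(inherits(spec, "stenosis_spec"))
  if (Kt <= 0) stop("Kt must be > 0", call. = FALSE)
  a_v <- poiseuille_coefficient(segment$profile, fluid)
  if (spec$ds == 0) {
    return(segment_law(a_v, 0, "poiseuille"))
  }
  d_throat <- mm_to_m(segment_diameter(segment, spec$center_s_mm))
  d_normal <- d_throat / (1 - spec$ds)
  A_s <- pi * d_throat^2 / 4
  A_0 <- pi * d_normal^2 / 4
  a_t <- Kt * (fluid$rho / 2) * (1 / A_s - 1 / A_0)^2
  segment_law(a_v, a_t, "stenosis_algebraic")
}

#' Fit a segment law to axisymmetric solver samples
#'
#' Runs the axisymmetric Navier-Stokes solver at each flow in `flow_grid`,
#' then least-squares fits `dP = a_v Q + a_t Q^2` through the origin with
#' `a_t` clamped at >= 0. This tabulated law is the high-fidelity backend
#' for stenosed segments.
#'
#' @param segment a [vessel_segment()] (typically narrowed).
#' @param fluid a [fluid_properties()].
#' @param flow_grid at least 3 distinct positive flows (m^3/s).
#' @param ... passed to [solve_axisym()] (grid and numerics control).
#' @return A [segment_law()] with provenance `"axisym_tabulated"`;
#'   attributes `samples` (data.frame of Q, dP) and `residual_rel` (max
#'   fit residual relative to the largest sampled drop).
#' @export
tabulate_from_axisym <- function(segment, fluid = fluid_properties(),
                                 flow_grid, ...) {
  flow_grid <- sort(unique(flow_grid))
  if (length(flow_grid) < 3L || any(flow_grid <= 0)) {
    stop("flow_grid must contain at least 3 distinct positive flows (fit is underdetermined otherwise)",
         call. = FALSE)
  }
  prof <- segment$profile
  dp <- vapply(flow_grid, function(Q) {
    f <- solve_axisym(prof, Q, fluid = fluid, ...)
    if (!f$converged) {
      stop(sprintf("axisymmetric solve did not converge at Q = %.4g m^3/s", Q),
           call. = FALSE)
    }
    # remove the straight-tube padding drop so the law covers the segment only
    pad_len <- m_to_mm(diff(range(f$z_m))) - diff(range(prof[, 1L]))
    d0 <- prof[1L, 2L]; dL <- prof[nrow(prof), 2L]
    pad_av <- 128 * fluid$mu * mm_to_m(prof[1L, 1L] - f$s0_mm) /
      (pi * mm_to_m(d0)^4) +
      128 * fluid$mu *
        mm_to_m(pad_len - (prof[1L, 1L] - f$s0_mm)) / (pi * mm_to_m(dL)^4)
    f$dp - pad_av * Q
  }, numeric(1))
  X <- cbind(flow_grid, flow_grid^2)
  beta <- coef(lm.fit(X, dp))
  if (is.na(beta[2L]) || beta[2L] < 0) {
    beta <- c(sum(dp * flow_grid) / sum(flow_grid^2), 0)
  }
  resid <- dp - X %*% beta
  law <- segment_law(beta[1L], beta[2L], "axisym_tabulated")
  attr(law, "samples") <- data.frame(Q_m3s = flow_grid, dp_pa = dp)
  attr(law, "residual_rel") <- max(abs(resid)) / max(abs(dp))
  law
}
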