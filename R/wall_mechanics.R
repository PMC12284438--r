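#' Holzapfel--Ogden constitutive parameters
#'
#' Container for the single-layer arterial wall model with one symmetric
#' pair of fiber families at +/- `beta_deg` from the vessel's longitudinal
#' axis. The ground matrix is neo-Hookean with stiffness `c_kpa`; the
#' fibers stiffen exponentially with fiber-strain invariant
#' `alpha = lambda_theta^2 cos^2(beta) + lambda_z^2 sin^2(beta) - 1`.
#'
#' @param c_kpa Ground-matrix stiffness (kPa), > 0.
#' @param k1_kpa Fiber stiffness scale (kPa), >= 0.
#' @param k2 Dimensionless fiber exponent, > 0.
#' @param beta_deg Effective fiber angle from the longitudinal axis
#'   (degrees), in \[0, 90\].
#' @return An object of class `ho_params`.
#' @examples
#' ho_params(10, 100.2, 5.3, 48.2)
#' @export
ho_params <- function(c_kpa, k1_kpa, k2, beta_deg) {
  stopifnot(is.numeric(c_kpa), length(c_kpa) == 1L, c_kpa > 0)
  stopifnot(is.numeric(k1_kpa), length(k1_kpa) == 1L, k1_kpa >= 0)
  stopifnot(is.numeric(k2), length(k2) == 1L, k2 > 0)
  stopifnot(is.numeric(beta_deg), length(beta_deg) == 1L,
            beta_deg >= 0, beta_deg <= 90)
  structure(list(c_kpa = c_kpa, k1_kpa = k1_kpa, k2 = k2,
                 beta_deg = beta_deg),
            class = "ho_params")
}

#' @export
print.ho_params <- function(x, ...) {
  cat(sprintf(
    "Holzapfel-Ogden wall: c = %.4g kPa, k1 = %.4g kPa, k2 = %.4g, beta = %.4g deg\n",
    x$c_kpa, x$k1_kpa, x$k2, x$beta_deg))
  invisible(x)
}

#' Principal stretch state of an incompressible wall element
#'
#' Exactly two of the three principal stretches may be given; the third is
#' filled in from incompressibility `lambda_r * lambda_theta * lambda_z = 1`.
#' If all three are given they must satisfy it to 1e-8.
#'
#' @param lambda_r,lambda_theta,lambda_z Principal stretches (radial,
#'   circumferential, axial); strictly positive.
#' @param p Optional hydrostatic pressure Lagrange multiplier (kPa),
#'   populated by boundary-condition solves.
#' @return Object of class `stretch_state` with fields `lambda_r`,
#'   `lambda_theta`, `lambda_z`, `p`.
#' @export
stretch_state <- function(lambda_r = NULL, lambda_theta = NULL,
                          lambda_z = NULL, p = NA_real_) {
  given <- !vapply(list(lambda_r, lambda_theta, lambda_z), is.null, logical(1))
  if (sum(given) < 2L)
    stop("at least two principal stretches must be given")
  if (is.null(lambda_r)) lambda_r <- 1 / (lambda_theta * lambda_z)
  if (is.null(lambda_theta)) lambda_theta <- 1 / (lambda_r * lambda_z)
  if (is.null(lambda_z)) lambda_z <- 1 / (lambda_r * lambda_theta)
  stopifnot(all(lambda_r > 0), all(lambda_theta > 0), all(lambda_z > 0))
  J <- lambda_r * lambda_theta * lambda_z
  if (any(abs(J - 1) > 1e-8))
    stop("stretches violate incompressibility: J = ",
         paste(signif(J[abs(J - 1) > 1e-8], 8), collapse = ", "))
  structure(list(lambda_r = lambda_r, lambda_theta = lambda_theta,
                 lambda_z = lambda_z, p = p),
            class = "stretch_state")
}

#' Reference wall geometry of a vessel segment
#'
#' @param r0 Reference (zero transmural pressure) inner radius, cm.
#' @param h0 Reference wall thickness, cm; must satisfy `0 < h0 < r0`.
#' @return Object of class `wall_geometry`.
#' @export
wall_geometry <- function(r0, h0) {
  stopifnot(r0 > 0, h0 > 0, h0 < r0)
  structure(list(r0 = r0, h0 = h0), class = "wall_geometry")
}

#' Fiber strain invariant
#'
#' `alpha = lambda_theta^2 cos^2(beta) + lambda_z^2 sin^2(beta) - 1`,
#' the excess of the squared fiber stretch over 1 for a fiber family at
#' angle beta from the longitudinal axis (in the theta-z plane). Negative
#' values indicate fiber shortening.
#'
#' @param stretch A [stretch_state()] (fields may be vectors).
#' @param beta_deg Fiber angle in degrees.
#' @return Numeric alpha (dimensionless).
#' @export
fiber_invariant <- function(stretch, beta_deg) {
  b <- beta_deg * pi / 180
  stretch$lambda_theta^2 * cos(b)^2 + stretch$lambda_z^2 * sin(b)^2 - 1
}

# fiber magnitude term 4 k1 alpha exp(k2 alpha^2), with the tension-only
# switch and an overflow guard; internal, vectorized
.fiber_factor <- function(alpha, params, tension_only = TRUE) {
  expo <- params$k2 * alpha^2
  if (any(expo > 500))
    stop(sprintf(
      "fiber exponent overflow: k2*alpha^2 = %.3g at alpha = %.4g",
      max(expo), alpha[which.max(expo)]))
  f <- 4 * params$k1_kpa * alpha * exp(expo)
  if (tension_only) f[alpha <= 0] <- 0
  f
}

#' Isochoric Cauchy stress components
#'
#' Deviatoric (trace-free) Cauchy stresses of the single-layer
#' Holzapfel--Ogden wall at a principal stretch state, in vessel polar
#' coordinates. The total Cauchy stress is `sigma = p I + sigma_bar`; the
#' hydrostatic part `p` is fixed by boundary conditions, not here.
#'
#' @inheritParams fiber_invariant
#' @param params An [ho_params()] object.
#' @param tension_only If `TRUE` (default) the fiber term is active only
#'   when the fiber invariant alpha > 0 (fibers do not support
#'   compression).
#' @return List with numeric fields `rr`, `theta`, `zz` (kPa); their sum
#'   is zero to numerical precision.
#' @export
isochoric_stress <- function(stretch, params, tension_only = TRUE) {
  b <- params$beta_deg * pi / 180
  alpha <- fiber_invariant(stretch, params$beta_deg)
  ff <- .fiber_factor(alpha, params, tension_only)
  s_rr <- params$c_kpa * stretch$lambda_r^2
  s_th <- params$c_kpa * stretch$lambda_theta^2 +
    ff * stretch$lambda_theta^2 * cos(b)^2
  s_zz <- params$c_kpa * stretch$lambda_z^2 +
    ff * stretch$lambda_z^2 * sin(b)^2
  m <- (s_rr + s_th + s_zz) / 3
  list(rr = s_rr - m, theta = s_th - m, zz = s_zz - m)
}

# circumferential-minus-radial isochoric stress difference (the transmural
# integrand; hydrostatic part cancels), kPa, vectorized
.sigma_diff_theta_rr <- function(lambda_r, lambda_theta, lambda_z, params,
                                 tension_only = TRUE) {
  b <- params$beta_deg * pi / 180
  alpha <- lambda_theta^2 * cos(b)^2 + lambda_z^2 * sin(b)^2 - 1
  ff <- .fiber_factor(alpha, params, tension_only)
  params$c_kpa * (lambda_theta^2 - lambda_r^2) +
    ff * lambda_theta^2 * cos(b)^2
}

# axial-minus-radial isochoric stress difference, kPa, vectorized
.sigma_diff_z_rr <- function(lambda_r, lambda_theta, lambda_z, params,
                             tension_only = TRUE) {
  b <- params$beta_deg * pi / 180
  alpha <- lambda_theta^2 * cos(b)^2 + lambda_z^2 * sin(b)^2 - 1
  ff <- .fiber_factor(alpha, params, tension_only)
  params$c_kpa * (lambda_z^2 - lambda_r^2) +
    ff * lambda_z^2 * sin(b)^2
}

#' Uniaxial stress response with stress-free lateral faces
#'
#' Solves the uniaxial boundary-value problem for a stretch `lam` imposed
#' in the loading direction: the two lateral normal Cauchy stresses are
#' zero, which together with incompressibility determines the hydrostatic
#' pressure and the free lateral stretch. Returns the Cauchy stress in the
#' loading direction.
#'
#' @param direction `"circumferential"` or `"longitudinal"`.
#' @param lam Stretch in the loading direction (vectorized), >= limits of
#'   the tension regime are the caller's concern; `lam = 1` gives zero
#'   stress.
#' @param params An [ho_params()].
#' @param tension_only Fiber tension-only switch, see [isochoric_stress()].
#' @return List with `stress` (Cauchy, kPa), and the solved `state`
#'   ([stretch_state()] with vector fields and hydrostatic `p`).
#' @examples
#' p <- ho_params(10, 100.2, 5.3, 48.2)
#' uniaxial_response("circumferential", c(1, 1.2, 1.5), p)$stress
#' @export
uniaxial_response <- function(direction = c("circumferential", "longitudinal"),
                              lam, params, tension_only = TRUE) {
  direction <- match.arg(direction)
  stopifnot(all(lam > 0))
  # residual in the free lateral stretch x: the in-plane lateral Cauchy
  # stress must vanish (radial one fixes p). Both residuals are strictly
  # increasing in x, so bisection is safe.
  if (direction == "longitudinal") {
    resid <- function(x, lz) {            # x = lambda_theta
      lr <- 1 / (x * lz)
      .sigma_diff_theta_rr(lr, x, lz, params, tension_only)
    }
  } else {
    resid <- function(x, lt) {            # x = lambda_z
      lr <- 1 / (x * lt)
      .sigma_diff_z_rr(lr, lt, x, params, tension_only)
    }
  }
  lo <- rep(0.01, length(lam)); hi <- rep(1.5, length(lam))
  fhi <- resid(hi, lam)
  k <- 0
  while (any(bad <- fhi < 0) && k < 10) {
    hi[bad] <- hi[bad] * 1.5
    fhi <- resid(hi, lam)
    k <- k + 1
  }
  if (any(fhi < 0))
    stop("uniaxial lateral-stretch solve failed to bracket; residual at ",
         "upper bound = ", min(fhi))
  for (i in seq_len(90)) {                # vectorized bisection, ~1e-16 rel
    mid <- 0.5 * (lo + hi)
    fm <- resid(mid, lam)
    take <- fm < 0
    lo[take] <- mid[take]; hi[!take] <- mid[!take]
  }
  x <- 0.5 * (lo + hi)
  if (direction == "longitudinal") {
    lt <- x; lz <- lam
  } else {
    lt <- lam; lz <- x
  }
  lr <- 1 / (lt * lz)
  stress <- if (direction == "longitudinal")
    .sigma_diff_z_rr(lr, lt, lz, params, tension_only)
  else
    .sigma_diff_theta_rr(lr, lt, lz, params, tension_only)
  sb <- isochoric_stress(
    structure(list(lambda_r = lr, lambda_theta = lt, lambda_z = lz),
              class = "stretch_state"),
    params, tension_only)
  state <- structure(list(lambda_r = lr, lambda_theta = lt, lambda_z = lz,
                          p = -sb$rr),
                     class = "stretch_state")
  list(stress = stress, state = state)
}

#' Convert uniaxial Cauchy stress to 2nd Piola--Kirchhoff stress
#'
#' For an incompressible uniaxial deformation the 2nd-PK stress in the
#' loading direction is `sigma / lam^2`; its conjugate strain is the
#' Green--Lagrange strain `E = (lam^2 - 1)/2`.
#'
#' @param sigma Cauchy stress (kPa), vectorized.
#' @param lam Stretch in the loading direction, > 0.
#' @return 2nd-PK stress (kPa).
#' @export
cauchy_to_second_pk <- function(sigma, lam) {
  stopifnot(all(lam > 0))
  sigma / lam^2
}

#' Green--Lagrange strain from stretch and back
#' @param lam Stretch (> 0).
#' @return Green strain `(lam^2 - 1)/2`.
#' @export
green_strain <- function(lam) (lam^2 - 1) / 2

#' @rdname green_strain
#' @param E Green strain (> -1/2).
#' @export
stretch_from_green <- function(E) {
  stopifnot(all(E > -0.5))
  sqrt(2 * E + 1)
}

# Gauss-Legendre nodes/weights on [-1, 1] via Golub-Welsch; cached
.gauss_legendre <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    i <- seq_len(n - 1)
    b <- i / sqrt(4 * i^2 - 1)
    J <- diag(0, n)
    J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    out <- list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
    cache[[key]] <<- out
    out
  }
})

#' Transmural pressure from lumen area (nonlinear tube law)
#'
#' Integrates the radial equilibrium of the deformed wall,
#' `P = integral_{ri}^{ro} (sigma_theta - sigma_rr)/r dr`, with the
#' through-wall stretch field obtained from the lumen area and wall
#' incompressibility at fixed axial stretch. This is the pressure--area
#' relation that closes the 1D flow equations.
#'
#' @param lumen_area Deformed lumen area (cm^2), vectorized, > 0.
#' @param geom A [wall_geometry()].
#' @param params An [ho_params()].
#' @param lambda_z Axial stretch during inflation (default 1).
#' @param tension_only Fiber tension-only switch.
#' @param n_quad Number of Gauss--Legendre points through the wall.
#' @return Transmural pressure (mmHg). Zero exactly at
#'   `lumen_area = pi r0^2` when `lambda_z = 1`.
#' @export
transmural_pressure <- function(lumen_area, geom, params, lambda_z = 1,
                                tension_only = TRUE, n_quad = 16) {
  stopifnot(all(lumen_area > 0))
  gl <- .gauss_legendre(n_quad)
  r0 <- geom$r0; Ro0 <- geom$r0 + geom$h0
  # reference radial coordinate R across the wall (quadrature nodes)
  Rm <- 0.5 * (Ro0 - r0) * gl$x + 0.5 * (Ro0 + r0)   # length n_quad
  wR <- 0.5 * (Ro0 - r0) * gl$w
  ri <- sqrt(lumen_area / pi)                        # length n_A
  # deformed radius of the material shell at R (wall incompressibility)
  r2 <- outer(ri^2, (Rm^2 - r0^2) / lambda_z, `+`)   # n_A x n_quad
  if (any(r2 <= 0))
    stop("wall inversion: deformed radius^2 <= 0 at lumen_area = ",
         signif(lumen_area[which(rowSums(r2 <= 0) > 0)[1]], 6))
  r <- sqrt(r2)
  lt <- sweep(r, 2, Rm, `/`)                         # lambda_theta(R)
  lr <- 1 / (lt * lambda_z)
  f <- .sigma_diff_theta_rr(lr, lt, lambda_z, params, tension_only)  # kPa
  # dr = R dR / (lambda_z r): integrand (f / r) dr = f R / (lambda_z r^2) dR
  integ <- sweep(f / r2, 2, Rm, `*`) / lambda_z
  P_kpa <- as.vector(integ %*% wR)
  kpa_to_mmhg(P_kpa)
}

#' Invert the tube law: lumen area at a given transmural pressure
#'
#' @param P Transmural pressure (mmHg), vectorized.
#' @inheritParams transmural_pressure
#' @return Lumen area (cm^2) with `transmural_pressure(area) = P` to
#'   ~1e-10 relative tolerance.
#' @export
area_from_pressure <- function(P, geom, params, lambda_z = 1,
                               tension_only = TRUE) {
  A0 <- pi * geom$r0^2
  vapply(P, function(p1) {
    g <- function(a) transmural_pressure(a, geom, params, lambda_z,
                                         tension_only) - p1
    lo <- 0.2 * A0; hi <- 3 * A0
    k <- 0
    while (g(lo) > 0 && k < 20) { lo <- lo * 0.7; k <- k + 1 }
    k <- 0
    while (g(hi) < 0 && k < 20) { hi <- hi * 1.3; k <- k + 1 }
    if (g(lo) > 0 || g(hi) < 0)
      stop(sprintf("tube-law inversion failed to bracket P = %.4g mmHg in [%.3g, %.3g] cm^2",
                   p1, lo, hi))
    stats::uniroot(g, c(lo, hi), tol = 1e-12 * A0)$root
  }, numeric(1))
}

#' Scale proximal wall stiffness
#'
#' Multiplies the stress-like material constants `c` and `k1` by the
#' proximal stiffness scaling factor S_p, leaving `k2` and `beta`
#' unchanged. Because the wall stress is linear in (c, k1) at fixed
#' stretch, the whole tube law scales by S_p.
#'
#' @param params An [ho_params()].
#' @param S_p Positive scale factor; 1 is the identity.
#' @return Scaled [ho_params()].
#' @export
apply_stiffness_scaling <- function(params, S_p) {
  stopifnot(is.numeric(S_p), length(S_p) == 1L, S_p > 0)
  ho_params(params$c_kpa * S_p, params$k1_kpa * S_p, params$k2,
            params$beta_deg)
}

#' Tangent stiffness of the tube law at the reference area
#'
#' Inflation-side derivative dP/dA at `A0 = pi r0^2`, used to build the
#' slope-matched linear tube law. The derivative is one-sided (towards
#' A > A0) because the fiber tension-only switch makes the law's slope
#' discontinuous at the reference area, and vessels operate on the
#' inflation side.
#'
#' @inheritParams transmural_pressure
#' @return dP/dA at the reference area (mmHg per cm^2).
#' @export
tube_law_tangent <- function(geom, params, lambda_z = 1,
                             tension_only = TRUE) {
  A0 <- pi * geom$r0^2
  h <- 1e-6 * A0
  # second-order one-sided difference on the inflation branch
  P1 <- transmural_pressure(A0 + h, geom, params, lambda_z, tension_only)
  P2 <- transmural_pressure(A0 + 2 * h, geom, params, lambda_z, tension_only)
  P0 <- transmural_pressure(A0, geom, params, lambda_z, tension_only)
  (4 * P1 - P2 - 3 * P0) / (2 * h)
}

#' Linear pressure--area law matched to the nonlinear law at reference
#'
#' `P = K (A - A0)` with `K` the tangent of the nonlinear tube law at the
#' reference area (or any supplied effective stiffness). Used to contrast
#' linear and nonlinear vessel behavior.
#'
#' @param lumen_area Lumen area (cm^2), vectorized.
#' @param geom A [wall_geometry()].
#' @param effective_stiffness Slope K (mmHg per cm^2), > 0; typically
#'   [tube_law_tangent()].
#' @return Pressure (mmHg).
#' @export
linear_tube_law <- function(lumen_area, geom, effective_stiffness) {
  stopifnot(effective_stiffness > 0)
  A0 <- pi * geom$r0^2
  effective_stiffness * (lumen_area - A0)
}
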