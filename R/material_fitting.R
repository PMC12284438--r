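#' Uniaxial stress--strain dataset
#'
#' One direction of a uniaxial tension test on an arterial strip,
#' reported as 2nd-Piola--Kirchhoff stress against Green--Lagrange
#' strain.
#'
#' @param direction `"circumferential"` or `"longitudinal"`.
#' @param strain Green--Lagrange strain samples, non-negative, strictly
#'   increasing.
#' @param stress 2nd-PK stress samples (kPa), non-negative, same length.
#' @return Object of class `uniaxial_dataset`.
#' @export
uniaxial_dataset <- function(direction = c("circumferential", "longitudinal"),
                             strain, stress) {
  direction <- match.arg(direction)
  stopifnot(length(strain) == length(stress), length(strain) >= 3L)
  if (any(strain < 0) || any(diff(strain) <= 0))
    stop("strain must be non-negative and strictly increasing")
  if (any(stress < -1e-8)) stop("stress must be non-negative")
  structure(list(direction = direction, strain = as.numeric(strain),
                 stress = as.numeric(pmax(stress, 0))),
            class = "uniaxial_dataset")
}

#' Read / write a uniaxial dataset as CSV (`green_strain,pk2_stress_kPa`)
#' @param path File path.
#' @param direction Dataset direction label.
#' @return A [uniaxial_dataset()].
#' @export
read_uniaxial_csv <- function(path, direction) {
  d <- utils::read.csv(path)
  uniaxial_dataset(direction, d[[1]], d[[2]])
}

#' @rdname read_uniaxial_csv
#' @param data A [uniaxial_dataset()].
#' @export
write_uniaxial_csv <- function(data, path) {
  utils::write.csv(data.frame(green_strain = data$strain,
                              pk2_stress_kPa = data$stress),
                   path, row.names = FALSE)
  invisible(path)
}

# model-predicted 2nd-PK stresses at the dataset's strain samples
.predict_pk2 <- function(data, params, tension_only = TRUE) {
  lam <- stretch_from_green(data$strain)
  sig <- uniaxial_response(data$direction, lam, params, tension_only)$stress
  cauchy_to_second_pk(sig, lam)
}

#' Fit Holzapfel--Ogden parameters to paired uniaxial datasets
#'
#' Jointly least-squares fits (c, k1, k2, beta) to circumferential and
#' longitudinal 2nd-PK stress--strain curves, with equal per-point
#' weights, using Levenberg--Marquardt from a seeded Latin-hypercube of
#' starting points (bounds: c in (0, 1e3\] kPa, k1 in \[0, 1e4\] kPa, k2
#' in (0, 1e2\], beta in \[0, 90\] degrees).
#'
#' @param circ,long [uniaxial_dataset()]s for the two directions.
#' @param n_starts Number of multi-start points.
#' @param seed Seed for the starting-point hypercube.
#' @param tension_only Fiber tension-only switch used by the model.
#' @return Object of class `ho_fit`: list with `params` ([ho_params()]),
#'   `residual_sse` (kPa^2), `per_direction_rmse` (kPa, named),
#'   `n_restarts_converged`, and `starts` diagnostics.
#' @export
fit_constitutive <- function(circ, long, n_starts = 12, seed = 1633548,
                             tension_only = TRUE) {
  stopifnot(inherits(circ, "uniaxial_dataset"),
            inherits(long, "uniaxial_dataset"))
  if (circ$direction != "circumferential" ||
      long$direction != "longitudinal")
    stop("datasets must be circumferential and longitudinal, in that order")
  lower <- c(c = 1e-3, k1 = 0, k2 = 1e-3, beta = 0)
  upper <- c(c = 1e3, k1 = 1e4, k2 = 1e2, beta = 90)
  resid_fn <- function(theta) {
    p <- ho_params(theta[1], max(theta[2], 0), theta[3], theta[4])
    c(.predict_pk2(circ, p, tension_only) - circ$stress,
      .predict_pk2(long, p, tension_only) - long$stress)
  }
  # seeded Latin-hypercube starting points (log scale for the stress-like
  # and exponent parameters)
  u <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    x <- lhs::randomLHS(n_starts, 4)
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
    x
  })
  starts <- cbind(
    c = 10^(u[, 1] * 3 - 1),            # 0.1 .. 100 kPa
    k1 = 10^(u[, 2] * 3),               # 1 .. 1000 kPa
    k2 = 10^(u[, 3] * 2 - 0.5),         # 0.3 .. 30
    beta = 15 + u[, 4] * 60)            # 15 .. 75 deg
  best <- NULL; n_conv <- 0L; diag_list <- list()
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 400, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) {
      diag_list[[i]] <- list(start = starts[i, ], sse = NA_real_,
                             message = "nls.lm error")
      next
    }
    sse <- sum(fit$fvec^2)
    n_conv <- n_conv + 1L
    diag_list[[i]] <- list(start = starts[i, ], sse = sse,
                           message = fit$message)
    if (is.null(best) || sse < best$sse)
      best <- list(par = stats::coef(fit), sse = sse)
  }
  if (is.null(best))
    stop("all restarts failed to converge; diagnostics: ",
         paste(vapply(diag_list, function(d) d$message, ""), collapse = "; "))
  p <- ho_params(unname(best$par[1]), unname(max(best$par[2], 0)),
                 unname(best$par[3]), unname(best$par[4]))
  rc <- .predict_pk2(circ, p, tension_only) - circ$stress
  rl <- .predict_pk2(long, p, tension_only) - long$stress
  structure(list(params = p, residual_sse = best$sse,
                 per_direction_rmse = c(
                   circumferential = sqrt(mean(rc^2)),
                   longitudinal = sqrt(mean(rl^2))),
                 n_restarts_converged = n_conv,
                 starts = diag_list),
            class = "ho_fit")
}

#' @export
print.ho_fit <- function(x, ...) {
  cat("Holzapfel-Ogden fit (", x$n_restarts_converged,
      " restarts converged)\n", sep = "")
  print(x$params)
  cat(sprintf("  SSE = %.4g kPa^2; RMSE circ = %.4g, long = %.4g kPa\n",
              x$residual_sse, x$per_direction_rmse[1],
              x$per_direction_rmse[2]))
  invisible(x)
}

#' Write a constitutive fit result to JSON
#' @param fit An `ho_fit`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(c_kPa = fit$params$c_kpa, k1_kPa = fit$params$k1_kpa,
         k2 = fit$params$k2, beta_deg = fit$params$beta_deg,
         residual_sse = fit$residual_sse,
         per_direction_rmse = as.list(fit$per_direction_rmse),
         n_restarts_converged = fit$n_restarts_converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Tangent stiffness of a stress--strain curve at a strain level
#'
#' Slope of the stress--strain curve at `E_star`, estimated from a local
#' quadratic fit over the 5 samples nearest to `E_star`.
#'
#' @param data A [uniaxial_dataset()].
#' @param E_star Green strain at which to evaluate (default 0.6); must be
#'   interior to the sampled range.
#' @return Slope (kPa per unit strain).
#' @export
stiffness_at_strain <- function(data, E_star = 0.6) {
  if (E_star <= min(data$strain) || E_star >= max(data$strain))
    stop(sprintf("E_star = %g outside sampled strain range [%g, %g]",
                 E_star, min(data$strain), max(data$strain)))
  idx <- order(abs(data$strain - E_star))[1:5]
  x <- data$strain[idx] - E_star
  y <- data$stress[idx]
  co <- stats::coef(stats::lm(y ~ x + I(x^2)))
  unname(co[2])
}

#' Stress at the reference peak stretch
#'
#' Stress interpolated at the Green strain corresponding to
#' `stretch_star` (default 1.5, i.e. E = 0.625, ~50% stretch).
#'
#' @param data A [uniaxial_dataset()].
#' @param stretch_star Peak stretch.
#' @return Interpolated 2nd-PK stress (kPa).
#' @export
peak_stress <- function(data, stretch_star = 1.5) {
  E_star <- green_strain(stretch_star)
  if (E_star > max(data$strain) + 1e-12)
    stop(sprintf("dataset reaches E = %g < required %g",
                 max(data$strain), E_star))
  stats::approx(data$strain, data$stress, xout = E_star, rule = 1)$y
}
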