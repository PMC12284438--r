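#' Configuration for self-similar synthetic pulmonary trees
#'
#' The generator emulates the morphometry of an intrapulmonary arterial
#' tree: a rooted binary tree in which each child's radius is the parent's
#' times `radius_ratio`, perturbed by a random asymmetry between the two
#' siblings, and lengths follow a fixed length-to-radius ratio.
#'
#' @param n_generations Number of branching generations below the root
#'   (>= 2); a symmetric tree has `2^n_generations` terminals.
#' @param root_radius Root (MPA) reference radius, cm.
#' @param root_length Root segment length, cm.
#' @param radius_ratio Per-generation radius ratio, in (0, 1).
#' @param length_to_radius Child length = this ratio times child radius.
#' @param asymmetry Sibling asymmetry `a` in \[0, 0.5): child radii are
#'   `r * radius_ratio * (1 + a)` and `r * radius_ratio * (1 - a)`, the
#'   larger branch assigned at random.
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @return A list of class `tree_gen_config`.
#' @export
tree_gen_config <- function(n_generations = 5, root_radius = 0.13,
                            root_length = 1.0, radius_ratio = 0.79,
                            length_to_radius = 6, asymmetry = 0.15,
                            seed = 1L) {
  stopifnot(n_generations >= 2, root_radius > 0, root_length > 0,
            radius_ratio > 0, radius_ratio < 1, length_to_radius > 0,
            asymmetry >= 0, asymmetry < 0.5)
  structure(list(n_generations = n_generations, root_radius = root_radius,
                 root_length = root_length, radius_ratio = radius_ratio,
                 length_to_radius = length_to_radius, asymmetry = asymmetry,
                 seed = as.integer(seed)),
            class = "tree_gen_config")
}

#' Generate a self-similar synthetic vascular tree
#'
#' @param cfg A [tree_gen_config()].
#' @param wall_ratio Wall thickness ratio h0/r0 applied to every segment.
#' @return A [vascular_tree()]. Deterministic for a given config + seed.
#' @examples
#' tr <- generate_tree(tree_gen_config(n_generations = 4, asymmetry = 0))
#' nrow(tr$segments)  # 31 segments, 16 terminals
#' @export
generate_tree <- function(cfg, wall_ratio = 0.10) {
  stopifnot(inherits(cfg, "tree_gen_config"))
  rows <- list()
  rows[[1]] <- data.frame(id = "s1", parent_id = NA_character_,
                          length_cm = cfg$root_length,
                          radius_cm = cfg$root_radius,
                          stringsAsFactors = FALSE)
  counter <- 1L
  frontier <- data.frame(id = "s1", radius = cfg$root_radius,
                         stringsAsFactors = FALSE)
  rng <- .seeded_rng(cfg$seed)
  for (g in seq_len(cfg$n_generations)) {
    nxt <- list()
    for (i in seq_len(nrow(frontier))) {
      sgn <- if (rng() < 0.5) 1 else -1
      fac <- c(1 + sgn * cfg$asymmetry, 1 - sgn * cfg$asymmetry)
      for (k in 1:2) {
        counter <- counter + 1L
        r <- frontier$radius[i] * cfg$radius_ratio * fac[k]
        id <- paste0("s", counter)
        rows[[length(rows) + 1L]] <- data.frame(
          id = id, parent_id = frontier$id[i],
          length_cm = cfg$length_to_radius * r, radius_cm = r,
          stringsAsFactors = FALSE)
        nxt[[length(nxt) + 1L]] <- data.frame(id = id, radius = r,
                                              stringsAsFactors = FALSE)
      }
    }
    frontier <- do.call(rbind, nxt)
  }
  seg <- do.call(rbind, rows)
  seg$wall_ratio <- wall_ratio
  vascular_tree(seg)
}

# local RNG stream that never touches the global .Random.seed
.seeded_rng <- function(seed) {
  state <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    s <- get(".Random.seed", .GlobalEnv)
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
    s
  })
  function(n = 1L) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    assign(".Random.seed", state, .GlobalEnv)
    x <- stats::runif(n)
    state <<- get(".Random.seed", .GlobalEnv)
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
    x
  }
}

#' Configuration for hypertensive remodeling of a synthetic tree
#'
#' Emulates the morphometric signature of pulmonary hypertension:
#' rarefaction ("pruning") of small distal vessels and narrowing of the
#' remaining distal lumens.
#'
#' @param prune_fraction Fraction of the initial terminal count removed by
#'   sibling-pair pruning, in \[0, 1). Each pruning event removes one
#'   sibling pair of terminal segments (their parent becomes terminal),
#'   reducing the terminal count by one.
#' @param distal_narrowing Multiplier in (0, 1\] applied to radii below
#'   `radius_threshold`.
#' @param radius_threshold Radius (cm) below which narrowing applies.
#' @param seed Integer seed for the pruning choices.
#' @return A list of class `ph_remodel_config`.
#' @export
ph_remodel_config <- function(prune_fraction = 0.25, distal_narrowing = 0.8,
                              radius_threshold = 0.04, seed = 1L) {
  stopifnot(prune_fraction >= 0, prune_fraction < 1,
            distal_narrowing > 0, distal_narrowing <= 1,
            radius_threshold > 0)
  structure(list(prune_fraction = prune_fraction,
                 distal_narrowing = distal_narrowing,
                 radius_threshold = radius_threshold, seed = as.integer(seed)),
            class = "ph_remodel_config")
}

#' Apply hypertensive remodeling to a synthetic tree
#'
#' @param tree A [vascular_tree()].
#' @param cfg A [ph_remodel_config()].
#' @return The remodeled [vascular_tree()].
#' @export
apply_ph_remodeling <- function(tree, cfg) {
  stopifnot(inherits(tree, "vascular_tree"),
            inherits(cfg, "ph_remodel_config"))
  seg <- tree$segments
  n0 <- length(tree$terminals)
  n_ops <- round(cfg$prune_fraction * n0)
  if (n0 - n_ops < 2)
    stop("over-pruning: would leave fewer than 2 terminals")
  rng <- .seeded_rng(cfg$seed)
  for (op in seq_len(n_ops)) {
    tr <- vascular_tree(seg)
    term <- tr$terminals
    # sibling pairs where both children are terminal
    pairs <- Filter(function(ch) length(ch) == 2 && all(ch %in% term),
                    tr$children)
    if (!length(pairs)) break
    pick <- names(pairs)[ceiling(rng() * length(pairs))]
    seg <- seg[!(seg$id %in% pairs[[pick]]), ]
  }
  sel <- seg$radius_cm < cfg$radius_threshold
  seg$radius_cm[sel] <- seg$radius_cm[sel] * cfg$distal_narrowing
  seg$length_cm[sel] <- seg$length_cm[sel]  # lengths unchanged
  vascular_tree(seg)
}

#' Morphometric distributions of a vascular tree
#'
#' Normalized histograms (fractions summing to 1) of segment lengths and
#' radii, for comparison of control and remodeled trees.
#'
#' @param tree A [vascular_tree()].
#' @param radius_breaks,length_breaks Histogram break points (cm); default
#'   10 equal bins over the observed range.
#' @return List with data.frames `radius` and `length`, columns
#'   `mid`, `fraction`.
#' @export
tree_morphometry <- function(tree, radius_breaks = NULL,
                             length_breaks = NULL) {
  one <- function(x, breaks) {
    if (is.null(breaks)) breaks <- seq(0, max(x) * 1.0001, length.out = 11)
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    data.frame(mid = h$mids, fraction = h$counts / length(x))
  }
  list(radius = one(tree$segments$radius_cm, radius_breaks),
       length = one(tree$segments$length_cm, length_breaks))
}

# -- Independent uniaxial oracle ---------------------------------------

# Strain energy of the incompressible single-layer H-O wall (kPa), as a
# function of three independent stretches. Used only via numeric
# differentiation: this oracle deliberately shares no stress formulas
# with the wall-mechanics module.
.ho_energy <- function(lr, lt, lz, params, tension_only = TRUE) {
  b <- params$beta_deg * pi / 180
  alpha <- lt^2 * cos(b)^2 + lz^2 * sin(b)^2 - 1
  W <- params$c_kpa / 2 * (lr^2 + lt^2 + lz^2 - 3)
  active <- if (tension_only) alpha > 0 else rep(TRUE, length(alpha))
  Wf <- ifelse(active,
               params$k1_kpa / params$k2 *
                 (exp(params$k2 * alpha^2) - 1),
               0)
  W + Wf
}

# Uniaxial Cauchy stress by energy minimization + numeric differentiation.
# The free lateral stretch minimizes the energy along the incompressible
# constraint (equivalent to zero lateral stress); the loading-direction
# stress is lam_i dW/dlam_i - lam_r dW/dlam_r evaluated by central
# differences (zero radial stress fixes the hydrostatic pressure).
.oracle_uniaxial_cauchy <- function(direction, lam, params,
                                    tension_only = TRUE) {
  h <- 1e-6
  vapply(lam, function(l1) {
    if (direction == "longitudinal") {
      obj <- function(lt) .ho_energy(1 / (lt * l1), lt, l1, params,
                                     tension_only)
    } else {
      obj <- function(lz) .ho_energy(1 / (lz * l1), l1, lz, params,
                                     tension_only)
    }
    opt <- stats::optimize(obj, c(0.011, 1.6), tol = 1e-10)
    x <- opt$minimum
    # Newton polish on the numeric energy gradient: golden-section leaves
    # ~1e-8 error in the lateral stretch, to which the stress is
    # first-order sensitive
    for (it in seq_len(40)) {
      g1 <- (obj(x + h) - obj(x - h)) / (2 * h)
      g2 <- (obj(x + h) - 2 * obj(x) + obj(x - h)) / h^2
      if (!is.finite(g1) || !is.finite(g2) || g2 <= 0) break
      step <- g1 / g2
      x <- x - step
      if (abs(step) < 1e-13) break
    }
    if (direction == "longitudinal") {
      lt <- x; lz <- l1
    } else {
      lt <- l1; lz <- x
    }
    lr <- 1 / (lt * lz)
    dWdl <- if (direction == "longitudinal")
      (.ho_energy(lr, lt, lz + h, params, tension_only) -
         .ho_energy(lr, lt, lz - h, params, tension_only)) / (2 * h)
    else
      (.ho_energy(lr, lt + h, lz, params, tension_only) -
         .ho_energy(lr, lt - h, lz, params, tension_only)) / (2 * h)
    dWdr <- (.ho_energy(lr + h, lt, lz, params, tension_only) -
               .ho_energy(lr - h, lt, lz, params, tension_only)) / (2 * h)
    l_load <- if (direction == "longitudinal") lz else lt
    l_load * dWdl - lr * dWdr
  }, numeric(1))
}

#' Generate synthetic uniaxial stress--strain datasets
#'
#' Emulates uniaxial testing of arterial tissue strips along the
#' circumferential and longitudinal directions up to 50% stretch. Stresses
#' come from an independent energy-minimization oracle (not from the
#' package's own stress reductions), converted to 2nd-Piola--Kirchhoff
#' stress vs Green--Lagrange strain, with optional multiplicative Gaussian
#' noise.
#'
#' @param params An [ho_params()].
#' @param max_stretch Largest stretch sampled (default 1.5, i.e. Green
#'   strain 0.625).
#' @param n_points Samples per direction (uniform in stretch from 1).
#' @param noise_sd_rel Relative standard deviation of multiplicative
#'   Gaussian noise (0 = noiseless).
#' @param seed Seed for the noise (unused when `noise_sd_rel = 0`).
#' @param tension_only Fiber tension-only switch.
#' @return List with elements `circumferential` and `longitudinal`, each a
#'   [uniaxial_dataset()].
#' @export
generate_uniaxial_data <- function(params, max_stretch = 1.5,
                                   n_points = 25, noise_sd_rel = 0,
                                   seed = 1L, tension_only = TRUE) {
  stopifnot(max_stretch > 1, n_points >= 5)
  lam <- seq(1, max_stretch, length.out = n_points)
  E <- green_strain(lam)
  rng_norm <- NULL
  if (noise_sd_rel > 0) {
    u <- .seeded_rng(seed)(4 * n_points)  # uniforms -> normals (Box-Muller)
    z <- sqrt(-2 * log(u[seq(1, 4 * n_points, 2)])) *
      cos(2 * pi * u[seq(2, 4 * n_points, 2)])
    rng_norm <- z
  }
  out <- list()
  for (d in c("circumferential", "longitudinal")) {
    sig <- .oracle_uniaxial_cauchy(d, lam, params, tension_only)
    pk2 <- sig / lam^2
    pk2[1] <- 0                         # stress-free reference state
    pk2[abs(pk2) < 1e-9] <- 0           # numeric-differentiation dust
    if (!is.null(rng_norm)) {
      idx <- if (d == "circumferential") seq_len(n_points)
             else n_points + seq_len(n_points)
      pk2 <- pk2 * (1 + noise_sd_rel * rng_norm[idx])
      pk2 <- pmax(pk2, 0)
      pk2[1] <- 0
    }
    out[[d]] <- uniaxial_dataset(d, E, pk2)
  }
  out
}

#' Generate a periodic right-ventricular ejection inflow waveform
#'
#' Half-sine ejection pulse over a fraction of the cycle and zero
#' elsewhere (no regurgitation), sampled so that the per-cycle volume
#' equals the stroke volume exactly.
#'
#' @param heart_rate Beats per minute.
#' @param stroke_volume Ejected volume per beat, mL.
#' @param ejection_fraction_of_cycle Fraction of the period occupied by
#'   ejection, in (0, 1).
#' @param n_samples Samples per cycle.
#' @return A flow [waveform()] (mL/s).
#' @export
generate_inflow <- function(heart_rate = 300, stroke_volume = 0.33,
                            ejection_fraction_of_cycle = 0.5,
                            n_samples = 256) {
  stopifnot(heart_rate > 0, stroke_volume > 0,
            ejection_fraction_of_cycle > 0, ejection_fraction_of_cycle < 1)
  T_ <- 60 / heart_rate
  t <- seq(0, T_, length.out = n_samples + 1L)[seq_len(n_samples)]
  t_ej <- ejection_fraction_of_cycle * T_
  q <- ifelse(t < t_ej, sin(pi * t / t_ej), 0)
  q <- q * stroke_volume / (mean(q) * T_)   # exact discrete cycle volume
  waveform(t, q, period = T_)
}
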