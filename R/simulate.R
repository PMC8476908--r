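# Synthetic EPID transmission-fluence simulator.
#
# Geometry: patient axes x = LR, y = AP, z = SI. The gantry rotates in the
# x-y plane; at gantry angle theta (degrees) the parallel beam direction is
# d = (sin t, -cos t, 0) and the imager in-plane axis is u = (cos t, sin t, 0);
# the imager row axis v is the SI axis at every angle. A couch shift
# (lr, si, ap) therefore displaces the projection by si along v at every
# angle, and by lr*cos t + ap*sin t along u, so in-plane shifts partially
# cancel when per-angle images are summed over the arcs.

#' Simulation configuration
#'
#' Study conditions for synthetic cohort generation. The defaults emulate the
#' measurement design this package targets: 40 patients, two partial arcs,
#' a 0.336 mm pixel pitch and a 200 cGy fraction dose. The default simulated
#' panel is 600x600 pixels (a desk-scale stand-in for the 1190x1190 panel
#' that still leaves a 512x512 centre crop); `image_size`/`pitch_mm` are free,
#' and reduced sizes conventionally scale the pitch so the physical field of
#' view is preserved.
#'
#' @param n_patients number of synthetic patients (default 40).
#' @param image_size panel side length in pixels (default 600).
#' @param pitch_mm pixel pitch in mm (default 0.336).
#' @param magnification imager-plane displacement per mm of couch shift
#'   (default 1; real EPID geometry magnifies shifts).
#' @param noise_sigma_frac s.d. of additive Gaussian detector noise as a
#'   fraction of the fraction dose (default 0.005).
#' @param angular_step_deg gantry sampling step along each arc (default 5).
#' @param dose_cgy fraction dose scale in cGy (default 200).
#' @param master_seed master seed from which all per-patient structure and
#'   per-map noise seeds are derived (default 1).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 40L, image_size = 600L,
                              pitch_mm = 0.336, magnification = 1,
                              noise_sigma_frac = 0.005,
                              angular_step_deg = 5, dose_cgy = 200,
                              master_seed = 1L) {
  stopifnot(n_patients >= 1, image_size >= 16, pitch_mm > 0,
            magnification > 0, noise_sigma_frac >= 0, angular_step_deg > 0,
            dose_cgy > 0)
  structure(list(n_patients = as.integer(n_patients),
                 image_size = as.integer(image_size),
                 pitch_mm = pitch_mm, magnification = magnification,
                 noise_sigma_frac = noise_sigma_frac,
                 angular_step_deg = angular_step_deg,
                 dose_cgy = dose_cgy,
                 master_seed = as.integer(master_seed)),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @param size reduced panel side in pixels.
#' @param ... passed on to [simulation_config()].
#' @details `reduced_config()` is a convenience preset that shrinks the panel
#'   while keeping the 600 x 0.336 mm field of view, so phantom and shifts
#'   keep their physical size.
#' @export
reduced_config <- function(size = 128L, ...) {
  simulation_config(image_size = size, pitch_mm = 0.336 * 600 / size, ...)
}

# Evaluate code with a temporary RNG state seeded at `seed`.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive k child seeds (< 2^31) from a parent seed, deterministically.
derive_seeds <- function(seed, k) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

#' Generate a synthetic head phantom
#'
#' Builds a per-patient head phantom as an ellipsoidal water-like body with a
#' bone-like skull shell plus 4-8 spherical internal heterogeneities (dense
#' positive and air-like negative attenuation offsets) whose positions,
#' sizes and contrasts vary
#' with the structure seed, giving each synthetic patient a distinct fluence
#' signature. A small orbital target volume (used to centre the apertures)
#' is also placed. Attenuation coefficients are water-scale linear
#' attenuation surrogates in 1/mm; heterogeneities lie fully inside the body
#' and never drive the total attenuation negative.
#'
#' @param patient_seed integer structure seed.
#' @param config a [simulation_config()].
#' @return An object of class `phantom_model`: a list with the primitive
#'   table `objects` (ellipsoid centres/semi-axes in mm and attenuation
#'   offsets), the `target` aperture-centring volume, `voxel_mm` and `seed`.
#'   [phantom_grid()] rasterises it to a voxel attenuation grid.
#' @export
generate_phantom <- function(patient_seed, config = simulation_config()) {
  stopifnot(is.numeric(patient_seed), length(patient_seed) == 1)
  local_seed(patient_seed, {
    body <- tibble::tibble(
      kind = "body",
      cx = stats::runif(1, -3, 3), cy = stats::runif(1, -3, 3),
      cz = stats::runif(1, -3, 3),
      a = stats::runif(1, 64, 74), b = stats::runif(1, 76, 88),
      c = stats::runif(1, 82, 92),
      mu = stats::runif(1, 0.0045, 0.0055))
    # bone-like skull shell: + on an outer ellipsoid, - on the inner one
    mu_bone <- stats::runif(1, 0.004, 0.006)
    thick <- stats::runif(1, 5, 7)
    skull <- tibble::tibble(
      kind = c("skull_outer", "skull_inner"),
      cx = body$cx, cy = body$cy, cz = body$cz,
      a = 0.96 * body$a - c(0, thick),
      b = 0.96 * body$b - c(0, thick),
      c = 0.96 * body$c - c(0, thick),
      mu = c(mu_bone, -mu_bone))
    n_het <- sample(4:8, 1)
    het <- tibble::tibble(
      kind = "het",
      # positions within 55% of the body semi-axes keep spheres inside the
      # skull's inner surface
      cx = body$cx + stats::runif(n_het, -0.55, 0.55) * body$a,
      cy = body$cy + stats::runif(n_het, -0.55, 0.55) * body$b,
      cz = body$cz + stats::runif(n_het, -0.55, 0.55) * body$c,
      a = stats::runif(n_het, 8, 16),
      mu = sample(c(-1, 1), n_het, replace = TRUE) *
        stats::runif(n_het, 0.002, 0.0045))
    het$b <- het$a; het$c <- het$a
    # |negative offset| < body mu, so attenuation along any ray stays >= 0
    het$mu <- pmax(het$mu, -0.9 * body$mu)
    # apertures: MLC-like modulation along the in-plane axis (half-width
    # ru), jaw-set SI extent rv wider than the head so the static field
    # border does not cut across the imaged anatomy
    target <- list(cx = body$cx + stats::runif(1, -5, 5),
                   cy = body$cy - 0.3 * body$b,
                   cz = body$cz + stats::runif(1, -8, 8),
                   ru = stats::runif(1, 50, 65),
                   rv = body$c * stats::runif(1, 1.25, 1.45))
    structure(list(objects = dplyr::bind_rows(body, skull, het),
                   target = target, voxel_mm = 2,
                   seed = as.integer(patient_seed)),
              class = "phantom_model")
  })
}

#' @rdname generate_phantom
#' @param phantom a `phantom_model`.
#' @param voxel_mm voxel edge length in mm.
#' @details `phantom_grid()` rasterises the phantom primitives to a 3D voxel
#'   attenuation grid (x, y, z order) covering the body's bounding box.
#' @export
phantom_grid <- function(phantom, voxel_mm = phantom$voxel_mm) {
  ob <- phantom$objects
  body <- ob[ob$kind == "body", ]
  xs <- seq(body$cx - body$a, body$cx + body$a, by = voxel_mm)
  ys <- seq(body$cy - body$b, body$cy + body$b, by = voxel_mm)
  zs <- seq(body$cz - body$c, body$cz + body$c, by = voxel_mm)
  g <- array(0, dim = c(length(xs), length(ys), length(zs)))
  for (i in seq_len(nrow(ob))) {
    o <- ob[i, ]
    dx2 <- ((xs - o$cx) / o$a)^2
    dy2 <- ((ys - o$cy) / o$b)^2
    dz2 <- ((zs - o$cz) / o$c)^2
    inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
    g <- g + o$mu * inside
  }
  structure(g, voxel_mm = voxel_mm, x = xs, y = ys, z = zs)
}

#' Arc delivery plan
#'
#' Two partial arcs — 240 to 120 degrees clockwise (through 0) and 120 back
#' to 240 counterclockwise — each with its own seeded aperture modulation.
#' The aperture at each gantry angle is a smooth-edged rectangle centred on
#' the projected target volume, with half-widths modulated by low-order
#' random harmonics of the gantry angle; apertures are machine-side and do
#' not move when the patient is shifted.
#'
#' @param plan_seed integer seed for the aperture modulation.
#' @param config a [simulation_config()] (supplies the angular step).
#' @return An object of class `plan_model` with an `arcs` tibble
#'   (`arc_id`, `start_deg`, `stop_deg`, `sense`, `step_deg`,
#'   `aperture_seed`).
#' @export
plan_model <- function(plan_seed, config = simulation_config()) {
  seeds <- derive_seeds(plan_seed, 2)
  arcs <- tibble::tibble(
    arc_id = 1:2,
    start_deg = c(240, 120), stop_deg = c(120, 240),
    sense = c("cw", "ccw"),
    step_deg = config$angular_step_deg,
    aperture_seed = seeds)
  structure(list(arcs = arcs, seed = as.integer(plan_seed)),
            class = "plan_model")
}

# Gantry angle sequence of one arc, degrees in [0, 360).
arc_angles <- function(start_deg, stop_deg, sense, step_deg) {
  span <- if (sense == "cw") (stop_deg - start_deg) %% 360
          else -((start_deg - stop_deg) %% 360)
  (start_deg + seq(0, span, by = if (sense == "cw") step_deg else -step_deg)) %% 360
}

# Smooth harmonic modulation coefficients for one arc's aperture.
aperture_params <- function(aperture_seed) {
  local_seed(aperture_seed, list(
    amp_u = stats::runif(2, 0.05, 0.2), pha_u = stats::runif(2, 0, 2 * pi),
    amp_v = stats::runif(2, 0.05, 0.2), pha_v = stats::runif(2, 0, 2 * pi),
    jit_u = stats::runif(2, -2, 2), jit_v = stats::runif(2, -2, 2),
    penumbra_mm = stats::runif(1, 2.5, 4)))
}

logistic <- function(x) 1 / (1 + exp(-x))

# Aperture transmission on the imager grid at one gantry angle.
aperture_mask <- function(u, v, theta_deg, target, par) {
  t_rad <- theta_deg * pi / 180
  tu <- target$cx * cos(t_rad) + target$cy * sin(t_rad) +
    par$jit_u[1] * sin(t_rad + par$pha_u[1]) + par$jit_u[2]
  tv <- target$cz + par$jit_v[1] * sin(t_rad + par$pha_v[1]) + par$jit_v[2]
  wu <- target$ru * (1 + par$amp_u[1] * sin(t_rad + par$pha_u[1]) +
                       par$amp_u[2] * sin(2 * t_rad + par$pha_u[2]))
  wv <- target$rv * (1 + par$amp_v[1] * sin(t_rad + par$pha_v[1]) +
                       par$amp_v[2] * sin(2 * t_rad + par$pha_v[2]))
  p <- par$penumbra_mm
  au <- logistic((u - (tu - wu)) / p) * logistic(((tu + wu) - u) / p)
  av <- logistic((v - (tv - wv)) / p) * logistic(((tv + wv) - v) / p)
  outer(av, au)
}

# Chord length of the parallel ray through imager pixel (u, v) at gantry
# angle theta through an axis-aligned ellipsoid. Vectorised over the grid:
# the quadratic's u- and v-dependent parts separate, so the discriminant is
# an outer sum.
ellipsoid_chords <- function(u, v, theta_deg, o) {
  t_rad <- theta_deg * pi / 180
  ct <- cos(t_rad); st <- sin(t_rad)
  A <- st^2 / o$a^2 + ct^2 / o$b^2
  ox <- u * ct - o$cx           # x-offset of ray origin, per column
  oy <- u * st - o$cy
  Bu <- 2 * (ox * st / o$a^2 - oy * ct / o$b^2)
  Cu <- ox^2 / o$a^2 + oy^2 / o$b^2
  Cv <- (v - o$cz)^2 / o$c^2
  disc <- outer(-4 * A * Cv, Bu^2 - 4 * A * (Cu - 1), `+`)
  sqrt(pmax(disc, 0)) / A
}

#' Simulate one transmission fluence map
#'
#' Projects the (shifted) phantom onto the imager plane at every gantry angle
#' of both arcs, attenuates the open beam exponentially along exact chord
#' lengths through the phantom primitives, applies the angle-specific
#' aperture, sums over all angles scaled so the open-field integrated dose
#' equals the fraction dose, and adds Gaussian detector noise.
#'
#' @param phantom a [generate_phantom()] result.
#' @param plan a [plan_model()].
#' @param error an [error_vector()] couch shift in mm.
#' @param config a [simulation_config()].
#' @param noise_seed seed for the detector noise draw.
#' @return A [fluence_map()] in cGy with the error vector attached.
#' @export
simulate_fluence <- function(phantom, plan, error = error_vector(),
                             config = simulation_config(), noise_seed = 1L) {
  error <- as_error_vector(error)
  n <- config$image_size
  fov_half <- n * config$pitch_mm / 2
  # pixel-centre coordinates in mm; rows (v) = SI, columns (u) = in-plane
  u <- (seq_len(n) - (n + 1) / 2) * config$pitch_mm
  v <- (seq_len(n) - (n + 1) / 2) * config$pitch_mm

  g <- config$magnification
  body <- phantom$objects[phantom$objects$kind == "body", ]
  in_plane_extent <- max(abs(body$cx) + body$a, abs(body$cy) + body$b)
  si_extent <- abs(body$cz) + body$c
  shift_in_plane <- g * sqrt(error[["lr"]]^2 + error[["ap"]]^2)
  shift_si <- g * abs(error[["si"]])
  fits_before <- in_plane_extent <= fov_half && si_extent <= fov_half
  if (g * max(abs(error)) > fov_half ||
      (fits_before && (in_plane_extent + shift_in_plane > fov_half ||
                       si_extent + shift_si > fov_half)))
    stop("error vector pushes the phantom outside the simulated field of view",
         call. = FALSE)

  # couch shift applied to the anatomy (not the machine-side apertures)
  ob <- phantom$objects
  ob$cx <- ob$cx + g * error[["lr"]]
  ob$cy <- ob$cy + g * error[["ap"]]
  ob$cz <- ob$cz + g * error[["si"]]

  arcs <- plan$arcs
  angle_sets <- lapply(seq_len(nrow(arcs)), function(i)
    arc_angles(arcs$start_deg[i], arcs$stop_deg[i], arcs$sense[i],
               arcs$step_deg[i]))
  n_angles <- sum(lengths(angle_sets))
  per_angle_dose <- config$dose_cgy / n_angles

  dose <- matrix(0, n, n)
  for (i in seq_len(nrow(arcs))) {
    par <- aperture_params(arcs$aperture_seed[i])
    for (theta in angle_sets[[i]]) {
      expo <- matrix(0, n, n)
      for (k in seq_len(nrow(ob)))
        expo <- expo + ob$mu[k] * ellipsoid_chords(u, v, theta, ob[k, ])
      dose <- dose + per_angle_dose *
        aperture_mask(u, v, theta, phantom$target, par) * exp(-expo)
    }
  }

  if (config$noise_sigma_frac > 0) {
    sigma <- config$noise_sigma_frac * config$dose_cgy
    dose <- dose + local_seed(noise_seed,
                              matrix(stats::rnorm(n * n, 0, sigma), n, n))
    dose <- pmax(dose, 0)
  }
  fluence_map(dose, pitch_mm = config$pitch_mm,
              patient_id = as.character(phantom$seed), error = error,
              meta = list(noise_seed = as.integer(noise_seed),
                          magnification = g))
}

#' Generate a labelled synthetic cohort
#'
#' For every synthetic patient, simulates the baseline acquisition plus one
#' map for each of the 27 error positions of the 0/2/4 mm design (the
#' no-error position is re-simulated with a fresh noise seed, mirroring a
#' repeat measurement), 28 maps per patient. Each map row carries its full
#' label set.
#'
#' @param config a [simulation_config()].
#' @param keep_maps if `FALSE`, drop the pixel data and keep only the record
#'   metadata (useful for census checks at scale).
#' @return A tibble with one row per map: `patient_id`, `serial`, `role`
#'   (`"baseline"` or `"error"`), `lr_mm`, `si_mm`, `ap_mm`, the label
#'   columns of [assign_labels()] (NA for the baseline), `noise_seed`, and a
#'   `map` list-column of [fluence_map()] objects (unless dropped).
#' @examples
#' \donttest{
#' cohort <- generate_cohort(reduced_config(size = 64, n_patients = 2))
#' nrow(cohort) # 56
#' }
#' @export
generate_cohort <- function(config = simulation_config(), keep_maps = TRUE) {
  stopifnot(config$n_patients >= 1)
  patient_seeds <- derive_seeds(config$master_seed, config$n_patients)
  grid <- design_error_grid()
  labels <- build_label_table()

  per_patient <- function(p) {
    pseed <- patient_seeds[p]
    phantom <- generate_phantom(pseed, config)
    plan <- plan_model(pseed, config)
    noise_seeds <- derive_seeds(pseed + 1L, nrow(grid) + 1L)
    sim <- function(e, ns) simulate_fluence(phantom, plan, e, config, ns)
    base_row <- tibble::tibble(
      patient_id = sprintf("P%03d", p), serial = 1L, role = "baseline",
      lr_mm = 0, si_mm = 0, ap_mm = 0, isocenter_mm = NA_real_,
      type1 = NA_integer_, type2_lr = NA_integer_, type2_si = NA_integer_,
      type2_ap = NA_integer_, type3 = NA_integer_,
      noise_seed = noise_seeds[1],
      map = list(sim(error_vector(), noise_seeds[1])))
    err_rows <- purrr::map(seq_len(nrow(grid)), function(i) {
      e <- error_vector(grid[i, "lr"], grid[i, "si"], grid[i, "ap"])
      lab <- labels[i, ]
      tibble::tibble(
        patient_id = sprintf("P%03d", p), serial = lab$serial, role = "error",
        lr_mm = lab$lr_mm, si_mm = lab$si_mm, ap_mm = lab$ap_mm,
        isocenter_mm = lab$isocenter_mm, type1 = lab$type1,
        type2_lr = lab$type2_lr, type2_si = lab$type2_si,
        type2_ap = lab$type2_ap, type3 = lab$type3,
        noise_seed = noise_seeds[i + 1L],
        map = list(sim(e, noise_seeds[i + 1L])))
    })
    dplyr::bind_rows(base_row, err_rows)
  }

  cohort <- dplyr::bind_rows(lapply(seq_len(config$n_patients), per_patient))
  if (!keep_maps) cohort$map <- NULL
  attr(cohort, "config") <- config
  cohort
}
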