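#' Default template dimensions
#'
#' Anatomical dimensions (mm) of the parametric thoracolumbar template,
#' scaled linearly with standing height from the reference adolescent
#' (157.2 cm). Sagittal curvature defaults are taken from adolescent
#' normative ranges; every value can be overridden.
#'
#' @param height_cm standing height used for isotropic scaling.
#' @param lumbar_lordosis_deg total L1-S1 lordosis (degrees).
#' @param thoracic_kyphosis_deg total T1-T12 kyphosis (degrees).
#' @return named list of dimensions.
#' @export
default_template_dims <- function(height_cm = 157.2,
                                  lumbar_lordosis_deg = 50,
                                  thoracic_kyphosis_deg = 38) {
  sc <- height_cm / 157.2
  list(
    scale = sc,
    s1_ap = 35 * sc, s1_ml = 40 * sc,
    sacrum_depth = 55 * sc,
    disc_h = 9 * sc,
    gp_h = 2.1 * sc,               # total growth-plate thickness (3 layers)
    dome_height = 3 * sc,          # sacral dome spherical-cap height
    body_h = c(L4 = 23, L5 = 24) * sc,
    body_ap = c(L4 = 34, L5 = 35) * sc,
    body_ml = c(L4 = 39, L5 = 40) * sc,
    pedicle_len = 12 * sc, pars_len = 10 * sc,
    hip_offset = 95 * sc,          # S1 midplate to bicoxofemoral axis
    hip_halfspan = 75 * sc,
    # beam-segment vertebrae, cranial to caudal (T1..T12, L1..L3)
    chain_levels = c(paste0("T", 1:12), paste0("L", 1:3)),
    chain_body_h = (c(seq(16, 21, length.out = 12),
                      seq(22, 23, length.out = 3))) * sc,
    chain_disc_h = (c(rep(5, 12), rep(8, 3))) * sc,
    chain_ap = (c(seq(20, 28, length.out = 12),
                  seq(30, 33, length.out = 3))) * sc,
    chain_ml = (c(seq(24, 32, length.out = 12),
                  seq(34, 38, length.out = 3))) * sc,
    rib_radius = seq(45, 115, length.out = 12) * sc,
    lumbar_lordosis = lumbar_lordosis_deg,
    thoracic_kyphosis = thoracic_kyphosis_deg
  )
}

# sagittal unit vectors for a plate tilted by theta degrees to the horizontal
# (plate descends anteriorly): along-plate anterior direction and upward normal
.plate_dir <- function(theta_deg) {
  t <- .rad(theta_deg)
  c(cos(t), 0, -sin(t))
}
.plate_normal <- function(theta_deg) {
  t <- .rad(theta_deg)
  c(sin(t), 0, cos(t))
}

# in-plane rotation in the sagittal (x-z) plane that increases plate tilt
# (rotates the anterior direction downward) by alpha degrees
.sagittal_rotation <- function(alpha_deg) {
  a <- .rad(alpha_deg)
  matrix(c(cos(a), 0, sin(a),
           0, 1, 0,
           -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
}

# 17 canonical landmarks of one vertebra from its inferior/superior plate
# centers and tilts
.vertebra_landmarks <- function(level, c_inf, theta_inf, c_sup, theta_sup,
                                ap, ml) {
  e_s <- .plate_dir(theta_sup); e_i <- .plate_dir(theta_inf)
  yhat <- c(0, 1, 0)
  centroid <- (c_inf + c_sup) / 2
  p_hat <- -.plate_dir((theta_inf + theta_sup) / 2)  # posterior
  pts <- rbind(
    sup_plate_ant = c_sup + ap / 2 * e_s,
    sup_plate_post = c_sup - ap / 2 * e_s,
    sup_plate_left = c_sup + ml / 2 * yhat,
    sup_plate_right = c_sup - ml / 2 * yhat,
    inf_plate_ant = c_inf + ap / 2 * e_i,
    inf_plate_post = c_inf - ap / 2 * e_i,
    inf_plate_left = c_inf + ml / 2 * yhat,
    inf_plate_right = c_inf - ml / 2 * yhat,
    sup_plate_center = c_sup,
    inf_plate_center = c_inf,
    body_centroid = centroid,
    pedicle_left = centroid + 0.62 * ap * p_hat + 0.35 * ml * yhat,
    pedicle_right = centroid + 0.62 * ap * p_hat - 0.35 * ml * yhat,
    transverse_left = centroid + 0.68 * ap * p_hat + 0.95 * ml * yhat,
    transverse_right = centroid + 0.68 * ap * p_hat - 0.95 * ml * yhat,
    spinous_tip = centroid + 1.45 * ap * p_hat - c(0, 0, 0.25 * ap),
    arch_center = centroid + 1.0 * ap * p_hat
  )
  data.frame(structure = level, index = seq_len(17),
             name = rownames(pts),
             x = pts[, 1], y = pts[, 2], z = pts[, 3],
             stringsAsFactors = FALSE, row.names = NULL)
}

.rib_landmarks <- function(level_idx, level, centroid, radius) {
  rows <- list()
  for (side in c("left", "right")) {
    sgn <- if (side == "left") 1 else -1
    t <- seq(0.15, 2.4, length.out = 11)
    pts <- cbind(centroid[1] - radius * 0.75 * cos(t) + 0.2 * radius,
                 centroid[2] + sgn * radius * sin(t),
                 centroid[3] - (t / 2.4) * 0.35 * radius)
    rows[[side]] <- data.frame(
      structure = sprintf("rib_%s_%s", level, side), index = 1:11,
      name = .rib_landmark_names, x = pts[, 1], y = pts[, 2], z = pts[, 3],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate the parametric template geometry
#'
#' Constructs the full landmark-based model the radiographic reconstruction
#' would deliver: 17 landmarks for each vertebra T1-L5, 11 per rib, 23 on the
#' pelvis, plus the sacrum, arranged so that the spino-pelvic parameters
#' measured from the landmarks ([measure_spinopelvic()]) equal the requested
#' targets. Default targets and patient scalars are the reference adolescent
#' case: PI 61 deg, SS 52 deg, Grade II slip, age 14, height 157.2 cm,
#' weight 45.5 kg.
#'
#' @param targets list with `PI`, `SS` (degrees) and `slip_pct` (%).
#' @param patient list with `age`, `height_cm`, `weight_kg`.
#' @param dims template dimensions, see [default_template_dims()].
#' @param include_ribs generate rib landmark arcs (12 levels, both sides).
#' @return a `spine_geometry` object: fields `landmarks` (a [landmark_set()]),
#'   `patient`, `dims`, `targets`.
#' @export
generate_template_geometry <- function(
    targets = list(PI = 61, SS = 52, slip_pct = 30),
    patient = list(age = 14, height_cm = 157.2, weight_kg = 45.5),
    dims = default_template_dims(patient$height_cm),
    include_ribs = TRUE) {
  PI_t <- targets$PI; SS_t <- targets$SS; slip_t <- targets$slip_pct
  PT_t <- PI_t - SS_t
  if (!is.finite(PI_t) || !is.finite(SS_t) || !is.finite(slip_t)) {
    stop("targets must be finite")
  }
  if (SS_t <= 5 || SS_t >= 80 || PT_t < -15 || PT_t > 45 ||
      slip_t < 0 || slip_t > 120) {
    stop(sprintf(
      "unrealizable spino-pelvic targets (PI=%g, SS=%g => PT=%g, slip=%g%%)",
      PI_t, SS_t, PT_t, slip_t))
  }

  m <- c(0, 0, 0)                       # S1 superior endplate midpoint
  yhat <- c(0, 1, 0)

  ## --- sacrum -------------------------------------------------------------
  e0 <- .plate_dir(SS_t); n0 <- .plate_normal(SS_t)
  ax <- .sagittal_rotation(15) %*% (-n0)  # sacral axis, tipped posteriorly
  sac <- rbind(
    s1_plate_ant = m + dims$s1_ap / 2 * e0,
    s1_plate_post = m - dims$s1_ap / 2 * e0,
    s1_plate_left = m + dims$s1_ml / 2 * yhat,
    s1_plate_right = m - dims$s1_ml / 2 * yhat,
    s1_plate_center = m,
    sacrum_centroid = m + 0.5 * dims$sacrum_depth * as.numeric(ax),
    sacrum_apex = m + 1.6 * dims$sacrum_depth * as.numeric(ax),
    ala_left = m + 0.9 * dims$s1_ml * yhat - c(0, 0, 10),
    ala_right = m - 0.9 * dims$s1_ml * yhat - c(0, 0, 10)
  )
  sacrum_df <- data.frame(structure = "sacrum", index = seq_len(nrow(sac)),
                          name = rownames(sac), x = sac[, 1], y = sac[, 2],
                          z = sac[, 3], stringsAsFactors = FALSE)

  ## --- pelvis (23 landmarks) ----------------------------------------------
  h <- m + dims$hip_offset * c(sin(.rad(PT_t)), 0, -cos(.rad(PT_t)))
  hs <- dims$hip_halfspan
  pel <- rbind(
    femoral_head_left = h + hs * yhat,
    femoral_head_right = h - hs * yhat,
    acetabulum_left = h + hs * yhat,
    acetabulum_right = h - hs * yhat,
    asis_left = h + c(30, 120, 40), asis_right = h + c(30, -120, 40),
    psis_left = m + c(-40, 45, 5), psis_right = m + c(-40, -45, 5),
    iliac_crest_left = m + c(-10, 130, 60),
    iliac_crest_right = m + c(-10, -130, 60),
    ischial_tuberosity_left = h + c(-15, 60, -70),
    ischial_tuberosity_right = h + c(-15, -60, -70),
    pubic_symphysis = h + c(40, 0, -50),
    pubic_tubercle_left = h + c(45, 30, -45),
    pubic_tubercle_right = h + c(45, -30, -45),
    sciatic_notch_left = m + c(-25, 55, -35),
    sciatic_notch_right = m + c(-25, -55, -35),
    iliac_spine_inf_left = h + c(25, 95, 15),
    iliac_spine_inf_right = h + c(25, -95, 15),
    sacroiliac_left = m + c(-20, 40, -5),
    sacroiliac_right = m + c(-20, -40, -5),
    pelvic_inlet_center = h + c(10, 0, -10),
    hip_axis_center = h
  )
  pelvis_df <- data.frame(structure = "pelvis", index = seq_len(23),
                          name = rownames(pel), x = pel[, 1], y = pel[, 2],
                          z = pel[, 3], stringsAsFactors = FALSE)

  ## --- lumbosacral detailed levels L5, L4 ---------------------------------
  lam <- dims$lumbar_lordosis
  # plate tilts walking cranially; lordosis fractions per interface
  th <- c(s1 = SS_t,
          l5i = SS_t - 0.25 * lam, l5s = SS_t - 0.40 * lam,
          l4i = SS_t - 0.50 * lam, l4s = SS_t - 0.62 * lam)
  step <- function(from, h, th_a, th_b) {
    from + h * .plate_normal((th_a + th_b) / 2)
  }
  c_l5i <- step(m, dims$disc_h + dims$gp_h, th["s1"], th["l5i"])
  c_l5s <- step(c_l5i, dims$body_h["L5"], th["l5i"], th["l5s"])
  c_l4i <- step(c_l5s, dims$disc_h, th["l5s"], th["l4i"])
  c_l4s <- step(c_l4i, dims$body_h["L4"], th["l4i"], th["l4s"])
  verts <- rbind(
    .vertebra_landmarks("L5", c_l5i, th["l5i"], c_l5s, th["l5s"],
                        dims$body_ap["L5"], dims$body_ml["L5"]),
    .vertebra_landmarks("L4", c_l4i, th["l4i"], c_l4s, th["l4s"],
                        dims$body_ap["L4"], dims$body_ml["L4"]))

  ## --- beam-segment levels L3..T1 (walk cranially) ------------------------
  nlev <- length(dims$chain_levels)     # T1..T12, L1..L3 cranio-caudal
  # tilts cranially above L4: remaining lumbar lordosis then kyphosis
  tilts <- numeric(nlev)
  names(tilts) <- dims$chain_levels
  tilts[c("L3", "L2", "L1")] <- SS_t - c(0.75, 0.87, 1.0) * lam
  kap <- dims$thoracic_kyphosis
  tilts[paste0("T", 12:1)] <- (SS_t - lam) - seq(0.08, 1, length.out = 12) * kap
  pos <- c_l4s
  th_prev <- th[["l4s"]]
  chain_rows <- list()
  rib_rows <- list()
  for (lv in rev(dims$chain_levels)) {      # caudal to cranial: L3 ... T1
    i <- match(lv, dims$chain_levels)
    th_i <- tilts[[lv]]
    c_inf <- pos + dims$chain_disc_h[i] * .plate_normal((th_prev + th_i) / 2)
    c_sup <- c_inf + dims$chain_body_h[i] * .plate_normal(th_i)
    chain_rows[[lv]] <- .vertebra_landmarks(lv, c_inf, th_i, c_sup, th_i,
                                            dims$chain_ap[i], dims$chain_ml[i])
    if (include_ribs && grepl("^T", lv)) {
      rib_rows[[lv]] <- .rib_landmarks(i, lv, (c_inf + c_sup) / 2,
                                       dims$rib_radius[i])
    }
    pos <- c_sup
    th_prev <- th_i
  }

  all_df <- do.call(rbind, c(list(sacrum_df, pelvis_df, verts),
                             chain_rows, rib_rows))
  lms <- landmark_set(all_df$structure, all_df$index, all_df$x, all_df$y,
                      all_df$z, name = all_df$name)
  geom <- structure(
    list(landmarks = lms, patient = patient, dims = dims,
         targets = list(PI = PI_t, SS = SS_t, slip_pct = slip_t)),
    class = "spine_geometry")
  geom <- apply_slip(geom, slip_t)   # also corrects the raw template's
                                     # wedge-induced offset when slip_t = 0

  got <- measure_spinopelvic(geom)
  if (abs(got$PI - PI_t) > 0.1 || abs(got$SS - SS_t) > 0.1 ||
      abs(got$slip_pct - slip_t) > 0.1) {
    stop("template generation failed to realize the requested targets")
  }
  geom
}

#' @export
print.spine_geometry <- function(x, ...) {
  p <- measure_spinopelvic(x)
  cat(sprintf(
    "<spine_geometry> %d landmarks | PI %.1f SS %.1f PT %.1f deg, slip %.1f%% (grade %s, %s)\n",
    nrow(x$landmarks), p$PI, p$SS, p$PT, p$slip_pct, p$grade, p$config_type))
  invisible(x)
}

#' Measure spino-pelvic parameters of a geometry
#'
#' Computes PI/SS/PT from the pelvis and sacrum landmarks and the slip
#' percentage from the L5 inferior endplate relative to the S1 superior
#' endplate (Taillard).
#'
#' @param geometry a `spine_geometry`.
#' @param cutoffs see [classification_cutoffs()].
#' @return a `spinopelvic_params`.
#' @export
measure_spinopelvic <- function(geometry, cutoffs = classification_cutoffs()) {
  lms <- geometry$landmarks
  slip <- slip_from_geometry(geometry)
  compute_spinopelvic_params(
    lms[lms$structure == "pelvis", ], lms[lms$structure == "sacrum", ],
    slip_pct = slip, cutoffs = cutoffs)
}

#' Slip percentage measured from a geometry's landmarks
#' @param geometry a `spine_geometry`.
#' @return slip percentage.
#' @export
slip_from_geometry <- function(geometry) {
  lms <- geometry$landmarks
  l5 <- landmark_coords(lms, "L5", c("inf_plate_ant", "inf_plate_post"))
  s1 <- landmark_coords(lms, "sacrum", c("s1_plate_ant", "s1_plate_post"))
  compute_slip_percentage(
    list(anterior = l5["inf_plate_ant", ], posterior = l5["inf_plate_post", ]),
    list(anterior = s1["s1_plate_ant", ], posterior = s1["s1_plate_post", ]))
}

.distal_structures <- function(geometry) c("sacrum", "pelvis")

#' Set the slip percentage of a geometry
#'
#' Rigidly offsets the pelvis and sacrum landmark groups along the
#' posteroanterior in-plane axis of the L5 inferior endplate so that the
#' measured Taillard slip percentage equals the target. Positive slip moves
#' L5 anteriorly relative to S1 (equivalently, the pelvis posteriorly in
#' L5's local frame); all other structures are untouched.
#'
#' @param geometry a `spine_geometry`.
#' @param target_slip_pct requested slip percentage (>= 0).
#' @return the modified geometry.
#' @export
apply_slip <- function(geometry, target_slip_pct) {
  if (is.na(target_slip_pct) || target_slip_pct < 0) {
    stop("target slip percentage must be non-negative")
  }
  lms <- geometry$landmarks
  l5 <- landmark_coords(lms, "L5", c("inf_plate_ant", "inf_plate_post"))
  s1 <- landmark_coords(lms, "sacrum", c("s1_plate_ant", "s1_plate_post"))
  a_hat <- l5["inf_plate_ant", ] - l5["inf_plate_post", ]
  a_hat <- a_hat / sqrt(sum(a_hat^2))
  d <- (s1["s1_plate_ant", ] - s1["s1_plate_post", ])[c(1, 3)]
  w <- sqrt(sum(d^2))
  e <- d / w
  s0 <- slip_from_geometry(geometry)
  proj <- sum(a_hat[c(1, 3)] * e)
  if (abs(proj) < 1e-9) {
    stop("L5 endplate axis is orthogonal to the S1 endplate; cannot set slip")
  }
  delta <- (target_slip_pct - s0) / 100 * w / proj
  groups <- .distal_structures(geometry)
  sel <- lms$structure %in% groups
  shift <- -delta * a_hat
  lms$x[sel] <- lms$x[sel] + shift[1]
  lms$y[sel] <- lms$y[sel] + shift[2]
  lms$z[sel] <- lms$z[sel] + shift[3]
  geometry$landmarks <- lms
  geometry
}

#' Set pelvic incidence and sacral slope of a geometry
#'
#' Applies sagittal-plane rotations about the center of the S1 superior
#' endplate: first the sacrum and pelvis rotate together until the sacral
#' slope matches its target (this leaves PI, a morphological parameter of
#' the sacro-pelvic complex, unchanged), then the pelvis rotates relative to
#' the sacrum until the pelvic incidence matches. Pairwise distances within
#' each rotated group are preserved exactly; the S1 plate center is a fixed
#' point.
#'
#' @param geometry a `spine_geometry`.
#' @param target_PI,target_SS targets in degrees.
#' @return the modified geometry (recomputed PI/SS within 0.1 deg of targets).
#' @export
apply_pelvic_rotation <- function(geometry, target_PI, target_SS) {
  p0 <- measure_spinopelvic(geometry)
  lms <- geometry$landmarks
  s1 <- landmark_coords(lms, "sacrum", c("s1_plate_ant", "s1_plate_post"))
  center <- colMeans(s1)

  rotate_group <- function(lms, structures, alpha_deg) {
    R <- .sagittal_rotation(alpha_deg)
    sel <- lms$structure %in% structures
    X <- t(cbind(lms$x[sel], lms$y[sel], lms$z[sel])) - center
    Xr <- R %*% X + center
    lms$x[sel] <- Xr[1, ]; lms$y[sel] <- Xr[2, ]; lms$z[sel] <- Xr[3, ]
    lms
  }
  # 1) whole sacro-pelvic block: set SS (PI invariant under rigid rotation)
  lms <- rotate_group(lms, c("sacrum", "pelvis"), target_SS - p0$SS)
  # 2) pelvis relative to sacrum: set PI (a sagittal rotation by beta
  #    decreases PT, hence PI, by beta)
  lms <- rotate_group(lms, "pelvis", p0$PI - target_PI)
  geometry$landmarks <- lms

  got <- measure_spinopelvic(geometry)
  if (abs(got$PI - target_PI) > 0.1 || abs(got$SS - target_SS) > 0.1) {
    stop("pelvic rotation failed to reach the requested PI/SS")
  }
  geometry
}

#' Simulate the radiographic reconstruction's landmark noise
#'
#' Perturbs every template landmark with isotropic Gaussian noise emulating
#' the 3.3 mm average accuracy of the multi-view reconstruction.
#'
#' @param template a `spine_geometry`.
#' @param noise_sd_mm isotropic standard deviation per axis (mm); default 3.3.
#' @param seed optional integer seed for reproducible draws.
#' @return a `landmark_set` with perturbed coordinates.
#' @export
generate_patient_landmarks <- function(template, noise_sd_mm = 3.3,
                                       seed = NULL) {
  if (noise_sd_mm < 0) stop("noise_sd_mm must be >= 0")
  lms <- template$landmarks
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  n <- nrow(lms)
  lms$x <- lms$x + stats::rnorm(n, 0, noise_sd_mm)
  lms$y <- lms$y + stats::rnorm(n, 0, noise_sd_mm)
  lms$z <- lms$z + stats::rnorm(n, 0, noise_sd_mm)
  lms
}
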