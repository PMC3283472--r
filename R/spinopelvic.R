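#' Spino-pelvic parameters
#'
#' Sagittal spino-pelvic parameters computed from anatomical landmarks.
#' All angles are measured in the sagittal (x-z) plane of the global frame
#' (x anterior, z superior, gravity along -z):
#' \itemize{
#'   \item sacral slope (SS): inclination of the S1 superior endplate to the
#'     horizontal (the plate descends anteriorly in a lordotic spine);
#'   \item pelvic tilt (PT): angle between the vertical and the line joining
#'     the bicoxofemoral (hip) axis midpoint to the S1 endplate midpoint;
#'   \item pelvic incidence (PI): angle between the perpendicular to the S1
#'     endplate at its midpoint and the line to the hip-axis midpoint.
#' }
#' With signed sagittal angles these satisfy the classical identity
#' PI = SS + PT exactly.
#'
#' @param pelvis_landmarks `landmark_set` (or subset) containing
#'   `femoral_head_left` and `femoral_head_right`.
#' @param sacrum_landmarks `landmark_set` containing `s1_plate_ant` and
#'   `s1_plate_post`.
#' @param slip_pct optional slip percentage to carry into the parameter set.
#' @param cutoffs classification cutoffs, see [classify_configuration()].
#' @return a `spinopelvic_params` list with fields `PI`, `SS`, `PT` (degrees),
#'   `slip_pct`, `grade`, `config_type`.
#' @export
compute_spinopelvic_params <- function(pelvis_landmarks, sacrum_landmarks,
                                       slip_pct = NA_real_,
                                       cutoffs = classification_cutoffs()) {
  fh <- landmark_coords(pelvis_landmarks,
                        names = c("femoral_head_left", "femoral_head_right"))
  s1 <- landmark_coords(sacrum_landmarks,
                        names = c("s1_plate_ant", "s1_plate_post"))
  a <- s1["s1_plate_ant", ]
  p <- s1["s1_plate_post", ]
  h <- colMeans(fh)                       # bicoxofemoral axis midpoint
  m <- (a + p) / 2                        # S1 endplate midpoint
  d <- a - p                              # along-plate, pointing anterior
  if (sqrt(d[1]^2 + d[3]^2) < 1e-9) stop("degenerate S1 endplate landmarks")
  SS <- .deg(atan2(-d[3], d[1]))
  # signed sagittal angle of a vector, measured from straight-down (-z)
  # towards anterior (+x)
  ang_down <- function(v) .deg(atan2(v[1], -v[3]))
  # downward endplate perpendicular: rotate the anterior along-plate
  # direction by -90 degrees about +y in the sagittal plane
  perp_down <- c(-(-d[3]), 0, -d[1]) / sqrt(d[1]^2 + d[3]^2)
  PI <- ang_down(h - m) - ang_down(perp_down)
  PT <- ang_down(h - m)
  params <- list(PI = unname(PI), SS = unname(SS), PT = unname(PT),
                 slip_pct = slip_pct,
                 grade = if (is.na(slip_pct)) NA_character_
                         else meyerding_grade(slip_pct),
                 config_type = NA_character_)
  class(params) <- "spinopelvic_params"
  if (!is.na(slip_pct)) {
    params$config_type <- classify_configuration(params, cutoffs)
  }
  params
}

.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180

#' @export
print.spinopelvic_params <- function(x, ...) {
  cat(sprintf(
    "<spinopelvic_params> PI %.1f deg  SS %.1f deg  PT %.1f deg\n",
    x$PI, x$SS, x$PT))
  if (!is.na(x$slip_pct)) {
    cat(sprintf("  slip %.1f%%  grade %s  type %s\n",
                x$slip_pct, x$grade, x$config_type))
  }
  invisible(x)
}

.plate_points <- function(plate, which) {
  if (is.list(plate) && !is.data.frame(plate)) {
    if (!which %in% names(plate)) stop("plate is missing its ", which, " point")
    return(as.numeric(plate[[which]]))
  }
  m <- as.matrix(plate)
  rn <- rownames(m)
  hit <- grep(which, rn)
  if (!length(hit)) stop("plate is missing its ", which, " point")
  as.numeric(m[hit[1], ])
}

#' Slip percentage (Taillard)
#'
#' Posteroanterior displacement of the L5 inferior endplate over the S1
#' superior endplate, divided by the anteroposterior width of the S1 superior
#' endplate, times 100. Positive values mean anterior slippage of L5, the
#' direction relevant to isthmic spondylolisthesis. Displacement and width are
#' measured along the S1 endplate direction projected on the sagittal plane.
#'
#' @param l5_inferior_plate,s1_superior_plate plate descriptions: either a
#'   named list with `anterior`/`posterior` 3-vectors, or a point matrix whose
#'   rownames contain "anterior"/"posterior" (landmark names such as
#'   `inf_plate_ant` work via partial matching by [slip_from_geometry()]).
#' @return slip percentage (numeric scalar).
#' @export
compute_slip_percentage <- function(l5_inferior_plate, s1_superior_plate) {
  a5 <- .plate_points(l5_inferior_plate, "anterior")
  p5 <- .plate_points(l5_inferior_plate, "posterior")
  a1 <- .plate_points(s1_superior_plate, "anterior")
  p1 <- .plate_points(s1_superior_plate, "posterior")
  d <- (a1 - p1)[c(1, 3)]
  w <- sqrt(sum(d^2))
  if (w < 1e-9) stop("S1 superior endplate has zero anteroposterior width")
  e <- d / w
  m5 <- ((a5 + p5) / 2)[c(1, 3)]
  m1 <- ((a1 + p1) / 2)[c(1, 3)]
  100 * sum((m5 - m1) * e) / w
}

#' Meyerding grade from slip percentage
#'
#' Standard Meyerding convention in 25% increments: 0 -> none, (0,25] -> I,
#' (25,50] -> II, (50,75] -> III, (75,100] -> IV, >100 -> V (spondyloptosis).
#'
#' @param slip_pct slip percentage, must be >= 0.
#' @return character grade: one of "none", "I".."V".
#' @export
meyerding_grade <- function(slip_pct) {
  slip_pct[slip_pct < 0 & slip_pct > -1e-9] <- 0   # measurement round-off
  if (any(is.na(slip_pct)) || any(slip_pct < 0)) {
    stop("slip percentage must be non-negative")
  }
  vapply(slip_pct, function(s) {
    if (s == 0) "none"
    else if (s <= 25) "I"
    else if (s <= 50) "II"
    else if (s <= 75) "III"
    else if (s <= 100) "IV"
    else "V"
  }, character(1))
}

#' Classification cutoffs for spondylolisthesis configuration types
#'
#' The clinical classification distinguishes, within low-grade slips,
#' "nutcracker" (low PI / low SS) from "shear" (high PI / high SS) types and,
#' within high-grade slips, "balanced" (high SS / low PT) from "retroverted"
#' (low SS / high PT) pelvises. The published classification gives no numeric
#' boundaries; the defaults below are configurable.
#'
#' @param pi_shear PI at or above which (with `ss_shear`) a low-grade slip is
#'   shear-type (degrees).
#' @param ss_shear SS cutoff paired with `pi_shear` (degrees).
#' @param pt_retro PT at or above which a high-grade pelvis is retroverted
#'   (degrees).
#' @return named list of cutoffs.
#' @export
classification_cutoffs <- function(pi_shear = 60, ss_shear = 50,
                                   pt_retro = 25) {
  list(pi_shear = pi_shear, ss_shear = ss_shear, pt_retro = pt_retro)
}

#' Classify a spondylolisthesis configuration
#'
#' @param params a `spinopelvic_params` (grade and PI/SS/PT known).
#' @param cutoffs see [classification_cutoffs()].
#' @return one of "nutcracker", "shear", "balanced", "retroverted".
#' @export
classify_configuration <- function(params, cutoffs = classification_cutoffs()) {
  grade <- params$grade
  if (is.null(grade) || is.na(grade)) {
    grade <- meyerding_grade(params$slip_pct)
  }
  high <- grade %in% c("III", "IV", "V")
  if (!high) {
    if (params$PI >= cutoffs$pi_shear && params$SS >= cutoffs$ss_shear) {
      "shear"
    } else {
      "nutcracker"
    }
  } else {
    if (params$PT >= cutoffs$pt_retro) "retroverted" else "balanced"
  }
}

#' Write a spino-pelvic parameter report as JSON
#'
#' @param params a `spinopelvic_params`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_spinopelvic_json <- function(params, path) {
  jsonlite::write_json(
    list(PI_deg = params$PI, SS_deg = params$SS, PT_deg = params$PT,
         slip_pct = params$slip_pct, grade = params$grade,
         config_type = params$config_type),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
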