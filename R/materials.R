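#' Default material library
#'
#' Linear-elastic properties for every anatomical region the detailed mesh
#' emits, taken from the spine finite-element literature: stiff cortical
#' shell, soft trabecular core, annulus fibrosus and near-incompressible
#' nucleus pulposus, the three growth-plate sub-zones (sensitive zone,
#' newly formed bone layer, transition zone), posterior bony arch, and
#' spring stiffnesses for ligaments and facet contact. All values are
#' defaults and can be overridden from a YAML configuration
#' ([material_library_from_yaml()]).
#'
#' @return a `material_library` data frame with columns `region`, `E`
#'   (MPa), `nu`, `spring_k` (N/mm, NA for solids).
#' @export
default_material_library <- function() {
  lib <- data.frame(
    region = c("cortical", "trabecular", "endplate",
               "annulus", "nucleus",
               "gp_sensitive", "gp_newbone", "gp_transition",
               "pedicle", "pars", "arch",
               "vertebra_beam", "disc_beam", "rib_beam", "pelvis_beam",
               "ligament_all", "ligament_pll", "ligament_isl", "facet"),
    E = c(12000, 100, 1000,
          4, 1,
          12, 50, 25,
          12000, 12000, 12000,
          10000, 150, 5000, 12000,
          NA, NA, NA, NA),
    nu = c(0.3, 0.2, 0.3,
           0.45, 0.499,
           0.45, 0.40, 0.45,
           0.3, 0.3, 0.3,
           0.3, 0.45, 0.3, 0.3,
           NA, NA, NA, NA),
    spring_k = c(rep(NA, 15), 20, 20, 10, 200),
    stringsAsFactors = FALSE)
  class(lib) <- c("material_library", "data.frame")
  lib
}

#' Look up solid material properties by region
#'
#' @param materials a `material_library`.
#' @param regions character vector of region labels.
#' @return data frame with columns `E`, `nu` (one row per input region).
#' @export
material_lookup <- function(materials, regions) {
  idx <- match(regions, materials$region)
  if (anyNA(idx)) {
    stop("no material defined for region(s): ",
         paste(unique(regions[is.na(idx)]), collapse = ", "))
  }
  out <- materials[idx, c("E", "nu")]
  if (anyNA(out$E) || anyNA(out$nu)) {
    stop("region(s) without solid properties used for solid elements: ",
         paste(unique(regions[is.na(materials$E[idx])]), collapse = ", "))
  }
  ok <- out$E > 0 & out$nu > 0 & out$nu < 0.5
  if (!all(ok)) stop("invalid material properties (need E > 0, 0 < nu < 0.5)")
  out
}

#' Merge material overrides into a library
#'
#' @param materials base `material_library`.
#' @param overrides named list: `region = list(E =, nu =, spring_k =)` or
#'   `region = <E>` shorthand.
#' @return the updated library.
#' @export
override_materials <- function(materials, overrides) {
  for (region in names(overrides)) {
    ov <- overrides[[region]]
    if (!is.list(ov)) ov <- list(E = ov)
    i <- match(region, materials$region)
    if (is.na(i)) {
      materials <- rbind(materials, data.frame(
        region = region, E = NA_real_, nu = NA_real_, spring_k = NA_real_))
      i <- nrow(materials)
    }
    for (fld in intersect(names(ov), c("E", "nu", "spring_k"))) {
      materials[[fld]][i] <- as.numeric(ov[[fld]])
    }
  }
  class(materials) <- c("material_library", "data.frame")
  materials
}

#' Read a model configuration from YAML
#'
#' The YAML schema has top-level blocks `targets` (PI, SS, slip_pct),
#' `patient` (age, height_cm, weight_kg), `materials` (per-region
#' overrides), `loading` (body weight fraction table, g, torsion spring
#' stiffness, follower tolerances) and `mesh` (resolution, ribs, pars
#' lysis, dome height). Every block is optional; defaults fill the gaps.
#'
#' @param path YAML file path.
#' @return a named list (`model_config`) merging the file over the defaults.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  merge_model_config(cfg)
}

#' Merge a configuration list over the package defaults
#' @param cfg partial configuration list (possibly NULL).
#' @return complete `model_config` list.
#' @export
merge_model_config <- function(cfg = NULL) {
  def <- list(
    targets = list(PI = 61, SS = 52, slip_pct = 30),
    patient = list(age = 14, height_cm = 157.2, weight_kg = 45.5),
    materials = list(),
    loading = list(
      g = 9.81,
      torsion_stiffness = 1000,       # N.mm/rad at each acetabulum
      follower_tol = 1e-3,            # rad, direction-change convergence
      follower_max_iter = 25,
      fraction_table = default_weight_fractions()),
    mesh = list(nx = 12, ny = 12, nz_body = 4, nz_disc = 2, nz_sacrum = 4,
                include_ribs = FALSE, pars_lysis = TRUE,
                dome_height_mm = 3))
  modifyList(def, if (is.null(cfg)) list() else cfg)
}

#' Default per-vertebra body-weight fraction table
#'
#' Fraction of total body weight applied at each vertebral body centroid,
#' following published trunk-segment weight distributions: head, neck and
#' arms enter at T1, thoracic and lumbar slices add their segmental mass
#' level by level. The table is fully overridable via the `loading` block
#' of the model configuration; cumulative fraction stays below 1.
#'
#' @return named numeric vector over T1..L5.
#' @export
default_weight_fractions <- function() {
  f <- c(0.14, rep(0.023, 11), rep(0.024, 5))
  names(f) <- c(paste0("T", 1:12), paste0("L", 1:5))
  f
}
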