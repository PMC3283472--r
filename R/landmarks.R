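#' Canonical landmark naming tables
#'
#' The multi-view radiographic reconstruction that this package emulates
#' delivers a fixed set of named 3D points per anatomical structure:
#' 17 per vertebra, 11 per rib and 23 on the pelvis. The tables below fix
#' the index -> name mapping so that landmark CSV files (which carry only
#' structure/index/coordinates) round-trip losslessly.
#'
#' @name landmark-names
#' @keywords internal
NULL

.vertebra_landmark_names <- c(
  "sup_plate_ant", "sup_plate_post", "sup_plate_left", "sup_plate_right",
  "inf_plate_ant", "inf_plate_post", "inf_plate_left", "inf_plate_right",
  "sup_plate_center", "inf_plate_center", "body_centroid",
  "pedicle_left", "pedicle_right", "transverse_left", "transverse_right",
  "spinous_tip", "arch_center"
)

.sacrum_landmark_names <- c(
  "s1_plate_ant", "s1_plate_post", "s1_plate_left", "s1_plate_right",
  "s1_plate_center", "sacrum_centroid", "sacrum_apex",
  "ala_left", "ala_right"
)

.pelvis_landmark_names <- c(
  "femoral_head_left", "femoral_head_right",
  "acetabulum_left", "acetabulum_right",
  "asis_left", "asis_right", "psis_left", "psis_right",
  "iliac_crest_left", "iliac_crest_right",
  "ischial_tuberosity_left", "ischial_tuberosity_right",
  "pubic_symphysis", "pubic_tubercle_left", "pubic_tubercle_right",
  "sciatic_notch_left", "sciatic_notch_right",
  "iliac_spine_inf_left", "iliac_spine_inf_right",
  "sacroiliac_left", "sacroiliac_right",
  "pelvic_inlet_center", "hip_axis_center"
)

.rib_landmark_names <- sprintf("rib_pt_%02d", 1:11)

.vertebra_levels <- c(paste0("T", 1:12), paste0("L", 1:5))

.landmark_names_for <- function(structure) {
  if (structure %in% .vertebra_levels) return(.vertebra_landmark_names)
  if (structure == "sacrum") return(.sacrum_landmark_names)
  if (structure == "pelvis") return(.pelvis_landmark_names)
  if (grepl("^rib_", structure)) return(.rib_landmark_names)
  NULL
}

#' Construct a landmark set
#'
#' A landmark set is the data model of the radiographic reconstruction: named
#' 3D points grouped by anatomical structure, in a global frame with x
#' anterior, y left and z superior (gravity along -z), coordinates in mm.
#'
#' @param structure character vector: structure id per point ("T1".."L5",
#'   "sacrum", "pelvis", "rib_<level>_<side>").
#' @param index integer point index within its structure (1-based).
#' @param x,y,z numeric coordinates in mm.
#' @param name optional point names; when omitted they are derived from the
#'   canonical per-structure naming tables.
#' @param validate when `TRUE` (default), enforce the reconstruction's point
#'   counts (17 per vertebra, 11 per rib, 23 on the pelvis) for structures
#'   that carry the full complement.
#' @return a `landmark_set` data frame with columns
#'   `structure, index, name, x, y, z`.
#' @export
landmark_set <- function(structure, index, x, y, z, name = NULL,
                         validate = TRUE) {
  n <- length(structure)
  stopifnot(length(index) == n, length(x) == n, length(y) == n,
            length(z) == n)
  if (!all(is.finite(c(x, y, z)))) {
    stop("landmark coordinates must be finite")
  }
  if (is.null(name)) {
    name <- character(n)
    for (s in unique(structure)) {
      sel <- structure == s
      nm <- .landmark_names_for(s)
      idx <- index[sel]
      if (!is.null(nm) && all(idx >= 1 & idx <= length(nm))) {
        name[sel] <- nm[idx]
      } else {
        name[sel] <- sprintf("pt_%02d", idx)
      }
    }
  }
  df <- data.frame(structure = as.character(structure),
                   index = as.integer(index), name = as.character(name),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[, c("structure", "index")])) {
    stop("duplicate (structure, index) pairs in landmark set")
  }
  class(df) <- c("landmark_set", "data.frame")
  if (validate) validate_landmark_set(df)
  df
}

#' Validate reconstruction point counts of a landmark set
#'
#' @param lms a `landmark_set`.
#' @return the landmark set, invisibly; errors on violated invariants.
#' @export
validate_landmark_set <- function(lms) {
  counts <- table(lms$structure)
  for (s in names(counts)) {
    expected <- if (s %in% .vertebra_levels) 17L
      else if (grepl("^rib_", s)) 11L
      else if (s == "pelvis") 23L
      else NA_integer_
    if (!is.na(expected) && counts[[s]] != expected) {
      stop(sprintf("structure '%s' has %d landmarks, expected %d",
                   s, counts[[s]], expected))
    }
  }
  invisible(lms)
}

#' Extract landmark coordinates as a matrix
#'
#' @param lms a `landmark_set`.
#' @param structure optional structure id filter.
#' @param names optional point-name filter (order preserved).
#' @return numeric matrix (n x 3) with rownames set to point names.
#' @export
landmark_coords <- function(lms, structure = NULL, names = NULL) {
  df <- lms
  if (!is.null(structure)) df <- df[df$structure %in% structure, , drop = FALSE]
  if (!is.null(names)) {
    miss <- setdiff(names, df$name)
    if (length(miss)) {
      stop("missing required landmarks: ", paste(miss, collapse = ", "))
    }
    df <- df[match(names, df$name), , drop = FALSE]
  }
  m <- as.matrix(df[, c("x", "y", "z")])
  rownames(m) <- df$name
  m
}

#' Replace coordinates of (a subset of) a landmark set
#'
#' @param lms a `landmark_set`.
#' @param coords n x 3 matrix of new coordinates.
#' @param structure optional structure filter selecting the rows replaced;
#'   row order must match `landmark_coords(lms, structure)`.
#' @return the updated landmark set.
#' @keywords internal
set_landmark_coords <- function(lms, coords, structure = NULL) {
  sel <- if (is.null(structure)) rep(TRUE, nrow(lms))
    else lms$structure %in% structure
  stopifnot(sum(sel) == nrow(coords))
  lms$x[sel] <- coords[, 1]
  lms$y[sel] <- coords[, 2]
  lms$z[sel] <- coords[, 3]
  lms
}

#' Read / write landmark CSV
#'
#' The on-disk interchange format is a plain CSV with one header row and
#' columns `structure,index,x_mm,y_mm,z_mm` (UTF-8). Point names are
#' reattached from the canonical naming tables on read.
#'
#' @param path file path.
#' @rdname landmark-csv
#' @return `read_landmark_csv`: a `landmark_set`.
#' @export
read_landmark_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("structure", "index", "x_mm", "y_mm", "z_mm")
  if (!all(required %in% names(df))) {
    stop("landmark CSV must have columns ", paste(required, collapse = ","))
  }
  landmark_set(df$structure, df$index, df$x_mm, df$y_mm, df$z_mm,
               validate = FALSE)
}

#' @param lms a `landmark_set` to write.
#' @rdname landmark-csv
#' @export
write_landmark_csv <- function(lms, path) {
  out <- data.frame(structure = lms$structure, index = lms$index,
                    x_mm = lms$x, y_mm = lms$y, z_mm = lms$z)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d points, %d structures\n",
              nrow(x), length(unique(x$structure))))
  counts <- table(x$structure)
  cat("  ", paste(sprintf("%s:%d", names(counts), counts), collapse = " "),
      "\n", sep = "")
  invisible(x)
}
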