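#' Build the L5 growth-plate local frame
#'
#' The analysis frame of the lumbosacral junction: origin at the middle
#' (centroid) of the growth-plate node cloud, the x'y'-plane on the plate,
#' y' oriented anteriorly in the sagittal plane, and z' normal to the plate
#' pointing opposite to gravity. x' = y' x z' completes a right-handed
#' orthonormal triad.
#'
#' @param plate_nodes m x 3 matrix of growth-plate node positions (m >= 3,
#'   not collinear).
#' @param gravity_direction unit gravity vector (default global -z).
#' @param anterior_direction global anterior direction used to fix y'.
#' @return a `plate_frame`: list with `origin` (mm) and `axes` (3 x 3 matrix
#'   with rows x', y', z').
#' @export
build_plate_frame <- function(plate_nodes, gravity_direction = c(0, 0, -1),
                              anterior_direction = c(1, 0, 0)) {
  X <- as.matrix(plate_nodes)
  if (nrow(X) < 3) stop("at least 3 plate nodes are required")
  origin <- colMeans(X)
  Xc <- sweep(X, 2, origin)
  sv <- svd(Xc)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300)) {
    stop("plate nodes are collinear; cannot define a plate frame")
  }
  zp <- sv$v[, 3]                      # plate normal (smallest variance)
  if (sum(zp * gravity_direction) > 0) zp <- -zp  # opposite to gravity
  yp <- anterior_direction - sum(anterior_direction * zp) * zp
  ny <- sqrt(sum(yp^2))
  if (ny < 1e-9) stop("anterior direction is normal to the plate")
  yp <- yp / ny
  xp <- c(yp[2] * zp[3] - yp[3] * zp[2],
          yp[3] * zp[1] - yp[1] * zp[3],
          yp[1] * zp[2] - yp[2] * zp[1])  # y' x z'
  axes <- rbind(xp = xp, yp = yp, zp = zp)
  structure(list(origin = origin, axes = axes), class = "plate_frame")
}

#' @export
print.plate_frame <- function(x, ...) {
  cat("<plate_frame> origin", sprintf("%.1f", x$origin), "mm\n")
  print(round(x$axes, 4))
  invisible(x)
}

.check_frame <- function(frame) {
  R <- frame$axes
  if (max(abs(R %*% t(R) - diag(3))) > 1e-8) {
    stop("plate frame axes are not orthonormal")
  }
  R
}

#' Transform a stress field into the plate frame
#'
#' Rotates each element stress tensor into the growth-plate local frame
#' (sigma' = R sigma R') and extracts the two scalars of interest:
#' \itemize{
#'   \item `sigma_n` = sigma'_z'z', the plate-normal stress (negative =
#'     compression, the component tied to growth modulation);
#'   \item `tau_slip` = sigma'_z'y', the shear on the plate acting along the
#'     sagittal anterior direction (positive = slip-promoting: the traction
#'     on the +z' face points anteriorly).
#' }
#'
#' @param stress_field a `stress_field` from [recover_hex_stresses()].
#' @param frame a [build_plate_frame()] result.
#' @return the stress field with added fields `S_local` (h x 6),
#'   `sigma_n`, `tau_slip`, `centroid_local` (h x 3) and `frame`.
#' @export
transform_to_plate_frame <- function(stress_field, frame) {
  R <- .check_frame(frame)
  S <- stress_field$S
  h <- nrow(S)
  S_local <- matrix(0, h, 6,
                    dimnames = list(NULL, c("xx", "yy", "zz", "xy", "yz", "zx")))
  for (e in seq_len(h)) {
    s <- S[e, ]
    Sm <- matrix(c(s[1], s[4], s[6],
                   s[4], s[2], s[5],
                   s[6], s[5], s[3]), 3, 3)
    Sl <- R %*% Sm %*% t(R)
    S_local[e, ] <- c(Sl[1, 1], Sl[2, 2], Sl[3, 3], Sl[1, 2], Sl[2, 3], Sl[1, 3])
  }
  stress_field$S_local <- S_local
  stress_field$sigma_n <- unname(S_local[, "zz"])
  stress_field$tau_slip <- unname(S_local[, "yz"])
  stress_field$centroid_local <-
    sweep(stress_field$centroid, 2, frame$origin) %*% t(R)
  colnames(stress_field$centroid_local) <- c("xp", "yp", "zp")
  stress_field$frame <- frame
  stress_field
}

#' Partition plate elements into anatomical regions
#'
#' Labels every element of one structure as dome (highest plate elevation),
#' lateral-left / lateral-right (largest |x'|), or anterior / posterior
#' (sign of y'), in that precedence. Elevation and laterality boundaries
#' are quantiles of the structure's element centroids in the plate frame.
#'
#' @param stress_field a plate-frame transformed stress field
#'   ([transform_to_plate_frame()]).
#' @param structure structure label to partition (default: all elements).
#' @param dome_height_quantile elements with z' elevation above this
#'   quantile form the dome region (default 0.8, i.e. top 20%).
#' @param lateral_quantile elements with |x'| above this quantile form the
#'   lateral bands (default 0.7).
#' @return a `region_partition`: character vector (one label per element of
#'   the structure, in element order) with attribute `elements` (their
#'   indices in the stress field).
#' @export
partition_plate_regions <- function(stress_field, structure = NULL,
                                    dome_height_quantile = 0.8,
                                    lateral_quantile = 0.7) {
  sel <- if (is.null(structure)) seq_len(nrow(stress_field$S))
    else which(stress_field$structure == structure)
  if (!length(sel)) stop("empty structure: no elements to partition")
  if (is.null(stress_field$centroid_local)) {
    stop("stress field must be transformed to the plate frame first")
  }
  C <- stress_field$centroid_local[sel, , drop = FALSE]
  # regions are defined within the structure's own transverse footprint
  # (the frame fixes the directions, the structure centroid the origin)
  C <- sweep(C, 2, colMeans(C))
  lab <- ifelse(C[, "yp"] >= 0, "anterior", "posterior")
  alx <- abs(C[, "xp"])
  # type-1 quantile + ">=" keeps tied |x'| columns of a structured grid whole
  lat <- alx >= stats::quantile(alx, lateral_quantile, type = 1) &
    alx > min(alx)
  lab[lat & C[, "xp"] > 0] <- "lateral-left"
  lab[lat & C[, "xp"] < 0] <- "lateral-right"
  dome <- C[, "zp"] > stats::quantile(C[, "zp"], dome_height_quantile) +
    1e-12 * max(abs(C[, "zp"]), 1)
  lab[dome] <- "dome"
  structure(lab, elements = sel, class = "region_partition")
}

#' Summarize normal and slip-shear stress per region
#'
#' Per region (and overall), reports the extreme and mean of the
#' plate-normal stress sigma_n (extreme = value of largest magnitude,
#' keeping its sign) and of the slip-promoting shear tau_slip (signed
#' maximum) over the elements. Regions of the partition scheme with no
#' elements are reported as missing rather than dropped.
#'
#' @param stress_field a plate-frame transformed stress field.
#' @param partition a [partition_plate_regions()] result.
#' @param structure label stored in the summary rows.
#' @return a `stress_summary` data frame with columns `structure`, `region`,
#'   `n_elements`, `sigma_n_max`, `sigma_n_mean`, `tau_slip_max`,
#'   `tau_slip_mean` (MPa); attribute `missing_regions`.
#' @export
summarize_stresses <- function(stress_field, partition,
                               structure = "structure") {
  sel <- attr(partition, "elements")
  sn <- stress_field$sigma_n[sel]
  ts <- stress_field$tau_slip[sel]
  all_regions <- c("anterior", "posterior", "lateral-left", "lateral-right",
                   "dome")
  rows <- lapply(c("all", all_regions), function(rg) {
    in_rg <- if (rg == "all") rep(TRUE, length(sn)) else partition == rg
    if (!any(in_rg)) {
      return(data.frame(structure = structure, region = rg, n_elements = 0L,
                        sigma_n_max = NA_real_, sigma_n_mean = NA_real_,
                        tau_slip_max = NA_real_, tau_slip_mean = NA_real_))
    }
    s <- sn[in_rg]; t <- ts[in_rg]
    data.frame(structure = structure, region = rg,
               n_elements = sum(in_rg),
               sigma_n_max = s[which.max(abs(s))],
               sigma_n_mean = mean(s),
               tau_slip_max = max(t),
               tau_slip_mean = mean(t))
  })
  out <- do.call(rbind, rows)
  attr(out, "missing_regions") <- out$region[out$n_elements == 0L]
  class(out) <- c("stress_summary", "data.frame")
  out
}

#' Signed percent difference
#'
#' Relative difference of `value_a` with respect to `value_b`, in percent:
#' 100 (a - b) / |b|. Used to compare stresses between configurations
#' (e.g. shear-type vs nutcracker-type cases).
#'
#' @param value_a,value_b numeric scalars; `value_b` must be nonzero.
#' @return percent difference.
#' @export
percent_difference <- function(value_a, value_b) {
  if (value_b == 0) stop("reference value is zero")
  100 * (value_a - value_b) / abs(value_b)
}

#' Write a stress summary as CSV
#'
#' Long format: one row per structure, region and statistic with the value
#' in MPa.
#'
#' @param summary a `stress_summary` (or several rbind-ed together).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_stress_summary_csv <- function(summary, path) {
  stats <- c("sigma_n_max", "sigma_n_mean", "tau_slip_max", "tau_slip_mean")
  long <- do.call(rbind, lapply(stats, function(st) {
    data.frame(structure = summary$structure, region = summary$region,
               stat = st, value_MPa = summary[[st]])
  }))
  long <- long[order(long$structure, long$region, long$stat), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
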