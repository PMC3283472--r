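test_that("the default template realizes the reference adolescent case", {
  g <- generate_template_geometry()
  p <- measure_spinopelvic(g)
  expect_equal(p$PI, 61, tolerance = 0.1)
  expect_equal(p$SS, 52, tolerance = 0.1)
  expect_equal(p$slip_pct, 30, tolerance = 0.1)
  expect_equal(p$grade, "II")
  expect_equal(g$patient$height_cm, 157.2)
  expect_equal(g$patient$weight_kg, 45.5)
  expect_equal(g$patient$age, 14)
})

test_that("the reconstruction data model carries 17/11/23 points per structure", {
  g <- generate_template_geometry(include_ribs = TRUE)
  counts <- table(g$landmarks$structure)
  for (lv in c(paste0("T", 1:12), paste0("L", 1:5))) {
    expect_equal(unname(counts[[lv]]), 17L)
  }
  expect_equal(unname(counts[["pelvis"]]), 23L)
  ribs <- grep("^rib_", names(counts), value = TRUE)
  expect_equal(length(ribs), 24)
  expect_true(all(counts[ribs] == 11))
})

test_that("requested targets round-trip through the geometry measurement", {
  g <- generate_template_geometry(targets = list(PI = 75, SS = 60, slip_pct = 80))
  p <- measure_spinopelvic(g)
  expect_equal(p$PI, 75, tolerance = 0.1)
  expect_equal(p$SS, 60, tolerance = 0.1)
  expect_equal(p$slip_pct, 80, tolerance = 0.1)

  set.seed(61)
  for (i in 1:20) {
    tg <- list(PI = runif(1, 45, 80), SS = runif(1, 35, 65),
               slip_pct = runif(1, 0, 100))
    tg$PI <- max(tg$PI, tg$SS - 5)
    p <- measure_spinopelvic(generate_template_geometry(targets = tg))
    expect_lt(abs(p$PI - tg$PI), 0.1)
    expect_lt(abs(p$SS - tg$SS), 0.1)
    expect_lt(abs(p$slip_pct - tg$slip_pct), 0.1)
  }

  expect_error(generate_template_geometry(
    targets = list(PI = 20, SS = 70, slip_pct = 30)), "unrealizable")
})

test_that("landmark noise emulates the reconstruction accuracy and is seed-reproducible", {
  g <- generate_template_geometry(include_ribs = FALSE)
  exact <- generate_patient_landmarks(g, noise_sd_mm = 0)
  expect_equal(exact, g$landmarks)

  a <- generate_patient_landmarks(g, seed = 7)
  b <- generate_patient_landmarks(g, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_patient_landmarks(g, seed = 8)))

  # mean displacement of N(0, sigma^2 I3) follows the chi_3 mean
  d <- sqrt((a$x - g$landmarks$x)^2 + (a$y - g$landmarks$y)^2 +
            (a$z - g$landmarks$z)^2)
  sigma <- 3.3
  chi3_mean <- sigma * sqrt(2) * gamma(2) / gamma(1.5)
  expect_equal(mean(d), chi3_mean, tolerance = 0.1)

  expect_error(generate_patient_landmarks(g, noise_sd_mm = -1), ">= 0")
})

test_that("landmark CSV round-trips through the interchange format", {
  g <- generate_template_geometry(include_ribs = FALSE)
  path <- tempfile(fileext = ".csv")
  write_landmark_csv(g$landmarks, path)
  back <- read_landmark_csv(path)
  expect_equal(back$structure, g$landmarks$structure)
  expect_equal(back$name, g$landmarks$name)
  expect_equal(back$x, g$landmarks$x, tolerance = 1e-9)
  unlink(path)
})

test_that("the detailed mesh is well-formed: positive Jacobians, 3-zone growth plates", {
  g <- generate_template_geometry()
  m <- build_detailed_mesh(g)
  expect_true(check_mesh_jacobians(m))

  gp <- m$hex_region[m$hex_structure == "s1_growth_plate"]
  expect_setequal(unique(gp), c("gp_sensitive", "gp_newbone", "gp_transition"))
  gp5 <- m$hex_region[m$hex_structure == "l5_growth_plate"]
  expect_setequal(unique(gp5), c("gp_sensitive", "gp_newbone", "gp_transition"))

  # required node groups are present
  expect_true(all(c("acetabulum_left", "acetabulum_right", "t1",
                    "centroid_chain", "l5_growth_plate") %in%
                  names(m$node_groups)))
  expect_equal(length(m$node_groups$centroid_chain), 17)  # T1..L5

  expect_error(mesh_resolution(nx = 3), "even")
  expect_error(mesh_resolution(nz_body = 1), "at least 2")
})

# connected components of the node-sharing hex graph restricted to L5
# structures; labels each component by the regions it contains
l5_components <- function(mesh) {
  sel <- which(mesh$hex_structure %in% c("L5_body", "L5_arch"))
  conn <- mesh$hex_conn[sel, , drop = FALSE]
  parent <- seq_len(nrow(conn))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  node_owner <- new.env(parent = emptyenv())
  for (e in seq_len(nrow(conn))) {
    for (nd in conn[e, ]) {
      key <- as.character(nd)
      if (is.null(node_owner[[key]])) node_owner[[key]] <- e
      else {
        ra <- find(node_owner[[key]]); rb <- find(e)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  comp <- vapply(seq_len(nrow(conn)), find, 1L)
  split(mesh$hex_region[sel], comp)
}

test_that("bilateral pars lysis disconnects the posterior arch from the body (brute-force graph check)", {
  g <- generate_template_geometry()
  m_lysis <- build_detailed_mesh(g, pars_lysis = TRUE)
  comps <- l5_components(m_lysis)
  # the lamina/spinous block ("arch" region) lives in its own component,
  # separated from every component that touches the vertebral body
  arch_comps <- vapply(comps, function(r) any(r == "arch"), logical(1))
  body_comps <- vapply(comps, function(r) any(r %in%
    c("cortical", "trabecular", "endplate")), logical(1))
  expect_true(any(arch_comps))
  expect_false(any(arch_comps & body_comps))
  # without lysis the pars elements reunite arch and body
  m_intact <- build_detailed_mesh(g, pars_lysis = FALSE)
  comps2 <- l5_components(m_intact)
  expect_equal(length(comps2), 1L)
  expect_true(any(unlist(comps2) == "pars"))
})

test_that("the material library covers every mesh region and obeys elastic bounds", {
  g <- generate_template_geometry(include_ribs = TRUE)
  m <- build_detailed_mesh(g, include_ribs = TRUE)
  lib <- default_material_library()
  regions <- unique(c(m$hex_region, m$beams$region, m$springs$region))
  expect_true(all(regions %in% lib$region))
  solid <- !is.na(lib$E)
  expect_true(all(lib$E[solid] > 0))
  expect_true(all(lib$nu[solid] > 0 & lib$nu[solid] < 0.5))
  expect_true(all(lib$spring_k[!solid] >= 0))
})

test_that("a YAML modulus override scales single-region stiffness linearly", {
  dir <- tempfile(); dir.create(dir)
  yml <- file.path(dir, "model.yaml")
  writeLines(c("materials:",
               "  trabecular:",
               "    E: 200"), yml)
  cfg <- read_model_config(yml)
  lib2 <- override_materials(default_material_library(), cfg$materials)
  expect_equal(lib2$E[lib2$region == "trabecular"], 200)

  mesh <- hex_column_mesh(2)
  K1 <- assemble_global_stiffness(mesh, default_material_library())$K
  K2 <- assemble_global_stiffness(mesh, lib2)$K
  ratio <- 200 / default_material_library()$E[
    default_material_library()$region == "trabecular"]
  expect_lt(max(abs(K2 - ratio * K1)), 1e-9 * max(abs(K1)))
  unlink(dir, recursive = TRUE)
})

test_that("two mesh resolutions agree on which region carries the most slip shear", {
  # regional means are the resolution-stable statistic (regional maxima are
  # local concentrations whose tie-breaks shift with element size)
  g <- generate_template_geometry()
  peak_region <- function(nx) {
    mesh <- build_detailed_mesh(g, resolution = mesh_resolution(nx, nx, 3, 2, 3))
    sys <- assemble_global_stiffness(mesh)
    sys <- apply_boundary_conditions(sys, standing_boundary_conditions(sys))
    U <- follower_equilibrium_iteration(sys, body_weight_distribution(45.5))
    sf <- recover_hex_stresses(mesh, U)
    fr <- build_plate_frame(mesh$nodes[mesh$node_groups$l5_growth_plate, ])
    sf <- transform_to_plate_frame(sf, fr)
    part <- partition_plate_regions(sf, "s1_growth_plate")
    sm <- summarize_stresses(sf, part, "s1_growth_plate")
    sm <- sm[sm$region != "all" & sm$n_elements > 0, ]
    sm$region[which.max(sm$tau_slip_mean)]
  }
  expect_equal(peak_region(6), peak_region(8))
})
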