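test_that("plate frame: origin at centroid, orthonormal, z' opposite gravity", {
  set.seed(41)
  pts <- cbind(runif(40, -20, 20), runif(40, -15, 15), rnorm(40, sd = 0.2))
  fr <- build_plate_frame(pts)
  expect_equal(fr$origin, colMeans(pts))
  R <- fr$axes
  expect_lt(max(abs(R %*% t(R) - diag(3))), 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
  expect_gt(R["zp", 3], 0.99)                  # horizontal plate: z' ~ +z
  expect_gt(sum(R["yp", ] * c(1, 0, 0)), 0.9)  # y' ~ anterior

  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(build_plate_frame(line), "collinear")
  expect_error(build_plate_frame(pts[1:2, ]), "at least 3")
})

test_that("tensor transformation matches the explicit traction oracle on random tensors", {
  set.seed(42)
  for (rep in 1:100) {
    s <- random_voigt()
    fr <- random_frame()
    sf <- structure(list(S = matrix(s, 1, 6,
                                    dimnames = list(NULL, c("xx","yy","zz","xy","yz","zx"))),
                         centroid = matrix(0, 1, 3),
                         region = "r", structure = "s"),
                    class = "stress_field")
    out <- transform_to_plate_frame(sf, fr)
    Sm <- voigt_to_matrix(s)
    n <- fr$axes["zp", ]; tvec <- fr$axes["yp", ]
    expect_equal(out$sigma_n, as.numeric(n %*% Sm %*% n), tolerance = 1e-9)
    expect_equal(out$tau_slip, as.numeric(tvec %*% Sm %*% n), tolerance = 1e-9)
    # rotation invariants
    Sl <- voigt_to_matrix(out$S_local[1, ])
    expect_equal(sum(diag(Sl)), sum(diag(Sm)), tolerance = 1e-9)
    vm <- function(M) sqrt(1.5 * sum((M - diag(3) * sum(diag(M)) / 3)^2))
    expect_equal(vm(Sl), vm(Sm), tolerance = 1e-9)
  }
})

test_that("sign conventions: compression negative, hydrostatic invariant, identity frame neutral", {
  id_frame <- structure(list(origin = c(0, 0, 0), axes = diag(3)), class = "plate_frame")
  rownames(id_frame$axes) <- c("xp", "yp", "zp")
  s <- random_voigt()
  sf <- structure(list(S = matrix(s, 1, 6,
                                  dimnames = list(NULL, c("xx","yy","zz","xy","yz","zx"))),
                       centroid = matrix(0, 1, 3), region = "r", structure = "s"),
                  class = "stress_field")
  out <- transform_to_plate_frame(sf, id_frame)
  expect_equal(out$S_local[1, ], sf$S[1, ], tolerance = 1e-12)

  p <- 2.5
  sf$S <- matrix(c(-p, -p, -p, 0, 0, 0), 1, 6,
                 dimnames = list(NULL, c("xx","yy","zz","xy","yz","zx")))
  out2 <- transform_to_plate_frame(sf, random_frame())
  expect_equal(out2$sigma_n, -p, tolerance = 1e-9)

  # uniaxial compression aligned with z': compressive normal, no slip shear
  sf$S <- matrix(c(0, 0, -p, 0, 0, 0), 1, 6,
                 dimnames = list(NULL, c("xx","yy","zz","xy","yz","zx")))
  out3 <- transform_to_plate_frame(sf, id_frame)
  expect_lt(out3$sigma_n, 0)
  expect_equal(out3$tau_slip, 0)

  bad <- id_frame; bad$axes[1, ] <- c(2, 0, 0)
  expect_error(transform_to_plate_frame(sf, bad), "orthonormal")
})

# a synthetic flat or domed plate as a stress field with unit tensors
plate_field <- function(nx = 8, ny = 8, dome = 0) {
  xs <- (seq_len(nx) - 0.5) / nx - 0.5
  ys <- (seq_len(ny) - 0.5) / ny - 0.5
  g <- expand.grid(x = xs * 30, y = ys * 40)
  z <- dome * pmax(0, 1 - (g$x / 15)^2 - (g$y / 20)^2)
  structure(list(
    S = matrix(rnorm(nrow(g) * 6), nrow(g), 6,
               dimnames = list(NULL, c("xx","yy","zz","xy","yz","zx"))),
    centroid = cbind(g$y, g$x, z),   # y' anterior along first in-plane axis
    region = rep("gp_sensitive", nrow(g)),
    structure = rep("plate", nrow(g))), class = "stress_field")
}

test_that("region partition is exhaustive, symmetric and finds the dome apex", {
  set.seed(43)
  id_frame <- structure(list(origin = c(0, 0, 0), axes = diag(3)), class = "plate_frame")
  rownames(id_frame$axes) <- c("xp", "yp", "zp")

  sf <- transform_to_plate_frame(plate_field(dome = 3), id_frame)
  part <- partition_plate_regions(sf, "plate")
  expect_equal(length(part), 64)
  expect_true(all(part %in% c("anterior", "posterior", "lateral-left",
                              "lateral-right", "dome")))
  expect_equal(sum(part == "anterior"), sum(part == "posterior"))
  expect_equal(sum(part == "lateral-left"), sum(part == "lateral-right"))

  # dome region contains the apex elements found by brute-force sort
  sel <- attr(part, "elements")
  elev <- sf$centroid_local[sel, "zp"]
  apex <- order(elev, decreasing = TRUE)[1:4]
  expect_true(all(part[apex] == "dome"))

  # flat plate: no dome, flagged as missing in the summary
  sf0 <- transform_to_plate_frame(plate_field(dome = 0), id_frame)
  part0 <- partition_plate_regions(sf0, "plate")
  expect_false(any(part0 == "dome"))
  sm0 <- summarize_stresses(sf0, part0, "plate")
  expect_true("dome" %in% attr(sm0, "missing_regions"))

  expect_error(partition_plate_regions(sf, "absent"), "empty structure")
})

test_that("stress summaries equal exhaustive enumeration on a toy field", {
  id_frame <- structure(list(origin = c(0, 0, 0), axes = diag(3)), class = "plate_frame")
  rownames(id_frame$axes) <- c("xp", "yp", "zp")
  sf <- structure(list(
    S = cbind(xx = 0, yy = 0, zz = c(-3, -1, 2, -2, 1, -5),
              xy = 0, yz = c(0.5, -0.2, 0.8, -0.9, 0.1, 0.4), zx = 0),
    centroid = cbind(0, c(-1, -1, -1, 1, 1, 1), 0),
    region = rep("r", 6), structure = rep("toy", 6)), class = "stress_field")
  sf <- transform_to_plate_frame(sf, id_frame)
  part <- partition_plate_regions(sf, "toy", lateral_quantile = 1)
  sm <- summarize_stresses(sf, part, "toy")
  ant <- sm[sm$region == "anterior", ]
  post <- sm[sm$region == "posterior", ]
  # brute force: anterior = elements 4:6, posterior = 1:3
  expect_equal(ant$sigma_n_max, -5)          # largest magnitude, sign kept
  expect_equal(ant$sigma_n_mean, mean(c(-2, 1, -5)))
  expect_equal(ant$tau_slip_max, 0.4)        # signed max
  expect_equal(post$sigma_n_max, -3)
  expect_equal(post$tau_slip_max, 0.8)
  expect_equal(sm$sigma_n_max[sm$region == "all"], -5)

  # constant field: max equals mean everywhere
  sfc <- sf; sfc$sigma_n <- rep(-2, 6); sfc$tau_slip <- rep(0.3, 6)
  smc <- summarize_stresses(sfc, part, "toy")
  ok <- smc$n_elements > 0
  expect_equal(smc$sigma_n_max[ok], smc$sigma_n_mean[ok])
  expect_equal(smc$tau_slip_max[ok], smc$tau_slip_mean[ok])
})

test_that("percent difference is the signed relative difference", {
  expect_equal(percent_difference(1.26, 1.00), 26)
  expect_equal(percent_difference(3, 3), 0)
  expect_equal(percent_difference(0.9, 1.0), -10)
  expect_error(percent_difference(1, 0), "zero")
})

test_that("the lumbosacral junction is in net compression under standing load", {
  m <- small_standing_model()
  U <- follower_equilibrium_iteration(m$sys, m$dist)
  sf <- recover_hex_stresses(m$mesh, U)
  fr <- build_plate_frame(m$mesh$nodes[m$mesh$node_groups$l5_growth_plate, ])
  sf <- transform_to_plate_frame(sf, fr)
  gp <- sf$structure == "s1_growth_plate"
  expect_lt(mean(sf$sigma_n[gp]), 0)
})
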