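#' Default mesh resolution
#'
#' In-plane and through-thickness element counts of the detailed L4-pelvis
#' hex mesh. `nx`/`ny` must be even (>= 4) so that midline and symmetric
#' arch attachments exist; growth plates always carry their three
#' physiological layers.
#'
#' @param nx,ny in-plane elements (anteroposterior, mediolateral).
#' @param nz_body,nz_disc,nz_sacrum through-thickness element counts.
#' @return named list.
#' @export
mesh_resolution <- function(nx = 6, ny = 6, nz_body = 3, nz_disc = 2,
                            nz_sacrum = 3) {
  if (nx < 4 || ny < 4 || nx %% 2 || ny %% 2) {
    stop("nx and ny must be even and >= 4")
  }
  if (nz_body < 2 || nz_disc < 2 || nz_sacrum < 2) {
    stop("at least 2 elements are required through each structure")
  }
  list(nx = nx, ny = ny, nz_body = nz_body, nz_disc = nz_disc,
       nz_sacrum = nz_sacrum)
}

# quad descriptor from a center and the anterior/left mid-edge points;
# evaluated bilinearly over (u, v) in [0,1]^2
.quad_eval <- function(center, ant, left, U, V) {
  a <- ant - center; l <- left - center
  cbind(center[1] + (2 * U - 1) * a[1] + (2 * V - 1) * l[1],
        center[2] + (2 * U - 1) * a[2] + (2 * V - 1) * l[2],
        center[3] + (2 * U - 1) * a[3] + (2 * V - 1) * l[3])
}

.unit <- function(v) v / sqrt(sum(v^2))
.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

# flip a hex connectivity row if its Jacobian at the center is negative
.orient_hex <- function(conn_row, nodes) {
  dN <- .hex_dN(0, 0, 0)
  J <- t(dN) %*% nodes[conn_row, ]
  if (det(J) < 0) conn_row[c(5:8, 1:4)] else conn_row
}

#' Check all hexahedra for positive Jacobians
#'
#' @param mesh a `spine_mesh`.
#' @return invisibly TRUE; errors listing any degenerate (non-positive
#'   Jacobian) elements.
#' @export
check_mesh_jacobians <- function(mesh) {
  if (is.null(mesh$hex_conn)) return(invisible(TRUE))
  dN0 <- .hex_dN(0, 0, 0)
  bad <- integer(0)
  for (e in seq_len(nrow(mesh$hex_conn))) {
    J <- t(dN0) %*% mesh$nodes[mesh$hex_conn[e, ], ]
    if (det(J) <= 0) bad <- c(bad, e)
  }
  if (length(bad)) {
    stop("degenerate (non-positive Jacobian) hex elements: ",
         paste(utils::head(bad, 20), collapse = ", "),
         if (length(bad) > 20) " ..." else "")
  }
  invisible(TRUE)
}

#' Build the detailed hybrid mesh from a geometry
#'
#' Meshes the L4-pelvis segment as a conforming structured hexahedral
#' column - sacrum (cortical shell, trabecular core), three-layer S1
#' growth plate with a parametric sacral-dome bulge, L5-S1 disc (annulus +
#' nucleus), three-layer L5 inferior growth plate, L5 and L4 bodies and
#' the L4-L5 disc - plus posterior arches (pedicle-pars-lamina hex loops;
#' bilateral pars lysis removes the L5 pars elements), tension-only
#' ligament springs (anterior/posterior longitudinal, interspinous), facet
#' springs, pelvis struts to the acetabula, and a T1-L3 beam chain with an
#' optional simplified rib cage.
#'
#' @param geometry a `spine_geometry`.
#' @param resolution see [mesh_resolution()].
#' @param include_ribs generate beam-loop ribs and costal bridges.
#' @param pars_lysis remove the bilateral L5 pars elements (isthmic defect).
#' @param dome_height_mm sacral dome height (0 disables the dome; default
#'   from the geometry's template dimensions).
#' @param materials material library supplying beam/spring properties.
#' @return a [spine_mesh()] with anatomical node groups.
#' @export
build_detailed_mesh <- function(geometry, resolution = mesh_resolution(),
                                include_ribs = FALSE, pars_lysis = TRUE,
                                dome_height_mm = NULL,
                                materials = default_material_library()) {
  res <- do.call(mesh_resolution, resolution[intersect(names(resolution),
    c("nx", "ny", "nz_body", "nz_disc", "nz_sacrum"))])
  nx <- res$nx; ny <- res$ny
  nu <- nx + 1L; nv <- ny + 1L
  if (is.null(dome_height_mm)) dome_height_mm <- geometry$dims$dome_height
  lms <- geometry$landmarks
  gp_h <- geometry$dims$gp_h
  sacrum_depth <- geometry$dims$sacrum_depth

  P3 <- function(structure, name) {
    as.numeric(landmark_coords(lms, structure, name))
  }

  ug <- rep((0:nx) / nx, times = nv)
  vg <- rep((0:ny) / ny, each = nu)
  quad_pts <- function(center, ant, left) .quad_eval(center, ant, left, ug, vg)

  ## ---- interface quads ----------------------------------------------------
  s1c <- P3("sacrum", "s1_plate_ant"); s1p <- P3("sacrum", "s1_plate_post")
  s1l <- P3("sacrum", "s1_plate_left"); s1ctr <- P3("sacrum", "s1_plate_center")
  sac_centroid <- P3("sacrum", "sacrum_centroid")
  n_s1 <- .unit(.cross3(s1c - s1p, s1l - P3("sacrum", "s1_plate_right")))
  if (n_s1[3] < 0) n_s1 <- -n_s1
  ax_sac <- .unit(sac_centroid - s1ctr)

  iface_s1_top <- quad_pts(s1ctr, s1c, s1l)      # top of S1 growth plate
  if (dome_height_mm > 0) {                      # parametric spherical-cap dome
    bulge <- pmax(0, 1 - ((2 * ug - 1)^2 + (2 * vg - 1)^2))
    iface_s1_top <- iface_s1_top +
      dome_height_mm * bulge %o% n_s1
  }
  iface_s1_gpb <- quad_pts(s1ctr - gp_h * n_s1, s1c - gp_h * n_s1,
                           s1l - gp_h * n_s1)
  iface_sac_base <- quad_pts(s1ctr + sacrum_depth * ax_sac,
                             s1c + sacrum_depth * ax_sac,
                             s1l + sacrum_depth * ax_sac)

  l5_quads <- lapply(c(inf = "inf", sup = "sup"), function(pl) {
    quad_pts(P3("L5", paste0(pl, "_plate_center")),
             P3("L5", paste0(pl, "_plate_ant")),
             P3("L5", paste0(pl, "_plate_left")))
  })
  n_l5i <- .unit(.cross3(
    P3("L5", "inf_plate_ant") - P3("L5", "inf_plate_post"),
    P3("L5", "inf_plate_left") - P3("L5", "inf_plate_right")))
  if (n_l5i[3] < 0) n_l5i <- -n_l5i
  iface_l5_gpb <- quad_pts(P3("L5", "inf_plate_center") - gp_h * n_l5i,
                           P3("L5", "inf_plate_ant") - gp_h * n_l5i,
                           P3("L5", "inf_plate_left") - gp_h * n_l5i)
  l4_quads <- lapply(c(inf = "inf", sup = "sup"), function(pl) {
    quad_pts(P3("L4", paste0(pl, "_plate_center")),
             P3("L4", paste0(pl, "_plate_ant")),
             P3("L4", paste0(pl, "_plate_left")))
  })

  ## ---- vertical stack -----------------------------------------------------
  body_region <- function(i, j, l, nl) {
    if (l == 1 || l == nl) "endplate"
    else if (i == 1 || i == nx || j == 1 || j == ny) "cortical"
    else "trabecular"
  }
  disc_region <- function(i, j, l, nl) {
    uc <- (i - 0.5) / nx * 2 - 1; vc <- (j - 0.5) / ny * 2 - 1
    if (sqrt(uc^2 + vc^2) < 0.5) "nucleus" else "annulus"
  }
  segs <- list(
    list(name = "sacrum", bottom = iface_sac_base, top = iface_s1_gpb,
         nl = res$nz_sacrum,
         region = function(i, j, l, nl) {
           if (l == 1 || i == 1 || i == nx || j == 1 || j == ny) "cortical"
           else "trabecular"
         }),
    list(name = "s1_growth_plate", bottom = iface_s1_gpb, top = iface_s1_top,
         nl = 3L,
         region = function(i, j, l, nl) {
           c("gp_newbone", "gp_transition", "gp_sensitive")[l]
         }),
    list(name = "disc_l5s1", bottom = iface_s1_top, top = iface_l5_gpb,
         nl = res$nz_disc, region = disc_region),
    list(name = "l5_growth_plate", bottom = iface_l5_gpb, top = l5_quads$inf,
         nl = 3L,
         region = function(i, j, l, nl) {
           c("gp_sensitive", "gp_transition", "gp_newbone")[l]
         }),
    list(name = "L5_body", bottom = l5_quads$inf, top = l5_quads$sup,
         nl = res$nz_body, region = body_region),
    list(name = "disc_l4l5", bottom = l5_quads$sup, top = l4_quads$inf,
         nl = res$nz_disc, region = disc_region),
    list(name = "L4_body", bottom = l4_quads$inf, top = l4_quads$sup,
         nl = res$nz_body, region = body_region))

  ifaces <- list(segs[[1]]$bottom)
  seg_k0 <- integer(length(segs))           # global interface index of bottom
  k <- 1L
  for (s in seq_along(segs)) {
    seg_k0[s] <- k
    nl <- segs[[s]]$nl
    for (l in seq_len(nl)) {
      t <- l / nl
      ifaces[[k + l]] <- (1 - t) * segs[[s]]$bottom + t * segs[[s]]$top
    }
    k <- k + nl
  }
  K <- length(ifaces)                       # number of interfaces
  nodes <- do.call(rbind, ifaces)           # (nu*nv*K) x 3
  idx <- function(i, j, kk) i + (j - 1L) * nu + (kk - 1L) * nu * nv

  conn <- vector("list", 2048); region <- character(0); struct <- character(0)
  nhex <- 0L
  conn <- matrix(0L, (K - 1L) * nx * ny + 64L, 8L)
  region <- character(nrow(conn)); struct <- character(nrow(conn))
  for (s in seq_along(segs)) {
    sg <- segs[[s]]
    for (l in seq_len(sg$nl)) {
      kk <- seg_k0[s] + l - 1L
      for (j in seq_len(ny)) for (i in seq_len(nx)) {
        nhex <- nhex + 1L
        conn[nhex, ] <- c(idx(i, j, kk), idx(i + 1L, j, kk),
                          idx(i + 1L, j + 1L, kk), idx(i, j + 1L, kk),
                          idx(i, j, kk + 1L), idx(i + 1L, j, kk + 1L),
                          idx(i + 1L, j + 1L, kk + 1L), idx(i, j + 1L, kk + 1L))
        region[nhex] <- sg$region(i, j, l, sg$nl)
        struct[nhex] <- sg$name
      }
    }
  }

  add_node <- function(p) {
    nodes <<- rbind(nodes, p)
    nrow(nodes)
  }
  add_hex <- function(nd, rg, st) {
    nhex <<- nhex + 1L
    if (nhex > nrow(conn)) {
      conn <<- rbind(conn, matrix(0L, 256L, 8L))
      region <<- c(region, character(256L)); struct <<- c(struct, character(256L))
    }
    conn[nhex, ] <<- .orient_hex(as.integer(nd), nodes)
    region[nhex] <<- rg; struct[nhex] <<- st
  }

  ## ---- posterior arches (pedicle - pars - lamina loop) --------------------
  jmid <- as.integer(ny / 2 + 1L); imid <- as.integer(nx / 2 + 1L)
  jl <- max(2L, min(ny, round(0.75 * nv)))
  jr1 <- nv + 1L - (jl + 1L); jr2 <- nv + 1L - jl
  arch_info <- list()
  for (lv in c("L5", "L4")) {
    s <- match(paste0(lv, "_body"), vapply(segs, `[[`, "", "name"))
    k0 <- seg_k0[s]
    kp <- k0 + as.integer(floor(segs[[s]]$nl / 2))
    p_hat <- .unit(P3(lv, "inf_plate_post") - P3(lv, "inf_plate_ant"))
    left_q <- c(idx(1L, jl, kp), idx(1L, jl + 1L, kp),
                idx(1L, jl + 1L, kp + 1L), idx(1L, jl, kp + 1L))
    right_q <- c(idx(1L, jr2, kp), idx(1L, jr1, kp),
                 idx(1L, jr1, kp + 1L), idx(1L, jr2, kp + 1L))
    Alb <- colMeans(nodes[c(left_q[1], left_q[2]), ])    # left, bottom mid
    Arb <- colMeans(nodes[c(right_q[1], right_q[2]), ])
    h_vec <- nodes[left_q[4], ] - nodes[left_q[1], ]
    v_hat <- .unit(h_vec)
    Mb <- (Alb + Arb) / 2
    y_lr <- .unit(Alb - Arb); half <- sqrt(sum((Alb - Arb)^2)) / 2
    depth <- 0.8 * sqrt(sum((P3(lv, "inf_plate_ant") -
                             P3(lv, "inf_plate_post"))^2))
    w_att <- sqrt(sum((nodes[left_q[2], ] - nodes[left_q[1], ])^2))
    ns <- 6L
    sections <- vector("list", ns + 1L)
    sections[[1]] <- left_q
    sections[[ns + 1L]] <- right_q
    for (q in 2:ns) {
      t <- (q - 1) / ns
      pb <- Mb + cos(pi * t) * half * y_lr + sin(pi * t) * depth * p_hat
      t_hat <- .unit(-sin(pi * t) * pi * half * y_lr +
                     cos(pi * t) * pi * depth * p_hat)
      w_hat <- .unit(.cross3(t_hat, v_hat))
      c1 <- add_node(pb - w_att / 2 * w_hat)
      c2 <- add_node(pb + w_att / 2 * w_hat)
      c3 <- add_node(pb + w_att / 2 * w_hat + h_vec)
      c4 <- add_node(pb - w_att / 2 * w_hat + h_vec)
      sections[[q]] <- c(c1, c2, c3, c4)
    }
    seg_regions <- c("pedicle", "pars", "arch", "arch", "pars", "pedicle")
    for (q in seq_len(ns)) {
      if (lv == "L5" && pars_lysis && seg_regions[q] == "pars") next
      add_hex(c(sections[[q]], sections[[q + 1L]]), seg_regions[q],
              paste0(lv, "_arch"))
    }
    arch_info[[lv]] <- list(
      center_top = sections[[4L]][4L],       # mid-arch node (spinous base)
      # inferior articular processes: on the arch side of the pars, so that
      # with a pars lysis the facet capsule still ties the loose arch to S1
      inf_left_lo = sections[[3L]][1L], inf_left_hi = sections[[3L]][4L],
      inf_right_lo = sections[[5L]][2L], inf_right_hi = sections[[5L]][3L],
      # superior articular processes: pedicle side (stay with the body)
      sup_left = sections[[2L]][4L], sup_right = sections[[6L]][3L])
  }

  ## ---- beams: pelvis struts and T1-L3 chain -------------------------------
  matE <- function(rg) materials$E[match(rg, materials$region)]
  beam_props <- function(rg, A, I, J) {
    E <- matE(rg)
    data.frame(E = E, G = E / 2.6, A = A, Iy = I, Iz = I, J = J,
               ox = 0, oy = 0, oz = 1, region = rg,
               stringsAsFactors = FALSE)
  }
  beams <- NULL
  add_beam <- function(n1, n2, props) {
    beams <<- rbind(beams, cbind(data.frame(n1 = n1, n2 = n2), props))
  }
  ac_l <- add_node(P3("pelvis", "acetabulum_left"))
  ac_r <- add_node(P3("pelvis", "acetabulum_right"))
  pelvis_pr <- beam_props("pelvis_beam", A = 300, I = 5e4, J = 1e5)
  for (tgt in c(idx(1L, jmid, 1L), idx(nu, jmid, 1L), idx(imid, nv, 1L))) {
    add_beam(ac_l, tgt, pelvis_pr)
  }
  for (tgt in c(idx(1L, jmid, 1L), idx(nu, jmid, 1L), idx(imid, 1L, 1L))) {
    add_beam(ac_r, tgt, pelvis_pr)
  }

  chain_levels <- c(paste0("T", 1:12), paste0("L", 1:3))
  chain_nodes <- integer(length(chain_levels))
  names(chain_nodes) <- chain_levels
  for (lv in chain_levels) chain_nodes[lv] <- add_node(P3(lv, "body_centroid"))
  vert_pr <- beam_props("vertebra_beam", A = 600, I = 3e4, J = 6e4)
  disc_pr <- beam_props("disc_beam", A = 600, I = 3e4, J = 6e4)
  for (s in seq_len(length(chain_levels) - 1L)) {
    n1 <- chain_nodes[s]; n2 <- chain_nodes[s + 1L]
    mid <- add_node((nodes[n1, ] + nodes[n2, ]) / 2)
    add_beam(n1, mid, vert_pr)      # cranial half: vertebral body
    add_beam(mid, n2, disc_pr)      # caudal half: intervertebral disc
  }
  # L3 -> L4 junction: tripod onto the L4 superior endplate resolves moments
  l4_top_k <- K
  l3_mid <- add_node((nodes[chain_nodes["L3"], ] +
                      nodes[idx(imid, jmid, l4_top_k), ]) / 2)
  add_beam(chain_nodes["L3"], l3_mid, disc_pr)
  for (tgt in c(idx(imid, jmid, l4_top_k), idx(2L, jmid, l4_top_k),
                idx(nx, jmid, l4_top_k))) {
    add_beam(l3_mid, tgt, vert_pr)
  }

  if (include_ribs) {
    rib_pr <- beam_props("rib_beam", A = 40, I = 500, J = 1000)
    rib_structs <- grep("^rib_", unique(lms$structure), value = TRUE)
    rib_end <- list()
    for (rs in rib_structs) {
      pts <- landmark_coords(lms, rs)
      ids <- integer(nrow(pts))
      for (r in seq_len(nrow(pts))) ids[r] <- add_node(pts[r, ])
      lv <- sub("^rib_(T\\d+)_.*$", "\\1", rs)
      add_beam(chain_nodes[lv], ids[1], rib_pr)
      for (r in seq_len(length(ids) - 1L)) add_beam(ids[r], ids[r + 1L], rib_pr)
      rib_end[[rs]] <- ids[length(ids)]
    }
    for (lv in paste0("T", 1:7)) {          # costal cartilage / sternum bridge
      l <- rib_end[[paste0("rib_", lv, "_left")]]
      r <- rib_end[[paste0("rib_", lv, "_right")]]
      if (!is.null(l) && !is.null(r)) add_beam(l, r, rib_pr)
    }
  }

  ## ---- ligament and facet springs -----------------------------------------
  springs <- NULL
  kspr <- function(rg) materials$spring_k[match(rg, materials$region)]
  add_spring <- function(n1, n2, rg, tension_only = TRUE) {
    springs <<- rbind(springs, data.frame(
      n1 = n1, n2 = n2, k = kspr(rg), tension_only = tension_only,
      region = rg, stringsAsFactors = FALSE))
  }
  seg_bounds <- c(seg_k0[-1], K)            # top interface of each segment
  lig_ks <- unique(c(seg_k0[2], seg_bounds[2:7]))   # S1 gp bottom .. L4 top
  for (s in seq_len(length(lig_ks) - 1L)) {
    add_spring(idx(nu, jmid, lig_ks[s]), idx(nu, jmid, lig_ks[s + 1L]),
               "ligament_all")
    add_spring(idx(1L, jmid, lig_ks[s]), idx(1L, jmid, lig_ks[s + 1L]),
               "ligament_pll")
  }
  sac_post_top <- idx(1L, jmid, seg_k0[2])
  add_spring(arch_info$L4$center_top, arch_info$L5$center_top, "ligament_isl")
  add_spring(arch_info$L5$center_top, sac_post_top, "ligament_isl")
  # facet joints (bidirectional capsule springs); the L5-S1 pairs anchor the
  # L5 inferior articular complex to the sacrum with non-parallel axes so the
  # arch stays kinematically constrained under bilateral pars lysis
  k_gpb <- seg_k0[2]
  add_spring(arch_info$L5$inf_left_lo, idx(1L, jl, k_gpb), "facet", FALSE)
  add_spring(arch_info$L5$inf_left_hi, idx(1L, jl + 1L, k_gpb), "facet", FALSE)
  add_spring(arch_info$L5$inf_left_lo, idx(1L, jl, k_gpb - 1L), "facet", FALSE)
  add_spring(arch_info$L5$inf_right_lo, idx(1L, jr2, k_gpb), "facet", FALSE)
  add_spring(arch_info$L5$inf_right_hi, idx(1L, jr1, k_gpb), "facet", FALSE)
  add_spring(arch_info$L5$inf_right_lo, idx(1L, jr2, k_gpb - 1L), "facet", FALSE)
  add_spring(arch_info$L4$inf_left_lo, arch_info$L5$sup_left, "facet", FALSE)
  add_spring(arch_info$L4$inf_right_lo, arch_info$L5$sup_right, "facet", FALSE)

  ## ---- node groups ---------------------------------------------------------
  body_center <- function(lv) {
    s <- match(paste0(lv, "_body"), vapply(segs, `[[`, "", "name"))
    idx(imid, jmid, seg_k0[s] + as.integer(floor(segs[[s]]$nl / 2)))
  }
  centroid_chain <- c(chain_nodes,
                      L4 = body_center("L4"), L5 = body_center("L5"))
  s_gp <- match("l5_growth_plate", vapply(segs, `[[`, "", "name"))
  gp_k <- seg_k0[s_gp]:(seg_k0[s_gp] + 3L)
  l5_gp_nodes <- as.integer(outer(outer(seq_len(nu), (seq_len(nv) - 1L) * nu,
                                        "+") , (gp_k - 1L) * nu * nv, "+"))
  node_groups <- list(
    acetabulum_left = ac_l, acetabulum_right = ac_r,
    t1 = unname(chain_nodes["T1"]),
    centroid_chain = centroid_chain,
    l5_growth_plate = l5_gp_nodes,
    s1_plate_center = idx(imid, jmid, seg_bounds[2]))

  conn <- conn[seq_len(nhex), , drop = FALSE]
  mesh <- spine_mesh(nodes, hex_conn = conn,
                     hex_region = region[seq_len(nhex)],
                     hex_structure = struct[seq_len(nhex)],
                     beams = beams, springs = springs,
                     node_groups = node_groups)
  check_mesh_jacobians(mesh)
  mesh
}
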