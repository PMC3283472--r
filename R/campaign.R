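#' Run one standing-load simulation case
#'
#' The per-case pipeline of the campaign: re-parameterize the template
#' geometry ([apply_pelvic_rotation()] then [apply_slip()]), build the
#' detailed mesh, assemble, apply standing boundary conditions, iterate the
#' body-weight follower load to equilibrium, and summarize growth-plate and
#' disc stresses in the L5 growth-plate frame.
#'
#' @param geometry base template `spine_geometry`.
#' @param PI_deg,SS_deg,slip_pct spino-pelvic targets of the case.
#' @param config a [merge_model_config()] list.
#' @param materials resolved material library.
#' @return list with `summary` (rbind-ed `stress_summary` rows for the S1
#'   growth plate and L5-S1 disc), `responses` (named scalar responses),
#'   `follower_iterations`, `params` (measured spino-pelvic parameters).
#' @export
run_case <- function(geometry, PI_deg, SS_deg, slip_pct,
                     config = merge_model_config(),
                     materials = override_materials(default_material_library(),
                                                    config$materials)) {
  geom <- apply_pelvic_rotation(geometry, PI_deg, SS_deg)
  geom <- apply_slip(geom, slip_pct)
  mc <- config$mesh
  mesh <- build_detailed_mesh(
    geom,
    resolution = mesh_resolution(mc$nx, mc$ny, mc$nz_body, mc$nz_disc,
                                 mc$nz_sacrum),
    include_ribs = isTRUE(mc$include_ribs),
    pars_lysis = isTRUE(mc$pars_lysis),
    dome_height_mm = mc$dome_height_mm,
    materials = materials)
  sys <- assemble_global_stiffness(mesh, materials)
  sys <- apply_boundary_conditions(
    sys, standing_boundary_conditions(sys, config$loading$torsion_stiffness))
  dist <- body_weight_distribution(
    config$patient$weight_kg,
    fraction_table = unlist(config$loading$fraction_table),
    g = config$loading$g)
  U <- follower_equilibrium_iteration(
    sys, dist, tol = config$loading$follower_tol,
    max_iter = config$loading$follower_max_iter)
  sf <- recover_hex_stresses(mesh, U, materials)
  frame <- build_plate_frame(mesh$nodes[mesh$node_groups$l5_growth_plate, ])
  sf <- transform_to_plate_frame(sf, frame)

  summaries <- list(); responses <- c()
  for (st in c("s1_growth_plate", "disc_l5s1")) {
    part <- partition_plate_regions(sf, st)
    summaries[[st]] <- summarize_stresses(sf, part, st)
    sel <- attr(part, "elements")
    sn <- sf$sigma_n[sel]; ts <- sf$tau_slip[sel]
    yp <- sf$centroid_local[sel, "yp"]
    top <- abs(ts) >= stats::quantile(abs(ts), 0.9, type = 1)
    key <- if (st == "s1_growth_plate") "gp" else "disc"
    responses[paste0(key, "_sigma_n_max")] <- sn[which.max(abs(sn))]
    responses[paste0(key, "_sigma_n_mean")] <- mean(sn)
    responses[paste0(key, "_tau_slip_max")] <- max(ts)
    responses[paste0(key, "_tau_slip_mean")] <- mean(ts)
    # anterior offset of the most stressed elements within the structure
    # (structure-relative, so rigid motion of the plate does not enter)
    responses[paste0(key, "_top_decile_yp")] <- mean(yp[top]) - mean(yp)
    ant <- summaries[[st]][summaries[[st]]$region == "anterior", ]
    responses[paste0(key, "_ant_sigma_n_mean")] <- ant$sigma_n_mean
    responses[paste0(key, "_ant_tau_slip_mean")] <- ant$tau_slip_mean
    responses[paste0(key, "_ant_tau_slip_max")] <- ant$tau_slip_max
  }
  list(summary = do.call(rbind, summaries),
       responses = responses,
       follower_iterations = attr(U, "follower_iterations"),
       params = measure_spinopelvic(geom),
       n_elements = n_elements(mesh))
}

#' Run the full simulation campaign
#'
#' Executes every case of the design with the per-case pipeline of
#' [run_case()]. A failing case (e.g. an unsolvable model) is recorded with
#' status "failed" and the campaign continues. Given identical
#' configuration and seed the campaign output is bitwise identical.
#'
#' @param template_config a [merge_model_config()] list (or NULL for the
#'   defaults).
#' @param design a `design_table`; default the packaged 10-case campaign.
#' @param seed integer seed recorded with the result (the deterministic
#'   pipeline itself draws no random numbers; the seed feeds optional
#'   landmark-noise emulation).
#' @param reconstruct_landmarks if TRUE, replace the template landmarks by
#'   a noisy reconstruction ([generate_patient_landmarks()]) before the
#'   campaign, using `seed`.
#' @param progress print one line per case.
#' @return a `campaign_result`: list with `design`, `responses` (one row
#'   per case), `summaries` (long stress-summary table), `diagnostics`,
#'   `config`, `seed`.
#' @export
run_simulation_campaign <- function(template_config = NULL,
                                    design = default_campaign_design(),
                                    seed = 1L,
                                    reconstruct_landmarks = FALSE,
                                    progress = FALSE) {
  config <- merge_model_config(template_config)
  materials <- override_materials(default_material_library(),
                                  config$materials)
  base <- generate_template_geometry(targets = config$targets,
                                     patient = config$patient,
                                     include_ribs = isTRUE(config$mesh$include_ribs))
  if (reconstruct_landmarks) {
    base$landmarks <- generate_patient_landmarks(base, seed = seed)
  }
  responses <- NULL; summaries <- NULL; diagnostics <- NULL
  for (i in seq_len(nrow(design))) {
    cs <- design[i, ]
    t0 <- proc.time()[3]
    out <- tryCatch(
      run_case(base, cs$PI_deg, cs$SS_deg, cs$slip_pct, config, materials),
      error = function(e) e)
    if (inherits(out, "error")) {
      diagnostics <- rbind(diagnostics, data.frame(
        case = cs$case, status = "failed", follower_iterations = NA_integer_,
        n_elements = NA_integer_, seconds = proc.time()[3] - t0,
        message = conditionMessage(out)))
      if (progress) message(sprintf("case %d: FAILED (%s)", cs$case,
                                    conditionMessage(out)))
      next
    }
    diagnostics <- rbind(diagnostics, data.frame(
      case = cs$case, status = "converged",
      follower_iterations = out$follower_iterations,
      n_elements = out$n_elements, seconds = proc.time()[3] - t0,
      message = ""))
    responses <- rbind(responses, cbind(
      data.frame(case = cs$case, PI_deg = cs$PI_deg, SS_deg = cs$SS_deg,
                 slip_pct = cs$slip_pct),
      as.data.frame(as.list(out$responses))))
    sm <- out$summary
    sm <- cbind(data.frame(case = cs$case), sm)
    summaries <- rbind(summaries, sm)
    if (progress) message(sprintf(
      "case %d (PI %g, SS %g, slip %g%%): %d elements, %d follower iterations",
      cs$case, cs$PI_deg, cs$SS_deg, cs$slip_pct, out$n_elements,
      out$follower_iterations))
  }
  rownames(responses) <- rownames(summaries) <- rownames(diagnostics) <- NULL
  structure(list(design = design, responses = responses,
                 summaries = summaries, diagnostics = diagnostics,
                 config = config, seed = seed),
            class = "campaign_result")
}

#' @export
print.campaign_result <- function(x, ...) {
  cat(sprintf("<campaign_result> %d cases (%d converged)\n",
              nrow(x$design), sum(x$diagnostics$status == "converged")))
  invisible(x)
}

#' Write campaign stress summaries as CSV
#'
#' @param campaign a `campaign_result`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_campaign_csv <- function(campaign, path) {
  df <- campaign$summaries
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 12))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Statistical analysis of a campaign
#'
#' Relates each stress response to each spino-pelvic factor with (i) a
#' one-way ANOVA of the response grouped by factor level and (ii) a
#' Pearson correlation across cases, mirroring the campaign's
#' significance level of 0.05. An optional Bonferroni correction over the
#' tested pairs is available (off by default).
#'
#' @param campaign a `campaign_result`.
#' @param factors factor columns of the response table.
#' @param responses response columns; default the growth-plate and disc
#'   stress extremes.
#' @param alpha significance level.
#' @param bonferroni apply Bonferroni correction over all tested pairs.
#' @return data frame with one row per factor x response: `F`, `p_anova`,
#'   `r`, `p_pearson`, `significant`.
#' @export
campaign_stats <- function(campaign,
                           factors = c("PI_deg", "SS_deg", "slip_pct"),
                           responses = c("gp_sigma_n_max", "gp_tau_slip_max",
                                         "disc_sigma_n_max",
                                         "disc_tau_slip_max"),
                           alpha = 0.05, bonferroni = FALSE) {
  rt <- campaign$responses
  rows <- list()
  for (fc in factors) for (rp in responses) {
    groups <- split(rt[[rp]], rt[[fc]])
    groups <- groups[vapply(groups, length, 1L) >= 2]
    an <- if (length(groups) >= 2) {
      tryCatch(one_way_anova(groups, alpha), error = function(e) NULL)
    }
    pc <- tryCatch(pearson_correlation(rt[[fc]], rt[[rp]]),
                   error = function(e) list(r = NA_real_, p = NA_real_))
    rows[[paste(fc, rp)]] <- data.frame(
      factor = fc, response = rp,
      F = if (is.null(an)) NA_real_ else an$F,
      p_anova = if (is.null(an)) NA_real_ else an$p,
      r = pc$r, p_pearson = pc$p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  m <- if (bonferroni) nrow(out) else 1
  out$significant <- pmin(1, out$p_pearson * m) < alpha
  out
}

#' Write a campaign statistics report as JSON
#'
#' @param stats a [campaign_stats()] table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_stats_json <- function(stats, path) {
  jsonlite::write_json(stats, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
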