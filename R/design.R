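#' Full factorial design table
#'
#' Cartesian product of the factor levels in lexicographic order (last
#' factor varies fastest), the classical 2^k layout when every factor has
#' two levels.
#'
#' @param factor_levels named list of numeric level vectors, e.g.
#'   `list(PI_deg = c(52, 75), SS_deg = c(45, 60), slip_pct = c(30, 80))`.
#' @return a `design_table` data frame with a `case` id column followed by
#'   one column per factor.
#' @export
full_factorial_design <- function(factor_levels) {
  if (!length(factor_levels) || any(!vapply(factor_levels, length, 1L))) {
    stop("every factor needs at least one level")
  }
  if (any(vapply(factor_levels, length, 1L) < 2)) {
    stop("every factor needs at least 2 levels")
  }
  grid <- expand.grid(rev(factor_levels), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(factor_levels)), drop = FALSE]
  out <- cbind(data.frame(case = seq_len(nrow(grid))), grid)
  rownames(out) <- NULL
  class(out) <- c("design_table", "data.frame")
  out
}

#' Filter a design by constraint rules
#'
#' Removes cases that violate any rule; a removal log (case ids and the
#' violated rule) is kept as an attribute. Rules are predicates over a
#' one-row case (data frame) returning TRUE to keep.
#'
#' @param design a `design_table`.
#' @param rules named list of predicate functions.
#' @return the constrained `design_table`, attribute `removed` logging the
#'   eliminated cases; warns when everything is eliminated.
#' @export
apply_design_constraints <- function(design, rules = list()) {
  if (!length(rules)) {
    attr(design, "removed") <- data.frame(case = integer(0),
                                          rule = character(0))
    return(design)
  }
  keep <- rep(TRUE, nrow(design))
  removed <- data.frame(case = integer(0), rule = character(0))
  for (rn in names(rules)) {
    ok <- vapply(seq_len(nrow(design)),
                 function(i) isTRUE(rules[[rn]](design[i, ])), logical(1))
    removed <- rbind(removed,
                     data.frame(case = design$case[keep & !ok], rule = rn))
    keep <- keep & ok
  }
  out <- design[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  class(out) <- c("design_table", "data.frame")
  if (!nrow(out)) warning("all design cases were eliminated by the constraints")
  out
}

#' Default constrained simulation campaign
#'
#' The packaged campaign over pelvic incidence, sacral slope and slip
#' percentage: a 2^3 factorial augmented with constraint-driven
#' replacements yields ten plausible low- and high-grade spondylolisthesis
#' configurations. Cases 1-4 are low grade (Grade II slip) from the
#' nutcracker (PI 52/SS 45) to the shear (PI 75/SS 60) morphology; cases
#' 5-10 are high grade at 60% and 80% slip with PI 60/75 and SS 45/60,
#' including the retroverted (case 5) vs balanced (case 6) contrast.
#'
#' @param baseline_slip_pct slip percentage of the low-grade cases.
#' @return a `design_table` with columns `case`, `PI_deg`, `SS_deg`,
#'   `slip_pct`, `grade`, `config_type`.
#' @export
default_campaign_design <- function(baseline_slip_pct = 30) {
  d <- data.frame(
    case = 1:10,
    PI_deg = c(52, 60, 68, 75, 75, 75, 75, 60, 75, 60),
    SS_deg = c(45, 50, 55, 60, 45, 60, 45, 45, 60, 60),
    slip_pct = c(rep(baseline_slip_pct, 4), 80, 80, 60, 80, 60, 80))
  d$grade <- meyerding_grade(d$slip_pct)
  d$config_type <- vapply(seq_len(nrow(d)), function(i) {
    classify_configuration(list(PI = d$PI_deg[i], SS = d$SS_deg[i],
                                PT = d$PI_deg[i] - d$SS_deg[i],
                                slip_pct = d$slip_pct[i],
                                grade = d$grade[i]))
  }, character(1))
  class(d) <- c("design_table", "data.frame")
  d
}

#' Annotate a design with derived grade and configuration type
#' @param design a `design_table` with PI_deg, SS_deg, slip_pct columns.
#' @return the design with `grade` and `config_type` columns.
#' @export
annotate_design <- function(design) {
  design$grade <- meyerding_grade(design$slip_pct)
  design$config_type <- vapply(seq_len(nrow(design)), function(i) {
    classify_configuration(list(
      PI = design$PI_deg[i], SS = design$SS_deg[i],
      PT = design$PI_deg[i] - design$SS_deg[i],
      slip_pct = design$slip_pct[i], grade = design$grade[i]))
  }, character(1))
  design
}

#' Read / write a design table CSV
#' @param path file path.
#' @rdname design-csv
#' @export
read_design_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case", "PI_deg", "SS_deg", "slip_pct")
  if (!all(need %in% names(d))) {
    stop("design CSV must have columns ", paste(need, collapse = ","))
  }
  class(d) <- c("design_table", "data.frame")
  annotate_design(d)
}

#' @param design a `design_table` to write.
#' @rdname design-csv
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(design[, intersect(
    c("case", "PI_deg", "SS_deg", "slip_pct"), names(design))],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: F = MS_between / MS_within with
#' k - 1 and N - k degrees of freedom, p-value from the F distribution
#' (computed via [stats::oneway.test()] with equal variances, the textbook
#' decomposition).
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @param alpha significance level for the flag (default 0.05).
#' @return an `anova_result` list: `F`, `p`, `df_between`, `df_within`,
#'   `significant`.
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("at least 2 groups are required")
  if (any(vapply(groups, length, 1L) < 2)) {
    stop("every group needs at least 2 observations")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (stats::var(values) < .Machine$double.eps * max(1, mean(values)^2)) {
    stop("degenerate input: all observations identical")
  }
  ft <- stats::oneway.test(values ~ g, var.equal = TRUE)
  res <- list(F = unname(ft$statistic), p = unname(ft$p.value),
              df_between = unname(ft$parameter[1]),
              df_within = unname(ft$parameter[2]),
              significant = unname(ft$p.value) < alpha)
  class(res) <- "anova_result"
  res
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%g, %g) = %.4g, p = %.4g%s\n",
              x$df_between, x$df_within, x$F, x$p,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Pearson correlation with two-sided test
#'
#' Standard product-moment correlation; the p-value comes from the exact t
#' transform (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with `r` and `p`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input vector: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = unname(ct$p.value))
}
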