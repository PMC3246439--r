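#' Configure an analysis run
#'
#' A run takes its specimens either from files (an outline table plus a
#' metadata table) or from the synthetic generator — exactly one of the
#' two. The configuration carries the Fourier settings (harmonic count,
#' resampling density, cumulative-power threshold), the seed, and toggles
#' for the individual statistics.
#'
#' @param outlines,metadata Paths to an outline table and a specimen
#'   metadata table (see [read_outlines()], [read_specimens()]).
#' @param simulate An [assemblage_spec()] to generate the sample instead.
#' @param harmonics Harmonic count for the Fourier fit.
#' @param power_threshold Cumulative-power check threshold.
#' @param n_points Resampling density.
#' @param seed Integer seed used for every stochastic step of the run.
#' @param tang_side Orientation mode passed to [orient_outlines()]. The
#'   default `"asis"` trusts the field's digitization convention (tang
#'   facing left) and only normalizes the traversal direction; use
#'   `"auto"`, `"left"` or `"right"` to engage the narrow-end detector on
#'   unconventional input.
#' @param welch,regressions,allometry,quantile_spread Analysis toggles.
#' @param bins Length classes for the quantile-spread summary.
#' @param projection `NULL` for no projection section, `"simulate"` to
#'   project a generated arrowhead-like population, or a path to a
#'   coefficient table of an external sample.
#' @param output_dir Optional directory for [write_report()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(outlines = NULL, metadata = NULL, simulate = NULL,
                       harmonics = 11, power_threshold = 0.99,
                       n_points = 512, seed = 1, tang_side = "asis",
                       welch = TRUE,
                       regressions = TRUE, allometry = TRUE,
                       quantile_spread = TRUE, bins = 4, projection = NULL,
                       output_dir = NULL) {
  from_files <- !is.null(outlines) && !is.null(metadata)
  if (identical(from_files, !is.null(simulate))) {
    rlang::abort(paste0(
      "supply exactly one input source: outlines+metadata paths, ",
      "or a simulation spec"
    ), class = "tangmorph_parameter_error")
  }
  if (harmonics < 1) {
    rlang::abort("harmonics must be at least 1",
      class = "tangmorph_parameter_error")
  }
  structure(as.list(environment())[names(formals(run_config))],
    class = "run_config")
}

#' Read a run configuration from a flat key=value file
#'
#' Lines of the form `key = value` (comments with `#`); recognized keys are
#' the arguments of [run_config()], with `simulate = true` standing for a
#' default [assemblage_spec()] of size `simulate_n` (default 400) seeded
#' from `seed`.
#'
#' @param path Path to the configuration file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) {
    rlang::abort(paste0("malformed config line: ", lines[bad][1]),
      class = "tangmorph_format_error")
  }
  vals <- stats::setNames(
    lapply(kv, function(p) parse_config_value(p[2])),
    vapply(kv, `[[`, character(1), 1)
  )
  seed <- as.integer(vals$seed %||% 1)
  args <- vals[intersect(names(vals), names(formals(run_config)))]
  args$seed <- seed
  if (isTRUE(vals$simulate)) {
    args$simulate <- assemblage_spec(
      n = as.integer(vals$simulate_n %||% 400), seed = seed)
  }
  if (identical(vals$projection, TRUE)) args$projection <- "simulate"
  do.call(run_config, args)
}

parse_config_value <- function(v) {
  if (tolower(v) %in% c("true", "false")) {
    return(tolower(v) == "true")
  }
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) {
    return(num)
  }
  v
}

# Load or simulate, then orient and resample; returns outlines, specimens,
# geometry and (for simulated runs) the ground truth.
prepare_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- generate_assemblage(config$simulate, n_points = config$n_points)
    outlines <- sim$outlines
    specimens <- sim$specimens
    truth <- sim$truth
  } else {
    outlines <- read_outlines(config$outlines)
    specimens <- read_specimens(config$metadata)
    truth <- NULL
  }
  outlines <- orient_outlines(outlines, tang_side = config$tang_side)
  outlines <- resample_outlines(outlines, config$n_points)
  list(
    outlines = outlines,
    specimens = specimens,
    geometry = measure_outlines(outlines),
    truth = truth
  )
}

#' Reduction-in-the-haft analysis
#'
#' The first analysis stage: are the tips of retouched pieces shorter than
#' those of unretouched pieces while tang lengths stay indistinguishable?
#' Uses the metadata tip/tang lengths when present, otherwise measures
#' them from the outlines with the shoulder detector, and reports Welch
#' comparisons of tip and tang length by retouch status, the measurement
#' table, and per-assemblage counts.
#'
#' @param config A [run_config()] whose metadata includes retouch flags.
#' @return A list of class `reduction_report`.
#' @export
run_reduction_analysis <- function(config) {
  inp <- prepare_inputs(config)
  sp <- inp$specimens
  if (!"retouched" %in% names(sp) || anyNA(sp$retouched)) {
    rlang::abort("metadata must include retouch flags for every specimen",
      class = "tangmorph_parameter_error")
  }
  if (length(unique(sp$retouched)) < 2) {
    rlang::abort(paste0(
      "no ", if (all(sp$retouched)) "unretouched" else "retouched",
      " group present; the comparison is undefined"
    ), class = "tangmorph_parameter_error")
  }
  measurements <- if (all(is.finite(sp$tip_length)) &&
      all(is.finite(sp$tang_length))) {
    sp[c("specimen_id", "length", "tang_length", "tip_length")]
  } else {
    measure_tang_tip(inp$outlines)[
      c("specimen_id", "length", "tang_length", "tip_length")]
  }
  md <- dplyr::left_join(measurements,
    sp[c("specimen_id", "retouched", "assemblage")], by = "specimen_id")
  counts <- dplyr::summarise(dplyr::group_by(md, .data$assemblage),
    n = dplyr::n(), n_retouched = sum(.data$retouched), .groups = "drop")
  structure(
    list(
      welch_tip = welch_test(md, tip_length, retouched),
      welch_tang = welch_test(md, tang_length, retouched),
      measurements = measurements,
      counts = counts,
      n = nrow(md),
      seed = config$seed
    ),
    class = "reduction_report"
  )
}

#' @export
print.reduction_report <- function(x, ...) {
  cat("Reduction analysis,", x$n, "specimens\n")
  cat(sprintf(
    "tip length, retouched vs not: t = %.2f, df = %.1f, p = %.3g\n",
    x$welch_tip$t, x$welch_tip$df, x$welch_tip$p))
  cat(sprintf(
    "tang length, retouched vs not: t = %.2f, df = %.1f, p = %.3g\n",
    x$welch_tang$t, x$welch_tang$df, x$welch_tang$p))
  invisible(x)
}

#' Shape-space analysis
#'
#' The second analysis stage: the Fourier shape space and its
#' size-dependence. Fits the standardized-coefficient PCA, reconstructs
#' the extreme shapes of the first three components, regresses PC2 and PC3
#' on length and tip length, fits the major-axis allometry of logged tang
#' on logged tip length with a seeded bootstrap isometry test, summarizes
#' the PC1 spread by length class, and optionally projects an external
#' population into the space with confidence ellipses and their overlap
#' relation.
#'
#' @param config A [run_config()].
#' @return A list of class `shape_report`.
#' @export
run_shape_analysis <- function(config) {
  inp <- prepare_inputs(config)
  coeffs <- efa_forward(inp$outlines, harmonics = config$harmonics)
  spectrum <- harmonic_spectrum(coeffs)
  std <- efa_standardize(coeffs, inp$geometry)
  space <- fit_shape_pca(std)
  extremes <- dplyr::bind_rows(lapply(1:3, function(k) {
    extreme_shapes(space, k, n_points = config$n_points)
  }))

  md <- dplyr::left_join(space$scores, inp$specimens, by = "specimen_id")
  report <- list(
    variance_fraction = space$variance_fraction,
    power_check = dplyr::summarise(
      dplyr::group_by(spectrum, .data$specimen_id),
      final = max(.data$cumulative_fraction), .groups = "drop"),
    space = space,
    extreme_shapes = extremes,
    scores = md,
    seed = config$seed
  )
  if (isTRUE(config$regressions)) {
    report$regression_pc2 <- regress_pc_on_size(md, "PC2")
    report$regression_pc3 <- regress_pc_on_size(md, "PC3")
  }
  if (isTRUE(config$allometry)) {
    report$allometry <- major_axis(md, log(tip_length), log(tang_length),
      seed = config$seed)
  }
  if (isTRUE(config$quantile_spread)) {
    report$spread_equal_n <- spread_by_length(md, PC1, length,
      mode = "equal_n", bins = config$bins, retouched = retouched)
    report$spread_equal_width <- spread_by_length(md, PC1, length,
      mode = "equal_width", bins = config$bins, retouched = retouched)
  }
  if (!is.null(config$projection)) {
    ext <- if (identical(config$projection, "simulate")) {
      proj_pop <- generate_projectile_population(
        n = 29, seed = config$seed + 1, n_points = config$n_points)
      proj_out <- resample_outlines(orient_outlines(proj_pop$outlines),
        config$n_points)
      efa_standardize(
        efa_forward(proj_out, harmonics = config$harmonics),
        measure_outlines(proj_out))
    } else {
      read_coefficients(config$projection)
    }
    if (coeff_harmonics(ext) != config$harmonics) {
      rlang::abort("projection reference has a different harmonic count",
        class = "tangmorph_parameter_error")
    }
    proj_scores <- project_shapes(space, ext)
    e_ref <- confidence_ellipse(space$scores)
    e_ext <- confidence_ellipse(proj_scores)
    k <- min(3, ncol(space$rotation))
    report$projection <- list(
      scores = proj_scores,
      ellipse_reference = e_ref,
      ellipse_external = e_ext,
      overlap = ellipse_overlap(e_ref, e_ext),
      score_var = tibble::tibble(
        component = paste0("PC", seq_len(k)),
        reference_var = vapply(seq_len(k), function(j)
          stats::var(space$scores[[paste0("PC", j)]]), double(1)),
        external_var = vapply(seq_len(k), function(j)
          stats::var(proj_scores[[paste0("PC", j)]]), double(1))
      )
    )
  }
  structure(report, class = "shape_report")
}

#' @export
print.shape_report <- function(x, ...) {
  vf <- x$variance_fraction
  cat(sprintf(
    "Shape space: PC1 %.1f%%, PC2 %.1f%%, PC3 %.1f%% (%.1f%% together)\n",
    100 * vf[1], 100 * vf[2], 100 * vf[3], 100 * sum(vf[1:3])))
  if (!is.null(x$allometry)) {
    cat(sprintf(
      "major-axis slope log(tang) on log(tip): %.3f, CI (%.3f, %.3f)\n",
      x$allometry$slope, x$allometry$ci_low, x$allometry$ci_high))
  }
  if (!is.null(x$projection)) {
    sv <- x$projection$score_var
    cat(sprintf(
      "projected population: ellipses %s; score variance (external/reference): %s\n",
      x$projection$overlap,
      paste(sprintf("%s %.2f", sv$component,
        sv$external_var / sv$reference_var), collapse = ", ")))
  }
  invisible(x)
}

#' Write a report to disk
#'
#' Writes a human-readable text summary plus machine-readable delimited
#' tables (scores, measurements, extreme-shape outlines) and a JSON
#' summary of the scalar statistics, every artifact individually
#' re-loadable.
#'
#' @param report A `reduction_report` or `shape_report`.
#' @param dir Output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  txt <- file.path(dir, "report.txt")
  sink(txt); on.exit(sink(), add = TRUE)
  print(report)
  sink(); on.exit()

  if (inherits(report, "reduction_report")) {
    readr::write_csv(report$measurements,
      file.path(dir, "measurements.csv"))
    readr::write_csv(report$counts, file.path(dir, "counts.csv"))
    jsonlite::write_json(
      list(welch_tip = report$welch_tip, welch_tang = report$welch_tang,
        n = report$n, seed = report$seed),
      file.path(dir, "statistics.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    readr::write_csv(report$scores, file.path(dir, "scores.csv"))
    write_outlines(report$extreme_shapes,
      file.path(dir, "extreme_shapes.csv"))
    stats_out <- list(
      variance_fraction = report$variance_fraction,
      eigenvalues = report$space$eigenvalues,
      seed = report$seed
    )
    if (!is.null(report$allometry)) stats_out$allometry <- report$allometry
    if (!is.null(report$regression_pc2)) {
      stats_out$regression_pc2 <- glance(report$regression_pc2)
      stats_out$regression_pc3 <- glance(report$regression_pc3)
    }
    if (!is.null(report$projection)) {
      stats_out$projection_overlap <- report$projection$overlap
      stats_out$projection_score_var <- report$projection$score_var
    }
    jsonlite::write_json(stats_out, file.path(dir, "statistics.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(dir)
}
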