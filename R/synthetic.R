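#' Ground-truth parameters for one synthetic tanged tool
#'
#' The generator's parameter vector: overall `length`, the fraction of it
#' taken by the tang (`tang_fraction`), the tang and blade half-widths
#' (blade wider than tang), the tip taper exponent `pointedness` (a
#' superellipse exponent: small values give a pointed tip, large values a
#' blunt, rounded, endscraper-like one), the side-to-side `asymmetry` s in
#' (-0.6, 0.6) (upper half-widths scaled by 1+s, lower by 1-s), the radial
#' jitter level, and the reduction bookkeeping.
#'
#' @param specimen_id Specimen identifier.
#' @param length Overall length, planar units.
#' @param tang_fraction Tang length as a fraction of `length`, in
#'   (0.1, 0.5) for an unreduced tool (staged reduction shortens the tip
#'   and may push the realized fraction higher).
#' @param tang_halfwidth,blade_halfwidth Half-widths of stem and blade;
#'   the blade must be wider.
#' @param pointedness Tip taper exponent q > 0.
#' @param asymmetry Side-to-side asymmetry s in (-0.6, 0.6).
#' @param reduction_step Completed resharpening steps (0 = unretouched).
#' @param noise_sd Jitter standard deviation as a fraction of the blade
#'   half-width.
#' @param seed Integer seed for the jitter.
#' @return A one-row tibble of class `tool_truth`.
#' @export
tool_truth <- function(specimen_id = "tool", length = 100,
                       tang_fraction = 0.3, tang_halfwidth = 14,
                       blade_halfwidth = 22, pointedness = 1.5,
                       asymmetry = 0, reduction_step = 0L,
                       noise_sd = 0.01, seed = NULL) {
  out <- tibble::tibble(
    specimen_id = specimen_id,
    length = length,
    tang_fraction = tang_fraction,
    tang_halfwidth = tang_halfwidth,
    blade_halfwidth = blade_halfwidth,
    pointedness = pointedness,
    asymmetry = asymmetry,
    reduction_step = as.integer(reduction_step),
    retouched = reduction_step > 0,
    noise_sd = noise_sd,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
  validate_truth(out)
  class(out) <- c("tool_truth", class(out))
  out
}

validate_truth <- function(truth) {
  with(truth, {
    upper_f <- if (all(reduction_step > 0)) 0.95 else 0.5
    if (any(length <= 0) ||
        any(tang_fraction <= 0.1 | tang_fraction >= upper_f) ||
        any(tang_halfwidth <= 0) ||
        any(blade_halfwidth <= tang_halfwidth) ||
        any(pointedness <= 0) ||
        any(asymmetry <= -0.6 | asymmetry >= 0.6) ||
        any(noise_sd < 0)) {
      rlang::abort("tool parameters out of bounds",
        class = "tangmorph_parameter_error")
    }
  })
  invisible(truth)
}

# Half-width profile of the silhouette on a fine grid over [0, L].
# Rounded tang base, constant stem, a notch of fixed depth (25 % of the
# tang half-width) just before the shoulder, a smooth cubic blend up to the
# blade, and a superelliptic taper to the tip.
tool_profile <- function(truth, m = 1024) {
  L <- truth$length
  TL <- truth$tang_fraction * L
  BL <- L - TL
  Wt <- truth$tang_halfwidth
  Wb <- truth$blade_halfwidth
  q <- truth$pointedness
  x <- seq(0, L, length.out = m)
  h <- numeric(m)

  r <- min(0.5 * TL, Wt)            # rounded base cap
  wn <- 0.10 * TL                   # notch width
  wb <- 0.03 * L                    # shoulder blend width
  smoothstep <- function(u) {
    u <- pmin(1, pmax(0, u))
    u * u * (3 - 2 * u)
  }

  base <- x < r
  h[base] <- Wt * sqrt(pmax(0, 1 - ((r - x[base]) / r)^2))
  stem <- x >= r & x < TL - wn
  h[stem] <- Wt
  notch <- x >= TL - wn & x < TL
  h[notch] <- Wt * (1 - 0.25 * smoothstep((x[notch] - (TL - wn)) / wn))

  blade <- x >= TL
  u <- (x[blade] - TL) / BL
  h_blade <- Wb * (1 - u^q)^(1 / q)
  s01 <- smoothstep((x[blade] - TL) / wb)
  h[blade] <- (1 - s01) * 0.75 * Wt + s01 * h_blade
  list(x = x, h = h)
}

#' Generate a synthetic tanged-tool outline
#'
#' Builds the closed silhouette described by a [tool_truth()] row: a
#' rounded-trapezoid tang joined through notched shoulders to a blade that
#' tapers to the tip with the superellipse exponent, the asymmetry applied
#' as the (1±s) scaling of the two edges. Gaussian jitter (sd =
#' `noise_sd * blade_halfwidth`, seeded, tapered to zero at the two ends)
#' is added to the half-width profile and shared by the two edges, so a
#' symmetric tool stays exactly mirror-symmetric and the s / -s pair are
#' exact mirror images under the same seed. The outline is returned
#' oriented tang-left and counterclockwise, resampled to `n_points` points.
#'
#' @param truth A one-row [tool_truth()] tibble.
#' @param n_points Points in the returned outline.
#' @return An outline tibble.
#' @export
generate_tool <- function(truth, n_points = 512) {
  validate_truth(truth)
  pr <- tool_profile(truth)
  m <- length(pr$x)
  eps <- if (truth$noise_sd > 0) {
    seed <- if (is.na(truth$seed)) NULL else truth$seed
    z <- with_seed(seed, stats::rnorm(m))
    taper <- sqrt(pmax(0, pr$h) / truth$blade_halfwidth)
    truth$noise_sd * truth$blade_halfwidth * z * pmin(1, taper)
  } else {
    numeric(m)
  }
  h_top <- pmax(0, (1 + truth$asymmetry) * pr$h + eps)
  h_bot <- pmax(0, (1 - truth$asymmetry) * pr$h + eps)
  xy <- rbind(
    cbind(pr$x, -h_bot),
    cbind(rev(pr$x[-c(1, m)]), rev(h_top[-c(1, m)]))
  )
  keep <- c(TRUE, rowSums(abs(diff(xy))) > 0)
  xy <- xy[keep, , drop = FALSE]
  mats <- list(resample_xy(xy, n_points))
  names(mats) <- truth$specimen_id
  outline_bind(mats)
}

# Closed-form state after `steps` resharpening steps: the tip shrinks by
# (1 - delta) per step with the tang's absolute length fixed; edge modes
# drift the asymmetry, rounding blunts the taper exponent.
reduce_truth <- function(truth, steps, mode, step_fraction, drift) {
  tang_len <- truth$tang_fraction * truth$length
  tip_len <- truth$length - tang_len
  tip_new <- tip_len * (1 - step_fraction)^steps
  s <- truth$asymmetry + switch(mode,
    edge_left = -drift * steps,
    edge_right = drift * steps,
    0
  )
  s <- pmin(0.599, pmax(-0.599, s))
  q <- if (mode == "rounding") {
    truth$pointedness * (1 + step_fraction)^steps
  } else {
    truth$pointedness
  }
  out <- truth
  out$length <- tang_len + tip_new
  out$tang_fraction <- tang_len / out$length
  out$asymmetry <- s
  out$pointedness <- q
  out$reduction_step <- truth$reduction_step + as.integer(steps)
  out$retouched <- out$reduction_step > 0
  if (!is.na(out$seed)) out$seed <- out$seed + as.integer(steps)
  out
}

#' Simulate staged resharpening of one tool
#'
#' Applies `steps` resharpening episodes to a tool: each step multiplies
#' the tip length by `1 - step_fraction` while the tang's absolute length
#' stays fixed (it sits in the haft). The trajectory modes mirror the
#' classic reduction hypotheses: `edge_left` / `edge_right` prefer one
#' lateral edge and drift the asymmetry by `drift` per step;
#' `symmetric_point` resharpens both edges evenly, keeping a pointed end;
#' `rounding` blunts the tip into an endscraper-like form by inflating the
#' taper exponent. The jitter is re-drawn at every step; tang length noise
#' belongs to lineage creation only, so tang length is constant along a
#' lineage.
#'
#' @param truth Starting [tool_truth()] row.
#' @param steps Number of resharpening steps (at least 1).
#' @param mode One of `"symmetric_point"`, `"edge_left"`, `"edge_right"`,
#'   `"rounding"`.
#' @param step_fraction Tip-length fraction removed per step, in (0, 0.3).
#' @param drift Asymmetry increment per step for the edge modes.
#' @param n_points Points per generated outline.
#' @return A list with `truth` (tibble of steps 0..`steps`) and `outlines`
#'   (outline tibble, specimens suffixed `_step<k>`).
#' @export
simulate_reduction <- function(truth, steps,
                               mode = c("symmetric_point", "edge_left",
                                 "edge_right", "rounding"),
                               step_fraction = 0.1, drift = 0.05,
                               n_points = 512) {
  mode <- match.arg(mode)
  if (steps < 1) {
    rlang::abort("steps must be at least 1",
      class = "tangmorph_parameter_error")
  }
  if (step_fraction <= 0 || step_fraction >= 0.3) {
    rlang::abort("step_fraction must lie in (0, 0.3)",
      class = "tangmorph_parameter_error")
  }
  states <- purrr::map(0:steps, function(k) {
    st <- reduce_truth(truth, k, mode, step_fraction, drift)
    st$specimen_id <- paste0(truth$specimen_id, "_step", k)
    st
  })
  truths <- dplyr::bind_rows(states)
  outlines <- dplyr::bind_rows(purrr::map(states, generate_tool,
    n_points = n_points))
  list(truth = truths, outlines = outlines)
}

#' Specification of a synthetic assemblage
#'
#' The stated world of the default synthetic assemblage: lineage parameters
#' are drawn once at creation (length normal, half-widths normal, tang
#' fraction uniform, taper exponent log-normal, asymmetry normal truncated
#' to ±0.2 so that edge drift cannot leave the valid range), and each
#' lineage is discarded — becomes the observed specimen — at a reduction
#' step drawn uniformly from `0:steps_max`, with the trajectory mode drawn
#' per lineage when `reduction = "mixed"`.
#'
#' @param n Number of specimens (lineages).
#' @param seed Integer seed; everything downstream is reproducible from it.
#' @param length_mean,length_sd Creation length distribution.
#' @param tang_fraction_range Uniform range of the creation tang fraction.
#' @param tang_halfwidth_mean,tang_halfwidth_sd Stem half-width.
#' @param blade_halfwidth_mean,blade_halfwidth_sd Blade half-width.
#' @param pointedness_meanlog,pointedness_sdlog Log-normal taper exponent.
#' @param asymmetry_sd Creation asymmetry standard deviation.
#' @param noise_sd Jitter level (fraction of the blade half-width).
#' @param reduction `"none"`, one trajectory mode, or `"mixed"`.
#' @param steps_max Maximum reduction step at discard.
#' @param step_fraction,drift Per-step tip shrinkage and asymmetry drift.
#' @return A list of class `assemblage_spec`.
#' @export
assemblage_spec <- function(n = 400, seed = 1,
                            length_mean = 100, length_sd = 10,
                            tang_fraction_range = c(0.24, 0.32),
                            tang_halfwidth_mean = 14, tang_halfwidth_sd = 1.5,
                            blade_halfwidth_mean = 22, blade_halfwidth_sd = 2,
                            pointedness_meanlog = log(1.5),
                            pointedness_sdlog = 0.2,
                            asymmetry_sd = 0.12, noise_sd = 0.01,
                            reduction = "mixed", steps_max = 5,
                            step_fraction = 0.1, drift = 0.07) {
  if (n < 1) {
    rlang::abort("n must be at least 1", class = "tangmorph_parameter_error")
  }
  modes <- c("none", "symmetric_point", "edge_left", "edge_right",
    "rounding", "mixed")
  if (!reduction %in% modes) {
    rlang::abort(paste0("reduction must be one of: ",
      paste(modes, collapse = ", ")), class = "tangmorph_parameter_error")
  }
  structure(as.list(environment()), class = "assemblage_spec")
}

#' Generate a synthetic assemblage with ground truth
#'
#' Draws `spec$n` tool lineages, reduces each to its discard step, and
#' returns the outlines, the specimen metadata records (retouched = any
#' reduction; lengths from the generator geometry; Bordes-style type codes
#' assigned from the trajectory mode) and the ground-truth parameter table
#' used by the parameter-recovery tests. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec An [assemblage_spec()].
#' @param n_points Points per outline.
#' @return A list with `outlines`, `specimens`, `truth`.
#' @export
generate_assemblage <- function(spec, n_points = 512) {
  stopifnot(inherits(spec, "assemblage_spec"))
  rtrunc_norm <- function(n, mean, sd, lo, hi) {
    pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
  }
  draws <- with_seed(spec$seed, {
    n <- spec$n
    tibble::tibble(
      specimen_id = sprintf("t%04d", seq_len(n)),
      length = rtrunc_norm(n, spec$length_mean, spec$length_sd,
        0.5 * spec$length_mean, 1.6 * spec$length_mean),
      tang_fraction = stats::runif(n, spec$tang_fraction_range[1],
        spec$tang_fraction_range[2]),
      tang_halfwidth = rtrunc_norm(n, spec$tang_halfwidth_mean,
        spec$tang_halfwidth_sd, 0.5 * spec$tang_halfwidth_mean,
        1.5 * spec$tang_halfwidth_mean),
      pointedness = stats::rlnorm(n, spec$pointedness_meanlog,
        spec$pointedness_sdlog),
      asymmetry = rtrunc_norm(n, 0, spec$asymmetry_sd, -0.2, 0.2),
      steps = if (spec$reduction == "none") {
        0L
      } else {
        sample(0:spec$steps_max, n, replace = TRUE)
      },
      mode = if (spec$reduction %in% c("none", "mixed")) {
        sample(c("symmetric_point", "edge_left", "edge_right", "rounding"),
          n, replace = TRUE)
      } else {
        spec$reduction
      },
      jitter_seed = sample.int(2^20, n),
      type_seed = sample.int(2^20, n)
    )
  })
  # blade half-width drawn with a floor above the tang half-width
  draws$blade_halfwidth <- with_seed(spec$seed + 1, {
    pmax(draws$tang_halfwidth * 1.15,
      rtrunc_norm(spec$n, spec$blade_halfwidth_mean, spec$blade_halfwidth_sd,
        0.5 * spec$blade_halfwidth_mean, 1.6 * spec$blade_halfwidth_mean))
  })

  rows <- purrr::map(seq_len(spec$n), function(i) {
    d <- draws[i, ]
    t0 <- tool_truth(
      specimen_id = d$specimen_id, length = d$length,
      tang_fraction = d$tang_fraction, tang_halfwidth = d$tang_halfwidth,
      blade_halfwidth = d$blade_halfwidth, pointedness = d$pointedness,
      asymmetry = d$asymmetry, noise_sd = spec$noise_sd, seed = d$jitter_seed
    )
    if (d$steps > 0) {
      t0 <- reduce_truth(t0, d$steps, d$mode, spec$step_fraction, spec$drift)
    }
    t0$mode <- d$mode
    t0
  })
  truth <- dplyr::bind_rows(rows)
  truth$elongation <- truth$length / (2 * truth$blade_halfwidth)
  outlines <- dplyr::bind_rows(purrr::map(rows, generate_tool,
    n_points = n_points))

  type_code <- purrr::map_int(seq_len(spec$n), function(i) {
    with_seed(draws$type_seed[i], {
      if (truth$reduction_step[i] == 0) {
        sample(1:4, 1)
      } else {
        switch(draws$mode[i],
          rounding = sample(30:31, 1),
          symmetric_point = sample(6:8, 1),
          sample(9:29, 1)
        )
      }
    })
  })
  specimens <- tibble::tibble(
    specimen_id = truth$specimen_id,
    assemblage = "synthetic",
    collection_class = "excavated",
    retouched = truth$retouched,
    type_code = type_code,
    length = truth$length,
    tang_length = truth$tang_fraction * truth$length,
    tip_length = (1 - truth$tang_fraction) * truth$length
  )
  list(outlines = outlines, specimens = as_specimens(specimens),
    truth = truth)
}

#' Generate an arrowhead-like comparison population
#'
#' A projectile-point population in the style of known tanged arrowheads:
#' strongly elongated (narrow blade relative to length), with a tight
#' asymmetry distribution and no reduction. Used as the external sample to
#' project into a tool-assemblage shape space.
#'
#' @param n Number of points (specimens), at least 3.
#' @param seed Integer seed.
#' @param n_points Points per outline.
#' @return A list with `outlines`, `specimens`, `truth`.
#' @export
generate_projectile_population <- function(n = 29, seed = 1, n_points = 512) {
  if (n < 3) {
    rlang::abort("n must be at least 3", class = "tangmorph_parameter_error")
  }
  spec <- assemblage_spec(
    n = n, seed = seed,
    length_mean = 110, length_sd = 10,
    tang_fraction_range = c(0.2, 0.3),
    tang_halfwidth_mean = 7, tang_halfwidth_sd = 0.8,
    blade_halfwidth_mean = 12, blade_halfwidth_sd = 1.2,
    pointedness_meanlog = log(1.1), pointedness_sdlog = 0.1,
    asymmetry_sd = 0.02, noise_sd = 0.01,
    reduction = "none"
  )
  out <- generate_assemblage(spec, n_points = n_points)
  out$specimens$assemblage <- "projectile"
  out
}
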