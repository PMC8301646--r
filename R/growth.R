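# Synthetic plant growth: genotype x treatment x day -> 3-D stick geometry.
#
# The plant is a stem (vertical segment) carrying branches (oblique
# segments) and leaves (discs at branch tips and along the stem). It is a
# fixture for segmentation and shape-trait code, not a botany model:
# organs are placed from a seeded template so that geometry at a later day
# is always a superset of geometry at an earlier day (monotone growth).

#' Drought treatments
#'
#' The four watering regimes: `C` control (90% field capacity throughout),
#' `IB40` 40% FC imposed at initial branching, `FL40` 40% FC at flowering,
#' `IB50FL50` 50% FC at both stages.
#' @export
TREATMENTS <- c("C", "IB40", "FL40", "IB50FL50")

# Stress episodes per treatment: onset stage and severity (fractional
# growth-rate reduction for a fully sensitive genotype). IB40 is the
# harshest regime (earliest onset at the strongest deficit), IB50FL50
# intermediate, FL40 mildest (late onset).
treatment_stress <- function(treatment, ib_day, fl_day) {
  switch(treatment,
    C = data.frame(onset = numeric(0), severity = numeric(0)),
    IB40 = data.frame(onset = ib_day, severity = 0.90),
    FL40 = data.frame(onset = fl_day, severity = 0.50),
    IB50FL50 = data.frame(onset = c(ib_day, fl_day), severity = c(0.75, 0.75)),
    stop_invalid(paste("unknown treatment:", treatment))
  )
}

# Severity in effect at day `t` (stress persists from onset to harvest).
severity_at <- function(treatment, t, ib_day, fl_day) {
  ep <- treatment_stress(treatment, ib_day, fl_day)
  if (!nrow(ep)) return(0)
  active <- ep$onset <= t
  if (!any(active)) 0 else max(ep$severity[active])
}

# Baseline development fraction (0 at sowing, -> 1 at maturity).
# Cubic-in-day saturation: most shoot biomass accumulates after the
# initial-branching stage (~day 66), as in conveyor-platform growth curves.
base_development <- function(day) day^3 / (day^3 + 95^3)

#' Development fraction under a treatment
#'
#' Integrates baseline development, scaling increments after each stress
#' onset by `1 - sensitivity * severity`. Monotone non-decreasing in `day`;
#' equal to the control trajectory up to the first onset.
#'
#' @param day Days after sowing (vectorised).
#' @param treatment One of `TREATMENTS`.
#' @param sensitivity Genotype drought sensitivity in \[0, 1\].
#' @param ib_day,fl_day Initial-branching and flowering stage days.
#' @return Development fraction(s) in \[0, 1).
#' @export
development_fraction <- function(day, treatment, sensitivity,
                                 ib_day = 66, fl_day = 100) {
  if (!treatment %in% TREATMENTS) {
    stop_invalid(paste("unknown treatment:", treatment))
  }
  vapply(day, function(d) {
    knots <- sort(unique(pmin(c(0, ib_day, fl_day), d)))
    knots <- c(knots, d)
    dev <- 0
    for (i in seq_len(length(knots) - 1)) {
      sev <- severity_at(treatment, knots[i], ib_day, fl_day)
      inc <- base_development(knots[i + 1]) - base_development(knots[i])
      dev <- dev + inc * (1 - sensitivity * sev)
    }
    dev
  }, numeric(1))
}

#' Grow a synthetic plant
#'
#' Produces the 3-D geometry of one plant of genotype `g` under a
#' treatment at a given day. A seeded organ template (branch azimuths,
#' attachment heights, leaf sizes) is drawn once, and the day determines
#' how much of the template is expressed, so geometry is deterministic
#' under a fixed seed and monotone in `day`. Under stress, development
#' after the onset day is slowed in proportion to the genotype's drought
#' sensitivity, and a fraction of organs (leaves first) turns non-green.
#'
#' @param g One-row tibble / list with `growth_rate`, `drought_sensitivity`,
#'   `senescence_propensity`, `branch_factor` (see [generate_genotypes()]).
#' @param treatment One of `TREATMENTS`.
#' @param day Days after sowing (>= 0).
#' @param seed Integer seed for the organ template.
#' @param ib_day,fl_day Stress-stage days.
#' @param senescence Optional explicit non-green organ fraction in
#'   \[0, 1\]; by default it is derived from the genotype's senescence
#'   propensity and accumulated stress exposure.
#' @return An object of class `plant_geometry`: `organs` tibble
#'   (`role`, `type`, endpoint/centre coordinates in mm, `size` = segment
#'   width or disc radius, `class` green/non-green), plus `height_mm`,
#'   `day`, `treatment`, `senescence_fraction`.
#' @export
grow_plant <- function(g, treatment, day, seed,
                       ib_day = 66, fl_day = 100, senescence = NULL) {
  if (!treatment %in% TREATMENTS) {
    stop_invalid(paste("unknown treatment:", treatment))
  }
  check_scalar_number(day, "day", min = 0)
  dev <- development_fraction(day, treatment, g$drought_sensitivity, ib_day, fl_day)
  height <- 300 * g$growth_rate * dev + 5  # mm; 5 mm seedling stem
  n_branch_max <- as.integer(g$branch_factor) * 2L

  tmpl <- with_seed(seed, {
    list(
      appear = runif(n_branch_max, 0.15, 0.75),   # development at emergence
      attach = attach <- runif(n_branch_max, 0.5, 0.95),  # height fraction on stem
      azim = runif(n_branch_max, 0, 2 * pi),
      # lower branches spread wider, upper ones steeper: the nested fan
      # avoids branch crossings (and hence enclosed background pockets)
      # in the projected silhouettes
      elev = (20 + 45 * (0.95 - attach) / 0.45) * pi / 180,
      rel_len = runif(n_branch_max, 0.35, 0.55),
      leaf_rel = runif(n_branch_max, 0.04, 0.07),    # leaf radius / height
      stem_leaf_h = runif(3, 0.3, 0.8),
      stem_leaf_az = runif(3, 0, 2 * pi)
    )
  })

  organs <- list(tibble(
    role = "stem", type = "segment",
    x0 = 0, y0 = 0, z0 = 0, x1 = 0, y1 = 0, z1 = height,
    size = 10, class = "green"
  ))
  visible <- which(tmpl$appear <= dev)
  for (i in visible) {
    z_att <- tmpl$attach[i] * height
    len <- tmpl$rel_len[i] * height *
      pmin(1, (dev - tmpl$appear[i]) / 0.25)  # branches elongate after emerging
    dx <- sin(tmpl$elev[i]) * cos(tmpl$azim[i])
    dy <- sin(tmpl$elev[i]) * sin(tmpl$azim[i])
    dz <- cos(tmpl$elev[i])
    organs <- c(organs, list(tibble(
      role = "branch", type = "segment",
      x0 = 0, y0 = 0, z0 = z_att,
      x1 = len * dx, y1 = len * dy, z1 = z_att + len * dz,
      size = 7.5, class = "green"
    )))
    organs <- c(organs, list(tibble(
      role = "leaf", type = "disc",
      x0 = len * dx, y0 = len * dy, z0 = z_att + len * dz,
      x1 = NA_real_, y1 = NA_real_, z1 = NA_real_,
      size = pmax(8, tmpl$leaf_rel[i] * height), class = "green"
    )))
  }
  if (dev > 0.1) {  # rosette leaves on the stem
    for (j in seq_along(tmpl$stem_leaf_h)) {
      organs <- c(organs, list(tibble(
        role = "leaf", type = "disc",
        x0 = 6 * cos(tmpl$stem_leaf_az[j]), y0 = 6 * sin(tmpl$stem_leaf_az[j]),
        z0 = tmpl$stem_leaf_h[j] * height,
        x1 = NA_real_, y1 = NA_real_, z1 = NA_real_,
        size = pmax(8, 0.055 * height), class = "green"
      )))
    }
  }
  organs <- list_rbind(organs)

  if (is.null(senescence)) {
    exposure <- stress_exposure(treatment, day, ib_day, fl_day)
    senescence <- min(1, g$senescence_propensity * exposure)
  }
  check_scalar_number(senescence, "senescence", min = 0, max = 1)
  n_sen <- ceiling(senescence * nrow(organs))
  if (n_sen > 0) {
    # leaves senesce first, then branches; the stem last
    ord <- order(match(organs$role, c("leaf", "branch", "stem")),
                 -organs$z0)
    organs$class[ord[seq_len(n_sen)]] <- "non_green"
  }
  structure(
    list(organs = organs, height_mm = height, day = day,
         treatment = treatment, senescence_fraction = senescence),
    class = "plant_geometry"
  )
}

# Accumulated stress exposure in [0, 1]: days under stress / 60, summed
# over episodes.
stress_exposure <- function(treatment, day, ib_day, fl_day) {
  ep <- treatment_stress(treatment, ib_day, fl_day)
  if (!nrow(ep)) return(0)
  min(1, sum(pmax(0, day - ep$onset) * ep$severity) / 60)
}

#' @export
print.plant_geometry <- function(x, ...) {
  cat("<plant_geometry> day", x$day, x$treatment, "-",
      nrow(x$organs), "organs, height", round(x$height_mm, 1), "mm,",
      round(100 * x$senescence_fraction), "% senescent\n")
  invisible(x)
}
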