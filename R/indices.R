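# Drought tolerance indices: primary (yield-based) and secondary
# (trait-ratio) indices.

#' Primary drought indices from control and stress yields
#'
#' For each genotype with yield `yp` under control and `ys` under stress
#' (population control mean `yp_bar`):
#' \deqn{YI = Ys/Yp,\quad GMP = \sqrt{Yp\,Ys},\quad MP = (Yp+Ys)/2,}
#' \deqn{TOL = Yp - Ys,\quad STI = Yp\,Ys / \bar{Yp}^2.}
#' The alternative yield-index definition relative to the stress
#' population mean, `Ys / mean(Ys)`, is available via
#' `yi_mode = "ratio_to_stress_mean"`.
#'
#' Zero denominators give an `NA` for the affected index (flagged in the
#' `undefined` column) without invalidating the others; `ys = 0` is a
#' legitimate boundary (YI = GMP = STI = 0).
#'
#' @param pairs Tibble with numeric columns `yp` and `ys` (>= 0), one row
#'   per genotype, and optionally `genotype`.
#' @param yp_bar Population mean of `yp`; computed from `pairs` if omitted.
#' @param yi_mode `"ratio_to_own_control"` (default) or
#'   `"ratio_to_stress_mean"`.
#' @return `pairs` with columns `yi`, `gmp`, `mp`, `tol`, `sti`,
#'   `yi_mode`, `undefined` appended.
#' @examples
#' primary_indices(tibble::tibble(yp = 4, ys = 1), yp_bar = 2)
#' @export
primary_indices <- function(pairs, yp_bar = NULL,
                            yi_mode = c("ratio_to_own_control",
                                        "ratio_to_stress_mean")) {
  yi_mode <- match.arg(yi_mode)
  stopifnot(all(c("yp", "ys") %in% names(pairs)))
  if (any(pairs$yp < 0 | pairs$ys < 0)) stop_invalid("yields must be >= 0")
  yp <- pairs$yp; ys <- pairs$ys
  yp_bar <- yp_bar %||% mean(yp)
  ys_bar <- mean(ys)
  yi <- switch(yi_mode,
    ratio_to_own_control = ifelse(yp > 0, ys / yp, NA_real_),
    ratio_to_stress_mean = if (ys_bar > 0) ys / ys_bar else rep(NA_real_, length(ys))
  )
  sti <- if (yp_bar > 0) yp * ys / yp_bar^2 else rep(NA_real_, length(yp))
  out <- pairs
  out$yi <- yi
  out$gmp <- sqrt(yp * ys)
  out$mp <- (yp + ys) / 2
  out$tol <- yp - ys
  out$sti <- sti
  out$yi_mode <- yi_mode
  out$undefined <- is.na(yi) | is.na(sti)
  as_tibble(out)
}

#' Secondary (trait-ratio) drought index
#'
#' The ratio of a trait's mean under stress to the all-genotype control
#' mean: values below 1 indicate the trait was depressed by the stress,
#' values at or above 1 that it was unaffected (or improved). The
#' alternative rendering `1 - Xt/Xc_mean` is available via `form`.
#'
#' @param xt Trait mean under stress (vectorised).
#' @param xc_mean Trait mean of all genotypes under control (> 0).
#' @param form `"ratio"` (default) or `"one_minus_ratio"`.
#' @return Dimensionless index.
#' @export
secondary_index <- function(xt, xc_mean, form = c("ratio", "one_minus_ratio")) {
  form <- match.arg(form)
  check_scalar_number(xc_mean, "xc_mean")
  if (xc_mean <= 0) stop_invalid("`xc_mean` must be > 0")
  r <- xt / xc_mean
  if (form == "ratio") r else 1 - r
}

#' Per-treatment drought-index table
#'
#' From a trait table (one row per plant), computes per treatment the
#' secondary indices for `brn`, `bdn`, `ph`, `db`, `sn`, `esb` (each the
#' treatment mean of the trait over the all-genotype control mean; the
#' control column is identically 1) and the primary yield indices (from
#' `sy` per genotype, then averaged per treatment). The result feeds an
#' index heatmap of trait performance under each stress level.
#'
#' @param traits Tibble with `genotype`, `treatment`, `sy` and any of the
#'   secondary-trait columns.
#' @param control Control treatment label (must be present).
#' @param form Secondary-index form, see [secondary_index()].
#' @return A tibble of class `index_table`: `(treatment, index, value)`.
#' @export
index_table <- function(traits, control = "C", form = c("ratio", "one_minus_ratio")) {
  form <- match.arg(form)
  stopifnot(all(c("genotype", "treatment", "sy") %in% names(traits)))
  if (!control %in% traits$treatment) stop_invalid("control treatment missing")
  trts <- unique(traits$treatment)
  empty <- setdiff(trts, traits$treatment[!is.na(traits$sy)])
  if (length(empty)) {
    warn(paste("treatment(s) with no data dropped:", paste(empty, collapse = ", ")))
    trts <- setdiff(trts, empty)
  }
  sec_traits <- intersect(c("brn", "bdn", "ph", "db", "sn", "esb"), names(traits))
  ctrl <- traits |> filter(.data$treatment == control)
  sec <- purrr::map(trts, function(tr) {
    sub <- traits |> filter(.data$treatment == tr)
    tibble(
      treatment = tr,
      index = paste0(toupper(sec_traits), "I"),
      value = unname(vapply(sec_traits, function(v) {
        secondary_index(mean(sub[[v]], na.rm = TRUE),
                        mean(ctrl[[v]], na.rm = TRUE), form)
      }, numeric(1)))
    )
  }) |> list_rbind()
  ctrl_means <- ctrl |> group_by(.data$genotype) |>
    summarise(yp = mean(.data$sy), .groups = "drop")
  yp_bar <- mean(ctrl_means$yp)
  prim <- purrr::map(setdiff(trts, control), function(tr) {
    pairs <- traits |> filter(.data$treatment == tr) |>
      group_by(.data$genotype) |>
      summarise(ys = mean(.data$sy), .groups = "drop") |>
      left_join(ctrl_means, by = "genotype")
    idx <- primary_indices(pairs, yp_bar = yp_bar)
    tibble(treatment = tr,
           index = c("YI", "GMP", "MP", "TOL", "STI"),
           value = c(mean(idx$yi, na.rm = TRUE), mean(idx$gmp),
                     mean(idx$mp), mean(idx$tol), mean(idx$sti, na.rm = TRUE)))
  }) |> list_rbind()
  structure(bind_rows(sec, prim) |> arrange(.data$treatment, .data$index),
            class = c("index_table", class(tibble())))
}

#' Per-genotype drought indices
#'
#' Primary yield indices per genotype (control vs one stress treatment)
#' together with per-genotype secondary trait ratios (the genotype's
#' stress trait mean over the all-genotype control mean), suitable for
#' joining onto cluster assignments.
#'
#' @param traits Trait tibble as in [index_table()].
#' @param stress Stress treatment label.
#' @param control Control treatment label.
#' @return A tibble keyed by `genotype` with `yp`, `ys`, `yi`, `gmp`,
#'   `mp`, `tol`, `sti` and `<trait>_i` ratio columns.
#' @export
genotype_indices <- function(traits, stress = "IB50FL50", control = "C") {
  stopifnot(all(c("genotype", "treatment", "sy") %in% names(traits)))
  if (!control %in% traits$treatment) stop_invalid("control treatment missing")
  if (!stress %in% traits$treatment) stop_invalid("stress treatment missing")
  sec_traits <- intersect(c("brn", "bdn", "ph", "db", "sn", "esb"), names(traits))
  ctrl <- traits |> filter(.data$treatment == control)
  sub <- traits |> filter(.data$treatment == stress)
  pairs <- sub |> group_by(.data$genotype) |>
    summarise(ys = mean(.data$sy), .groups = "drop") |>
    left_join(ctrl |> group_by(.data$genotype) |>
                summarise(yp = mean(.data$sy), .groups = "drop"),
              by = "genotype")
  out <- primary_indices(pairs, yp_bar = mean(ctrl$sy, na.rm = TRUE))
  for (v in sec_traits) {
    xc <- mean(ctrl[[v]], na.rm = TRUE)
    gm <- sub |> group_by(.data$genotype) |>
      summarise(xt = mean(.data[[v]], na.rm = TRUE), .groups = "drop")
    out[[paste0(v, "_i")]] <- secondary_index(
      gm$xt[match(out$genotype, gm$genotype)], xc)
  }
  out
}
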