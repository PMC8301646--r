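# BLUE-adjusted genotype means for dynamic growth curves.

#' Best linear unbiased estimates of genotype means
#'
#' Fits the two-way additive fixed-effects model
#' `value = genotype + block + error` (both as classification factors) per
#' timepoint and returns the least-squares adjusted genotype means — the
#' marginal means averaged over blocks with equal weight (sum-to-zero
#' block constraint). In a balanced complete design these equal the raw
#' genotype means exactly; with missing cells they are the normal-equation
#' solution. Plotted over time they give the dynamic growth curve of each
#' genotype.
#'
#' @param df Tibble with columns `genotype`, `block`, `value`, and
#'   optionally `day` (fits are per day).
#' @return An object of class `blue_estimates`; [tidy()] gives
#'   `(genotype, day, estimate, se, df)`, [glance()] model metadata.
#' @export
blue_adjusted_means <- function(df) {
  stopifnot(all(c("genotype", "block", "value") %in% names(df)))
  if (dplyr::n_distinct(df$genotype) < 2 || dplyr::n_distinct(df$block) < 2) {
    stop_invalid("need >= 2 genotypes and >= 2 blocks")
  }
  if (!"day" %in% names(df)) df$day <- NA_real_
  check_connected_design(df)
  fits <- df |>
    group_by(.data$day) |>
    dplyr::group_map(function(sub, key) {
      sub$genotype <- factor(sub$genotype)
      sub$block <- factor(sub$block)
      fit <- lm(value ~ genotype + block, data = sub)
      em <- as.data.frame(emmeans::emmeans(fit, "genotype"))
      tibble(genotype = as.character(em$genotype), day = key$day,
             estimate = em$emmean, se = em$SE, df = em$df)
    })
  est <- list_rbind(fits)
  structure(
    list(estimates = est,
         n_obs = nrow(df),
         n_genotypes = dplyr::n_distinct(df$genotype),
         n_blocks = dplyr::n_distinct(df$block),
         n_days = dplyr::n_distinct(df$day)),
    class = "blue_estimates"
  )
}

# A genotype x block design must be connected for all adjusted means to be
# estimable; report the disconnected groups by name otherwise.
check_connected_design <- function(df) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("g:", df$genotype),
               to = paste0("b:", df$block)),
    directed = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    groups <- split(names(comp$membership), comp$membership)
    desc <- vapply(groups, function(v) paste(sort(v), collapse = ", "),
                   character(1))
    abort(paste0("disconnected genotype/block design; components:\n  ",
                 paste(desc, collapse = "\n  ")),
          class = "phenodrought_disconnected_design")
  }
  invisible(TRUE)
}

#' @method tidy blue_estimates
#' @export
tidy.blue_estimates <- function(x, ...) x$estimates

#' @method glance blue_estimates
#' @export
glance.blue_estimates <- function(x, ...) {
  tibble(n_obs = x$n_obs, n_genotypes = x$n_genotypes,
         n_blocks = x$n_blocks, n_days = x$n_days)
}

#' @export
print.blue_estimates <- function(x, ...) {
  cat("<blue_estimates>", x$n_genotypes, "genotypes x", x$n_blocks,
      "blocks,", x$n_days, "timepoint(s),", x$n_obs, "observations\n")
  print(x$estimates)
  invisible(x)
}

#' Growth curves from BLUE estimates
#'
#' @param object A [blue_adjusted_means()] fit with a `day` column.
#' @param ... Unused.
#' @return A ggplot: adjusted ESB mean vs day, one line per genotype.
#' @method autoplot blue_estimates
#' @export
autoplot.blue_estimates <- function(object, ...) {
  est <- object$estimates
  ggplot2::ggplot(est, ggplot2::aes(x = .data$day, y = .data$estimate,
                                    colour = .data$genotype)) +
    ggplot2::geom_line() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$estimate - .data$se,
                                      ymax = .data$estimate + .data$se,
                                      fill = .data$genotype),
                         alpha = 0.2, colour = NA) +
    ggplot2::labs(x = "days after sowing", y = "adjusted mean",
                  title = "Dynamic growth curves (BLUE-adjusted means)") +
    ggplot2::theme_minimal()
}
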