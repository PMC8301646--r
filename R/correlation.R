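#' Pairwise Pearson correlation matrix with significance
#'
#' Pairwise-complete Pearson correlations between all numeric columns,
#' with the two-sided t-test p-value and significance stars
#' (`***` p < 0.001, `**` p < 0.01, `*` p < 0.05). Zero-variance columns
#' yield an undefined (NA) correlation, flagged rather than propagated
#' as NaN.
#'
#' @param df A data frame; non-numeric columns are ignored.
#' @param min_n Minimum complete pairs per cell (default 3).
#' @return A tibble of class `pearson_matrix`: `(var1, var2, r, p, n,
#'   stars, undefined)`, symmetric with a unit diagonal.
#' @examples
#' pearson_matrix(data.frame(x = 1:10, y = 2 * (1:10) + 1))
#' @export
pearson_matrix <- function(df, min_n = 3) {
  num <- df[vapply(df, is.numeric, logical(1))]
  if (ncol(num) < 2) stop_invalid("need at least two numeric columns")
  vars <- names(num)
  grid <- tidyr::expand_grid(var1 = vars, var2 = vars)
  rows <- purrr::pmap(grid, function(var1, var2) {
    x <- num[[var1]]; y <- num[[var2]]
    ok <- complete.cases(x, y)
    n <- sum(ok)
    if (n < min_n) {
      return(tibble(var1 = var1, var2 = var2, r = NA_real_, p = NA_real_,
                    n = n, undefined = TRUE))
    }
    if (var1 == var2) {
      return(tibble(var1 = var1, var2 = var2, r = 1, p = 0, n = n,
                    undefined = FALSE))
    }
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(tibble(var1 = var1, var2 = var2, r = NA_real_, p = NA_real_,
                    n = n, undefined = TRUE))
    }
    r <- cor(x[ok], y[ok])
    p <- if (abs(r) >= 1) 0 else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      2 * pt(-abs(tt), df = n - 2)
    }
    tibble(var1 = var1, var2 = var2, r = r, p = p, n = n, undefined = FALSE)
  })
  out <- list_rbind(rows) |>
    mutate(stars = dplyr::case_when(
      is.na(p) ~ "",
      p < 0.001 ~ "***",
      p < 0.01 ~ "**",
      p < 0.05 ~ "*",
      TRUE ~ ""
    ))
  structure(out, class = c("pearson_matrix", class(tibble())))
}

#' Wide form of a correlation matrix
#'
#' @param x A [pearson_matrix()] result.
#' @return A numeric matrix of correlations.
#' @export
as_cor_matrix <- function(x) {
  wide <- tidyr::pivot_wider(x[, c("var1", "var2", "r")],
                             names_from = "var2", values_from = "r")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$var1
  m
}
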