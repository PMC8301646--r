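# Genotype classification into drought-tolerance clusters from (ESB, SY)
# under stress.

#' Simulate a tiered genotype performance population
#'
#' Draws per-genotype (ESB, SY) stress performance from `tiers` Gaussian
#' groups whose centres lie `separation` within-tier standard deviations
#' apart along the performance diagonal (tier 1 = highest biomass and
#' yield). This plants a known tolerance grouping in the feature plane for
#' cluster-recovery studies.
#'
#' @param n Number of genotypes.
#' @param tiers Number of planted tolerance tiers.
#' @param separation Distance between adjacent tier centres, in units of
#'   the within-tier standard deviation.
#' @param sd Within-tier standard deviation (feature units).
#' @param seed Integer seed.
#' @return A tibble `(genotype, esb, sy, tier)`.
#' @export
simulate_tiered_performance <- function(n = 200, tiers = 4, separation = 5,
                                        sd = 1, seed = 1) {
  check_scalar_number(n, "n", min = tiers)
  with_seed(seed, {
    centre <- separation * sd * (tiers:1)
    tier <- sort(rep_len(seq_len(tiers), n))
    tibble(
      genotype = sprintf("G%03d", seq_len(n)),
      esb = 30 + centre[tier] + rnorm(n, 0, sd),
      sy = 10 + centre[tier] + rnorm(n, 0, sd),
      tier = tier
    )
  })
}

# k-means++ seeding: spread initial centres with probability proportional
# to squared distance from the nearest centre chosen so far.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- x[sample.int(n, 1, prob = prob), ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
  }
  centers
}

#' Cluster genotypes by stress performance
#'
#' K-means clustering of genotypes on (ESB, SY) measured under drought
#' stress. Features are standardized to zero mean / unit variance first
#' (kilopixels and grams are incommensurate), then Lloyd's algorithm with
#' k-means++ initialization is run `restarts` times and the solution with
#' the lowest total within-cluster sum of squares kept. Cluster labels are
#' renamed by descending centroid performance (standardized ESB + SY, ties
#' by SY), so cluster 1 is always the high-biomass / high-yield group and
#' cluster `k` the lowest — the drought-tolerance reading of the clusters.
#'
#' @param df Tibble with columns `genotype` and the two feature columns.
#' @param k Number of clusters (default 4).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param restarts Independent restarts (default 25).
#' @param standardize Standardize features first (default TRUE).
#' @param features Feature column names, default `c("esb", "sy")`.
#' @return An object of class `tolerance_clusters`: `$assignments`
#'   (`genotype`, features, `cluster`), `$centers` (per cluster, both
#'   standardized and original units, sizes and within-cluster SS),
#'   `$tot_withinss`, `$k`.
#' @export
kmeans_cluster <- function(df, k = 4, seed, restarts = 25,
                           standardize = TRUE, features = c("esb", "sy")) {
  stopifnot(all(c("genotype", features) %in% names(df)))
  x <- as.matrix(df[, features])
  if (any(!is.finite(x))) stop_invalid("features must be finite")
  n <- nrow(x)
  check_scalar_number(k, "k", min = 1)
  if (n < k) stop_invalid("fewer points than clusters")
  n_distinct_pts <- nrow(unique(x))
  if (n_distinct_pts < k) {
    warn(sprintf("only %d distinct points; reducing k from %d", n_distinct_pts, k))
    k <- n_distinct_pts
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- if (standardize) scale(x, center = ctr, scale = scl) else x
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      init <- kmeanspp_init(xs, k)
      fit <- tryCatch(
        kmeans(xs, centers = init, iter.max = 100, algorithm = "Lloyd"),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
        best <- fit
      }
    }
  })
  if (is.null(best)) stop_invalid("k-means failed on every restart")
  # rename clusters by descending performance score
  score <- rowSums(best$centers)
  ord <- order(-score, -best$centers[, 2])
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  cluster <- relabel[best$cluster]
  centers_std <- best$centers[ord, , drop = FALSE]
  centers_orig <- sweep(sweep(centers_std, 2, scl, "*"), 2, ctr, "+")
  if (!standardize) centers_orig <- centers_std
  centers <- tibble(
    cluster = seq_len(k),
    size = as.integer(table(factor(cluster, levels = seq_len(k)))),
    withinss = best$withinss[ord]
  )
  for (j in seq_along(features)) {
    centers[[paste0(features[j], "_std")]] <- centers_std[, j]
    centers[[features[j]]] <- centers_orig[, j]
  }
  assignments <- df |> select("genotype", dplyr::all_of(features)) |>
    mutate(cluster = cluster)
  structure(
    list(assignments = assignments, centers = centers,
         tot_withinss = best$tot.withinss, k = k,
         standardize = standardize, features = features),
    class = "tolerance_clusters"
  )
}

#' @method tidy tolerance_clusters
#' @export
tidy.tolerance_clusters <- function(x, ...) x$centers

#' @method glance tolerance_clusters
#' @export
glance.tolerance_clusters <- function(x, ...) {
  tibble(k = x$k, n = nrow(x$assignments), tot_withinss = x$tot_withinss)
}

#' @export
print.tolerance_clusters <- function(x, ...) {
  cat("<tolerance_clusters> k =", x$k, "on", nrow(x$assignments),
      "genotypes; total within-SS", signif(x$tot_withinss, 4), "\n")
  print(x$centers)
  invisible(x)
}

#' Cluster scatter plot
#'
#' @param object A [kmeans_cluster()] result.
#' @param ... Unused.
#' @return A ggplot of the two features coloured by cluster, centroids
#'   marked.
#' @method autoplot tolerance_clusters
#' @export
autoplot.tolerance_clusters <- function(object, ...) {
  f <- object$features
  ggplot2::ggplot(object$assignments,
                  ggplot2::aes(x = .data[[f[1]]], y = .data[[f[2]]],
                               colour = factor(.data$cluster))) +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = object$centers, shape = 4, size = 4,
                        stroke = 2, show.legend = FALSE) +
    ggplot2::labs(colour = "cluster",
                  title = "Genotype clusters by stress performance") +
    ggplot2::theme_minimal()
}

#' Drought-tolerance report
#'
#' Joins cluster assignments with per-genotype drought indices and flags
#' cluster-1 genotypes (high biomass, high yield under stress) as
#' candidate drought-tolerant material.
#'
#' @param clusters A [kmeans_cluster()] result.
#' @param indices A [genotype_indices()] tibble covering the same
#'   genotypes.
#' @return A tibble: `genotype`, `cluster`, `candidate`, the primary
#'   indices and any secondary `_i` columns.
#' @export
tolerance_report <- function(clusters, indices) {
  stopifnot(inherits(clusters, "tolerance_clusters"))
  if (is.null(indices) || !nrow(indices)) stop_invalid("`indices` is empty")
  a <- clusters$assignments
  unmatched <- c(setdiff(a$genotype, indices$genotype),
                 setdiff(indices$genotype, a$genotype))
  if (length(unmatched)) {
    stop_invalid(paste("genotypes not shared by clusters and indices:",
                       paste(sort(unique(unmatched)), collapse = ", ")))
  }
  a |>
    left_join(indices, by = "genotype") |>
    mutate(candidate = .data$cluster == 1L) |>
    arrange(.data$cluster, dplyr::desc(.data$sy))
}
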