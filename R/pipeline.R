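# End-to-end pipeline: simulate -> segment -> traits -> indices -> cluster.

#' Pipeline configuration
#'
#' Everything the demo pipeline needs, seeded from one master seed. The
#' default demo (8 genotypes, control vs combined-stage stress, 3 blocks,
#' 64 x 64 px images at three imaging days) runs in well under a minute
#' and exercises every stage.
#'
#' @param n_genotypes Number of genotypes.
#' @param treatments Treatments simulated (first must include control `C`).
#' @param reps Blocks.
#' @param image_size Image side length in pixels.
#' @param px_per_mm Rendering scale.
#' @param imaging_days Days plants are imaged.
#' @param k Clusters.
#' @param seed Master seed; all stage seeds derive from it.
#' @param stress Stress treatment used for indices and clustering.
#' @param tiers Optional planted tolerance tiers (see
#'   [generate_genotypes()]).
#' @param noise_sd,salt_pepper Image noise settings.
#' @param write_images Also write per-view PNGs (requires `png`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_genotypes = 8, treatments = c("C", "IB50FL50"),
                            reps = 3, image_size = 64, px_per_mm = 0.25,
                            imaging_days = c(40, 80, 120), k = 4, seed = 1,
                            stress = "IB50FL50", tiers = NULL,
                            noise_sd = 8, salt_pepper = 0.001,
                            write_images = FALSE) {
  if (!"C" %in% treatments) stop_invalid("`treatments` must include control C")
  if (!stress %in% treatments) stop_invalid("`stress` must be a simulated treatment")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full drought-phenotyping pipeline
#'
#' Simulates a genotype panel, the replicated experiment, and multi-view
#' images per plant and imaging day; segments every view; compiles digital
#' traits; computes the drought-index table and per-genotype indices;
#' clusters genotypes on (ESB, SY) under stress; and writes all artifacts
#' as CSV plus a run log to `out_dir`. Fully reproducible: a fixed master
#' seed yields byte-identical CSV output.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with every intermediate result (`genotypes`,
#'   `experiment`, `traits`, `index_table`, `genotype_indices`,
#'   `clusters`, `report`) and `files`, the CSV paths written.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage `", name, "` failed: ", conditionMessage(e)),
            class = "phenodrought_pipeline_error")
    })
  }
  seeds <- derive_seeds(config$seed, 4)

  genotypes <- run_stage("simulate-genotypes",
    generate_genotypes(config$n_genotypes, seed = seeds[1], tiers = config$tiers))
  experiment <- run_stage("simulate-experiment",
    generate_experiment(genotypes, design = "splitplot", seed = seeds[2],
                        reps = config$reps) |>
      filter(.data$treatment %in% config$treatments))

  rcfg <- render_config(width = config$image_size, height = config$image_size,
                        px_per_mm = config$px_per_mm,
                        noise_sd = config$noise_sd,
                        salt_pepper = config$salt_pepper)
  scfg <- seg_config()
  plants <- tidyr::expand_grid(
    genotype = genotypes$genotype,
    treatment = config$treatments,
    block = paste0("B", seq_len(config$reps)),
    day = config$imaging_days
  )
  plant_seeds <- derive_seeds(seeds[3], nrow(plants))
  seg_rows <- run_stage("segment", {
    purrr::pmap(cbind(plants, .seed = plant_seeds),
      function(genotype, treatment, block, day, .seed) {
        g <- genotypes[genotypes$genotype == genotype, ]
        geom <- grow_plant(g, treatment, day, seed = .seed)
        iset <- render_views(geom, rcfg, seed = .seed + 1,
                             plant_id = paste(genotype, treatment, block, sep = "_"),
                             day = day)
        if (config$write_images) {
          write_image_set(iset, file.path(out_dir, "images"))
        }
        purrr::imap(iset$views, function(img, view) {
          tibble(plant_id = iset$plant_id, genotype = genotype,
                 treatment = treatment, block = block, day = day, view = view,
                 class_map = list(segment_plant(img, scfg)$class_map))
        }) |> list_rbind()
      }) |> list_rbind()
  })
  traits <- run_stage("traits", compile_digital_traits(seg_rows))
  traits <- traits |>
    left_join(distinct(seg_rows, .data$plant_id, .data$genotype,
                       .data$treatment, .data$block),
              by = "plant_id")

  # measured ESB at the last imaging day, per genotype under stress
  esb_stress <- traits |>
    filter(.data$treatment == config$stress, .data$day == max(config$imaging_days)) |>
    group_by(.data$genotype) |>
    summarise(esb = mean(.data$esb), .groups = "drop")
  sy_stress <- experiment |>
    filter(.data$treatment == config$stress) |>
    group_by(.data$genotype) |>
    summarise(sy = mean(.data$sy), .groups = "drop")
  cluster_input <- left_join(esb_stress, sy_stress, by = "genotype")

  idx_table <- run_stage("indices", index_table(experiment))
  g_idx <- run_stage("indices", genotype_indices(experiment, stress = config$stress))
  clusters <- run_stage("cluster",
    kmeans_cluster(cluster_input, k = config$k, seed = seeds[4]))
  report <- run_stage("report", tolerance_report(clusters, g_idx))

  files <- c(
    genotypes = write_pipeline_csv(genotypes, out_dir, "genotypes.csv"),
    experiment = write_pipeline_csv(experiment, out_dir, "experiment.csv"),
    traits = write_pipeline_csv(traits, out_dir, "traits.csv"),
    index_table = write_pipeline_csv(idx_table, out_dir, "index_table.csv"),
    genotype_indices = write_pipeline_csv(g_idx, out_dir, "genotype_indices.csv"),
    clusters = write_pipeline_csv(clusters$assignments, out_dir, "clusters.csv"),
    report = write_pipeline_csv(report, out_dir, "report.csv")
  )
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    "phenodrought pipeline run",
    paste0("master_seed: ", config$seed),
    paste0("stage_seeds: ", paste(seeds, collapse = ", ")),
    paste0("n_genotypes: ", config$n_genotypes),
    paste0("treatments: ", paste(config$treatments, collapse = ", ")),
    paste0("reps: ", config$reps),
    paste0("image_size: ", config$image_size),
    paste0("imaging_days: ", paste(config$imaging_days, collapse = ", ")),
    paste0("k: ", config$k),
    paste0("files: ", paste(basename(files), collapse = ", "))
  ), log_path)
  invisible(list(genotypes = genotypes, experiment = experiment,
                 traits = traits, index_table = idx_table,
                 genotype_indices = g_idx, clusters = clusters,
                 report = report, files = c(files, log = log_path)))
}

write_pipeline_csv <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  readr::write_csv(df, path)
  path
}
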