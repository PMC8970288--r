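#' Run configuration
#'
#' Bundles everything one end-to-end run needs: where the scene manifest
#' lives, the shell, typing, basket and sampler settings, and the output
#' directory. A single `seed` fans out to fixed per-stage offsets so stages
#' are reproducible in isolation.
#'
#' @param manifest path to a scene manifest (see [read_scene_manifest()]).
#' @param out_dir output directory.
#' @param shell a [shell_config()].
#' @param border_margin exclusion margin at the image border, um.
#' @param chat_threshold,nos_threshold intensity thresholds for automatic
#'   typing.
#' @param basket_n_min,basket_c_min,basket_bins basket detector settings.
#' @param chains,warmup,draws sampler settings.
#' @param seed master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(manifest, out_dir = "perishell_run",
                       shell = shell_config(), border_margin = 0.5,
                       chat_threshold = 100, nos_threshold = 100,
                       basket_n_min = 15, basket_c_min = 1 / 3, basket_bins = 64,
                       chains = 4, warmup = 1000, draws = 1000, seed = 1) {
  structure(list(manifest = manifest, out_dir = out_dir, shell = shell,
                 border_margin = border_margin,
                 chat_threshold = chat_threshold, nos_threshold = nos_threshold,
                 basket_n_min = basket_n_min, basket_c_min = basket_c_min,
                 basket_bins = basket_bins, chains = chains, warmup = warmup,
                 draws = draws, seed = seed),
            class = "run_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Quantify scenes: typing, exclusions, shell densities, baskets
#'
#' The deterministic first half of the pipeline, from loaded scenes to the
#' density table, basket calls and association tests.
#'
#' @param scenes list of [ganglion_scene()] objects.
#' @param labels list of label tibbles parallel to `scenes`.
#' @param failed_cells list of character vectors of mesh-repair failures per
#'   scene (from [load_scene()]).
#' @param config a [run_config()] (manifest may be `NULL` when scenes are
#'   passed directly).
#' @return A list: `typed` (typed cells with morphometry, all scenes),
#'   `densities`, `basket_calls`, `basket_tables`, `association` (chi-square
#'   per marker), `counts` (bookkeeping tibble).
#' @export
quantify_scenes <- function(scenes, labels, config = run_config(NULL),
                            failed_cells = NULL) {
  stopifnot(length(scenes) == length(labels))
  typed_all <- list()
  dens_all <- list()
  calls_all <- list()
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    typed <- classify_cells(labels[[i]],
                            chat_threshold = config$chat_threshold,
                            nos_threshold = config$nos_threshold)
    typed <- apply_exclusions(typed, sc, border_margin = config$border_margin,
                              failed_cells = if (is.null(failed_cells)) character()
                                             else failed_cells[[i]])
    morpho <- morphometry(sc$cells)
    typed <- dplyr::left_join(typed, morpho, by = "cell_id")
    typed$subject_id <- sc$subject_id
    typed$ganglion_id <- sc$ganglion_id

    att <- attribute_spots(sc$cells, sc$spots, config$shell)
    dens <- compute_densities(sc, typed, config$shell, attributed = att)
    calls <- detect_baskets(att, sc$cells, typed,
                            n_min = config$basket_n_min,
                            c_min = config$basket_c_min,
                            bins = config$basket_bins)
    # basket analysis covers included cells only
    calls <- calls[calls$cell_id %in% typed$cell_id[typed$included], ]

    typed_all[[i]] <- typed
    dens_all[[i]] <- dens
    calls_all[[i]] <- calls
    stage_log("quantify", "scene %s/%s: %d cells (%d included), %d spots",
              sc$subject_id, sc$ganglion_id, length(sc$cells),
              sum(typed$included), nrow(sc$spots))
  }
  typed <- dplyr::bind_rows(typed_all)
  densities <- dplyr::bind_rows(dens_all)
  calls <- dplyr::bind_rows(calls_all)
  if (nrow(calls)) {
    bs <- basket_summary(calls, typed)
    association <- purrr::map_dfr(varicosity_markers, function(mk) {
      tab <- bs$tables[[mk]]
      res <- tryCatch(chisq_association(tab[, colSums(tab) > 0, drop = FALSE]),
                      error = function(e) tibble::tibble(chi2 = NA_real_,
                                                         df = NA_real_,
                                                         p_value = NA_real_))
      dplyr::mutate(res, marker = mk, .before = 1)
    })
  } else {
    bs <- list(summary = tibble::tibble(), tables = list())
    association <- tibble::tibble(marker = character(), chi2 = numeric(),
                                  df = numeric(), p_value = numeric())
  }
  counts <- tibble::tibble(
    reconstructed = nrow(typed) + length(unlist(failed_cells)),
    repair_failed = length(unlist(failed_cells)),
    excluded = sum(!typed$included),
    analysed = sum(typed$included))
  list(typed = typed, densities = densities, basket_calls = calls,
       basket_summary = bs$summary, basket_tables = bs$tables,
       association = association, counts = counts)
}

#' Run the full pipeline
#'
#' Ingests the scenes listed in the config's manifest, applies QC/typing,
#' computes shell densities and basket calls with the chi-square association
#' test, fits the negative-binomial mixed model, and writes all intermediate
#' tables plus a JSON report into the output directory. Deterministic given
#' the config seed.
#'
#' @param config a [run_config()].
#' @param scenes,labels,failed_cells optionally pass materialised scenes
#'   directly instead of reading the manifest.
#' @return A `run_report` list (invisibly written to
#'   `out_dir/report.json`): stage counts, density table, basket results,
#'   posterior summaries and the six density-ratio results.
#' @export
run_pipeline <- function(config, scenes = NULL, labels = NULL,
                         failed_cells = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(scenes)) {
    entries <- read_scene_manifest(config$manifest)
    base_dir <- dirname(config$manifest)
    loaded <- lapply(entries, load_scene, base_dir = base_dir)
    scenes <- lapply(loaded, `[[`, "scene")
    labels <- lapply(loaded, `[[`, "labels")
    failed_cells <- lapply(loaded, `[[`, "failed_cells")
    stage_log("ingest", "%d scenes loaded", length(scenes))
  }
  q <- quantify_scenes(scenes, labels, config, failed_cells)
  if (q$counts$analysed == 0)
    rlang::abort("no cells for analysis", class = "perishell_pipeline_error")

  rows <- build_model_input(q$densities, q$typed)
  stage_log("model", "%d rows (%d cells) entering the NB mixed model",
            nrow(rows), length(unique(rows$cell_id)))
  fit <- fit_nb_glmm(rows, chains = config$chains, warmup = config$warmup,
                     draws = config$draws, seed = config$seed + 1000L)
  dens_post <- mean_densities(fit)
  ratios <- density_ratios(fit)

  anova_sa <- tryCatch(morphometric_anova(q$typed, "surface_area_um2"),
                       error = function(e) NULL)
  anova_vol <- tryCatch(morphometric_anova(q$typed, "volume_um3"),
                        error = function(e) NULL)

  report <- list(
    config = config[setdiff(names(config), "shell")],
    shell = unclass(config$shell),
    counts = q$counts,
    type_proportions = type_proportions(q$typed),
    densities = q$densities,
    basket_summary = q$basket_summary,
    association = q$association,
    posterior_densities = dens_post,
    density_ratios = ratios,
    model_glance = glance.nb_glmm(fit),
    anova_surface_area = anova_sa,
    anova_volume = anova_vol,
    version = as.character(utils::packageVersion("perishell")))
  class(report) <- "run_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_density_table(q$densities, file.path(config$out_dir, "densities.csv"),
                        overwrite = TRUE)
    utils::write.csv(q$basket_calls, file.path(config$out_dir, "basket_calls.csv"),
                     row.names = FALSE)
    utils::write.csv(rows, file.path(config$out_dir, "model_input.csv"),
                     row.names = FALSE)
    utils::write.csv(tidy.nb_glmm(fit), file.path(config$out_dir, "posterior.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      report[c("counts", "type_proportions", "association",
               "posterior_densities", "density_ratios", "model_glance",
               "shell", "version")],
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
    stage_log("report", "written to %s", config$out_dir)
  }
  report$fit <- fit
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Perisomatic shell density pipeline report\n")
  cat(sprintf("  cells: %d reconstructed, %d excluded, %d analysed\n",
              x$counts$reconstructed, x$counts$excluded, x$counts$analysed))
  cat("  posterior mean densities (per 1,000 um^3):\n")
  print(x$posterior_densities)
  cat("  density ratios:\n")
  print(x$density_ratios)
  invisible(x)
}

#' Simulate scenes to disk
#'
#' Wraps [generate_ganglia()] and writes the scenes, label tables, manifest
#' and truth JSON into a directory, ready to be consumed by [run_pipeline()].
#'
#' @param params a [generator_params()].
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param overwrite overwrite existing files.
#' @return The manifest path, invisibly; the truth manifest is written next to
#'   it as `truth.json`.
#' @export
simulate_scenes <- function(params = generator_params(), out_dir, seed = 1,
                            overwrite = FALSE) {
  gen <- generate_ganglia(params, seed = seed)
  man <- write_scene_set(gen$scenes, gen$labels, out_dir, overwrite = overwrite)
  jsonlite::write_json(
    list(seed = seed,
         params = lapply(unclass(params), function(x) if (is.matrix(x)) as.data.frame(x) else x),
         cells = gen$truth),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_log("simulate", "%d scenes written to %s", length(gen$scenes), out_dir)
  invisible(man)
}
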