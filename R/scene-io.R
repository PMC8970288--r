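#' Read and write varicosity spot tables
#'
#' Spot tables are comma-separated UTF-8 CSV with a required header
#' `marker,x_um,y_um,z_um`; coordinates in micrometres. Unknown marker strings,
#' non-numeric coordinates and missing columns each raise a distinct
#' `perishell_parse_error` naming the offending row and field.
#'
#' @param path CSV file path.
#' @return `read_spots()` returns a tibble with columns `marker`, `x_um`,
#'   `y_um`, `z_um` (row order preserved); split into per-marker sets with
#'   [spot_sets()].
#' @export
read_spots <- function(path) {
  if (!file.exists(path))
    rlang::abort(sprintf("spot file not found: %s", path), class = "perishell_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0) {
    miss <- setdiff(c("marker", "x_um", "y_um", "z_um"), names(df))
    if (length(miss))
      rlang::abort(sprintf("spot table is missing column(s): %s",
                           paste(miss, collapse = ", ")),
                   class = "perishell_parse_error")
    return(tibble::tibble(marker = character(), x_um = numeric(),
                          y_um = numeric(), z_um = numeric()))
  }
  validate_spots(df)
}

#' @rdname read_spots
#' @param spots tibble with columns `marker`, `x_um`, `y_um`, `z_um`.
#' @param overwrite overwrite an existing file (default `FALSE`).
#' @export
write_spots <- function(spots, path, overwrite = FALSE) {
  spots <- validate_spots(spots)
  check_overwrite(path, overwrite)
  utils::write.csv(spots, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_overwrite <- function(path, overwrite) {
  if (file.exists(path) && !overwrite)
    rlang::abort(sprintf("file exists: %s (use overwrite = TRUE)", path),
                 class = "perishell_io_error")
}

#' Read and write cell label/QC tables
#'
#' One row per cell: manual ChAT/NOS calls, the exclusion flag with its
#' mandatory reason, and optional manual basket calls per marker. Columns
#' `cell_id,chat,nos,excluded,exclusion_reason,basket_th,basket_enk`; boolean
#' columns accept TRUE/FALSE; `basket_*` may be empty (NA) meaning no manual
#' call.
#'
#' @param path CSV file path.
#' @return A tibble with the columns above, logicals parsed.
#' @export
read_cell_labels <- function(path) {
  if (!file.exists(path))
    rlang::abort(sprintf("label file not found: %s", path), class = "perishell_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cell_labels(df)
}

validate_cell_labels <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("cell_id", "chat", "nos", "excluded", "exclusion_reason")
  miss <- setdiff(need, names(df))
  if (length(miss))
    rlang::abort(sprintf("label table is missing column(s): %s", paste(miss, collapse = ", ")),
                 class = "perishell_parse_error")
  df$cell_id <- as.character(df$cell_id)
  if (anyDuplicated(df$cell_id))
    rlang::abort("duplicate cell_id in label table", class = "perishell_parse_error")
  for (col in c("chat", "nos", "excluded")) df[[col]] <- as.logical(df[[col]])
  if (!"basket_th" %in% names(df)) df$basket_th <- NA
  if (!"basket_enk" %in% names(df)) df$basket_enk <- NA
  df$basket_th <- as.logical(df$basket_th)
  df$basket_enk <- as.logical(df$basket_enk)
  df$exclusion_reason <- as.character(df$exclusion_reason)
  df$exclusion_reason[is.na(df$exclusion_reason)] <- ""
  bad <- which(df$excluded %in% TRUE & !nzchar(df$exclusion_reason))
  if (length(bad))
    rlang::abort(sprintf("cell '%s': excluded without an exclusion_reason", df$cell_id[bad[1]]),
                 class = "perishell_parse_error")
  df[c("cell_id", "chat", "nos", "excluded", "exclusion_reason", "basket_th", "basket_enk")]
}

#' @rdname read_cell_labels
#' @param labels tibble of cell labels.
#' @param overwrite overwrite an existing file (default `FALSE`).
#' @export
write_cell_labels <- function(labels, path, overwrite = FALSE) {
  labels <- validate_cell_labels(labels)
  check_overwrite(path, overwrite)
  utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write per-cell density tables
#'
#' The canonical result table of the shell-density stage: one row per included
#' cell x marker, with the shell count, shell volume and density per 1,000
#' cubic micrometres. Round-trips exactly through CSV.
#'
#' @param path CSV file path.
#' @return A tibble with columns `subject_id`, `ganglion_id`, `cell_id`,
#'   `cell_type`, `marker`, `count`, `shell_volume_um3`, `density_per_1000um3`.
#' @export
read_density_table <- function(path) {
  if (!file.exists(path))
    rlang::abort(sprintf("density table not found: %s", path), class = "perishell_io_error")
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("subject_id", "ganglion_id", "cell_id", "cell_type", "marker",
            "count", "shell_volume_um3", "density_per_1000um3")
  miss <- setdiff(need, names(df))
  if (length(miss))
    rlang::abort(sprintf("density table is missing column(s): %s",
                         paste(miss, collapse = ", ")),
                 class = "perishell_parse_error")
  for (col in c("subject_id", "ganglion_id", "cell_id", "cell_type", "marker"))
    df[[col]] <- as.character(df[[col]])
  df$count <- as.integer(df$count)
  df[need]
}

#' @rdname read_density_table
#' @param records density tibble as produced by [compute_densities()].
#' @param overwrite overwrite an existing file (default `FALSE`).
#' @export
write_density_table <- function(records, path, overwrite = FALSE) {
  need <- c("subject_id", "ganglion_id", "cell_id", "cell_type", "marker",
            "count", "shell_volume_um3", "density_per_1000um3")
  miss <- setdiff(need, names(records))
  if (length(miss))
    rlang::abort(sprintf("density records missing column(s): %s",
                         paste(miss, collapse = ", ")),
                 class = "perishell_parse_error")
  check_overwrite(path, overwrite)
  utils::write.csv(records[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Scene manifests
#'
#' A run is described by a YAML manifest listing, per scene, the subject and
#' ganglion ids, mesh file paths, the spot and label CSV paths, the imaged
#' bounding box and the voxel size. `read_scene_manifest()` parses and checks
#' the manifest; `load_scene()` materialises one entry into a
#' [ganglion_scene()] plus its label table. Cells whose mesh fails watertight
#' repair are dropped with a warning and recorded in the returned
#' `failed_cells` field, mirroring the exclusion of imperfect reconstructions.
#'
#' @param path YAML manifest path.
#' @return `read_scene_manifest()`: a list of scene entries.
#' @export
read_scene_manifest <- function(path) {
  if (!file.exists(path))
    rlang::abort(sprintf("manifest not found: %s", path), class = "perishell_io_error")
  man <- yaml::read_yaml(path)
  if (is.null(man$scenes) || !length(man$scenes))
    rlang::abort("manifest lists no scenes", class = "perishell_parse_error")
  man$scenes
}

#' @rdname read_scene_manifest
#' @param entry one element of the manifest `scenes` list.
#' @param base_dir directory that relative paths in the manifest resolve
#'   against.
#' @return `load_scene()`: a list with elements `scene` ([ganglion_scene()]),
#'   `labels` (tibble) and `failed_cells` (character).
#' @export
load_scene <- function(entry, base_dir = ".") {
  rp <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  failed <- character()
  cells <- list()
  for (mp in entry$meshes) {
    m <- tryCatch(read_mesh(rp(mp)), perishell_mesh_error = function(e) e)
    if (inherits(m, "error")) {
      warning(sprintf("scene %s/%s: dropping cell from '%s': %s",
                      entry$subject_id, entry$ganglion_id, mp, conditionMessage(m)),
              call. = FALSE)
      failed <- c(failed, sub("\\.[^.]+$", "", basename(mp)))
    } else {
      cells[[length(cells) + 1L]] <- m
    }
  }
  spots <- read_spots(rp(entry$spots))
  labels <- read_cell_labels(rp(entry$labels))
  bbox <- if (!is.null(entry$bbox)) matrix(unlist(entry$bbox), nrow = 2, byrow = TRUE)
  voxel <- if (!is.null(entry$voxel_size)) as.numeric(unlist(entry$voxel_size)) else c(0.5, 0.5, 1)
  scene <- ganglion_scene(entry$subject_id, entry$ganglion_id, cells, spots,
                          bbox = bbox, voxel_size = voxel)
  list(scene = scene, labels = labels, failed_cells = failed)
}

#' @rdname read_scene_manifest
#' @param scenes list of [ganglion_scene()] objects.
#' @param labels list of label tibbles parallel to `scenes`.
#' @param dir output directory (created if missing).
#' @return `write_scene_set()`: the manifest path, invisibly.
#' @export
write_scene_set <- function(scenes, labels, dir, overwrite = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- vector("list", length(scenes))
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    tag <- sprintf("%s_%s", sc$subject_id, sc$ganglion_id)
    sdir <- file.path(dir, tag)
    dir.create(sdir, showWarnings = FALSE)
    mesh_paths <- character(length(sc$cells))
    for (j in seq_along(sc$cells)) {
      mesh_paths[j] <- file.path(tag, sprintf("%s.ply", names(sc$cells)[j]))
      write_mesh(sc$cells[[j]], file.path(dir, mesh_paths[j]), overwrite = overwrite)
    }
    spot_path <- file.path(tag, "spots.csv")
    label_path <- file.path(tag, "labels.csv")
    write_spots(sc$spots, file.path(dir, spot_path), overwrite = overwrite)
    write_cell_labels(labels[[i]], file.path(dir, label_path), overwrite = overwrite)
    entries[[i]] <- list(subject_id = sc$subject_id, ganglion_id = sc$ganglion_id,
                         meshes = as.list(mesh_paths), spots = spot_path,
                         labels = label_path,
                         bbox = list(as.numeric(sc$bbox[1, ]), as.numeric(sc$bbox[2, ])),
                         voxel_size = as.numeric(sc$voxel_size))
  }
  man_path <- file.path(dir, "manifest.yaml")
  if (file.exists(man_path) && !overwrite)
    rlang::abort(sprintf("file exists: %s (use overwrite = TRUE)", man_path),
                 class = "perishell_io_error")
  yaml::write_yaml(list(scenes = entries), man_path)
  invisible(man_path)
}
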