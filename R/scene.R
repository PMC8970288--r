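#' Markers and cell types
#'
#' The two varicosity markers quantified by the pipeline (tyrosine hydroxylase
#' and enkephalin) and the four ChAT/NOS immunoreactivity classes, in their
#' canonical order. The first three cell types are the ones entering the
#' density model; ChAT-/NOS- cells are kept in morphometric and basket outputs
#' only.
#'
#' @export
varicosity_markers <- c("TH", "ENK")

#' @rdname varicosity_markers
#' @export
cell_types <- c("ChAT+/NOS-", "ChAT-/NOS+", "ChAT+/NOS+", "ChAT-/NOS-")

#' @rdname varicosity_markers
#' @export
modelled_cell_types <- c("ChAT+/NOS-", "ChAT-/NOS+", "ChAT+/NOS+")

#' Assemble a ganglion scene
#'
#' A `ganglion_scene` bundles everything imaged in one ganglion: the cell-body
#' meshes, the marker-tagged varicosity point tables, the axis-aligned imaged
#' bounding box and the voxel size of the source stack (dz defaults to the
#' 1 um z-step of the acquisitions).
#'
#' @param subject_id,ganglion_id identifiers; ganglia are nested in subjects.
#' @param cells list of [surface_mesh()] objects with unique `cell_id`s.
#' @param spots tibble with columns `marker`, `x_um`, `y_um`, `z_um`.
#' @param bbox 2 x 3 matrix, rows = (lo, hi), columns = (x, y, z), um. Computed
#'   from the cell meshes (padded by 2 um) when omitted.
#' @param voxel_size length-3 positive numeric (dx, dy, dz) in um.
#' @return An object of class `ganglion_scene`.
#' @export
ganglion_scene <- function(subject_id, ganglion_id, cells, spots,
                           bbox = NULL, voxel_size = c(0.5, 0.5, 1.0)) {
  ids <- vapply(cells, function(m) as.character(attr(m, "cell_id")), character(1))
  if (anyDuplicated(ids))
    rlang::abort(sprintf("duplicate cell_id in scene: %s",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                 class = "perishell_scene_error")
  names(cells) <- ids
  spots <- validate_spots(spots)
  if (is.null(bbox)) {
    allv <- do.call(rbind, lapply(cells, function(m) m$vertices))
    bbox <- rbind(apply(allv, 2, min) - 2, apply(allv, 2, max) + 2)
  }
  bbox <- as.matrix(bbox)
  stopifnot(nrow(bbox) == 2, ncol(bbox) == 3, all(bbox[1, ] < bbox[2, ]))
  if (any(voxel_size <= 0))
    rlang::abort("voxel_size components must be > 0", class = "perishell_scene_error")
  for (m in cells) {
    V <- m$vertices
    if (any(sweep(V, 2, bbox[1, ], "<")) || any(sweep(V, 2, bbox[2, ], ">")))
      rlang::abort(sprintf("cell '%s' has vertices outside the scene bbox",
                           attr(m, "cell_id")), class = "perishell_scene_error")
  }
  structure(list(subject_id = as.character(subject_id),
                 ganglion_id = as.character(ganglion_id),
                 cells = cells, spots = spots, bbox = bbox,
                 voxel_size = as.numeric(voxel_size)),
            class = "ganglion_scene")
}

#' @export
print.ganglion_scene <- function(x, ...) {
  cat(sprintf("<ganglion_scene %s/%s: %d cells, %d spots (%s)>\n",
              x$subject_id, x$ganglion_id, length(x$cells), nrow(x$spots),
              paste(sprintf("%s: %d", varicosity_markers,
                            vapply(varicosity_markers,
                                   function(m) sum(x$spots$marker == m), integer(1))),
                    collapse = ", ")))
  invisible(x)
}

validate_spots <- function(spots) {
  spots <- tibble::as_tibble(spots)
  need <- c("marker", "x_um", "y_um", "z_um")
  miss <- setdiff(need, names(spots))
  if (length(miss))
    rlang::abort(sprintf("spot table is missing column(s): %s", paste(miss, collapse = ", ")),
                 class = "perishell_parse_error")
  bad <- which(!spots$marker %in% varicosity_markers)
  if (length(bad))
    rlang::abort(sprintf("row %d: unknown marker '%s' (expected %s)",
                         bad[1], spots$marker[bad[1]],
                         paste(varicosity_markers, collapse = "/")),
                 class = "perishell_parse_error")
  for (col in c("x_um", "y_um", "z_um")) {
    v <- spots[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        rlang::abort(sprintf("row %d: non-numeric coordinate in column '%s'", bad[1], col),
                     class = "perishell_parse_error")
      spots[[col]] <- vn
    }
    if (any(!is.finite(spots[[col]])))
      rlang::abort(sprintf("row %d: non-finite coordinate in column '%s'",
                           which(!is.finite(spots[[col]]))[1], col),
                   class = "perishell_parse_error")
  }
  spots[need]
}

spot_matrix <- function(spots) {
  unname(as.matrix(spots[, c("x_um", "y_um", "z_um")]))
}

#' Split a spot table into per-marker sets
#'
#' @param spots a validated spot tibble.
#' @return A named list of tibbles, one per marker present, row order preserved.
#' @export
spot_sets <- function(spots) {
  spots <- validate_spots(spots)
  split(spots, factor(spots$marker, levels = varicosity_markers), drop = TRUE)
}
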