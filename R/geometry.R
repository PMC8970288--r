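#' Shell configuration
#'
#' Parameters of the perisomatic shell: the region within `half_width` um of
#' the cell surface on either side (default 1 um, i.e. the 2 um thick shell
#' running from 1 um inside the membrane to 1 um outside). Shell volumes are
#' measured by voxel-centre counting at `voxel_pitch` um; shells are not
#' clipped to the imaged bounding box unless `clip_to_bbox` is set (intended
#' for sensitivity analysis only).
#'
#' @param half_width shell half-width t in um (> 0).
#' @param voxel_pitch voxelization pitch in um; must be at most `half_width/2`.
#' @param clip_to_bbox clip shell volumes to the scene bounding box.
#' @return A `shell_config` list.
#' @export
shell_config <- function(half_width = 1.0, voxel_pitch = 0.25, clip_to_bbox = FALSE) {
  if (!is.numeric(half_width) || half_width <= 0)
    rlang::abort("half_width must be > 0", class = "perishell_config_error")
  if (!is.numeric(voxel_pitch) || voxel_pitch <= 0 || voxel_pitch > half_width / 2)
    rlang::abort("voxel_pitch must satisfy 0 < pitch <= half_width/2",
                 class = "perishell_config_error")
  structure(list(half_width = half_width, voxel_pitch = voxel_pitch,
                 clip_to_bbox = isTRUE(clip_to_bbox)),
            class = "shell_config")
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) return(spot_matrix(validate_spots(points)))
  p <- as.matrix(points)
  if (is.null(dim(p)) || length(p) == 3) p <- matrix(as.numeric(p), ncol = 3)
  storage.mode(p) <- "double"
  stopifnot(ncol(p) == 3, all(is.finite(p)))
  p
}

#' Signed distance from points to a cell surface
#'
#' Negative inside the cell, positive outside, zero on the surface; the
#' magnitude is the minimum Euclidean distance to any surface triangle.
#' Requires a watertight mesh (guaranteed by [surface_mesh()]).
#'
#' @param mesh a [surface_mesh()].
#' @param points an n x 3 matrix, length-3 vector, or spot tibble.
#' @return Numeric vector of signed distances in um.
#' @export
signed_distance <- function(mesh, points) {
  stopifnot(inherits(mesh, "surface_mesh"))
  P <- as_point_matrix(points)
  d <- cpp_min_dist(mesh$vertices, mesh$faces - 1L, P)
  # points within numerical tolerance of the surface count as on it (sign +);
  # the parity ray test is ill-posed when the ray origin lies on a triangle
  inside <- rep(FALSE, nrow(P))
  off <- d > 1e-4
  if (any(off))
    inside[off] <- cpp_inside(mesh$vertices, mesh$faces - 1L, P[off, , drop = FALSE])
  ifelse(inside, -d, d)
}

#' Shell membership
#'
#' `TRUE` iff the point lies within `cfg$half_width` of the cell surface
#' (inside or outside); the boundary is inclusive.
#'
#' @inheritParams signed_distance
#' @param cfg a [shell_config()].
#' @return Logical vector.
#' @export
in_shell <- function(mesh, points, cfg = shell_config()) {
  stopifnot(inherits(mesh, "surface_mesh"))
  P <- as_point_matrix(points)
  cpp_in_shell(mesh$vertices, mesh$faces - 1L, P, cfg$half_width)
}

#' Shell volume
#'
#' Volume of the region within `half_width` um of the cell surface, estimated
#' by counting voxel centres on a grid of pitch `cfg$voxel_pitch` covering the
#' mesh bounding box padded by the half-width. Converges to the exact shell
#' volume as the pitch shrinks. With `cfg$clip_to_bbox`, voxels outside `bbox`
#' are not counted.
#'
#' @inheritParams in_shell
#' @param bbox optional 2 x 3 scene bounding box; required when
#'   `cfg$clip_to_bbox` is `TRUE`.
#' @return Scalar volume in um^3.
#' @export
shell_volume <- function(mesh, cfg = shell_config(), bbox = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  clip <- cfg$clip_to_bbox
  if (clip && is.null(bbox))
    rlang::abort("clip_to_bbox requires a bbox", class = "perishell_config_error")
  lo <- if (clip) as.numeric(bbox[1, ]) else numeric(3)
  hi <- if (clip) as.numeric(bbox[2, ]) else numeric(3)
  cpp_shell_volume(mesh$vertices, mesh$faces - 1L, cfg$half_width,
                   cfg$voxel_pitch, clip, lo, hi)
}

#' Sample points uniformly inside a cell's shell
#'
#' Rejection sampling from the uniform distribution on the +/- `half_width`
#' shell of a mesh, driven by the R RNG (so `set.seed()` governs
#' reproducibility).
#'
#' @inheritParams in_shell
#' @param n number of points.
#' @return An n x 3 matrix of coordinates in um.
#' @export
sample_shell_points <- function(mesh, n, cfg = shell_config()) {
  stopifnot(inherits(mesh, "surface_mesh"), n >= 0)
  if (n == 0) return(matrix(numeric(0), 0, 3))
  cpp_sample_in_shell(mesh$vertices, mesh$faces - 1L, cfg$half_width,
                      as.integer(n), 10000L)
}

#' Attribute spots to their nearest cell
#'
#' Each varicosity spot is attributed to at most one cell: the cell whose
#' surface it is closest to (by unsigned distance), and only if that minimum
#' distance is within the shell half-width. Exact distance ties are broken
#' deterministically in favour of the lexicographically smallest `cell_id`.
#' Spots farther than the half-width from every cell remain unattributed
#' (`cell_id` `NA`).
#'
#' @param cells list of [surface_mesh()] objects with unique ids.
#' @param spots spot tibble (`marker`, `x_um`, `y_um`, `z_um`).
#' @param cfg a [shell_config()].
#' @return A tibble: one row per spot with `marker`, coordinates, the winning
#'   `cell_id` (or `NA`) and `distance_um` to that cell's surface.
#' @export
attribute_spots <- function(cells, spots, cfg = shell_config()) {
  if (!length(cells))
    rlang::abort("attribute_spots needs at least one cell", class = "perishell_scene_error")
  spots <- validate_spots(spots)
  ids <- vapply(cells, function(m) as.character(attr(m, "cell_id")), character(1))
  if (anyDuplicated(ids))
    rlang::abort("duplicate cell_id among cells", class = "perishell_scene_error")
  P <- spot_matrix(spots)
  n <- nrow(P)
  best <- rep(Inf, n)
  winner <- rep(NA_character_, n)
  # lexicographic order makes the tie-break deterministic: earlier cells win
  # ties because later candidates must be strictly closer
  ord <- order(ids)
  for (i in ord) {
    m <- cells[[i]]
    d <- cpp_min_dist_capped(m$vertices, m$faces - 1L, P, cfg$half_width)
    take <- d < best
    best[take] <- d[take]
    winner[take] <- ids[i]
  }
  tibble::tibble(marker = spots$marker, x_um = spots$x_um, y_um = spots$y_um,
                 z_um = spots$z_um, cell_id = winner,
                 distance_um = ifelse(is.finite(best), best, NA_real_))
}

#' Per-cell shell densities
#'
#' The core quantification: for every included cell and every marker, the
#' number of spots uniquely attributed to that cell's +/- `half_width` shell,
#' the shell volume, and the density per 1,000 um^3. Attribution runs over all
#' cells in the scene (included or not) so that spots closest to an excluded
#' cell are dropped rather than reassigned to the runner-up; excluded cells
#' then contribute no output row.
#'
#' @param scene a [ganglion_scene()].
#' @param labels label tibble (see [read_cell_labels()]) or a typed-cell
#'   tibble from [apply_exclusions()]; must cover every cell in the scene.
#'   Cells are treated as included unless flagged `excluded`/`!included`.
#' @param cfg a [shell_config()].
#' @param attributed optional precomputed attribution table from
#'   [attribute_spots()] run on this scene's cells and spots (it is computed
#'   here when omitted).
#' @return A density tibble (see [read_density_table()] for columns), one row
#'   per included cell x marker, zero counts included.
#' @export
compute_densities <- function(scene, labels, cfg = shell_config(),
                              attributed = NULL) {
  stopifnot(inherits(scene, "ganglion_scene"))
  labels <- tibble::as_tibble(labels)
  ids <- names(scene$cells)
  miss <- setdiff(ids, labels$cell_id)
  if (length(miss))
    rlang::abort(sprintf("labels missing for cell(s): %s", paste(miss, collapse = ", ")),
                 class = "perishell_scene_error")
  lab <- labels[match(ids, labels$cell_id), ]
  included <- if ("included" %in% names(lab)) lab$included else !(lab$excluded %in% TRUE)
  type <- if ("cell_type" %in% names(lab)) lab$cell_type
          else cell_type_from_flags(lab$chat, lab$nos)

  att <- if (is.null(attributed)) attribute_spots(scene$cells, scene$spots, cfg)
         else attributed
  counts <- att |>
    dplyr::filter(!is.na(.data$cell_id)) |>
    dplyr::count(.data$cell_id, .data$marker, name = "count")

  grid <- tidyr::expand_grid(cell_id = ids[included], marker = varicosity_markers)
  vols <- vapply(ids[included], function(id)
    shell_volume(scene$cells[[id]], cfg,
                 bbox = if (cfg$clip_to_bbox) scene$bbox else NULL), numeric(1))
  grid |>
    dplyr::left_join(counts, by = c("cell_id", "marker")) |>
    dplyr::mutate(
      count = as.integer(dplyr::coalesce(.data$count, 0L)),
      subject_id = scene$subject_id,
      ganglion_id = scene$ganglion_id,
      cell_type = type[included][match(.data$cell_id, ids[included])],
      shell_volume_um3 = unname(vols[.data$cell_id]),
      density_per_1000um3 = 1000 * .data$count / .data$shell_volume_um3) |>
    dplyr::select("subject_id", "ganglion_id", "cell_id", "cell_type", "marker",
                  "count", "shell_volume_um3", "density_per_1000um3")
}
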