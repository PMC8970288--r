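#' Generator parameters for synthetic ganglia
#'
#' Defaults emulate the study design the pipeline targets: 7 subjects with 2
#' reconstructed ganglia each and about 35 analysable cells per ganglion; four
#' ChAT/NOS classes in 38/42/12/8 percent proportions with the published
#' per-type mean cell volumes; TH and ENK varicosity shell densities at the
#' published per-type posterior medians (ChAT-/NOS- cells, which the density
#' model excludes, get lower background densities); negative-binomial
#' overdispersion of shell counts; lognormal subject and ganglion random
#' variation; and ENK (and rare TH) baskets concentrated on ChAT+/NOS- cells.
#'
#' @param n_subjects number of subjects.
#' @param ganglia_per_subject ganglia per subject.
#' @param cells_per_ganglion mean cells per ganglion (Poisson).
#' @param type_props proportions of the four ChAT/NOS classes (sum to 1).
#' @param type_volumes_um3 mean cell volume per class, um^3.
#' @param volume_cv lognormal coefficient of variation of cell volume.
#' @param densities matrix 4 x 2 (type x marker) of true shell densities per
#'   1,000 um^3.
#' @param nb_shape per-marker negative-binomial shape phi (smaller = more
#'   overdispersion).
#' @param sd_subject,sd_ganglion random-effect SDs on the log-density scale.
#' @param basket_prob matrix 4 x 2 of per-cell basket probabilities.
#' @param basket_multiplier factor applied to the expected count of a basket
#'   cell.
#' @param background_per_um3 homogeneous background spot intensity per um^3
#'   per marker (outside all shells).
#' @param mesh_subdiv icosphere subdivision level of the cell meshes.
#' @return A `generator_params` list (validated).
#' @export
generator_params <- function(
    n_subjects = 7,
    ganglia_per_subject = 2,
    cells_per_ganglion = 35,
    type_props = c(0.38, 0.42, 0.12, 0.08),
    type_volumes_um3 = c(4566, 3177, 6078, 2156),
    volume_cv = 0.30,
    densities = matrix(c(7.43, 5.59, 6.02, 5.00,
                         19.52, 12.99, 13.22, 12.00),
                       nrow = 4, dimnames = list(cell_types, varicosity_markers)),
    nb_shape = c(TH = 3, ENK = 3),
    sd_subject = 0.2,
    sd_ganglion = 0.1,
    basket_prob = matrix(c(0.02, 0, 0, 0,
                           0.10, 0, 0, 0),
                         nrow = 4, dimnames = list(cell_types, varicosity_markers)),
    basket_multiplier = 3,
    background_per_um3 = 1e-4,
    mesh_subdiv = 3) {
  p <- list(n_subjects = n_subjects, ganglia_per_subject = ganglia_per_subject,
            cells_per_ganglion = cells_per_ganglion, type_props = type_props,
            type_volumes_um3 = type_volumes_um3, volume_cv = volume_cv,
            densities = densities, nb_shape = nb_shape,
            sd_subject = sd_subject, sd_ganglion = sd_ganglion,
            basket_prob = basket_prob, basket_multiplier = basket_multiplier,
            background_per_um3 = background_per_um3, mesh_subdiv = mesh_subdiv)
  if (abs(sum(p$type_props) - 1) > 1e-8)
    rlang::abort("type_props must sum to 1", class = "perishell_config_error")
  if (any(p$densities < 0) || any(p$nb_shape <= 0) ||
      p$sd_subject < 0 || p$sd_ganglion < 0)
    rlang::abort("densities must be >= 0, nb_shape > 0, random-effect SDs >= 0",
                 class = "perishell_config_error")
  if (p$n_subjects < 1 || p$ganglia_per_subject < 1 || p$cells_per_ganglion <= 0)
    rlang::abort("design sizes must be positive", class = "perishell_config_error")
  structure(p, class = "generator_params")
}

# sample ellipsoid semi-axes for a target volume with jittered axis ratios
sample_semi_axes <- function(target_volume) {
  ratios <- c(1, 0.75, 0.6) * stats::runif(3, 0.9, 1.1)
  ratios <- ratios / max(ratios)
  a <- (3 * target_volume / (4 * pi * prod(ratios[2:3])))^(1 / 3)
  a * ratios
}

#' Generate synthetic ganglion scenes with known ground truth
#'
#' Cells are randomly oriented ellipsoid meshes placed without overlap on a
#' jittered grid inside a slab; per cell and marker a shell count is drawn
#' from a negative binomial with mean true_density x shell_volume x subject x
#' ganglion effect (times the basket multiplier for basket cells) and that
#' many spots are placed uniformly inside the +/- 1 um shell; background spots
#' are a homogeneous Poisson process in the slab outside all shells. The same
#' seed reproduces the output exactly. Ground-truth basket flags are written
#' into the label tables as manual basket calls.
#'
#' @param params a [generator_params()] list.
#' @param seed integer seed.
#' @param shell a [shell_config()] used for the truth shell volumes.
#' @return A list with `scenes` (list of [ganglion_scene()]), `labels` (list
#'   of label tibbles parallel to scenes), and `truth` (tibble with every
#'   sampled latent: type, semi-axes, shell volume, random effects, basket
#'   flags and expected counts per marker), with `params` attached as an
#'   attribute.
#' @export
generate_ganglia <- function(params = generator_params(), seed = 1,
                             shell = shell_config()) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(seed)
  sdlog <- sqrt(log(1 + params$volume_cv^2))
  subj_eff <- stats::rnorm(params$n_subjects, 0, params$sd_subject)

  scenes <- list()
  labels <- list()
  truth <- list()
  for (s in seq_len(params$n_subjects)) {
    for (g in seq_len(params$ganglia_per_subject)) {
      gang_eff <- stats::rnorm(1, 0, params$sd_ganglion)
      n_cells <- max(2L, stats::rpois(1, params$cells_per_ganglion))
      types <- sample(cell_types, n_cells, replace = TRUE, prob = params$type_props)
      tvol <- params$type_volumes_um3[match(types, cell_types)]
      vols <- stats::rlnorm(n_cells, log(tvol) - sdlog^2 / 2, sdlog)
      axes <- lapply(vols, sample_semi_axes)
      amax <- max(vapply(axes, max, numeric(1)))

      # jittered grid placement: non-overlap by construction
      pitch <- 2 * amax + 3
      ncol_grid <- ceiling(sqrt(n_cells))
      ix <- (seq_len(n_cells) - 1) %% ncol_grid
      iy <- (seq_len(n_cells) - 1) %/% ncol_grid
      centers <- cbind(ix * pitch + stats::runif(n_cells, -1, 1),
                       iy * pitch + stats::runif(n_cells, -1, 1),
                       stats::runif(n_cells, -1, 1))

      ids <- sprintf("S%dG%d_c%03d", s, g, seq_len(n_cells))
      cells <- vector("list", n_cells)
      shell_vols <- numeric(n_cells)
      for (i in seq_len(n_cells)) {
        cells[[i]] <- ellipsoid_mesh(axes[[i]], center = centers[i, ],
                                     rotation = random_rotation(),
                                     subdiv = params$mesh_subdiv, cell_id = ids[i])
        shell_vols[i] <- shell_volume(cells[[i]], shell)
      }

      basket <- matrix(FALSE, n_cells, 2, dimnames = list(NULL, varicosity_markers))
      expected <- matrix(0, n_cells, 2, dimnames = list(NULL, varicosity_markers))
      realized <- matrix(0L, n_cells, 2, dimnames = list(NULL, varicosity_markers))
      spot_list <- list()
      for (mk in varicosity_markers) {
        dens <- params$densities[match(types, cell_types), mk]
        basket[, mk] <- stats::runif(n_cells) <
          params$basket_prob[match(types, cell_types), mk]
        mult <- ifelse(basket[, mk], params$basket_multiplier, 1)
        expected[, mk] <- dens / 1000 * shell_vols *
          exp(subj_eff[s] + gang_eff) * mult
        counts <- stats::rnbinom(n_cells, mu = expected[, mk],
                                 size = params$nb_shape[[mk]])
        realized[, mk] <- as.integer(counts)
        for (i in seq_len(n_cells)) {
          if (counts[i] == 0) next
          P <- sample_shell_points(cells[[i]], counts[i], shell)
          spot_list[[length(spot_list) + 1L]] <-
            tibble::tibble(marker = mk, x_um = P[, 1], y_um = P[, 2], z_um = P[, 3])
        }
      }

      # bbox covering all cells with margin so no border exclusions arise
      allv <- do.call(rbind, lapply(cells, function(m) m$vertices))
      bbox <- rbind(apply(allv, 2, min) - 3, apply(allv, 2, max) + 3)

      # background spots: homogeneous Poisson in the slab, outside all shells
      slab_vol <- prod(bbox[2, ] - bbox[1, ])
      for (mk in varicosity_markers) {
        n_bg <- stats::rpois(1, params$background_per_um3 * slab_vol)
        if (n_bg > 0) {
          P <- cbind(stats::runif(n_bg, bbox[1, 1], bbox[2, 1]),
                     stats::runif(n_bg, bbox[1, 2], bbox[2, 2]),
                     stats::runif(n_bg, bbox[1, 3], bbox[2, 3]))
          keep <- rep(TRUE, n_bg)
          for (m in cells) {
            if (!any(keep)) break
            keep[keep] <- !cpp_in_shell(m$vertices, m$faces - 1L,
                                        P[keep, , drop = FALSE], shell$half_width)
          }
          if (any(keep))
            spot_list[[length(spot_list) + 1L]] <-
              tibble::tibble(marker = mk, x_um = P[keep, 1],
                             y_um = P[keep, 2], z_um = P[keep, 3])
        }
      }

      spots <- if (length(spot_list)) dplyr::bind_rows(spot_list)
               else tibble::tibble(marker = character(), x_um = numeric(),
                                   y_um = numeric(), z_um = numeric())
      subject_id <- sprintf("S%d", s)
      ganglion_id <- sprintf("G%d", g)
      scenes[[length(scenes) + 1L]] <-
        ganglion_scene(subject_id, ganglion_id, cells, spots, bbox = bbox)
      labels[[length(labels) + 1L]] <- tibble::tibble(
        cell_id = ids,
        chat = types %in% c("ChAT+/NOS-", "ChAT+/NOS+"),
        nos = types %in% c("ChAT-/NOS+", "ChAT+/NOS+"),
        excluded = FALSE, exclusion_reason = "",
        basket_th = basket[, "TH"], basket_enk = basket[, "ENK"])
      truth[[length(truth) + 1L]] <- tibble::tibble(
        subject_id = subject_id, ganglion_id = ganglion_id, cell_id = ids,
        cell_type = types, volume_um3 = vols,
        semi_a = vapply(axes, `[`, numeric(1), 1),
        semi_b = vapply(axes, `[`, numeric(1), 2),
        semi_c = vapply(axes, `[`, numeric(1), 3),
        shell_volume_um3 = shell_vols,
        subject_effect = subj_eff[s], ganglion_effect = gang_eff,
        basket_th = basket[, "TH"], basket_enk = basket[, "ENK"],
        expected_th = expected[, "TH"], expected_enk = expected[, "ENK"],
        count_th = realized[, "TH"], count_enk = realized[, "ENK"],
        true_density_th = params$densities[match(types, cell_types), "TH"],
        true_density_enk = params$densities[match(types, cell_types), "ENK"])
    }
  }
  truth <- dplyr::bind_rows(truth)
  attr(truth, "params") <- params
  attr(truth, "seed") <- seed
  list(scenes = scenes, labels = labels, truth = truth)
}

#' Single-sphere test fixture
#'
#' One spherical cell at the origin with exactly `n_spots_in_shell` spots
#' placed uniformly inside its +/- 1 um shell; the workhorse fixture for the
#' geometric acceptance checks.
#'
#' @param radius sphere radius, um (> 1).
#' @param n_spots_in_shell number of shell spots to place.
#' @param seed integer seed.
#' @param marker marker tag for the spots.
#' @param shell a [shell_config()].
#' @return A list with `scene` ([ganglion_scene()]) and `labels` (tibble).
#' @export
make_sphere_fixture <- function(radius = 5, n_spots_in_shell = 10, seed = 1,
                                marker = "TH", shell = shell_config()) {
  stopifnot(radius > shell$half_width)
  set.seed(seed)
  cell <- sphere_mesh(radius, cell_id = "sphere1")
  spots <- if (n_spots_in_shell > 0) {
    P <- sample_shell_points(cell, n_spots_in_shell, shell)
    tibble::tibble(marker = marker, x_um = P[, 1], y_um = P[, 2], z_um = P[, 3])
  } else {
    tibble::tibble(marker = character(), x_um = numeric(), y_um = numeric(),
                   z_um = numeric())
  }
  scene <- ganglion_scene("S1", "G1", list(cell), spots)
  labels <- tibble::tibble(cell_id = "sphere1", chat = TRUE, nos = FALSE,
                           excluded = FALSE, exclusion_reason = "",
                           basket_th = NA, basket_enk = NA)
  list(scene = scene, labels = labels)
}
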