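#' Quasi-uniform directions on the unit sphere
#'
#' Deterministic Fibonacci-sphere points, used as angular bin centres for the
#' basket coverage statistic.
#'
#' @param n number of directions.
#' @return An n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n = 64) {
  i <- seq_len(n) - 0.5
  phi <- pi * (sqrt(5) - 1)  # golden angle
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi * i), r * sin(phi * i), z)
}

#' Detect pericellular varicosity baskets
#'
#' Quantifies the visually defined "basket": a dense arrangement of
#' varicosities encircling a cell body. For each cell x marker the in-shell
#' spots attributed to the cell are mapped to directions from the cell
#' centroid; each direction is assigned to its nearest of `bins` Fibonacci
#' sphere bin centres, and coverage is the fraction of bins occupied. A basket
#' is called when the shell count is at least `n_min` and coverage at least
#' `c_min`. Manual basket flags in the typed-cell table override automatic
#' calls.
#'
#' @param attributed spot attribution tibble from [attribute_spots()].
#' @param cells list of [surface_mesh()] objects (for centroids).
#' @param typed optional typed-cell tibble carrying manual `basket_th` /
#'   `basket_enk` calls.
#' @param n_min minimum shell count (default 15).
#' @param c_min minimum angular coverage fraction (default 1/3).
#' @param bins number of angular bins (default 64).
#' @return A tibble `cell_id`, `marker`, `shell_count`, `coverage`,
#'   `is_basket`, `source` ("auto" or "manual"); one row per cell x marker.
#' @export
detect_baskets <- function(attributed, cells, typed = NULL,
                           n_min = 15, c_min = 1 / 3, bins = 64) {
  ids <- vapply(cells, function(m) as.character(attr(m, "cell_id")), character(1))
  centroids <- t(vapply(cells, mesh_centroid, numeric(3)))
  rownames(centroids) <- ids
  B <- fibonacci_sphere(bins)

  grid <- tidyr::expand_grid(cell_id = ids, marker = varicosity_markers)
  res <- purrr::pmap_dfr(grid, function(cell_id, marker) {
    sp <- attributed[!is.na(attributed$cell_id) &
                     attributed$cell_id == cell_id & attributed$marker == marker, ]
    k <- nrow(sp)
    if (k == 0) {
      cov <- 0
    } else {
      d <- cbind(sp$x_um, sp$y_um, sp$z_um) -
        matrix(centroids[cell_id, ], k, 3, byrow = TRUE)
      nrm <- sqrt(rowSums(d^2))
      if (any(nrm < 1e-9))
        rlang::abort(sprintf("cell '%s': spot coincides with centroid, direction undefined",
                             cell_id), class = "perishell_basket_error")
      d <- d / nrm
      # nearest bin centre = max dot product
      occupied <- unique(max.col(d %*% t(B)))
      cov <- length(occupied) / bins
    }
    tibble::tibble(cell_id = cell_id, marker = marker, shell_count = k,
                   coverage = cov, is_basket = k >= n_min && cov >= c_min,
                   source = "auto")
  })

  if (!is.null(typed)) {
    typed <- tibble::as_tibble(typed)
    man <- typed |>
      dplyr::select("cell_id", TH = "basket_th", ENK = "basket_enk") |>
      tidyr::pivot_longer(c("TH", "ENK"), names_to = "marker", values_to = "manual")
    res <- res |>
      dplyr::left_join(man, by = c("cell_id", "marker")) |>
      dplyr::mutate(
        source = ifelse(!is.na(.data$manual), "manual", .data$source),
        is_basket = dplyr::coalesce(.data$manual, .data$is_basket)) |>
      dplyr::select(-"manual")
  }
  res
}

#' Pearson chi-square association test
#'
#' Classical Pearson chi-square on a contingency table (no continuity
#' correction): expected counts from the row/column margins, df =
#' (r-1)(c-1), p from the upper tail.
#'
#' @param table matrix (or table) of non-negative counts, at least 2 x 2.
#' @return A tibble `chi2`, `df`, `p_value`.
#' @export
chisq_association <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    rlang::abort("contingency table must be at least 2 x 2", class = "perishell_basket_error")
  if (any(table < 0) || any(table != round(table)))
    rlang::abort("contingency table must hold non-negative integer counts",
                 class = "perishell_basket_error")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    rlang::abort("contingency table has a zero margin", class = "perishell_basket_error")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  tibble::tibble(chi2 = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = unname(ht$p.value))
}

#' Summarise basket calls by cell type
#'
#' Builds the basket x cell-type contingency for each marker: per type, the
#' number of basket cells and the percentage of all that marker's baskets they
#' represent, plus the (basket, no basket) x type table used for the
#' association test on included cells.
#'
#' @param calls basket-call tibble from [detect_baskets()].
#' @param typed typed-cell tibble with `cell_type` (and optionally
#'   `included`; only included cells are tabulated).
#' @return A list with `summary` (tibble marker x cell_type: `n_baskets`,
#'   `percent_of_baskets`, `n_cells`) and `tables` (named list of 2 x 4
#'   basket/no-basket matrices per marker).
#' @export
basket_summary <- function(calls, typed) {
  typed <- tibble::as_tibble(typed)
  if ("included" %in% names(typed)) typed <- dplyr::filter(typed, .data$included)
  joined <- dplyr::inner_join(calls, typed[c("cell_id", "cell_type")], by = "cell_id")
  if (!nrow(joined))
    rlang::abort("basket calls and typed cells share no cell_id", class = "perishell_basket_error")
  joined$cell_type <- factor(as.character(joined$cell_type), levels = cell_types)

  summary <- joined |>
    dplyr::group_by(.data$marker, .data$cell_type, .drop = FALSE) |>
    dplyr::summarise(n_baskets = sum(.data$is_basket),
                     n_cells = dplyr::n(), .groups = "drop_last") |>
    dplyr::mutate(percent_of_baskets =
                    if (sum(.data$n_baskets) > 0)
                      100 * .data$n_baskets / sum(.data$n_baskets)
                    else rep(0, dplyr::n())) |>
    dplyr::ungroup()

  tables <- lapply(stats::setNames(varicosity_markers, varicosity_markers), function(mk) {
    sub <- joined[joined$marker == mk, ]
    tab <- rbind(
      basket = as.integer(table(sub$cell_type[sub$is_basket])),
      no_basket = as.integer(table(sub$cell_type[!sub$is_basket])))
    colnames(tab) <- cell_types
    tab
  })
  list(summary = summary, tables = tables)
}
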