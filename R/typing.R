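cell_type_from_flags <- function(chat, nos) {
  dplyr::case_when(
    chat & !nos ~ "ChAT+/NOS-",
    !chat & nos ~ "ChAT-/NOS+",
    chat & nos ~ "ChAT+/NOS+",
    !chat & !nos ~ "ChAT-/NOS-",
    TRUE ~ NA_character_)
}

#' Classify cells by ChAT/NOS immunoreactivity
#'
#' Assigns each cell one of the four ChAT/NOS classes. Explicit boolean calls
#' in the label table take precedence; where a call is missing, the channel
#' mean intensity is compared against its threshold (positive iff mean >
#' threshold). A cell with neither a manual call nor intensities for the
#' missing channel is an error.
#'
#' @param labels label tibble (see [read_cell_labels()]); `chat`/`nos` may be
#'   `NA` where intensities should decide.
#' @param channel_means optional tibble `cell_id`, `chat_mean`, `nos_mean`.
#' @param chat_threshold,nos_threshold intensity thresholds (same units as the
#'   channel means).
#' @return A typed-cell tibble: `cell_id`, `chat`, `nos`, `cell_type`, plus the
#'   label table's exclusion and basket columns carried through.
#' @export
classify_cells <- function(labels, channel_means = NULL,
                           chat_threshold = 100, nos_threshold = 100) {
  labels <- validate_cell_labels(labels)
  chat <- labels$chat
  nos <- labels$nos
  if (!is.null(channel_means)) {
    channel_means <- tibble::as_tibble(channel_means)
    idx <- match(labels$cell_id, channel_means$cell_id)
    chat_auto <- channel_means$chat_mean[idx] > chat_threshold
    nos_auto <- channel_means$nos_mean[idx] > nos_threshold
    chat <- dplyr::coalesce(chat, chat_auto)
    nos <- dplyr::coalesce(nos, nos_auto)
  }
  bad <- which(is.na(chat) | is.na(nos))
  if (length(bad))
    rlang::abort(sprintf("cell '%s' has neither manual ChAT/NOS labels nor channel intensities",
                         labels$cell_id[bad[1]]),
                 class = "perishell_typing_error")
  tibble::tibble(cell_id = labels$cell_id, chat = chat, nos = nos,
                 cell_type = factor(cell_type_from_flags(chat, nos), levels = cell_types),
                 excluded_manual = labels$excluded %in% TRUE,
                 exclusion_reason = labels$exclusion_reason,
                 basket_th = labels$basket_th, basket_enk = labels$basket_enk)
}

#' Apply the exclusion rules
#'
#' A cell is excluded from analysis when (a) it carries a manual exclusion
#' flag (e.g. a single surface representing two merged cells), (b) its mesh
#' bounding box comes within `border_margin` um of a face of the imaged
#' bounding box (incomplete cell at the image edge), or (c) its mesh failed
#' watertight repair (passed in via `failed_cells`). Geometry is never
#' modified; the included and excluded sets partition the input.
#'
#' @param typed typed-cell tibble from [classify_cells()].
#' @param scene the [ganglion_scene()] holding the cell meshes.
#' @param border_margin distance to the bbox faces under which a cell counts
#'   as cut off, um.
#' @param failed_cells character vector of cell ids whose mesh failed repair.
#' @return The input tibble with `included` (logical) and updated
#'   `exclusion_reason`.
#' @export
apply_exclusions <- function(typed, scene, border_margin = 0.5,
                             failed_cells = character()) {
  typed <- tibble::as_tibble(typed)
  reason <- dplyr::coalesce(typed$exclusion_reason, "")
  reason[!nzchar(reason) & typed$excluded_manual] <- "manual"
  included <- !typed$excluded_manual
  for (i in seq_len(nrow(typed))) {
    id <- typed$cell_id[i]
    if (id %in% failed_cells) {
      included[i] <- FALSE
      if (!nzchar(reason[i])) reason[i] <- "mesh repair failed"
      next
    }
    m <- scene$cells[[id]]
    if (is.null(m)) next
    V <- m$vertices
    lo <- apply(V, 2, min)
    hi <- apply(V, 2, max)
    if (any(lo - scene$bbox[1, ] < border_margin) ||
        any(scene$bbox[2, ] - hi < border_margin)) {
      included[i] <- FALSE
      if (!nzchar(reason[i])) reason[i] <- "border"
    }
  }
  typed$included <- included
  typed$exclusion_reason <- reason
  typed
}

#' Cell-type counts and pooled percentages
#'
#' Counts of included cells per ChAT/NOS class and the pooled percentage each
#' class represents. Percentages are exact quotients of the pooled counts (not
#' per-specimen means).
#'
#' @param typed typed-cell tibble; only rows with `included` (or all rows when
#'   the column is absent) are counted.
#' @return A tibble `cell_type`, `n`, `percent`, all four classes present.
#' @export
type_proportions <- function(typed) {
  typed <- tibble::as_tibble(typed)
  if ("included" %in% names(typed)) typed <- dplyr::filter(typed, .data$included)
  if (!nrow(typed))
    rlang::abort("no included cells", class = "perishell_typing_error")
  tab <- table(factor(as.character(typed$cell_type), levels = cell_types))
  tibble::tibble(cell_type = cell_types, n = as.integer(tab),
                 percent = 100 * as.integer(tab) / sum(tab))
}

#' Proportion of intrinsically immunoreactive somata
#'
#' The simple pooled proportion of cell bodies positive for a marker (e.g.
#' TH-immunoreactive somata among all HuC/D cells counted).
#'
#' @param n_positive,n_total non-negative counts, `n_total` > 0.
#' @return A tibble `n_positive`, `n_total`, `percent`.
#' @export
soma_proportion <- function(n_positive, n_total) {
  stopifnot(n_total > 0, n_positive >= 0, n_positive <= n_total)
  tibble::tibble(n_positive = as.integer(n_positive), n_total = as.integer(n_total),
                 percent = 100 * n_positive / n_total)
}
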