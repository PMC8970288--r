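#' Read and write cell-body meshes
#'
#' `read_mesh()` reads an ASCII PLY, OBJ or STL file (format chosen by
#' extension), validates the mesh and attempts a single repair pass; an
#' irreparably non-watertight mesh raises a `perishell_mesh_error`, the signal
#' that the cell must be excluded from analysis. Coordinates are micrometres by
#' convention; no unit auto-detection is attempted. Binary PLY/STL variants are
#' rejected with a clear error.
#'
#' @param path file path ending in `.ply`, `.obj` or `.stl`.
#' @param cell_id identifier to attach; defaults to the file stem.
#' @return A [surface_mesh()].
#' @export
read_mesh <- function(path, cell_id = NULL) {
  if (!file.exists(path))
    rlang::abort(sprintf("mesh file not found: %s", path), class = "perishell_io_error")
  if (is.null(cell_id))
    cell_id <- sub("\\.[^.]+$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  raw <- switch(ext,
    ply = parse_ply(path),
    obj = parse_obj(path),
    stl = parse_stl(path),
    rlang::abort(sprintf("unsupported mesh format '.%s' (use ASCII PLY, OBJ or STL)", ext),
                 class = "perishell_io_error"))
  surface_mesh(raw$vertices, raw$faces, cell_id = cell_id)
}

parse_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply")
    rlang::abort(sprintf("%s: not a PLY file", path), class = "perishell_io_error")
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end))
    rlang::abort(sprintf("%s: PLY header has no end_header", path), class = "perishell_io_error")
  hdr <- trimws(lines[seq_len(hdr_end)])
  fmt <- grep("^format ", hdr, value = TRUE)
  if (!length(fmt) || !grepl("ascii", fmt[1]))
    rlang::abort(sprintf("%s: only ASCII PLY is supported", path), class = "perishell_io_error")
  nv <- as.integer(sub("^element vertex +", "", grep("^element vertex ", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("^element face +", "", grep("^element face ", hdr, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf))
    rlang::abort(sprintf("%s: PLY header missing vertex/face counts", path),
                 class = "perishell_io_error")
  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vl <- strsplit(trimws(body[seq_len(nv)]), "[[:space:]]+")
  V <- t(vapply(vl, function(x) as.numeric(x[1:3]), numeric(3)))
  fl <- strsplit(trimws(body[nv + seq_len(nf)]), "[[:space:]]+")
  F <- t(vapply(fl, function(x) {
    k <- as.integer(x[1])
    if (is.na(k) || k != 3L)
      rlang::abort(sprintf("%s: only triangular faces supported", path),
                   class = "perishell_io_error")
    as.integer(x[2:4]) + 1L
  }, integer(3)))
  if (any(!is.finite(V)))
    rlang::abort(sprintf("%s: non-numeric vertex coordinate", path), class = "perishell_io_error")
  list(vertices = V, faces = F)
}

parse_obj <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vlines <- grep("^v[[:space:]]", lines, value = TRUE)
  flines <- grep("^f[[:space:]]", lines, value = TRUE)
  if (!length(vlines) || !length(flines))
    rlang::abort(sprintf("%s: OBJ file has no vertices or faces", path),
                 class = "perishell_io_error")
  V <- t(vapply(strsplit(vlines, "[[:space:]]+"),
                function(x) as.numeric(x[2:4]), numeric(3)))
  F <- t(vapply(strsplit(flines, "[[:space:]]+"), function(x) {
    idx <- sub("/.*$", "", x[-1])
    if (length(idx) != 3L)
      rlang::abort(sprintf("%s: only triangular faces supported", path),
                   class = "perishell_io_error")
    as.integer(idx)
  }, integer(3)))
  if (any(!is.finite(V)))
    rlang::abort(sprintf("%s: non-numeric vertex coordinate", path), class = "perishell_io_error")
  list(vertices = V, faces = F)
}

parse_stl <- function(path) {
  head <- readBin(path, "raw", n = 5)
  if (!identical(rawToChar(head), "solid"))
    rlang::abort(sprintf("%s: binary STL is not supported (ASCII only)", path),
                 class = "perishell_io_error")
  lines <- trimws(readLines(path, warn = FALSE))
  vl <- grep("^vertex[[:space:]]", lines, value = TRUE)
  if (length(vl) %% 3 != 0)
    rlang::abort(sprintf("%s: STL vertex count not a multiple of 3", path),
                 class = "perishell_io_error")
  P <- t(vapply(strsplit(vl, "[[:space:]]+"), function(x) as.numeric(x[2:4]), numeric(3)))
  if (any(!is.finite(P)))
    rlang::abort(sprintf("%s: non-numeric vertex coordinate", path), class = "perishell_io_error")
  # weld vertices shared between facets
  key <- apply(round(P, 6), 1, paste, collapse = ",")
  uid <- match(key, unique(key))
  V <- P[!duplicated(key), , drop = FALSE]
  F <- matrix(uid, ncol = 3, byrow = TRUE)
  list(vertices = V, faces = F)
}

#' @rdname read_mesh
#' @param mesh a `surface_mesh` to write.
#' @param overwrite overwrite an existing file (default `FALSE`).
#' @export
write_mesh <- function(mesh, path, overwrite = FALSE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (file.exists(path) && !overwrite)
    rlang::abort(sprintf("file exists: %s (use overwrite = TRUE)", path),
                 class = "perishell_io_error")
  V <- mesh$vertices
  F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(V)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(F)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
  invisible(path)
}
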