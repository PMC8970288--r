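test_that("spot tables parse, split per marker, and round-trip", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  spots <- tibble::tibble(marker = c("TH", "TH", "ENK", "TH"),
                          x_um = c(1.5, 2, 3, -4.25), y_um = c(0, 1, 2, 3),
                          z_um = c(9, 8, 7, 6.125))
  write_spots(spots, tmp)
  back <- read_spots(tmp)
  expect_equal(back, spots)
  sets <- spot_sets(back)
  expect_named(sets, c("TH", "ENK"))
  expect_equal(nrow(sets$TH), 3)
  expect_equal(sets$TH$x_um, c(1.5, 2, -4.25))  # order preserved
})

test_that("an empty spot file with header yields an empty table", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("marker,x_um,y_um,z_um", tmp)
  sp <- read_spots(tmp)
  expect_equal(nrow(sp), 0)
  expect_length(spot_sets(sp), 0)
})

test_that("spot parse errors name the offending row and field", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("marker,x_um,y_um,z_um", "XYZ,1,2,3"), tmp)
  expect_error(read_spots(tmp), "row 1.*XYZ", class = "perishell_parse_error")
  writeLines(c("marker,x_um,y_um,z_um", "TH,1,2,3", "ENK,oops,2,3"), tmp)
  expect_error(read_spots(tmp), "row 2.*x_um", class = "perishell_parse_error")
  writeLines(c("marker,x_um,y_um", "TH,1,2"), tmp)
  expect_error(read_spots(tmp), "z_um", class = "perishell_parse_error")
})

test_that("label tables round-trip and enforce exclusion reasons", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  lab <- tibble::tibble(cell_id = c("a", "b"), chat = c(TRUE, FALSE),
                        nos = c(FALSE, TRUE), excluded = c(FALSE, TRUE),
                        exclusion_reason = c("", "merged surface"),
                        basket_th = c(NA, TRUE), basket_enk = c(FALSE, NA))
  write_cell_labels(lab, tmp)
  expect_equal(read_cell_labels(tmp), lab)
  bad <- lab
  bad$exclusion_reason[2] <- ""
  expect_error(write_cell_labels(bad, tmp, overwrite = TRUE),
               class = "perishell_parse_error")
})

test_that("density tables round-trip through CSV for random records", {
  set.seed(5)
  n <- 100
  rec <- tibble::tibble(
    subject_id = sprintf("S%d", sample(7, n, TRUE)),
    ganglion_id = sprintf("G%d", sample(2, n, TRUE)),
    cell_id = sprintf("c%03d", seq_len(n)),
    cell_type = sample(cell_types, n, TRUE),
    marker = sample(varicosity_markers, n, TRUE),
    count = as.integer(rpois(n, 40)),
    shell_volume_um3 = round(runif(n, 500, 9000), 6),
    density_per_1000um3 = NA_real_)
  rec$density_per_1000um3 <- 1000 * rec$count / rec$shell_volume_um3
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_density_table(rec, tmp)
  back <- read_density_table(tmp)
  expect_equal(back$count, rec$count)
  expect_equal(back$density_per_1000um3, rec$density_per_1000um3, tolerance = 1e-9)
  expect_equal(back[c("subject_id", "cell_id", "cell_type", "marker")],
               rec[c("subject_id", "cell_id", "cell_type", "marker")])
  # header-only file for an empty record list
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_density_table(rec[0, ], tmp2)
  expect_equal(length(readLines(tmp2)), 1)
  expect_error(write_density_table(rec, tmp), class = "perishell_io_error")
})

test_that("meshes round-trip through PLY and parse from OBJ and STL", {
  m <- ellipsoid_mesh(c(4, 3, 2.5), subdiv = 1, cell_id = "cell7")
  dir <- withr::local_tempdir()
  ply <- file.path(dir, "cell7.ply")
  write_mesh(m, ply)
  back <- read_mesh(ply)
  expect_equal(back$vertices, m$vertices, tolerance = 1e-5)
  expect_equal(mesh_volume(back), mesh_volume(m), tolerance = 1e-4)
  expect_equal(attr(back, "cell_id"), "cell7")

  obj <- file.path(dir, "cell8.obj")
  writeLines(c(sprintf("v %.6f %.6f %.6f", m$vertices[, 1], m$vertices[, 2],
                       m$vertices[, 3]),
               sprintf("f %d %d %d", m$faces[, 1], m$faces[, 2], m$faces[, 3])), obj)
  back2 <- read_mesh(obj)
  expect_equal(mesh_volume(back2), mesh_volume(m), tolerance = 1e-6)

  stl <- file.path(dir, "cell9.stl")
  tri <- lapply(seq_len(nrow(m$faces)), function(i) {
    v <- m$vertices[m$faces[i, ], , drop = FALSE]
    c("facet normal 0 0 0", "outer loop",
      sprintf("vertex %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]),
      "endloop", "endfacet")
  })
  writeLines(c("solid cell9", unlist(tri), "endsolid cell9"), stl)
  back3 <- read_mesh(stl)
  expect_equal(mesh_volume(back3), mesh_volume(m), tolerance = 1e-4)
})

test_that("a scene set writes to disk and loads back through the manifest", {
  set.seed(21)
  sc <- random_test_scene(2, 40)
  scene <- ganglion_scene("S1", "G1", sc$cells, sc$spots)
  labels <- make_labels(names(scene$cells))
  dir <- withr::local_tempdir()
  man <- write_scene_set(list(scene), list(labels), dir)
  entries <- read_scene_manifest(man)
  expect_length(entries, 1)
  loaded <- load_scene(entries[[1]], base_dir = dir)
  expect_s3_class(loaded$scene, "ganglion_scene")
  expect_equal(sort(names(loaded$scene$cells)), sort(names(scene$cells)))
  expect_equal(nrow(loaded$scene$spots), nrow(scene$spots))
  expect_equal(loaded$labels, labels)
})

test_that("a scene entry with an irreparable mesh drops the cell with a warning", {
  set.seed(27)
  sc <- random_test_scene(2, 30)
  scene <- ganglion_scene("S1", "G1", sc$cells, sc$spots)
  labels <- make_labels(names(scene$cells))
  dir <- withr::local_tempdir()
  man <- write_scene_set(list(scene), list(labels), dir)
  # overwrite one mesh with an open hemisphere: must fail watertight repair
  base <- sphere_mesh(4, subdiv = 2)
  ctr <- t(vapply(seq_len(nrow(base$faces)), function(i)
    colMeans(base$vertices[base$faces[i, ], ]), numeric(3)))
  hemi <- list(vertices = base$vertices,
               faces = base$faces[ctr[, 3] < 0, , drop = FALSE])
  entry <- read_scene_manifest(man)[[1]]
  broken_path <- file.path(dir, entry$meshes[[1]])
  con <- file(broken_path, "w")
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(hemi$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(hemi$faces)),
               "property list uchar int vertex_indices", "end_header",
               sprintf("%.6f %.6f %.6f", hemi$vertices[, 1], hemi$vertices[, 2],
                       hemi$vertices[, 3]),
               sprintf("3 %d %d %d", hemi$faces[, 1] - 1L, hemi$faces[, 2] - 1L,
                       hemi$faces[, 3] - 1L)), con)
  close(con)
  expect_warning(loaded <- load_scene(entry, base_dir = dir), "dropping cell")
  expect_length(loaded$failed_cells, 1)
  expect_equal(length(loaded$scene$cells), 1)
})

test_that("scenes reject duplicate ids and out-of-bbox vertices", {
  m1 <- sphere_mesh(3, cell_id = "dup")
  m2 <- sphere_mesh(3, c(10, 0, 0), cell_id = "dup")
  sp <- tibble::tibble(marker = "TH", x_um = 0, y_um = 0, z_um = 0)
  expect_error(ganglion_scene("S", "G", list(m1, m2), sp),
               class = "perishell_scene_error")
  m2 <- sphere_mesh(3, c(10, 0, 0), cell_id = "b")
  bb <- rbind(c(-4, -4, -4), c(5, 4, 4))  # m2 pokes out
  expect_error(ganglion_scene("S", "G", list(m1, m2), sp, bbox = bb),
               class = "perishell_scene_error")
})
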