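# OFF / VTK legacy mesh I/O.

test_that("write/read round trip is bit-exact in both formats", {
  mesh <- make_platelet_mesh(1e-6, 0.25, 150)
  for (fmt in c("off", "vtk")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_mesh(mesh, path)
    back <- read_mesh(path)
    expect_identical(back$vertices, mesh$vertices)
    expect_identical(back$triangles, mesh$triangles)
    expect_equal(back$V0, mesh$V0, tolerance = 1e-15)
  }
})

test_that("malformed files raise parse errors with a line reference", {
  p <- tempfile(fileext = ".off")
  writeLines(c("OFF", "4 2 0", "0 0 0", "1 0 0", "0 1 0"), p)
  expect_error(read_mesh(p), "truncated")
  writeLines(c("NOTOFF", "1 1 0"), p)
  expect_error(read_mesh(p), "OFF header")
  p2 <- tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 2.0", "x", "ASCII",
               "DATASET POLYDATA"), p2)
  expect_error(read_mesh(p2), "POINTS")
  expect_error(read_mesh(tempfile(fileext = ".stl")), "unsupported")
})

test_that("receptor sites export as CSV", {
  mesh <- place_receptors(make_platelet_mesh(1e-6, 0.25, 120), 50, seed = 1)
  p <- tempfile(fileext = ".csv")
  write_receptor_sites(mesh, p)
  back <- utils::read.csv(p)
  expect_identical(nrow(back), 50L)
  expect_identical(back$triangle, mesh$receptors$triangle)
})
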