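# Plain-text mesh I/O: OFF and VTK legacy ASCII polydata. Hand-rolled because
# no installed package handles these formats; write->read round trips are
# bit-exact (17 significant digits).

#' Read and write triangulated meshes (OFF, VTK legacy polydata)
#'
#' @param path File path.
#' @param format `"off"` or `"vtk"`; inferred from the file extension when
#'   omitted.
#' @return `read_mesh()` returns a `platelet_mesh` (reference geometry taken
#'   from the file contents); `write_mesh()` returns `path` invisibly.
#' @export
read_mesh <- function(path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% c("off", "vtk")) {
    stop("unsupported mesh format: ", format)
  }
  lines <- readLines(path)
  switch(format, off = .read_off(lines, path), vtk = .read_vtk(lines, path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_err <- function(path, i, msg) {
  stop(sprintf("%s:%d: %s", path, i, msg), call. = FALSE)
}

.read_off <- function(lines, path) {
  keep <- !grepl("^\\s*(#|$)", lines)
  ln <- which(keep)
  body <- lines[keep]
  if (length(body) < 2 || toupper(trimws(body[1])) != "OFF") {
    .parse_err(path, 1, "expected OFF header")
  }
  counts <- scan(text = body[2], quiet = TRUE)
  if (length(counts) < 2) .parse_err(path, ln[2], "expected 'nv nf ne' counts")
  nv <- counts[1]; nf <- counts[2]
  if (length(body) < 2 + nv + nf) {
    .parse_err(path, length(lines), "file truncated: fewer lines than declared")
  }
  verts <- matrix(NA_real_, nv, 3)
  for (i in seq_len(nv)) {
    v <- suppressWarnings(scan(text = body[2 + i], quiet = TRUE))
    if (length(v) != 3 || anyNA(v)) .parse_err(path, ln[2 + i], "bad vertex line")
    verts[i, ] <- v
  }
  tris <- matrix(NA_integer_, nf, 3)
  for (i in seq_len(nf)) {
    f <- suppressWarnings(scan(text = body[2 + nv + i], quiet = TRUE))
    if (length(f) != 4 || f[1] != 3) {
      .parse_err(path, ln[2 + nv + i], "expected a triangle face '3 i j k'")
    }
    tris[i, ] <- as.integer(f[2:4]) + 1L  # OFF is 0-based
  }
  .finish_mesh(verts, tris)
}

.read_vtk <- function(lines, path) {
  ip <- grep("^POINTS", lines)
  if (length(ip) != 1) .parse_err(path, 1, "missing POINTS section")
  nv <- as.integer(strsplit(trimws(lines[ip]), "\\s+")[[1]][2])
  vals <- scan(text = lines[(ip + 1):length(lines)], n = 3 * nv, quiet = TRUE)
  verts <- matrix(vals, nv, 3, byrow = TRUE)
  ipoly <- grep("^POLYGONS", lines)
  if (length(ipoly) != 1) .parse_err(path, ip, "missing POLYGONS section")
  hdr <- as.integer(strsplit(trimws(lines[ipoly]), "\\s+")[[1]][2:3])
  nf <- hdr[1]
  fv <- scan(text = lines[(ipoly + 1):length(lines)], n = hdr[2], quiet = TRUE)
  fv <- matrix(fv, nf, hdr[2] / nf, byrow = TRUE)
  if (ncol(fv) != 4 || any(fv[, 1] != 3)) {
    .parse_err(path, ipoly, "only triangle polygons are supported")
  }
  .finish_mesh(verts, matrix(as.integer(fv[, 2:4] + 1L), nf, 3))
}

#' @rdname read_mesh
#' @param mesh A `platelet_mesh`.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  v <- format(mesh$vertices, digits = 17, scientific = TRUE, trim = TRUE)
  vlines <- paste(v[, 1], v[, 2], v[, 3])
  t0 <- mesh$triangles - 1L
  flines <- paste(3, t0[, 1], t0[, 2], t0[, 3])
  out <- switch(format,
    off = c("OFF",
            paste(nrow(mesh$vertices), nrow(mesh$triangles), nrow(mesh$edges)),
            vlines, flines),
    vtk = c("# vtk DataFile Version 2.0",
            "platelet surface mesh", "ASCII", "DATASET POLYDATA",
            paste("POINTS", nrow(mesh$vertices), "double"), vlines,
            paste("POLYGONS", nrow(mesh$triangles), 4 * nrow(mesh$triangles)),
            flines),
    stop("unsupported mesh format: ", format)
  )
  writeLines(out, path)
  invisible(path)
}

#' Export receptor sites as CSV
#'
#' Columns: `site`, `triangle`, barycentric `u`/`v`, `n_receptors`.
#' @param mesh A `platelet_mesh` with receptors placed.
#' @param path Output CSV path.
#' @export
write_receptor_sites <- function(mesh, path) {
  utils::write.csv(mesh$receptors, path, row.names = FALSE)
  invisible(path)
}
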