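#' Write a surface mesh as STL
#'
#' STL carries no attributes, so region tags are written to a JSON sidecar
#' (see [write_region_tags()]); coordinates are written in mm as stored.
#'
#' @param mesh a `surface_mesh`.
#' @param path output file path.
#' @param binary write binary STL (default) or ASCII.
#' @param tags also write `<path>.tags.json` with the region tags and neck
#'   plane (default TRUE).
#' @return the path, invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE, tags = TRUE) {
  v <- mesh$vertices
  tr <- mesh$triangles
  nrm <- triangle_normals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nrow(tr)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(tr))) {
      writeBin(as.numeric(c(nrm[i, ], t(v[tr[i, ], ]))), con,
               size = 4, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid hemoflow", con)
    for (i in seq_len(nrow(tr))) {
      writeLines(sprintf("facet normal %.9e %.9e %.9e",
                         nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
      writeLines("  outer loop", con)
      for (k in 1:3)
        writeLines(sprintf("    vertex %.9e %.9e %.9e",
                           v[tr[i, k], 1], v[tr[i, k], 2], v[tr[i, k], 3]), con)
      writeLines("  endloop", con)
      writeLines("endfacet", con)
    }
    writeLines("endsolid hemoflow", con)
  }
  if (tags) write_region_tags(mesh, paste0(path, ".tags.json"))
  invisible(path)
}

#' Read an STL surface (binary or ASCII)
#'
#' Vertices repeated across facets are merged exactly. If a
#' `<path>.tags.json` sidecar exists it is used for region tags and the neck
#' plane; otherwise every triangle is tagged `"wall"`.
#'
#' @param path STL file path.
#' @param validate passed to [surface_mesh()].
#' @return a `surface_mesh`.
#' @export
read_stl <- function(path, validate = TRUE) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  is_ascii <- identical(rawToChar(head[1:5]), "solid")
  if (!is_ascii) {
    nt <- readBin(con, "integer", 1, size = 4, endian = "little")
    raw_rest <- readBin(con, "raw", nt * 50)
    close(con)
    m <- matrix(raw_rest, nrow = 50)
    coords <- matrix(0, nt * 3, 3)
    for (i in seq_len(nt)) {
      vals <- readBin(m[13:48, i], "numeric", 9, size = 4, endian = "little")
      coords[(3 * i - 2):(3 * i), ] <- matrix(vals, 3, 3, byrow = TRUE)
    }
  } else {
    close(con)
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
    nt <- nrow(coords) / 3
  }
  key <- apply(coords, 1, paste, collapse = "_")
  uid <- !duplicated(key)
  verts <- coords[uid, , drop = FALSE]
  idx <- match(key, key[uid])
  tris <- matrix(idx, ncol = 3, byrow = TRUE)
  tagfile <- paste0(path, ".tags.json")
  tags <- rep("wall", nrow(tris))
  neck <- NULL
  if (file.exists(tagfile)) {
    side <- read_region_tags(tagfile)
    if (length(side$region_tags) == nrow(tris)) tags <- side$region_tags
    neck <- side$neck_plane
  }
  surface_mesh(verts, tris, tags, neck_plane = neck, validate = validate)
}

#' Write / read the region-tag sidecar (JSON)
#'
#' @param mesh a `surface_mesh`.
#' @param path JSON path.
#' @return the path (write) or a list with `region_tags` and `neck_plane`
#'   (read).
#' @export
write_region_tags <- function(mesh, path) {
  obj <- list(region_tags = mesh$region_tags)
  if (!is.null(mesh$neck_plane))
    obj$neck_plane <- list(point = mesh$neck_plane$point,
                           normal = mesh$neck_plane$normal)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_region_tags
#' @export
read_region_tags <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(region_tags = as.character(obj$region_tags), neck_plane = NULL)
  if (!is.null(obj$neck_plane))
    out$neck_plane <- list(point = as.numeric(obj$neck_plane$point),
                           normal = as.numeric(obj$neck_plane$normal))
  out
}

xml_data_array <- function(con, name, values, ncomp, type = "Float64") {
  writeLines(sprintf('<DataArray type="%s" Name="%s" NumberOfComponents="%d" format="ascii">',
                     type, name, ncomp), con)
  writeLines(paste(format(values, digits = 12, scientific = TRUE, trim = TRUE),
                   collapse = " "), con)
  writeLines("</DataArray>", con)
}

#' Write a surface mesh as VTK XML PolyData (.vtp)
#'
#' Region tags are written as integer cell data (`region_id`, with the
#' label mapping in the field data) so the round trip is lossless; optional
#' per-triangle or per-vertex scalar fields can be attached.
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @param cell_data optional named list of per-triangle numeric vectors.
#' @param point_data optional named list of per-vertex numeric vectors.
#' @return the path, invisibly.
#' @export
write_vtp <- function(mesh, path, cell_data = NULL, point_data = NULL) {
  v <- mesh$vertices
  tr <- mesh$triangles
  lev <- sort(unique(mesh$region_tags))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines('<?xml version="1.0"?>', con)
  writeLines('<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">', con)
  writeLines('<PolyData>', con)
  writeLines(sprintf('<Piece NumberOfPoints="%d" NumberOfPolys="%d">',
                     nrow(v), nrow(tr)), con)
  writeLines('<Points>', con)
  xml_data_array(con, "Points", as.vector(t(v)), 3)
  writeLines('</Points>', con)
  writeLines('<Polys>', con)
  xml_data_array(con, "connectivity", as.vector(t(tr)) - 1L, 1, "Int32")
  xml_data_array(con, "offsets", seq_len(nrow(tr)) * 3L, 1, "Int32")
  writeLines('</Polys>', con)
  writeLines('<CellData>', con)
  xml_data_array(con, "region_id", match(mesh$region_tags, lev) - 1L, 1, "Int32")
  for (nm in names(cell_data)) xml_data_array(con, nm, cell_data[[nm]], 1)
  writeLines('</CellData>', con)
  if (!is.null(point_data)) {
    writeLines('<PointData>', con)
    for (nm in names(point_data)) xml_data_array(con, nm, point_data[[nm]], 1)
    writeLines('</PointData>', con)
  }
  writeLines('</Piece>', con)
  writeLines(sprintf('<!-- region levels: %s -->', paste(lev, collapse = ",")), con)
  writeLines('</PolyData>', con)
  writeLines('</VTKFile>', con)
  invisible(path)
}

#' Write a volume mesh as VTK XML UnstructuredGrid (.vtu)
#'
#' @param vmesh a `volume_mesh`.
#' @param path output path.
#' @param point_data optional named list of per-vertex numeric vectors
#'   (length n or n x 3 matrices, written with 3 components).
#' @return the path, invisibly.
#' @export
write_vtu <- function(vmesh, path, point_data = NULL) {
  v <- vmesh$vertices
  tt <- vmesh$tets
  con <- file(path, "w")
  on.exit(close(con))
  writeLines('<?xml version="1.0"?>', con)
  writeLines('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">', con)
  writeLines('<UnstructuredGrid>', con)
  writeLines(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">',
                     nrow(v), nrow(tt)), con)
  writeLines('<Points>', con)
  xml_data_array(con, "Points", as.vector(t(v)), 3)
  writeLines('</Points>', con)
  writeLines('<Cells>', con)
  xml_data_array(con, "connectivity", as.vector(t(tt)) - 1L, 1, "Int32")
  xml_data_array(con, "offsets", seq_len(nrow(tt)) * 4L, 1, "Int32")
  xml_data_array(con, "types", rep(10L, nrow(tt)), 1, "UInt8")
  writeLines('</Cells>', con)
  if (!is.null(point_data)) {
    writeLines('<PointData>', con)
    for (nm in names(point_data)) {
      val <- point_data[[nm]]
      if (is.matrix(val)) xml_data_array(con, nm, as.vector(t(val)), ncol(val))
      else xml_data_array(con, nm, val, 1)
    }
    writeLines('</PointData>', con)
  }
  writeLines('</Piece>', con)
  writeLines('</UnstructuredGrid>', con)
  writeLines('</VTKFile>', con)
  invisible(path)
}
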