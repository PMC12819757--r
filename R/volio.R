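#' Write a volume grid to NIfTI
#'
#' Geometry convention: voxel sizes go in `pixdim`, the world position of the
#' centre of voxel (1,1,1) in the sform translation (code 2), spatial units
#' mm. 4-D (component-last) volumes are written as 4-D NIfTI. Complex volumes
#' must be written via [write_complex_volume()] (paired real/imag files).
#'
#' @param grid a [volume_grid()].
#' @param path output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "volume_grid"))
  if (is.complex(grid$values))
    stop("complex volumes are stored as paired files; use write_complex_volume()")
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  vals <- grid$values
  storage.mode(vals) <- "double"
  img <- RNifti::asNifti(vals)
  RNifti::`pixdim<-`(img, grid$spacing) -> img
  m <- diag(c(grid$spacing, 1))
  m[1:3, 4] <- grid$origin
  RNifti::`sform<-`(img, structure(m, code = 2L)) -> img
  RNifti::`pixunits<-`(img, c("mm", "s")) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume into a volume grid
#'
#' Requires mm spatial units (unknown units are accepted and assumed mm).
#' Spacing is taken from `pixdim`, origin from the sform translation; rotated
#' or axis-permuted sforms are rejected rather than silently reinterpreted.
#'
#' @param path NIfTI file path.
#' @return A [volume_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  un <- RNifti::pixunits(img)[1]
  if (!un %in% c("mm", "Unknown"))
    stop("volume ", path, " has spatial units '", un, "'; only mm is supported")
  d <- dim(img)
  if (!(length(d) %in% c(3L, 4L)))
    stop("expected a 3-D or 4-D volume, got ", length(d), "-D: ", path)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  sp <- RNifti::pixdim(img)[1:3]
  if (any(abs(rot - diag(sp)) > 1e-4 * max(sp)))
    stop("volume ", path, " has a rotated or permuted orientation matrix; ",
         "re-orient to the project axis convention before reading")
  vals <- array(as.numeric(img), d)
  volume_grid(vals, sp, xf[1:3, 4])
}

#' Write / read a complex volume as paired real and imaginary NIfTI files
#'
#' `enc_{direction}_real.nii.gz` / `enc_{direction}_imag.nii.gz` naming is
#' used by the pipeline; any `*_real*` / `*_imag*` pair works here.
#'
#' @param vol a [complex_volume()].
#' @param real_path,imag_path output/input paths for the two parts.
#' @param direction,lambda encoding direction and wavelength (mm) for reading.
#' @return Paths (write) or a [complex_volume()] (read).
#' @export
write_complex_volume <- function(vol, real_path, imag_path) {
  stopifnot(inherits(vol, "complex_volume"))
  g <- vol$grid
  write_volume(grid_with_values(g, array(Re(g$values), dim(g$values))), real_path)
  write_volume(grid_with_values(g, array(Im(g$values), dim(g$values))), imag_path)
  invisible(c(real_path, imag_path))
}

#' @rdname write_complex_volume
#' @export
read_complex_volume <- function(real_path, imag_path, direction, lambda) {
  if (!file.exists(imag_path))
    stop("complex volume expected a real/imaginary pair but the imaginary ",
         "part is missing: ", imag_path)
  re <- read_volume(real_path)
  im <- read_volume(imag_path)
  if (!grid_same_geometry(re, im)) stop_geometry_mismatch(re, im, "real/imag parts")
  complex_volume(grid_with_values(re, array(complex(real = re$values,
                                                    imaginary = im$values),
                                            dim(re$values))),
                 direction, lambda)
}

#' Write a surface mesh to binary STL
#'
#' @param mesh a `surface_mesh` (see [extract_surface_mesh()]).
#' @param path output `.stl` path.
#' @return `path`, invisibly.
#' @export
write_mesh_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(nrm^2))
  deg <- len < 1e-14
  if (any(deg))
    stop("degenerate (zero-area) triangle at index ", which(deg)[1])
  nrm <- nrm / len
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  writeBin(as.integer(nrow(tr)), con, size = 4L, endian = "little")
  # 12 floats per facet (normal + 3 vertices) + 2-byte attribute count
  dat <- t(cbind(nrm,
                 v[tr[, 1], , drop = FALSE],
                 v[tr[, 2], , drop = FALSE],
                 v[tr[, 3], , drop = FALSE]))
  for (i in seq_len(nrow(tr))) {
    writeBin(as.numeric(dat[, i]), con, size = 4L, endian = "little")
    writeBin(as.integer(0L), con, size = 2L, endian = "little")
  }
  invisible(path)
}

vtu_da <- function(name, values, ncomp, type = "Float64") {
  sprintf('<DataArray type="%s" Name="%s" NumberOfComponents="%d" format="ascii">\n%s\n</DataArray>',
          type, name, ncomp,
          paste(format(values, digits = 17, scientific = TRUE, trim = TRUE),
                collapse = " "))
}

#' Write a mesh with nodal fields to VTU (VTK unstructured grid, ASCII XML)
#'
#' Accepts a `tet_mesh` (cells written as VTK tetrahedra, type 10) or a
#' `surface_mesh` (triangles, type 5). `point_data` is a named list of nodal
#' fields: numeric vectors (scalars) or matrices with one row per node.
#'
#' @param mesh a `tet_mesh` or `surface_mesh`.
#' @param path output `.vtu` path.
#' @param point_data named list of per-node fields.
#' @return `path`, invisibly.
#' @export
write_mesh_vtu <- function(mesh, path, point_data = list()) {
  if (inherits(mesh, "tet_mesh")) {
    cells <- mesh$tets; vtk_type <- 10L; coords <- mesh$nodes
    if (!is.null(mesh$displacement) && is.null(point_data$displacement))
      point_data$displacement <- mesh$displacement
  } else if (inherits(mesh, "surface_mesh")) {
    cells <- mesh$triangles; vtk_type <- 5L; coords <- mesh$vertices
  } else stop("mesh must be a tet_mesh or surface_mesh")
  npts <- nrow(coords); ncell <- nrow(cells); k <- ncol(cells)
  pd <- ""
  if (length(point_data)) {
    das <- vapply(names(point_data), function(nm) {
      f <- point_data[[nm]]
      if (is.matrix(f)) {
        stopifnot(nrow(f) == npts)
        vtu_da(nm, as.vector(t(f)), ncol(f))
      } else {
        stopifnot(length(f) == npts)
        vtu_da(nm, f, 1L)
      }
    }, character(1))
    pd <- paste0("<PointData>\n", paste(das, collapse = "\n"), "\n</PointData>\n")
  }
  xml <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">\n',
    '<UnstructuredGrid>\n',
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">\n', npts, ncell),
    "<Points>\n", vtu_da("Points", as.vector(t(coords)), 3L), "\n</Points>\n",
    pd,
    "<Cells>\n",
    vtu_da("connectivity", as.vector(t(cells)) - 1L, 1L, "Int64"), "\n",
    vtu_da("offsets", seq_len(ncell) * k, 1L, "Int64"), "\n",
    vtu_da("types", rep(vtk_type, ncell), 1L, "UInt8"), "\n",
    "</Cells>\n</Piece>\n</UnstructuredGrid>\n</VTKFile>\n")
  writeLines(xml, path)
  invisible(path)
}

#' Read back a VTU file written by [write_mesh_vtu()]
#'
#' @param path `.vtu` path.
#' @return A list with `nodes`, `cells`, `cell_type` and `point_data`.
#' @export
read_mesh_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  get_da <- function(xpath) {
    nd <- xml2::xml_find_first(piece, xpath)
    if (is.na(nd)) return(NULL)
    list(values = as.numeric(strsplit(trimws(xml2::xml_text(nd)), "\\s+")[[1]]),
         ncomp = as.integer(xml2::xml_attr(nd, "NumberOfComponents")))
  }
  pts <- get_da(".//Points/DataArray")
  nodes <- matrix(pts$values, ncol = 3L, byrow = TRUE)
  conn <- get_da(".//Cells/DataArray[@Name='connectivity']")$values
  offs <- get_da(".//Cells/DataArray[@Name='offsets']")$values
  k <- offs[1]
  cells <- matrix(as.integer(conn) + 1L, ncol = k, byrow = TRUE)
  type <- get_da(".//Cells/DataArray[@Name='types']")$values[1]
  pd_nodes <- xml2::xml_find_all(piece, ".//PointData/DataArray")
  point_data <- list()
  for (nd in pd_nodes) {
    nm <- xml2::xml_attr(nd, "Name")
    nc <- as.integer(xml2::xml_attr(nd, "NumberOfComponents"))
    v <- as.numeric(strsplit(trimws(xml2::xml_text(nd)), "\\s+")[[1]])
    point_data[[nm]] <- if (nc > 1L) matrix(v, ncol = nc, byrow = TRUE) else v
  }
  list(nodes = nodes, cells = cells, cell_type = type, point_data = point_data)
}

#' Write a results table to CSV (RFC 4180, '.' decimal)
#'
#' @param records a data frame / tibble.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
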