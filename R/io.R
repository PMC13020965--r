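#' Read / write XYZ point-cloud text files
#'
#' Whitespace- or comma-delimited text with three numeric columns (mm);
#' comment lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return A [point_cloud()].
#' @export
read_xyz <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^\\s*(#|$)", txt)]
  m <- do.call(rbind, lapply(strsplit(trimws(txt), "[[:space:],]+"), function(s)
    as.numeric(s[nzchar(s)])))
  .stop_if(ncol(m) < 3 || anyNA(m[, 1:3]), "expected 3 numeric columns in %s", path)
  point_cloud(m[, 1:3, drop = FALSE])
}

#' @rdname read_xyz
#' @param cloud a [point_cloud()].
#' @export
write_xyz <- function(cloud, path) {
  stopifnot(inherits(cloud, "lapw_point_cloud"))
  writeLines(sprintf("%.10g %.10g %.10g", cloud$points[, 1], cloud$points[, 2],
                     cloud$points[, 3]), path)
  invisible(path)
}

#' Write a surface mesh as ASCII STL
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param name solid name.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, name = "surface") {
  stopifnot(inherits(mesh, "lapw_surface"))
  fn <- .face_normals(mesh$vertices, mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (i in seq_len(nrow(mesh$triangles))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", fn[i, 1], fn[i, 2], fn[i, 3]), con)
    writeLines("    outer loop", con)
    for (k in 1:3) {
      v <- mesh$vertices[mesh$triangles[i, k], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", v[1], v[2], v[3]), con)
    }
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' Read an STL surface (ASCII or binary)
#'
#' Vertices are merged exactly (identical coordinates); windings are kept as
#' stored.
#'
#' @param path STL file.
#' @return A [surface_mesh()].
#' @export
read_stl <- function(path) {
  head_bytes <- readBin(path, "raw", 80)
  is_ascii <- grepl("^solid", rawToChar(head_bytes[1:5]))
  if (is_ascii) {
    txt <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex", txt, value = TRUE)
    vm <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                                function(s) as.numeric(s[2:4])))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    nt <- readBin(con, "integer", 1, size = 4, endian = "little")
    vm <- matrix(0, 3 * nt, 3)
    for (i in seq_len(nt)) {
      readBin(con, "numeric", 3, size = 4, endian = "little")  # facet normal
      for (k in 1:3)
        vm[3 * (i - 1) + k, ] <- readBin(con, "numeric", 3, size = 4, endian = "little")
      readBin(con, "raw", 2)
    }
  }
  key <- apply(vm, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- vm[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  tris <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(verts, tris)
}

#' Write a volume mesh as a legacy-VTK unstructured grid (ASCII)
#'
#' Stores the tetrahedra, the element field `subdomain`, optional element
#' vector fields (e.g. fiber triads) and optional point fields (e.g. the
#' transmural coordinate).
#'
#' @param mesh a [volume_mesh()].
#' @param path output path (`.vtk`).
#' @param cell_vectors named list of `E x 3` matrices.
#' @param point_scalars named list of length-V vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_vectors = list(), point_scalars = list()) {
  stopifnot(inherits(mesh, "lapw_volume_mesh"))
  v <- mesh$vertices; tets <- mesh$tets
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "lapwsim volume mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(apply(v, 1, function(p) paste(format(p, digits = 12), collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", nrow(tets), 5 * nrow(tets)), con)
  writeLines(apply(tets - 1L, 1, function(t) paste(c(4, t), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(tets)), con)
  writeLines(rep("10", nrow(tets)), con)
  if (!is.null(mesh$transmural)) point_scalars$transmural <- mesh$transmural
  if (length(point_scalars)) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    for (nm in names(point_scalars)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(point_scalars[[nm]], digits = 12), con)
    }
  }
  writeLines(sprintf("CELL_DATA %d", nrow(tets)), con)
  writeLines(c("SCALARS subdomain int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$subdomain), con)
  for (nm in names(cell_vectors)) {
    writeLines(sprintf("VECTORS %s double", nm), con)
    writeLines(apply(cell_vectors[[nm]], 1,
                     function(p) paste(format(p, digits = 12), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a legacy-VTK unstructured grid written by [write_vtk()]
#'
#' @param path `.vtk` file.
#' @return A [volume_mesh()] with attribute `cell_vectors` (named list) when
#'   vector fields are present.
#' @export
read_vtk <- function(path) {
  txt <- readLines(path)
  num <- function(line) as.numeric(strsplit(trimws(line), "\\s+")[[1]])
  ip <- grep("^POINTS", txt)[1]
  np <- as.integer(strsplit(txt[ip], "\\s+")[[1]][2])
  verts <- do.call(rbind, lapply(txt[(ip + 1):(ip + np)], num))
  ic <- grep("^CELLS", txt)[1]
  nc <- as.integer(strsplit(txt[ic], "\\s+")[[1]][2])
  cells <- do.call(rbind, lapply(txt[(ic + 1):(ic + nc)], num))
  .stop_if(any(cells[, 1] != 4), "only tetrahedral cells are supported")
  tets <- cells[, 2:5, drop = FALSE] + 1L
  sub <- NULL; tm <- NULL
  isub <- grep("^SCALARS subdomain", txt)
  if (length(isub)) sub <- as.integer(txt[(isub[1] + 2):(isub[1] + 1 + nc)])
  itm <- grep("^SCALARS transmural", txt)
  if (length(itm)) tm <- as.numeric(txt[(itm[1] + 2):(itm[1] + 1 + np)])
  mesh <- volume_mesh(verts, tets, sub, tm)
  iv <- grep("^VECTORS", txt)
  if (length(iv)) {
    cv <- list()
    for (i in iv) {
      nm <- strsplit(txt[i], "\\s+")[[1]][2]
      cv[[nm]] <- do.call(rbind, lapply(txt[(i + 1):(i + nc)], num))
    }
    attr(mesh, "cell_vectors") <- cv
  }
  mesh
}

#' Write / read an EGM set as CSV plus JSON sidecar
#'
#' The CSV holds time (ms) in the first column and one column per electrode;
#' the sidecar (same path with `.json` appended) records electrode
#' coordinates, provenance, the sample rate and any filter settings.
#'
#' @param set an [egm_set()].
#' @param path CSV path.
#' @param meta extra metadata to store in the sidecar.
#' @return `path`, invisibly.
#' @export
write_egm_csv <- function(set, path, meta = list()) {
  stopifnot(inherits(set, "egm_set"))
  df <- data.frame(time_ms = set$time, set$phi)
  names(df) <- c("time_ms", sprintf("electrode_%d", seq_len(ncol(set$phi))))
  write.csv(df, path, row.names = FALSE)
  sidecar <- c(list(electrodes = unname(apply(set$electrodes, 1, as.numeric, simplify = FALSE)),
                    provenance = set$provenance, sample_rate = set$sample_rate), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_egm_csv
#' @export
read_egm_csv <- function(path) {
  df <- read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  el <- if (is.matrix(side$electrodes)) side$electrodes
        else do.call(rbind, lapply(side$electrodes, as.numeric))
  egm_set(df$time_ms, as.matrix(df[, -1, drop = FALSE]), el,
          provenance = side$provenance, sample_rate = side$sample_rate)
}
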