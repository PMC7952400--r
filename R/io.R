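#' Read and write image volumes as NIfTI-1
#'
#' Volumes are stored with an axis-aligned affine (spacing on the diagonal,
#' origin in the translation column); gzipped files are supported. Masks
#' are written as 0/1 volumes and re-binarised on read.
#'
#' @param image an \linkS4class{ImageVolume} or \linkS4class{BinaryMask}.
#' @param file path ending in .nii or .nii.gz.
#' @param frame frame index to attach on read.
#' @param mask read as a \linkS4class{BinaryMask}.
#' @return \code{readNiftiVolume} returns an \linkS4class{ImageVolume} (or
#'   \linkS4class{BinaryMask}); \code{writeNiftiVolume} the file path,
#'   invisibly.
#' @export
writeNiftiVolume <- function(image, file) {
  stopifnot(is(image, "ImageVolume"))
  a <- voxels(image)
  if (is.logical(a)) a <- array(as.double(a), dim = dim(a))
  attr(a, "pixdim") <- voxelSpacing(image)
  img <- RNifti::asNifti(a, datatype = "double")
  aff <- rbind(cbind(diag(voxelSpacing(image)), worldOrigin(image)),
               c(0, 0, 0, 1))
  RNifti::`qform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' @rdname writeNiftiVolume
#' @export
readNiftiVolume <- function(file, frame = 0L, mask = FALSE) {
  img <- RNifti::readNifti(file)
  aff <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- aff[1:3, 4]
  dat <- array(as.double(img), dim = dim(img))
  if (mask)
    BinaryMask(array(dat > 0.5, dim = dim(dat)), spacing = spacing,
               origin = origin, frame = frame)
  else
    ImageVolume(dat, spacing = spacing, origin = origin, frame = frame)
}

#' Read and write surface meshes (ASCII PLY and legacy VTK)
#'
#' Minimal readers/writers for triangle meshes: ASCII PLY 1.0
#' (element/property header, vertex and face lists) and legacy VTK
#' POLYDATA. AHA labels, when present, are stored as a PLY face property
#' \code{label} / a VTK CELL_DATA scalar.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param file output path.
#' @return \code{readMeshPLY} returns a \linkS4class{SurfaceMesh}; the
#'   writers return the path invisibly.
#' @export
writeMeshPLY <- function(mesh, file) {
  v <- meshVertices(mesh)
  f <- meshTriangles(mesh) - 1L
  lab <- ahaLabels(mesh)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               if (!is.null(lab)) "property int label",
               "end_header"), con)
  writeLines(sprintf("%.8g %.8g %.8g", v[, 1], v[, 2], v[, 3]), con)
  if (is.null(lab))
    writeLines(sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  else
    writeLines(sprintf("3 %d %d %d %d", f[, 1], f[, 2], f[, 3], lab), con)
  invisible(file)
}

#' @rdname writeMeshPLY
#' @export
readMeshPLY <- function(file) {
  lines <- readLines(file)
  endh <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  hasLab <- any(grepl("^property int label", lines[seq_len(endh)]))
  vl <- lines[endh + seq_len(nv)]
  v <- matrix(as.numeric(unlist(strsplit(vl, " "))), ncol = 3, byrow = TRUE)
  fl <- lines[endh + nv + seq_len(nf)]
  parts <- strsplit(fl, " ")
  f <- t(vapply(parts, function(p) as.integer(p[2:4]), integer(3))) + 1L
  lab <- if (hasLab)
    vapply(parts, function(p) as.integer(p[5]), integer(1)) else NULL
  SurfaceMesh(v, f, lab)
}

#' @rdname writeMeshPLY
#' @export
writeMeshVTK <- function(mesh, file) {
  v <- meshVertices(mesh)
  f <- meshTriangles(mesh) - 1L
  lab <- ahaLabels(mesh)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "endocardial surface", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(v))), con)
  writeLines(sprintf("%.8g %.8g %.8g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)), con)
  writeLines(sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  if (!is.null(lab)) {
    writeLines(c(sprintf("CELL_DATA %d", nrow(f)),
                 "SCALARS label int 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%d", lab), con)
  }
  invisible(file)
}

#' Read and write landmark sets as CSV
#'
#' Plain CSV with columns \code{name, x, y, z, frame}.
#'
#' @param landmarks a \linkS4class{LandmarkSet} or list of them (one per
#'   frame).
#' @param file CSV path.
#' @return \code{readLandmarks} returns a list of per-frame
#'   \linkS4class{LandmarkSet}s (a single set if only one frame is
#'   present); writers return the path invisibly.
#' @export
writeLandmarks <- function(landmarks, file) {
  if (is(landmarks, "LandmarkSet")) landmarks <- list(landmarks)
  df <- do.call(rbind, lapply(landmarks, function(l) {
    p <- landmarkPoints(l)
    data.frame(name = rownames(p), x = p[, 1], y = p[, 2], z = p[, 3],
               frame = frameIndex(l))
  }))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeLandmarks
#' @export
readLandmarks <- function(file) {
  df <- read.csv(file)
  out <- lapply(split(df, df$frame), function(d) {
    m <- unname(as.matrix(d[, c("x", "y", "z")]))
    rownames(m) <- d$name
    LandmarkSet(m, frame = d$frame[1])
  })
  if (length(out) == 1L) out[[1]] else unname(out)
}

#' Write strain curves and bullseye tables as CSV
#'
#' \code{writeStrainCurves} writes the tidy (frame, time, segment, metric,
#' value) table. \code{writeBullseye} writes one 16-value row per frame for
#' a chosen metric, mirroring a 16-segment bullseye display.
#'
#' @param curveSet a \linkS4class{StrainCurveSet}.
#' @param file CSV path.
#' @param metric one of \code{E_cc}, \code{E_zz}, \code{area_ratio},
#'   \code{squeez}.
#' @return the path, invisibly.
#' @export
writeStrainCurves <- function(curveSet, file) {
  write.csv(curveTable(curveSet), file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeStrainCurves
#' @export
writeBullseye <- function(curveSet, file, metric = "E_cc") {
  cv <- curveTable(curveSet)
  cv <- cv[cv$metric == metric, ]
  wide <- do.call(rbind, lapply(split(cv, cv$frame), function(d) {
    d <- d[order(d$segment), ]
    setNames(as.data.frame(rbind(d$value)),
             paste0("segment_", d$segment))
  }))
  wide <- cbind(frame = sort(unique(cv$frame)), wide)
  write.csv(wide, file, row.names = FALSE)
  invisible(file)
}

#' Serialise transforms to a JSON container
#'
#' Stores grid geometry and displacement arrays (column-major, with dims)
#' for an \linkS4class{FfdTransform} or a dense
#' \linkS4class{DisplacementField} in a single self-describing JSON file.
#'
#' @param transform an \linkS4class{FfdTransform} or
#'   \linkS4class{DisplacementField}.
#' @param file JSON path.
#' @return \code{readTransform} returns the stored object; the writer
#'   returns the path invisibly.
#' @export
writeTransform <- function(transform, file) {
  if (is(transform, "FfdTransform")) {
    obj <- list(
      type = "ffd",
      domain = transform@domain,
      hyper = transform@hyper,
      grids = lapply(transform@grids, function(fr) lapply(fr, function(g) list(
        dim = dim(controlPoints(g)), spacing = g@spacing,
        origin = worldOrigin(g), level = g@level,
        phi = as.numeric(controlPoints(g))))))
  } else if (is(transform, "DisplacementField")) {
    obj <- list(type = "dense", dim = dim(fieldArray(transform)),
                spacing = voxelSpacing(transform),
                origin = worldOrigin(transform),
                field = as.numeric(fieldArray(transform)))
  } else stop("unsupported transform type")
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeTransform
#' @export
readTransform <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  if (obj$type == "dense") {
    DisplacementField(array(num(obj$field), dim = num(obj$dim)),
                      spacing = num(obj$spacing), origin = num(obj$origin))
  } else {
    rebuild <- function(g) new("ControlPointGrid",
                               phi = array(num(g$phi), dim = num(g$dim)),
                               spacing = num(g$spacing),
                               origin = num(g$origin),
                               level = as.integer(g$level))
    gridList <- lapply(obj$grids, function(fr) lapply(fr, rebuild))
    new("FfdTransform", grids = gridList,
        domain = list(dim = as.integer(num(obj$domain$dim)),
                      origin = num(obj$domain$origin),
                      spacing = num(obj$domain$spacing)),
        hyper = lapply(obj$hyper, function(x)
          if (is.list(x)) unlist(x) else x),
        trace = numeric(0))
  }
}
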