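# Readers/writers for the interchange formats used across the pipeline.
# PLY is the canonical format (double-precision, carries normals); STL and OBJ
# are supported for interop with clinical meshing tools; XYZ for plain clouds.
# Units are millimetres and are never read from or written to files.

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

parse_ply_header <- function(raw) {
  end_pat <- charToRaw("end_header")
  idx <- which(raw == end_pat[1])
  pos <- NA_integer_
  for (i in idx) {
    if (i + length(end_pat) - 1L <= length(raw) &&
        identical(raw[i:(i + length(end_pat) - 1L)], end_pat)) { pos <- i; break }
  }
  if (is.na(pos)) stop("not a PLY file (no end_header)", call. = FALSE)
  nl <- pos + length(end_pat)
  while (nl <= length(raw) && raw[nl] != as.raw(10L)) nl <- nl + 1L
  header <- strsplit(rawToChar(raw[1:(pos - 1L)]), "\r?\n")[[1]]
  if (!grepl("^ply", header[1])) stop("not a PLY file", call. = FALSE)
  fmt_line <- grep("^format", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  list(format = fmt, elements = elements, body_start = nl + 1L)
}

read_ply <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (!length(raw)) stop(sprintf("format error: empty file '%s'", path), call. = FALSE)
  hd <- parse_ply_header(raw)
  ve <- hd$elements[["vertex"]]
  if (is.null(ve)) stop(sprintf("format error: no vertex element in '%s'", path), call. = FALSE)
  pnames <- vapply(ve$props, function(p) p$name, "")
  if (!all(c("x", "y", "z") %in% pnames))
    stop(sprintf("format error: vertex element lacks x/y/z in '%s'", path), call. = FALSE)
  fe <- hd$elements[["face"]]
  if (hd$format == "ascii") {
    body <- strsplit(rawToChar(raw[hd$body_start:length(raw)]), "\r?\n")[[1]]
    body <- body[nzchar(trimws(body))]
    vlines <- body[seq_len(ve$count)]
    vt <- matrix(as.numeric(unlist(strsplit(trimws(vlines), "\\s+"))),
                 nrow = ve$count, byrow = TRUE)
    vmat <- vt[, match(c("x", "y", "z"), pnames), drop = FALSE]
    nmat <- if (all(c("nx", "ny", "nz") %in% pnames))
      vt[, match(c("nx", "ny", "nz"), pnames), drop = FALSE] else NULL
    faces <- NULL
    if (!is.null(fe) && fe$count > 0L) {
      flines <- body[ve$count + seq_len(fe$count)]
      fl <- strsplit(trimws(flines), "\\s+")
      cnt <- vapply(fl, function(t) as.integer(t[1]), 1L)
      if (any(cnt != 3L))
        stop(sprintf("format error: non-triangular faces in '%s'", path), call. = FALSE)
      faces <- matrix(as.integer(unlist(lapply(fl, function(t) t[2:4]))),
                      ncol = 3, byrow = TRUE) + 1L
    }
  } else if (hd$format == "binary_little_endian") {
    types <- vapply(ve$props, function(p) p$type, "")
    if (length(unique(types)) != 1L)
      stop(sprintf("format error: mixed vertex property types in '%s'", path), call. = FALSE)
    sz <- ply_type_size[[types[1]]]
    np <- length(ve$props)
    nbytes <- ve$count * np * sz
    what <- if (types[1] %in% c("float", "float32", "double", "float64")) "double" else "integer"
    vals <- readBin(raw[hd$body_start:(hd$body_start + nbytes - 1L)], what,
                    n = ve$count * np, size = sz, endian = "little")
    vt <- matrix(vals, nrow = ve$count, byrow = TRUE)
    vmat <- vt[, match(c("x", "y", "z"), pnames), drop = FALSE]
    nmat <- if (all(c("nx", "ny", "nz") %in% pnames))
      vt[, match(c("nx", "ny", "nz"), pnames), drop = FALSE] else NULL
    faces <- NULL
    if (!is.null(fe) && fe$count > 0L) {
      fp <- fe$props[[1]]
      if (!fp$list) stop(sprintf("format error: face element has no index list in '%s'", path), call. = FALSE)
      csz <- ply_type_size[[fp$count_type]]
      isz <- ply_type_size[[fp$type]]
      rec <- csz + 3L * isz
      off <- hd$body_start + nbytes
      fraw <- raw[off:(off + fe$count * rec - 1L)]
      fm <- matrix(fraw, nrow = rec)
      cnt <- as.integer(fm[1, ])  # count byte(s); assume count fits first byte
      if (any(cnt != 3L))
        stop(sprintf("format error: non-triangular faces in '%s'", path), call. = FALSE)
      ib <- as.vector(fm[(csz + 1L):rec, ])
      faces <- matrix(readBin(ib, "integer", n = 3L * fe$count, size = isz,
                              endian = "little"),
                      ncol = 3, byrow = TRUE) + 1L
    }
  } else stop(sprintf("format error: unsupported PLY format '%s'", hd$format), call. = FALSE)
  if (anyNA(vmat) || !all(is.finite(vmat)))
    stop(sprintf("format error: non-finite coordinates in '%s'", path), call. = FALSE)
  list(vertices = vmat, faces = faces, normals = nmat)
}

write_ply <- function(path, vertices, faces = NULL, normals = NULL, binary = TRUE) {
  con <- file(path, "wb")
  on.exit(close(con))
  np <- nrow(vertices)
  nf <- if (is.null(faces)) 0L else nrow(faces)
  props <- c("x", "y", "z", if (!is.null(normals)) c("nx", "ny", "nz"))
  hdr <- c("ply",
           sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", np),
           sprintf("property double %s", props),
           if (nf > 0L) c(sprintf("element face %d", nf),
                          "property list uchar int vertex_indices"),
           "end_header")
  writeLines(hdr, con)
  vdata <- if (is.null(normals)) vertices else cbind(vertices, normals)
  if (binary) {
    writeBin(as.numeric(t(vdata)), con, size = 8, endian = "little")
    if (nf > 0L) {
      ib <- writeBin(as.integer(t(faces) - 1L), raw(), size = 4, endian = "little")
      rec <- rbind(as.raw(3L), matrix(ib, nrow = 12L))
      writeBin(as.vector(rec), con)
    }
  } else {
    writeLines(apply(vdata, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
    if (nf > 0L)
      writeLines(paste(3L, faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L), con)
  }
  invisible(NULL)
}

weld_vertices <- function(vertices, faces, tol = 1e-6) {
  key <- apply(round(vertices / tol) * tol, 1, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  new_v <- vertices[first, , drop = FALSE]
  new_f <- matrix(map[faces], ncol = 3)
  list(vertices = new_v, faces = new_f)
}

read_stl <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 84L) {
    txt <- rawToChar(raw)
    if (!grepl("facet", txt))
      stop(sprintf("format error: empty or truncated STL '%s'", path), call. = FALSE)
  }
  is_ascii <- length(raw) >= 5L && identical(rawToChar(raw[1:5]), "solid") &&
    grepl("facet", rawToChar(head(raw, 2000L)))
  if (is_ascii) {
    lines <- strsplit(rawToChar(raw), "\r?\n")[[1]]
    vlines <- grep("^\\s*vertex", lines, value = TRUE)
    if (!length(vlines)) stop(sprintf("format error: no facets in '%s'", path), call. = FALSE)
    vals <- as.numeric(unlist(lapply(strsplit(trimws(vlines), "\\s+"),
                                     function(t) t[2:4])))
    verts <- matrix(vals, ncol = 3, byrow = TRUE)
  } else {
    ntri <- readBin(raw[81:84], "integer", size = 4, endian = "little")
    if (length(raw) < 84L + ntri * 50L)
      stop(sprintf("format error: truncated binary STL '%s'", path), call. = FALSE)
    recs <- matrix(raw[85:(84L + ntri * 50L)], nrow = 50L)
    vb <- as.vector(recs[13:48, ])  # 9 floats per facet, after the normal
    verts <- matrix(readBin(vb, "double", n = 9L * ntri, size = 4,
                            endian = "little"),
                    ncol = 3, byrow = TRUE)
  }
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  weld_vertices(verts, faces)
}

write_stl <- function(path, vertices, faces) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("skullrec binary STL"), raw(80 - 19)), con)
  nf <- nrow(faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  n <- cbind(
    (v2[, 2] - v1[, 2]) * (v3[, 3] - v1[, 3]) - (v2[, 3] - v1[, 3]) * (v3[, 2] - v1[, 2]),
    (v2[, 3] - v1[, 3]) * (v3[, 1] - v1[, 1]) - (v2[, 1] - v1[, 1]) * (v3[, 3] - v1[, 3]),
    (v2[, 1] - v1[, 1]) * (v3[, 2] - v1[, 2]) - (v2[, 2] - v1[, 2]) * (v3[, 1] - v1[, 1]))
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  fl <- writeBin(as.numeric(t(cbind(n, v1, v2, v3))), raw(), size = 4, endian = "little")
  fm <- matrix(fl, nrow = 48L)
  rec <- rbind(fm, as.raw(0L), as.raw(0L))
  writeBin(as.vector(rec), con)
  invisible(NULL)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  if (!length(vlines)) stop(sprintf("format error: no vertices in '%s'", path), call. = FALSE)
  verts <- matrix(as.numeric(unlist(lapply(strsplit(trimws(vlines), "\\s+"),
                                           function(t) t[2:4]))),
                  ncol = 3, byrow = TRUE)
  faces <- NULL
  if (length(flines)) {
    fl <- lapply(strsplit(trimws(flines), "\\s+"), function(t) {
      ix <- as.integer(sub("/.*$", "", t[-1]))
      if (length(ix) != 3L)
        stop(sprintf("format error: non-triangular faces in '%s'", path), call. = FALSE)
      ix
    })
    faces <- do.call(rbind, fl)
  }
  list(vertices = verts, faces = faces)
}

write_obj <- function(path, vertices, faces) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(vertices, 1, function(r)
    paste("v", paste(sprintf("%.17g", r), collapse = " "))), con)
  writeLines(paste("f", faces[, 1], faces[, 2], faces[, 3]), con)
  invisible(NULL)
}

#' Read a triangle mesh (PLY, STL, or OBJ)
#'
#' Dialect is auto-detected from the extension and header. STL per-facet
#' vertices are welded with tolerance 1e-6 mm.
#'
#' @param path file path.
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop(sprintf("I/O error: cannot read '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  parsed <- switch(ext,
    ply = read_ply(path),
    stl = read_stl(path),
    obj = read_obj(path),
    stop(sprintf("format error: unsupported mesh extension '%s'", ext), call. = FALSE))
  if (is.null(parsed$faces) || nrow(parsed$faces) == 0L)
    stop(sprintf("format error: mesh '%s' has no faces", path), call. = FALSE)
  if (nrow(parsed$vertices) == 0L)
    stop(sprintf("format error: mesh '%s' has no vertices", path), call. = FALSE)
  triangle_mesh(parsed$vertices, parsed$faces, parsed$normals)
}

#' Write a triangle mesh
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param format one of "ply_binary", "ply_ascii", "stl", "obj".
#' @export
write_mesh <- function(mesh, path, format = c("ply_binary", "ply_ascii", "stl", "obj")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  format <- match.arg(format)
  switch(format,
    ply_binary = write_ply(path, mesh$vertices, mesh$faces, mesh$vertex_normals, binary = TRUE),
    ply_ascii  = write_ply(path, mesh$vertices, mesh$faces, mesh$vertex_normals, binary = FALSE),
    stl = write_stl(path, mesh$vertices, mesh$faces),
    obj = write_obj(path, mesh$vertices, mesh$faces))
  invisible(path)
}

#' Read a point cloud (PLY or XYZ)
#'
#' @param path file path.
#' @return A [point_cloud()]; normals are read when the file carries them.
#' @export
read_cloud <- function(path) {
  if (!file.exists(path)) stop(sprintf("I/O error: cannot read '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    parsed <- read_ply(path)
    nm <- parsed$normals
    if (!is.null(nm)) {
      len <- sqrt(rowSums(nm^2))
      ok <- is.finite(len) & len > 0
      nm[ok, ] <- nm[ok, , drop = FALSE] / len[ok]
      nm[!ok, ] <- NA_real_
      if (all(!ok)) nm <- NULL
    }
    point_cloud(parsed$vertices, nm)
  } else if (ext == "xyz") {
    txt <- readLines(path, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(txt), "\\s+"))))
    if (anyNA(vals)) stop(sprintf("format error: NaN coordinates in '%s'", path), call. = FALSE)
    point_cloud(matrix(vals, ncol = 3, byrow = TRUE))
  } else stop(sprintf("format error: unsupported cloud extension '%s'", ext), call. = FALSE)
}

#' Write a point cloud
#'
#' The XYZ format carries coordinates only; normals are dropped.
#'
#' @param cloud a [point_cloud()].
#' @param path output path.
#' @param format one of "ply_binary", "ply_ascii", "xyz".
#' @export
write_cloud <- function(cloud, path, format = c("ply_binary", "ply_ascii", "xyz")) {
  stopifnot(inherits(cloud, "point_cloud"))
  format <- match.arg(format)
  if (format == "xyz") {
    writeLines(apply(cloud$points, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), path)
  } else {
    write_ply(path, cloud$points, faces = NULL, normals = cloud$normals,
              binary = format == "ply_binary")
  }
  invisible(path)
}

#' Read a dataset manifest (JSON)
#'
#' Schema violations are rejected with the offending field named; in
#' particular quality-score-1 records (discarded scans) are refused.
#'
#' @param path JSON file path.
#' @return A [dataset_manifest()].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("I/O error: cannot read '%s'", path), call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$records)) stop("manifest error: missing field 'records'", call. = FALSE)
  records <- lapply(doc$records, function(r) {
    for (f in c("sample_id", "quality_score", "split", "seed"))
      if (is.null(r[[f]])) stop(sprintf("manifest error: missing field '%s'", f), call. = FALSE)
    defect <- if (!is.null(r$defect))
      defect_spec(unlist(r$defect$center), r$defect$base_side, r$defect$height)
    sample_record(r$sample_id, r$quality_score, r$split, r$seed, defect)
  })
  dataset_manifest(records)
}

#' Write a dataset manifest (JSON)
#'
#' @param manifest a [dataset_manifest()].
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  doc <- list(
    schema_version = manifest$schema_version,
    records = lapply(manifest$records, function(r) {
      out <- list(sample_id = r$sample_id, quality_score = r$quality_score,
                  split = r$split, seed = r$seed)
      if (!is.null(r$defect))
        out$defect <- list(center = r$defect$center,
                           base_side = r$defect$base_side, height = r$defect$height)
      out
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
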