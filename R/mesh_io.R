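# Readers and writers for the three standard surface-mesh exchange formats.
# PLY is read in both ASCII and binary little-endian dialects; all formats are
# written as ASCII for diffability. Faces are 1-based internally; the 0-based
# conventions of PLY/OFF and the 1-based convention of OBJ are translated at
# the file boundary. Vertices are taken as stored: de-duplication and welding
# are preprocessing's job, keeping I/O lossless.

#' Read a tooth mesh from PLY, OBJ or OFF
#'
#' @param path file path.
#' @param format one of `"ply"`, `"obj"`, `"off"` or `"auto"` (default:
#'   inferred from the file extension, falling back to content sniffing).
#' @param oriented logical; mark the mesh as occlusally oriented (`FALSE`
#'   unless the caller knows otherwise).
#' @return A validated [ToothMesh-class]; winding consistency is checked.
#' @examples
#' tmp <- tempfile(fileext = ".ply")
#' writeMesh(toothMesh(rbind(c(0,0,0), c(1,0,0), c(0,1,0)), rbind(c(1,2,3))), tmp)
#' readMesh(tmp)
#' @export
readMesh <- function(path, format = c("auto", "ply", "obj", "off"),
                     oriented = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mesh file does not exist: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("ply", "obj", "off")) ext else {
      head4 <- readChar(path, 4, useBytes = TRUE)
      if (identical(substr(head4, 1, 3), "ply")) "ply"
      else if (identical(substr(head4, 1, 3), "OFF")) "off"
      else "obj"
    }
  }
  parsed <- switch(format,
                   ply = .readPLY(path),
                   obj = .readOBJ(path),
                   off = .readOFF(path))
  if (nrow(parsed$faces) == 0)
    stop("empty mesh: '", path, "' contains no faces")
  mesh <- toothMesh(parsed$vertices, parsed$faces, oriented = oriented)
  validateMesh(mesh)
  message(sprintf("read %s mesh '%s': %d vertices, %d faces",
                  format, basename(path), nVertices(mesh), nFaces(mesh)))
  mesh
}

#' Write a tooth mesh to PLY, OBJ or OFF
#'
#' Writes ASCII dialects of all three formats.
#'
#' @param mesh a [ToothMesh-class].
#' @param path output file path.
#' @param format one of `"ply"`, `"obj"`, `"off"`; default inferred from the
#'   file extension.
#' @return `path`, invisibly.
#' @export
writeMesh <- function(mesh, path, format = c("auto", "ply", "obj", "off")) {
  format <- match.arg(format)
  validObject(mesh)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("ply", "obj", "off"))
      stop("unknown mesh format tag: '", ext, "'")
    format <- ext
  }
  v <- mesh@vertices
  f <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  vfmt <- function(m) apply(m, 1, function(r) paste(format(r, digits = 17), collapse = " "))
  ok <- tryCatch({
    switch(format,
      ply = {
        writeLines(c("ply", "format ascii 1.0",
                     "comment written by dentopo (ascii dialect)",
                     paste("element vertex", nrow(v)),
                     "property double x", "property double y", "property double z",
                     paste("element face", nrow(f)),
                     "property list uchar int vertex_indices",
                     "end_header"), con)
        writeLines(vfmt(v), con)
        writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
      },
      obj = {
        writeLines("# written by dentopo", con)
        writeLines(paste("v", vfmt(v)), con)
        writeLines(paste("f", f[, 1], f[, 2], f[, 3]), con)
      },
      off = {
        writeLines("OFF", con)
        writeLines(paste(nrow(v), nrow(f), 0L), con)
        writeLines(vfmt(v), con)
        writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
      })
    TRUE
  }, error = function(e) stop("failed to write '", path, "': ", conditionMessage(e)))
  invisible(path)
}

.plyTypeSize <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                  short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                  int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                  float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.plyReadScalar <- function(raw, offset, type) {
  sz <- .plyTypeSize[[type]]
  bytes <- raw[(offset + 1):(offset + sz)]
  val <- switch(type,
    char = , int8 = readBin(bytes, "integer", 1, 1, signed = TRUE, endian = "little"),
    uchar = , uint8 = readBin(bytes, "integer", 1, 1, signed = FALSE, endian = "little"),
    short = , int16 = readBin(bytes, "integer", 1, 2, signed = TRUE, endian = "little"),
    ushort = , uint16 = readBin(bytes, "integer", 1, 2, signed = FALSE, endian = "little"),
    int = , int32 = , uint = , uint32 = readBin(bytes, "integer", 1, 4, endian = "little"),
    float = , float32 = readBin(bytes, "numeric", 1, 4, endian = "little"),
    double = , float64 = readBin(bytes, "numeric", 1, 8, endian = "little"))
  list(value = val, offset = offset + sz)
}

.readPLY <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  # header is ASCII terminated by "end_header\n"; locate it in the raw bytes
  # before any text conversion (the body may be binary)
  marker <- charToRaw("end_header\n")
  hdrEndByte <- NA_integer_
  limit <- length(raw) - length(marker) + 1L
  for (i in seq_len(min(limit, 65536L))) {
    if (raw[i] == marker[1] &&
        identical(raw[i:(i + length(marker) - 1L)], marker)) {
      hdrEndByte <- i + length(marker) - 1L
      break
    }
  }
  if (is.na(hdrEndByte))
    stop("format error in '", path, "': end_header not found")
  txt <- rawToChar(raw[seq_len(hdrEndByte)])
  lines <- strsplit(txt, "\r?\n")[[1]]
  if (length(lines) == 0 || !identical(lines[1], "ply"))
    stop("format error in '", path, "' at line 1: not a PLY file")
  fmt <- NULL
  elements <- list()
  cur <- NULL
  hdrLines <- 0L
  for (i in seq_along(lines)) {
    hdrLines <- i
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(tok) == 0) next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("format error in '", path, "' at line ", i,
                             ": property outside element")
      if (tok[2] == "list")
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[5], list = TRUE, countType = tok[3], type = tok[4])
      else
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
    if (i == length(lines))
      stop("format error in '", path, "': end_header not found")
  }
  if (is.null(fmt)) stop("format error in '", path, "': missing format line")
  if (!"vertex" %in% names(elements) || !"face" %in% names(elements))
    stop("format error in '", path, "': vertex/face elements missing")

  vEl <- elements$vertex
  fEl <- elements$face
  vPropNames <- vapply(vEl$props, `[[`, "", "name")
  xyzIdx <- match(c("x", "y", "z"), vPropNames)
  if (anyNA(xyzIdx)) stop("format error in '", path, "': vertex x/y/z properties missing")

  if (identical(fmt, "ascii")) {
    allLines <- strsplit(rawToChar(raw), "\r?\n")[[1]]
    body <- allLines[(hdrLines + 1):length(allLines)]
    body <- body[nzchar(trimws(body))]
    need <- vEl$count + fEl$count
    if (length(body) < need)
      stop("format error in '", path, "': expected ", need,
           " data lines, found ", length(body))
    vtok <- strsplit(trimws(body[seq_len(vEl$count)]), "[[:space:]]+")
    verts <- t(vapply(vtok, function(tk) as.numeric(tk[xyzIdx]), numeric(3)))
    ftok <- strsplit(trimws(body[vEl$count + seq_len(fEl$count)]), "[[:space:]]+")
    faces <- matrix(0L, fEl$count, 3)
    for (r in seq_len(fEl$count)) {
      tk <- suppressWarnings(as.integer(ftok[[r]]))
      if (is.na(tk[1]) || tk[1] != 3L)
        stop("face ", r, " in '", path, "' is not a triangle (vertex count ",
             ftok[[r]][1], ")")
      faces[r, ] <- tk[2:4] + 1L
    }
    list(vertices = verts, faces = faces)
  } else if (identical(fmt, "binary_little_endian")) {
    offset <- hdrEndByte
    verts <- matrix(NA_real_, vEl$count, 3)
    for (r in seq_len(vEl$count)) {
      vals <- numeric(length(vEl$props))
      for (p in seq_along(vEl$props)) {
        pr <- vEl$props[[p]]
        if (isTRUE(pr$list)) stop("format error in '", path,
                                  "': list property on vertex element")
        res <- .plyReadScalar(raw, offset, pr$type)
        vals[p] <- res$value
        offset <- res$offset
      }
      verts[r, ] <- vals[xyzIdx]
    }
    faces <- matrix(0L, fEl$count, 3)
    for (r in seq_len(fEl$count)) {
      for (p in seq_along(fEl$props)) {
        pr <- fEl$props[[p]]
        if (isTRUE(pr$list)) {
          res <- .plyReadScalar(raw, offset, pr$countType)
          cnt <- res$value; offset <- res$offset
          if (pr$name == "vertex_indices" || pr$name == "vertex_index") {
            if (cnt != 3L) stop("face ", r, " in '", path,
                                "' is not a triangle (vertex count ", cnt, ")")
            for (k in 1:3) {
              res <- .plyReadScalar(raw, offset, pr$type)
              faces[r, k] <- res$value + 1L
              offset <- res$offset
            }
          } else {
            for (k in seq_len(cnt)) offset <- .plyReadScalar(raw, offset, pr$type)$offset
          }
        } else {
          offset <- .plyReadScalar(raw, offset, pr$type)$offset
        }
      }
    }
    list(vertices = verts, faces = faces)
  } else {
    stop("format error in '", path, "': unsupported PLY dialect '", fmt,
         "' (ascii and binary_little_endian are supported)")
  }
}

.readOBJ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vIdx <- grep("^v[[:space:]]", lines)
  fIdx <- grep("^f[[:space:]]", lines)
  if (!length(vIdx)) stop("format error in '", path, "': no vertex lines")
  verts <- t(vapply(strsplit(trimws(lines[vIdx]), "[[:space:]]+"),
                    function(tk) as.numeric(tk[2:4]), numeric(3)))
  if (anyNA(verts)) {
    bad <- vIdx[which(apply(is.na(verts), 1, any))[1]]
    stop("format error in '", path, "' at line ", bad, ": bad vertex")
  }
  faces <- matrix(0L, length(fIdx), 3)
  for (r in seq_along(fIdx)) {
    tk <- strsplit(trimws(lines[fIdx[r]]), "[[:space:]]+")[[1]][-1]
    if (length(tk) != 3)
      stop("face ", r, " in '", path, "' is not a triangle (", length(tk), " corners)")
    idx <- suppressWarnings(as.integer(sub("/.*$", "", tk)))
    if (anyNA(idx))
      stop("format error in '", path, "' at line ", fIdx[r], ": bad face indices")
    faces[r, ] <- idx
  }
  list(vertices = verts, faces = faces)   # OBJ is already 1-based
}

.readOFF <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (!length(lines) || !grepl("^OFF", lines[1]))
    stop("format error in '", path, "' at line 1: missing OFF header")
  cnt <- as.integer(strsplit(trimws(lines[2]), "[[:space:]]+")[[1]])
  nv <- cnt[1]; nf <- cnt[2]
  if (is.na(nv) || is.na(nf))
    stop("format error in '", path, "' at line 2: bad counts")
  if (length(lines) < 2 + nv + nf)
    stop("format error in '", path, "': truncated file")
  verts <- t(vapply(strsplit(trimws(lines[2 + seq_len(nv)]), "[[:space:]]+"),
                    function(tk) as.numeric(tk[1:3]), numeric(3)))
  faces <- matrix(0L, nf, 3)
  for (r in seq_len(nf)) {
    tk <- as.integer(strsplit(trimws(lines[2 + nv + r]), "[[:space:]]+")[[1]])
    if (tk[1] != 3L)
      stop("face ", r, " in '", path, "' is not a triangle (vertex count ", tk[1], ")")
    faces[r, ] <- tk[2:4] + 1L
  }
  list(vertices = verts, faces = faces)
}
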