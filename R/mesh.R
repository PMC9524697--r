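# Torso surface meshes: minimal PLY (ASCII / binary little-endian) and OBJ
# readers, axis normalization to the internal convention (up = +z,
# anterior = +y), and a PLY writer for synthetic torsos.

#' Construct a torso mesh
#'
#' @param vertices three-column numeric matrix of vertex coordinates (mm),
#'   already in the internal frame: x lateral, y anterior, z superior.
#' @param faces three-column integer matrix of 1-based vertex indices.
#' @return object of class `torso_mesh` with elements `vertices`, `faces`.
#' @export
torso_mesh <- function(vertices, faces) {
  v <- as.matrix(vertices); storage.mode(v) <- "double"
  f <- as.matrix(faces); storage.mode(f) <- "integer"
  dimnames(v) <- dimnames(f) <- NULL
  if (ncol(v) != 3 || nrow(v) < 4)
    validation_error("mesh needs >= 4 vertices with 3 coordinates each")
  if (ncol(f) != 3 || nrow(f) < 4)
    validation_error("mesh needs >= 4 triangular faces")
  if (anyNA(v) || any(!is.finite(v))) validation_error("non-finite vertex coordinates")
  if (anyNA(f) || min(f) < 1 || max(f) > nrow(v))
    validation_error("face indices out of range")
  structure(list(vertices = v, faces = f), class = "torso_mesh")
}

#' @export
print.torso_mesh <- function(x, ...) {
  zr <- range(x$vertices[, 3])
  cat(sprintf("torso_mesh: %d vertices, %d triangles, vertical extent %.1f..%.1f mm\n",
              nrow(x$vertices), nrow(x$faces), zr[1], zr[2]))
  invisible(x)
}

# Parse an axis spec like "z", "+z", "-y" into (index, sign).
#' @keywords internal
#' @noRd
parse_axis <- function(spec) {
  s <- tolower(trimws(spec))
  sign <- 1
  if (grepl("^[+-]", s)) {
    if (substr(s, 1, 1) == "-") sign <- -1
    s <- substring(s, 2)
  }
  i <- match(s, c("x", "y", "z"))
  if (is.na(i)) validation_error(paste0("invalid axis spec: ", spec))
  c(index = i, sign = sign)
}

#' Load a torso mesh from PLY or OBJ
#'
#' Reads the file and permutes/flips coordinates so that the vertical body
#' axis becomes +z (superior) and the anterior direction becomes +y. The
#' lateral axis is completed right-handed (x = y cross z points to the
#' subject's right under the usual scanner convention).
#'
#' @param path path to a `.ply` (ASCII or binary little-endian) or `.obj` file.
#' @param up_axis axis of the input file pointing superior, e.g. `"z"`, `"-y"`.
#' @param anterior_axis axis of the input file pointing anterior.
#' @return a [torso_mesh] in the internal frame.
#' @export
load_mesh <- function(path, up_axis = "z", anterior_axis = "y") {
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    ply = read_ply(path),
    obj = read_obj(path),
    format_error("unsupported mesh format (use .ply or .obj)"))
  up <- parse_axis(up_axis)
  ant <- parse_axis(anterior_axis)
  if (up["index"] == ant["index"])
    validation_error("up_axis and anterior_axis must differ")
  v <- m$vertices
  zc <- v[, up["index"]] * up["sign"]
  yc <- v[, ant["index"]] * ant["sign"]
  # complete a right-handed frame: x = y cross z in the source basis
  e <- function(i, s) { u <- numeric(3); u[i] <- s; u }
  xdir <- crossprod3(e(ant["index"], ant["sign"]), e(up["index"], up["sign"]))
  xc <- v %*% xdir
  torso_mesh(cbind(xc, yc, zc)[, , drop = FALSE], m$faces)
}

#' @keywords internal
#' @noRd
crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ---- PLY ----

#' Read a PLY mesh file
#'
#' Supports ASCII and binary little-endian PLY with float/double vertex
#' properties and uchar/int face index lists; polygon faces are fan
#' triangulated. Non-geometry properties are skipped.
#'
#' @param path file path.
#' @return list with `vertices` (n x 3) and `faces` (m x 3, 1-based).
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) format_error("not a PLY file: truncated header")
    header <- c(header, line)
    if (trimws(line) == "end_header") break
    if (length(header) > 500) format_error("not a PLY file: header too long")
  }
  if (length(header) == 0 || trimws(header[1]) != "ply")
    format_error("not a PLY file: missing 'ply' magic")
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1) format_error("PLY: missing format line")
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    format_error(paste0("PLY: unsupported format ", fmt))

  # parse element/property declarations in order
  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (!"vertex" %in% names(elements) || !"face" %in% names(elements))
    format_error("PLY: needs vertex and face elements")

  type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                 short = 2, ushort = 2, int16 = 2, uint16 = 2,
                 int = 4, uint = 4, int32 = 4, uint32 = 4,
                 float = 4, float32 = 4, double = 8, float64 = 8)
  read_bin_scalar <- function(type, n = 1) {
    sz <- type_size[[type]]
    if (is.null(sz)) format_error(paste0("PLY: unknown type ", type))
    if (type %in% c("float", "float32", "double", "float64"))
      readBin(con, "double", n = n, size = sz, endian = "little")
    else
      readBin(con, "integer", n = n, size = sz, endian = "little",
              signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
  }

  verts <- NULL; faces <- list()
  if (fmt == "ascii") {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    pos <- 1
    for (el in elements) {
      rows <- txt[pos:(pos + el$count - 1)]
      pos <- pos + el$count
      if (el$name == "vertex") {
        pnames <- vapply(el$props, `[[`, "", "name")
        mat <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
        ix <- match(c("x", "y", "z"), pnames)
        if (anyNA(ix)) format_error("PLY: vertex element lacks x/y/z")
        verts <- mat[, ix, drop = FALSE]
      } else if (el$name == "face") {
        faces <- lapply(strsplit(trimws(rows), "\\s+"), function(tk) {
          k <- as.integer(tk[1])
          as.integer(tk[2:(1 + k)])
        })
      }
    }
  } else {
    for (el in elements) {
      if (el$name == "vertex") {
        pnames <- vapply(el$props, `[[`, "", "name")
        ptypes <- vapply(el$props, `[[`, "", "type")
        if (any(vapply(el$props, `[[`, TRUE, "list")))
          format_error("PLY: list property on vertex element unsupported")
        if (length(unique(ptypes)) == 1) {
          all_vals <- read_bin_scalar(ptypes[1], n = el$count * length(pnames))
          mat <- matrix(all_vals, ncol = length(pnames), byrow = TRUE)
        } else {
          mat <- matrix(NA_real_, el$count, length(pnames))
          for (r in seq_len(el$count))
            for (ci in seq_along(ptypes))
              mat[r, ci] <- read_bin_scalar(ptypes[ci])
        }
        ix <- match(c("x", "y", "z"), pnames)
        if (anyNA(ix)) format_error("PLY: vertex element lacks x/y/z")
        verts <- mat[, ix, drop = FALSE]
      } else if (el$name == "face") {
        p <- el$props[[1]]
        if (!p$list) format_error("PLY: face element must have a list property")
        faces <- vector("list", el$count)
        for (r in seq_len(el$count)) {
          k <- read_bin_scalar(p$count_type)
          faces[[r]] <- read_bin_scalar(p$type, n = k)
        }
      } else {
        # skip unknown fixed-size elements
        sizes <- vapply(el$props, function(p) type_size[[p$type]], 0)
        invisible(readBin(con, "raw", n = el$count * sum(sizes)))
      }
    }
  }
  if (is.null(verts) || length(faces) == 0)
    validation_error("PLY: mesh has no vertices or no faces")
  tri <- fan_triangulate(faces)
  list(vertices = verts, faces = tri + 1L)  # PLY indices are 0-based
}

#' Read an OBJ mesh file
#'
#' Parses `v` and `f` records; texture/normal references in face tokens
#' (`v/vt/vn`) are ignored and polygon faces are fan triangulated.
#'
#' @param path file path.
#' @return list with `vertices` (n x 3) and `faces` (m x 3, 1-based).
#' @export
read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", txt, value = TRUE)
  flines <- grep("^f\\s", txt, value = TRUE)
  if (length(vlines) == 0 || length(flines) == 0)
    format_error("OBJ: no vertices or no faces found")
  verts <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(tk)
    as.numeric(tk[2:4])))
  nv <- nrow(verts)
  faces <- lapply(strsplit(trimws(flines), "\\s+"), function(tk) {
    ix <- as.integer(vapply(tk[-1], function(t) strsplit(t, "/")[[1]][1], ""))
    ix[ix < 0] <- nv + 1L + ix[ix < 0]  # negative indices count from the end
    ix - 1L
  })
  tri <- fan_triangulate(faces)
  list(vertices = verts, faces = tri + 1L)
}

# fan triangulation of polygon index lists (0-based in, 0-based out)
#' @keywords internal
#' @noRd
fan_triangulate <- function(faces) {
  tris <- lapply(faces, function(ix) {
    k <- length(ix)
    if (k < 3) format_error("mesh face with fewer than 3 vertices")
    if (k == 3) return(matrix(ix, 1))
    cbind(ix[1], ix[2:(k - 1)], ix[3:k])
  })
  do.call(rbind, tris)
}

#' Write a torso mesh as ASCII PLY
#'
#' @param mesh a [torso_mesh].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(paste(v[, 1], v[, 2], v[, 3]), con)
  writeLines(paste(3, f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}
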