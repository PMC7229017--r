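# STL and PLY readers/writers. No mesh-I/O package exists in the supported
# dependency stack, so both formats are implemented here from their public
# format definitions. All coordinates are taken as millimetres verbatim (the
# formats carry no unit metadata).

infer_format <- function(path, format = NULL) {
  if (!is.null(format)) {
    format <- match.arg(tolower(format), c("stl", "ply"))
    return(format)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("stl", "ply")) {
    return(ext)
  }
  abort_radcs(sprintf("cannot infer mesh format from '%s'; pass `format`",
                      path), "radcs_format_error")
}

#' Read a surface mesh from STL or PLY
#'
#' Supports ASCII and binary STL, and ASCII and binary little-endian PLY.
#' Binary vs ASCII is auto-detected. Vertices of STL files (which store bare
#' triangles) are merged on exact coordinate equality.
#'
#' @param path path to the mesh file.
#' @param format `"stl"`, `"ply"`, or `NULL` to infer from the extension.
#' @return A [tri_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) {
    abort_radcs(sprintf("mesh file '%s' does not exist", path),
                "radcs_format_error")
  }
  format <- infer_format(path, format)
  if (format == "stl") read_stl(path) else read_ply(path)
}

#' Write a surface mesh to STL or PLY
#'
#' ASCII output prints coordinates with 17 significant digits (lossless for
#' doubles). Binary PLY stores doubles and also round-trips losslessly; binary
#' STL is constrained by its format definition to 32-bit floats (about 1e-5 mm
#' at bone scale).
#'
#' @param mesh a [tri_mesh()].
#' @param path output path.
#' @param format `"stl"`, `"ply"`, or `NULL` to infer from the extension.
#' @param binary write the binary variant of the format.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  assert_tri_mesh(mesh)
  format <- infer_format(path, format)
  if (format == "stl") {
    if (binary) write_stl_binary(mesh, path) else write_stl_ascii(mesh, path)
  } else {
    if (binary) write_ply_binary(mesh, path) else write_ply_ascii(mesh, path)
  }
  invisible(path)
}

face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(n^2))
  len[len < 1e-300] <- 1
  n / len
}

# ---- STL ---------------------------------------------------------------

is_binary_stl <- function(path) {
  sz <- file.info(path)$size
  if (sz < 84) {
    return(FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!is.na(ntri) && ntri >= 0 && sz == 84 + 50 * as.numeric(ntri)) {
    return(TRUE)
  }
  FALSE
}

dedupe_triangle_soup <- function(coords) {
  # coords: (3*ntri) x 3 matrix in face order
  key <- paste(sprintf("%.17g", coords[, 1L]),
               sprintf("%.17g", coords[, 2L]),
               sprintf("%.17g", coords[, 3L]))
  idx <- match(key, key)                 # first occurrence index
  uniq <- sort(unique(idx))
  remap <- integer(nrow(coords))
  remap[uniq] <- seq_along(uniq)
  faces <- matrix(remap[idx], ncol = 3L, byrow = TRUE)
  tri_mesh(coords[uniq, , drop = FALSE], faces)
}

read_stl <- function(path) {
  if (is_binary_stl(path)) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80L)
    ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (ntri < 1L) {
      abort_radcs("binary STL contains no triangles", "radcs_format_error")
    }
    body <- readBin(con, "raw", 50L * ntri)
    if (length(body) < 50L * ntri) {
      abort_radcs("binary STL truncated", "radcs_format_error")
    }
    rec <- matrix(body, nrow = 50L)
    coords <- matrix(0, 3L * ntri, 3L)
    for (k in 0:2) {                      # the three vertices per record
      off <- 12L + 12L * k
      flo <- readBin(rec[(off + 1L):(off + 12L), , drop = FALSE],
                     "double", size = 4L, n = 3L * ntri, endian = "little")
      coords[seq.int(k + 1L, by = 3L, length.out = ntri), ] <-
        matrix(flo, ncol = 3L, byrow = TRUE)
    }
    if (any(!is.finite(coords))) {
      abort_radcs("binary STL contains non-finite coordinates",
                  "radcs_format_error")
    }
    return(dedupe_triangle_soup(coords))
  }
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) < 3L || length(vl) %% 3L != 0L) {
    abort_radcs("ASCII STL parse failure: vertex count not a multiple of 3",
                "radcs_format_error")
  }
  if (!any(grepl("^\\s*endsolid", lines))) {
    abort_radcs("ASCII STL truncated: missing endsolid", "radcs_format_error")
  }
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) {
    as.numeric(p[2:4])
  }))
  if (any(!is.finite(nums))) {
    abort_radcs("ASCII STL contains unparsable coordinates",
                "radcs_format_error")
  }
  dedupe_triangle_soup(nums)
}

write_stl_ascii <- function(mesh, path) {
  nrm <- face_normals(mesh)
  f <- mesh$faces
  v <- mesh$vertices
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid radcs", con)
  tri_txt <- vapply(seq_len(nrow(f)), function(i) {
    p <- v[f[i, ], , drop = FALSE]
    paste0(sprintf(" facet normal %.17g %.17g %.17g\n  outer loop\n",
                   nrm[i, 1L], nrm[i, 2L], nrm[i, 3L]),
           paste(sprintf("   vertex %.17g %.17g %.17g",
                         p[, 1L], p[, 2L], p[, 3L]), collapse = "\n"),
           "\n  endloop\n endfacet")
  }, character(1L))
  writeLines(tri_txt, con)
  writeLines("endsolid radcs", con)
}

write_stl_binary <- function(mesh, path) {
  nrm <- face_normals(mesh)
  f <- mesh$faces
  v <- mesh$vertices
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "radcs binary STL"))[1:80]
  writeBin(hdr, con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(f))) {
    p <- v[f[i, ], , drop = FALSE]
    writeBin(c(nrm[i, ], t(p)), con, size = 4L, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
}

# ---- PLY ---------------------------------------------------------------

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_values <- function(raw, offset, type, n) {
  sz <- ply_type_size[[type]]
  bytes <- raw[(offset + 1L):(offset + sz * n)]
  what <- if (type %in% c("float", "float32", "double", "float64")) {
    "double"
  } else {
    "integer"
  }
  signed <- !(type %in% c("uchar", "uint8", "ushort", "uint16"))
  readBin(bytes, what, n = n, size = sz, signed = signed, endian = "little")
}

read_ply <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  # header is ASCII terminated by "end_header\n"
  nl <- which(raw == as.raw(10L))
  header_lines <- character(0)
  start <- 1L
  hdr_end <- NA_integer_
  for (pos in nl) {
    ln <- rawToChar(raw[start:(pos - 1L)])
    ln <- sub("\r$", "", ln)
    header_lines <- c(header_lines, ln)
    start <- pos + 1L
    if (identical(trimws(ln), "end_header")) {
      hdr_end <- pos
      break
    }
  }
  if (is.na(hdr_end) || length(header_lines) < 3L ||
      trimws(header_lines[1L]) != "ply") {
    abort_radcs("not a PLY file or truncated header", "radcs_format_error")
  }
  fmt_line <- grep("^format ", header_lines, value = TRUE)
  if (length(fmt_line) != 1L) {
    abort_radcs("PLY header missing format line", "radcs_format_error")
  }
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1L]][2L]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    abort_radcs(sprintf("unsupported PLY format '%s'", fmt),
                "radcs_format_error")
  }

  # parse element/property declarations
  elements <- list()
  cur <- NULL
  for (ln in header_lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (tok[1L] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2L], count = as.integer(tok[3L]),
                  props = list())
    } else if (tok[1L] == "property" && !is.null(cur)) {
      if (tok[2L] == "list") {
        cur$props[[tok[5L]]] <- list(kind = "list",
                                     count_type = tok[3L], type = tok[4L])
      } else {
        cur$props[[tok[3L]]] <- list(kind = "scalar", type = tok[2L])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face)) {
    abort_radcs("PLY file must declare vertex and face elements",
                "radcs_format_error")
  }

  if (fmt == "ascii") {
    body <- strsplit(trimws(rawToChar(raw[(hdr_end + 1L):length(raw)])),
                     "\r?\n")[[1L]]
    body <- body[nzchar(trimws(body))]
    nv <- elements$vertex$count
    nf <- elements$face$count
    if (length(body) < nv + nf) {
      abort_radcs("PLY body truncated", "radcs_format_error")
    }
    vprops <- names(elements$vertex$props)
    vt <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]),
                                         "\\s+"), as.numeric))
    xyz <- vt[, match(c("x", "y", "z"), vprops), drop = FALSE]
    ftok <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
    faces <- do.call(rbind, lapply(ftok, function(p) {
      cnt <- as.integer(p[1L])
      if (cnt != 3L) {
        abort_radcs("only triangular PLY faces are supported",
                    "radcs_format_error")
      }
      as.integer(p[2:4])
    }))
  } else {
    off <- hdr_end
    vprops <- elements$vertex$props
    if (any(vapply(vprops, function(p) p$kind, "") != "scalar")) {
      abort_radcs("list-typed vertex properties are not supported",
                  "radcs_format_error")
    }
    types <- vapply(vprops, function(p) p$type, "")
    sizes <- ply_type_size[types]
    nv <- elements$vertex$count
    rec <- sum(sizes)
    if (length(raw) < off + rec * nv) {
      abort_radcs("PLY body truncated", "radcs_format_error")
    }
    same <- length(unique(types)) == 1L
    if (same) {
      all_vals <- ply_read_values(raw, off, types[[1L]],
                                  nv * length(types))
      vt <- matrix(all_vals, ncol = length(types), byrow = TRUE)
    } else {
      vt <- matrix(0, nv, length(types))
      prop_off <- cumsum(c(0L, head(sizes, -1L)))
      for (j in seq_along(types)) {
        vt[, j] <- vapply(seq_len(nv), function(i) {
          ply_read_values(raw, off + rec * (i - 1L) + prop_off[j],
                          types[[j]], 1L)
        }, numeric(1L))
      }
    }
    colnames(vt) <- names(vprops)
    xyz <- vt[, c("x", "y", "z"), drop = FALSE]
    off <- off + rec * nv

    fp <- elements$face$props[[1L]]
    if (is.null(fp) || fp$kind != "list") {
      abort_radcs("PLY face element must carry a list property",
                  "radcs_format_error")
    }
    csz <- ply_type_size[[fp$count_type]]
    isz <- ply_type_size[[fp$type]]
    nf <- elements$face$count
    frec <- csz + 3L * isz
    if (length(raw) < off + frec * nf) {
      abort_radcs("PLY body truncated", "radcs_format_error")
    }
    counts <- vapply(seq_len(nf), function(i) {
      ply_read_values(raw, off + frec * (i - 1L), fp$count_type, 1L)
    }, numeric(1L))
    if (any(counts != 3)) {
      abort_radcs("only triangular PLY faces are supported",
                  "radcs_format_error")
    }
    faces <- t(vapply(seq_len(nf), function(i) {
      as.integer(ply_read_values(raw, off + frec * (i - 1L) + csz,
                                 fp$type, 3L))
    }, integer(3L)))
  }
  if (any(!is.finite(xyz))) {
    abort_radcs("PLY contains non-finite coordinates", "radcs_format_error")
  }
  tri_mesh(xyz, faces + 1L)
}

ply_header <- function(mesh, fmt, vtype) {
  c("ply",
    sprintf("format %s 1.0", fmt),
    "comment radcs mesh",
    sprintf("element vertex %d", nrow(mesh$vertices)),
    sprintf("property %s x", vtype),
    sprintf("property %s y", vtype),
    sprintf("property %s z", vtype),
    sprintf("element face %d", nrow(mesh$faces)),
    "property list uchar int vertex_indices",
    "end_header")
}

write_ply_ascii <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(ply_header(mesh, "ascii", "double"), con)
  v <- mesh$vertices
  writeLines(sprintf("%.17g %.17g %.17g", v[, 1L], v[, 2L], v[, 3L]), con)
  f <- mesh$faces - 1L
  writeLines(sprintf("3 %d %d %d", f[, 1L], f[, 2L], f[, 3L]), con)
}

write_ply_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(
    paste(ply_header(mesh, "binary_little_endian", "double"),
          collapse = "\n"), "\n")), con)
  writeBin(as.numeric(t(mesh$vertices)), con, size = 8L, endian = "little")
  f <- mesh$faces - 1L
  for (i in seq_len(nrow(f))) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(f[i, ]), con, size = 4L, endian = "little")
  }
}
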