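# PLY and OBJ input/output. PLY files are written either as ASCII or
# binary_little_endian, with double-precision coordinates and optional uchar
# RGB; meshes add the usual `list uchar int vertex_indices` face element.
# The reader handles both encodings and arbitrary extra vertex properties.

ply_type_size <- c(
  char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
  short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
  int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
  float = 4L, float32 = 4L, double = 8L, float64 = 8L
)

# Decode `n` packed scalars of a PLY type from a raw vector.
ply_decode <- function(bytes, type, n) {
  switch(type,
    char = , int8 = readBin(bytes, integer(), n, size = 1, signed = TRUE,
                            endian = "little"),
    uchar = , uint8 = readBin(bytes, integer(), n, size = 1, signed = FALSE,
                              endian = "little"),
    short = , int16 = readBin(bytes, integer(), n, size = 2, signed = TRUE,
                              endian = "little"),
    ushort = , uint16 = readBin(bytes, integer(), n, size = 2, signed = FALSE,
                                endian = "little"),
    int = , int32 = , uint = , uint32 =
      readBin(bytes, integer(), n, size = 4, endian = "little"),
    float = , float32 = readBin(bytes, double(), n, size = 4,
                                endian = "little"),
    double = , float64 = readBin(bytes, double(), n, size = 8,
                                 endian = "little"),
    stop_io(sprintf("Unsupported PLY type '%s'.", type))
  )
}

parse_ply_header <- function(con) {
  magic <- readLines(con, 1)
  if (!identical(trimws(magic), "ply")) stop_io("Not a PLY file.")
  format <- NULL
  elements <- list()
  cur <- NULL
  repeat {
    line <- readLines(con, 1)
    if (length(line) == 0L) stop_io("Unexpected end of PLY header.")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "comment") next
    if (tok[1] == "format") {
      format <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (!format %in% c("ascii", "binary_little_endian")) {
    stop_io(sprintf("Unsupported PLY format '%s'.", format))
  }
  list(format = format, elements = elements)
}

#' Read a PLY file
#'
#' Supports ASCII and binary little-endian encodings. Files with a `face`
#' element are returned as a [triangle_mesh()]; otherwise a [point_cloud()]
#' (RGB preserved when present).
#'
#' @param path file path.
#' @param unit_state unit state to stamp on the result (`"cm"` or
#'   `"uncalibrated"`).
#' @return A [point_cloud()] or [triangle_mesh()].
#' @export
read_ply <- function(path, unit_state = "cm") {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- parse_ply_header(con)
  data <- list()
  if (hdr$format == "ascii") {
    all_lines <- readLines(con)
    at <- 0L
    for (el in hdr$elements) {
      rows <- strsplit(trimws(all_lines[at + seq_len(el$count)]), "\\s+")
      at <- at + el$count
      mat <- NULL
      if (!any(vapply(el$props, `[[`, logical(1), "list"))) {
        mat <- matrix(as.numeric(unlist(rows)), ncol = length(el$props),
                      byrow = TRUE)
      }
      vals <- list()
      for (p in seq_along(el$props)) {
        pr <- el$props[[p]]
        if (pr$list) {
          vals[[pr$name]] <- lapply(rows, function(r) {
            r <- as.numeric(r)
            r[-1][seq_len(r[1])]
          })
        } else {
          vals[[pr$name]] <- mat[, p]
        }
      }
      data[[el$name]] <- vals
    }
  } else {
    bytes <- readBin(con, raw(), n = file.size(path))
    pos <- 0L
    for (el in hdr$elements) {
      is_list <- vapply(el$props, `[[`, logical(1), "list")
      vals <- list()
      if (!any(is_list)) {
        sizes <- vapply(el$props, function(pr) ply_type_size[[pr$type]],
                        integer(1))
        rowsize <- sum(sizes)
        blk <- matrix(bytes[pos + seq_len(rowsize * el$count)],
                      nrow = rowsize)
        off <- 0L
        for (p in seq_along(el$props)) {
          pr <- el$props[[p]]
          vals[[pr$name]] <- ply_decode(
            as.vector(blk[off + seq_len(sizes[p]), , drop = FALSE]),
            pr$type, el$count
          )
          off <- off + sizes[p]
        }
        pos <- pos + rowsize * el$count
      } else if (length(el$props) == 1L && is_list[1]) {
        pr <- el$props[[1]]
        csize <- ply_type_size[[pr$count_type]]
        isize <- ply_type_size[[pr$type]]
        first_cnt <- ply_decode(bytes[pos + seq_len(csize)], pr$count_type, 1L)
        rowsize <- csize + first_cnt * isize
        cnt_pos <- pos + (seq_len(el$count) - 1L) * rowsize
        uniform <- el$count == 0L ||
          all(ply_decode(bytes[rep(cnt_pos, each = csize) +
                                 seq_len(csize)],
                         pr$count_type, el$count) == first_cnt)
        if (uniform) {
          blk <- matrix(bytes[pos + seq_len(rowsize * el$count)],
                        nrow = rowsize)
          items <- ply_decode(as.vector(blk[-seq_len(csize), , drop = FALSE]),
                              pr$type, first_cnt * el$count)
          m <- matrix(items, nrow = first_cnt)
          vals[[pr$name]] <- lapply(seq_len(el$count), function(i) m[, i])
          pos <- pos + rowsize * el$count
        } else {
          out <- vector("list", el$count)
          p2 <- pos
          for (i in seq_len(el$count)) {
            cnt <- ply_decode(bytes[p2 + seq_len(csize)], pr$count_type, 1L)
            out[[i]] <- ply_decode(
              bytes[p2 + csize + seq_len(cnt * isize)], pr$type, cnt
            )
            p2 <- p2 + csize + cnt * isize
          }
          vals[[pr$name]] <- out
          pos <- p2
        }
      } else {
        stop_io("PLY elements mixing list and scalar properties are not supported.")
      }
      data[[el$name]] <- vals
    }
  }
  v <- data$vertex
  if (is.null(v)) stop_io("PLY file has no vertex element.")
  xyz <- cbind(v$x, v$y, v$z)
  if (!is.null(data$face)) {
    fl <- data$face[[1]]
    if (any(vapply(fl, length, integer(1)) != 3L)) {
      stop_io("Only triangle meshes are supported.")
    }
    faces <- do.call(rbind, fl) + 1L
    return(triangle_mesh(xyz, faces, unit_state = unit_state))
  }
  rgb <- if (all(c("red", "green", "blue") %in% names(v))) {
    cbind(v$red, v$green, v$blue)
  } else {
    NULL
  }
  point_cloud(xyz, rgb = rgb, unit_state = unit_state)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write a point cloud or mesh to PLY
#'
#' @param x a [point_cloud()] (RGB written as uchar when present) or a
#'   [triangle_mesh()].
#' @param path output path.
#' @param binary write binary little-endian (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_ply <- function(x, path, binary = TRUE) {
  if (is_triangle_mesh(x)) {
    return(write_ply_mesh(x, path, binary))
  }
  xyz <- cloud_xyz(x)
  has_rgb <- all(c("r", "g", "b") %in% names(x))
  hdr <- c(
    "ply",
    sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
    sprintf("element vertex %d", nrow(xyz)),
    "property double x", "property double y", "property double z",
    if (has_rgb) c("property uchar red", "property uchar green",
                   "property uchar blue"),
    "end_header"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (binary) {
    xyz_raw <- matrix(writeBin(as.double(t(xyz)), raw(), size = 8,
                               endian = "little"), nrow = 24)
    if (has_rgb) {
      rgb_raw <- matrix(as.raw(t(cbind(x$r, x$g, x$b))), nrow = 3)
      writeBin(as.vector(rbind(xyz_raw, rgb_raw)), con)
    } else {
      writeBin(as.vector(xyz_raw), con)
    }
  } else {
    lines <- paste(fmt_num(xyz[, 1]), fmt_num(xyz[, 2]), fmt_num(xyz[, 3]))
    if (has_rgb) lines <- paste(lines, x$r, x$g, x$b)
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

write_ply_mesh <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  hdr <- c(
    "ply",
    sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
    sprintf("element vertex %d", nrow(v)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (binary) {
    writeBin(as.double(t(v)), con, size = 8, endian = "little")
    f0 <- t(f - 1L)
    blk <- vapply(seq_len(ncol(f0)), function(i) {
      c(as.raw(3L), writeBin(as.integer(f0[, i]), raw(), size = 4,
                             endian = "little"))
    }, raw(13))
    writeBin(as.vector(blk), con)
  } else {
    writeLines(paste(fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])),
               con, sep = "\n")
    writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
               con, sep = "\n")
  }
  invisible(path)
}

#' Write a triangle mesh to Wavefront OBJ
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  if (!is_triangle_mesh(mesh)) stop_input("`mesh` must be a triangle_mesh.")
  v <- mesh$vertices
  f <- mesh$faces
  lines <- c(
    paste("v", fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])),
    paste("f", f[, 1], f[, 2], f[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a Wavefront OBJ triangle mesh
#'
#' @param path file path.
#' @param unit_state unit state to stamp on the mesh.
#' @return A [triangle_mesh()].
#' @export
read_obj <- function(path, unit_state = "cm") {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(t) {
    as.numeric(t[2:4])
  }))
  f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(t) {
    as.integer(sub("/.*", "", t[2:4]))
  }))
  triangle_mesh(v, f, unit_state = unit_state)
}
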