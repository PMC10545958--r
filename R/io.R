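# File formats: STL, Abaqus .inp subset, pressure CSV, VTK, PLY ---------------

#' Write a surface mesh as STL
#'
#' Both ASCII and binary little-endian STL are supported; coordinates are
#' stored as float32 as the format requires.
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @param binary write binary STL (default ASCII).
#' @export
write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices; tr <- mesh$triangles
  n <- triangle_normals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", paste0("footform stl ",
                                             mesh$label %||% "mesh")))
    writeBin(hdr[1:80], con)
    writeBin(as.integer(nrow(tr)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(tr))) {
      writeBin(as.numeric(n[i, ]), con, size = 4, endian = "little")
      writeBin(as.numeric(t(v[tr[i, ], ])), con, size = 4, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    nm <- mesh$label %||% "mesh"
    writeLines(paste("solid", nm), con)
    for (i in seq_len(nrow(tr))) {
      writeLines(sprintf("  facet normal %.9e %.9e %.9e",
                         n[i, 1], n[i, 2], n[i, 3]), con)
      writeLines("    outer loop", con)
      for (k in 1:3) {
        p <- v[tr[i, k], ]
        writeLines(sprintf("      vertex %.9e %.9e %.9e", p[1], p[2], p[3]),
                   con)
      }
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines(paste("endsolid", nm), con)
  }
  invisible(path)
}

#' Read an STL file (ASCII or binary)
#'
#' The format is auto-detected. Duplicate vertices are welded at a 1e-6 mm
#' tolerance so watertight connectivity is recovered from the triangle soup.
#'
#' @param path STL file path.
#' @return a `surface_mesh`.
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head_raw <- readBin(con, "raw", n = min(sz, 512))
  close(con)
  is_ascii <- sz >= 6 &&
    identical(rawToChar(head_raw[1:5]), "solid") &&
    {
      txt <- tryCatch(suppressWarnings(rawToChar(head_raw)),
                      error = function(e) "")
      grepl("facet", txt, fixed = TRUE) || sz < 84
    }
  if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) {
    if (any(grepl("^\\s*endsolid", lines)))
      stop_input("zero-triangle STL file: ", path)
    stop_input("STL parse error: no vertex lines in ", path)
  }
  if (length(vl) %% 3L != 0L)
    stop_input("truncated ASCII STL: vertex count not a multiple of 3")
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4]), numeric(3)))
  label <- sub("^solid\\s*", "", trimws(lines[1]))
  weld_soup(nums, if (nzchar(label)) label else NULL)
}

read_stl_binary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 80)
  ntri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (is.na(ntri) || ntri < 0)
    stop_input("truncated binary STL at byte 80: bad triangle count")
  if (ntri == 0) stop_input("zero-triangle STL file: ", path)
  expect <- 84 + ntri * 50
  if (sz < expect)
    stop_input("truncated binary STL: expected ", expect, " bytes, found ",
               sz, " (byte offset ", sz, ")")
  v <- matrix(0, 3L * ntri, 3)
  for (i in seq_len(ntri)) {
    rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    readBin(con, "raw", n = 2)
    v[3L * (i - 1L) + 1:3, ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
  }
  weld_soup(v, NULL)
}

# weld duplicate vertices of a triangle soup (rows in triangle order)
weld_soup <- function(coords, label, tol = 1e-6) {
  key <- paste(round(coords[, 1] / tol), round(coords[, 2] / tol),
               round(coords[, 3] / tol))
  uid <- match(key, unique(key))
  first <- !duplicated(uid)
  verts <- coords[first, , drop = FALSE]
  tris <- matrix(uid, ncol = 3, byrow = TRUE)
  surface_mesh(verts, tris, label = label)
}

#' Write a tetrahedral mesh as an Abaqus .inp subset
#'
#' Emits `*NODE`, `*ELEMENT, TYPE=C3D4`, and one `*NSET`/`*ELSET` block per
#' node/element set. Ids on disk are 1-based (Abaqus dialect), matching the
#' in-memory 1-based R indexing.
#'
#' @param mesh a `tet_mesh`.
#' @param path output path.
#' @export
write_inp <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("*HEADING", con)
  writeLines("footform tetrahedral mesh export", con)
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.9g, %.9g, %.9g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines("*ELEMENT, TYPE=C3D4", con)
  writeLines(sprintf("%d, %d, %d, %d, %d", seq_len(nrow(mesh$tets)),
                     mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                     mesh$tets[, 4]), con)
  write_set <- function(kw, nm, ids) {
    writeLines(sprintf("*%s, %s=%s", kw,
                       if (kw == "NSET") "NSET" else "ELSET", nm), con)
    if (length(ids))
      writeLines(vapply(split(ids, ceiling(seq_along(ids) / 8)),
                        paste, character(1), collapse = ", "), con)
  }
  for (nm in names(mesh$node_sets))
    write_set("NSET", nm, mesh$node_sets[[nm]])
  for (nm in names(mesh$element_sets))
    write_set("ELSET", nm, mesh$element_sets[[nm]])
  invisible(path)
}

#' Read an Abaqus .inp subset into a tetrahedral mesh
#'
#' Parses `*NODE`, `*ELEMENT, TYPE=C3D4` and `*NSET`/`*ELSET` blocks (plain
#' id lists and the `GENERATE` form `first, last, step`). Unsupported
#' keywords are skipped with a warning. File ids may be arbitrary 1-based
#' labels; they are remapped to dense internal ids and the mapping is kept
#' in `provenance$node_id_map` / `provenance$element_id_map`.
#'
#' @param path .inp file path.
#' @return a `tet_mesh`.
#' @export
read_inp <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\*\\*", lines)]  # comments
  kw_idx <- grep("^\\*", lines)
  if (!length(kw_idx)) stop_input("no keywords found in ", path)
  nodes <- NULL; node_ids <- NULL
  elems <- NULL; elem_ids <- NULL
  nsets <- list(); elsets <- list()
  for (b in seq_along(kw_idx)) {
    start <- kw_idx[b]
    end <- if (b < length(kw_idx)) kw_idx[b + 1L] - 1L else length(lines)
    kw <- toupper(lines[start])
    body <- lines[seq(start + 1L, length.out = max(0L, end - start))]
    body <- body[nzchar(trimws(body))]
    parts <- function(s) strsplit(trimws(s), "\\s*,\\s*")[[1]]
    if (grepl("^\\*NODE\\b", kw)) {
      rows <- lapply(body, parts)
      node_ids <- vapply(rows, function(r) as.integer(r[1]), integer(1))
      nodes <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    } else if (grepl("^\\*ELEMENT\\b", kw)) {
      if (!grepl("TYPE\\s*=\\s*C3D4", kw))
        stop_input("only C3D4 elements are supported (line ", start, ")")
      rows <- lapply(body, parts)
      elem_ids <- vapply(rows, function(r) as.integer(r[1]), integer(1))
      elems <- t(vapply(rows, function(r) as.integer(r[2:5]), integer(4)))
    } else if (grepl("^\\*(NSET|ELSET)\\b", kw)) {
      is_nset <- grepl("^\\*NSET", kw)
      nm <- sub(paste0("(?i).*", if (is_nset) "NSET" else "ELSET",
                       "\\s*=\\s*([^,]+).*"), "\\1", lines[start],
                perl = TRUE)
      nm <- trimws(nm)
      ids <- integer(0)
      if (grepl("GENERATE", kw)) {
        for (ln in body) {
          p <- as.integer(parts(ln))
          step <- if (length(p) >= 3 && !is.na(p[3])) p[3] else 1L
          ids <- c(ids, seq(p[1], p[2], by = step))
        }
      } else {
        ids <- as.integer(unlist(lapply(body, parts)))
        ids <- ids[!is.na(ids)]
      }
      if (is_nset) nsets[[nm]] <- ids else elsets[[nm]] <- ids
    } else if (grepl("^\\*HEADING", kw)) {
      # informational
    } else {
      warning("skipping unsupported keyword at line ", start, ": ",
              lines[start])
    }
  }
  if (is.null(nodes)) stop_input("no *NODE block in ", path)
  if (is.null(elems)) stop_input("no *ELEMENT block in ", path)
  nmap <- integer(max(node_ids)); nmap[node_ids] <- seq_along(node_ids)
  bad <- which(!(elems %in% node_ids))
  if (length(bad)) {
    row <- ((bad[1] - 1L) %% nrow(elems)) + 1L
    stop_input("element ", elem_ids[row], " references unknown node (",
               "element block row ", row, ")")
  }
  elems_int <- matrix(nmap[elems], ncol = 4)
  emap <- integer(max(elem_ids)); emap[elem_ids] <- seq_along(elem_ids)
  nsets <- lapply(nsets, function(ids) {
    if (any(ids > length(nmap)) || any(nmap[ids] == 0L))
      stop_input("node set references unknown node")
    unname(nmap[ids])
  })
  elsets <- lapply(elsets, function(ids) {
    if (any(ids > length(emap)) || any(emap[ids] == 0L))
      stop_input("element set references unknown element")
    unname(emap[ids])
  })
  tet_mesh(nodes, elems_int, element_sets = elsets, node_sets = nsets,
           provenance = list(node_id_map = node_ids,
                             element_id_map = elem_ids, source = path))
}

#' Write a pressure series as CSV
#'
#' One row per frame: `time_s`, then row-major cell pressures in kPa.
#' Grid geometry is stored in `#`-prefixed header comments.
#'
#' @param series a `pressure_series`.
#' @param path output path.
#' @export
write_pressure_csv <- function(series, path) {
  d <- dim(series$frames)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# footform pressure series: nrow=%d ncol=%d cell_l=%g cell_w=%g freq=%g",
                     d[2], d[3], series$cell_size[1], series$cell_size[2],
                     series$freq), con)
  cols <- as.vector(t(outer(seq_len(d[2]), seq_len(d[3]),
                            function(r, c) sprintf("p_r%02d_c%02d", r, c))))
  writeLines(paste(c("time_s", cols), collapse = ","), con)
  for (i in seq_len(d[1])) {
    row <- as.vector(t(matrix(series$frames[i, , ], d[2], d[3])))
    writeLines(paste(c(sprintf("%.6f", (i - 1) / series$freq),
                       sprintf("%.6g", row)), collapse = ","), con)
  }
  invisible(path)
}

#' Read a pressure series CSV
#' @param path CSV path written by [write_pressure_csv()].
#' @return a `pressure_series`.
#' @export
read_pressure_csv <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!grepl("^# footform pressure series", first))
    stop_input("not a footform pressure CSV: ", path)
  get_num <- function(key) as.numeric(sub(paste0(".*", key, "="), "",
                          regmatches(first, regexpr(paste0(key, "=[0-9.]+"),
                                                    first))))
  nr <- as.integer(get_num("nrow")); nc <- as.integer(get_num("ncol"))
  cl <- get_num("cell_l"); cw <- get_num("cell_w"); fq <- get_num("freq")
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  nt <- nrow(df)
  frames <- array(0, dim = c(nt, nr, nc))
  pm <- as.matrix(df[, -1, drop = FALSE])
  for (i in seq_len(nt))
    frames[i, , ] <- matrix(pm[i, ], nr, nc, byrow = TRUE)
  pressure_series(frames, cell_size = c(cl, cw), freq = fq)
}

#' Read a loose Pedar-style ASCII pressure export
#'
#' Parses frame-per-block text: each block starts with a line containing
#' `time` and a number, followed by grid rows of whitespace-separated kPa
#' values (heel row first).
#'
#' @param path text file path.
#' @param cell_size cell dimensions (mm).
#' @return a `pressure_series`.
#' @export
read_pedar_ascii <- function(path, cell_size = c(10, 10)) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("time", lines, ignore.case = TRUE)
  if (!length(hdr)) stop_input("no frame blocks found in ", path)
  times <- as.numeric(sub(".*[Tt]ime[^0-9]*([0-9.]+).*", "\\1", lines[hdr]))
  blocks <- lapply(seq_along(hdr), function(b) {
    start <- hdr[b] + 1L
    end <- if (b < length(hdr)) hdr[b + 1L] - 1L else length(lines)
    rows <- lines[start:end]
    rows <- rows[nzchar(trimws(rows))]
    t(vapply(strsplit(trimws(rows), "\\s+"), as.numeric,
             numeric(length(strsplit(trimws(rows[1]), "\\s+")[[1]]))))
  })
  d <- dim(blocks[[1]])
  frames <- array(0, dim = c(length(blocks), d[1], d[2]))
  for (i in seq_along(blocks)) frames[i, , ] <- blocks[[i]]
  freq <- if (length(times) > 1 && diff(times[1:2]) > 0)
    1 / diff(times[1:2]) else 50
  pressure_series(frames, cell_size = cell_size, freq = round(freq, 6))
}

#' Write an unstructured-grid legacy VTK file of a tet mesh
#'
#' @param mesh a `tet_mesh`.
#' @param path output path.
#' @param cell_data optional named list of per-element numeric vectors.
#' @param point_data optional named list of per-node numeric vectors or
#'   3-column matrices (vectors fields).
#' @export
write_vtk <- function(mesh, path, cell_data = list(), point_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0", "footform unstructured grid",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", ne, 5L * ne), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$tets[, 1] - 1L,
                     mesh$tets[, 2] - 1L, mesh$tets[, 3] - 1L,
                     mesh$tets[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("10", ne), con)
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", ne), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
                 con)
      writeLines(sprintf("%.9g", cell_data[[nm]]), con)
    }
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nn), con)
    for (nm in names(point_data)) {
      pd <- point_data[[nm]]
      if (is.matrix(pd) && ncol(pd) == 3) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(sprintf("%.9g %.9g %.9g", pd[, 1], pd[, 2], pd[, 3]), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.9g", pd), con)
      }
    }
  }
  invisible(path)
}

#' Write a surface mesh with a per-vertex scalar as ASCII PLY
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @param scalar optional per-vertex numeric (stored as property `quality`).
#' @export
write_ply <- function(mesh, path, scalar = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$triangles)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property double x", "property double y", "property double z")
  if (!is.null(scalar)) hdr <- c(hdr, "property double quality")
  hdr <- c(hdr, sprintf("element face %d", nt),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  if (is.null(scalar))
    writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
  else
    writeLines(sprintf("%.9g %.9g %.9g %.9g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3], scalar), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  invisible(path)
}

#' Write an error map as CSV (vertex id, signed distance)
#' @param distances per-vertex distances from [error_map()].
#' @param path output path.
#' @export
write_error_map_csv <- function(distances, path) {
  df <- data.frame(vertex = seq_along(distances),
                   distance_mm = as.numeric(distances))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
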