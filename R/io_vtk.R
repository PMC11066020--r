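# File dialects. One dialect per purpose, documented bit-exactly:
#  * volume mesh (+ optional velocity frames): legacy ASCII VTK unstructured
#    grid. Tetrahedra are VTK cell type 10; boundary triangles are carried in
#    the same file as cell type 5. A CELL_DATA integer array
#    `boundary_label` encodes 0 = interior tet, 1 = wall, 2 = inlet,
#    3 = outlet_ica, 4 = outlet_eca. Velocity frames are POINT_DATA FIELD
#    arrays `velocity_frame_<k>` (3 components, cm/s); the cardiac period is
#    recorded in the title line as `period=<s>`.
#  * surfaces: ASCII STL (labels in a CSV sidecar, one label per facet).
#  * waveforms: CSV with columns time_s, flow_mL_s (see read_waveform).

LABEL_CODES <- c(interior = 0L, wall = 1L, inlet = 2L,
                 outlet_ica = 3L, outlet_eca = 4L)

fmt_num <- function(x) trimws(formatC(x, format = "g", digits = 12))

#' Write a volume mesh (and optionally a velocity field) to legacy ASCII VTK
#'
#' @param mesh A [volume_mesh()].
#' @param path Output path.
#' @param field Optional [velocity_field()] on the mesh vertices; frames are
#'   written as point-data arrays `velocity_frame_<k>`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, field = NULL) {
  stopifnot(inherits(mesh, "volume_mesh"))
  nv <- nrow(mesh$vertices)
  tets <- mesh$tetrahedra
  btri <- mesh$boundary$triangles
  # boundary triangles re-expressed in volume vertex indices
  btri_vol <- matrix(mesh$boundary_map[btri], ncol = 3L)
  ncell <- nrow(tets) + nrow(btri_vol)
  title <- "bulbflow unstructured grid"
  if (!is.null(field)) {
    stopifnot(inherits(field, "velocity_field"))
    if (nrow(field$values[[1L]]) != nv)
      stop("field vertex count does not match mesh", call. = FALSE)
    title <- sprintf("bulbflow unstructured grid period=%s", fmt_num(field$period))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nv)), con)
  writeLines(apply(mesh$vertices, 1L, function(r) paste(fmt_num(r), collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", ncell, 5L * nrow(tets) + 4L * nrow(btri_vol)), con)
  writeLines(paste(4L, tets[, 1L] - 1L, tets[, 2L] - 1L, tets[, 3L] - 1L, tets[, 4L] - 1L), con)
  writeLines(paste(3L, btri_vol[, 1L] - 1L, btri_vol[, 2L] - 1L, btri_vol[, 3L] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", ncell), con)
  writeLines(as.character(c(rep(10L, nrow(tets)), rep(5L, nrow(btri_vol)))), con)
  writeLines(sprintf("CELL_DATA %d", ncell), con)
  writeLines(c("SCALARS boundary_label int 1", "LOOKUP_TABLE default"), con)
  codes <- c(rep(0L, nrow(tets)), unname(LABEL_CODES[mesh$boundary$labels]))
  writeLines(as.character(codes), con)
  if (!is.null(field)) {
    nf <- length(field$values)
    writeLines(sprintf("POINT_DATA %d", nv), con)
    writeLines(sprintf("FIELD velocity %d", nf), con)
    for (k in seq_len(nf)) {
      writeLines(sprintf("velocity_frame_%d 3 %d double", k - 1L, nv), con)
      writeLines(apply(field$values[[k]], 1L,
                       function(r) paste(fmt_num(r), collapse = " ")), con)
    }
  }
  invisible(path)
}

# tokenizer keeping a token -> source line map for error reporting
vtk_tokens <- function(lines) {
  sp <- strsplit(trimws(lines), "[ \t]+")
  lens <- lengths(sp)
  list(tok = unlist(sp, use.names = FALSE),
       line = rep(seq_along(lines), lens))
}

vtk_error <- function(msg, state) {
  ln <- if (state$pos <= length(state$line)) state$line[state$pos] else NA_integer_
  stop(sprintf("VTK parse error at line %s: %s", ln, msg), call. = FALSE)
}

vtk_take <- function(state, n) {
  if (state$pos + n - 1L > length(state$tok))
    vtk_error(sprintf("unexpected end of file (wanted %d more tokens)", n), state)
  out <- state$tok[state$pos:(state$pos + n - 1L)]
  state$pos <- state$pos + n
  assign("pos", state$pos, envir = state$env)
  out
}

#' Read a volume mesh (and any velocity field) from legacy ASCII VTK
#'
#' Accepts the dialect written by [write_mesh()]: tetrahedral cells plus
#' labeled boundary triangles. Any other cell type raises an
#' unsupported-cell error; malformed content raises a parse error naming the
#' offending line.
#'
#' @param path VTK file path.
#' @return A list with elements `mesh` (a [volume_mesh()]) and `field`
#'   (a [velocity_field()] or `NULL`).
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5L || !startsWith(lines[1L], "# vtk DataFile"))
    stop("VTK parse error at line 1: not a legacy VTK file", call. = FALSE)
  title <- lines[2L]
  period <- NA_real_
  pm <- regmatches(title, regexec("period=([0-9eE.+-]+)", title))[[1L]]
  if (length(pm) == 2L) period <- as.numeric(pm[2L])
  tk <- vtk_tokens(lines[-(1:2)])
  env <- new.env(); assign("pos", 1L, envir = env)
  state <- list(tok = tk$tok, line = tk$line + 2L, pos = 1L, env = env)
  nxt <- function(n) {
    state$pos <- get("pos", envir = env)
    vtk_take(state, n)
  }
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) {
      state$pos <- get("pos", envir = env) - length(x)
      vtk_error(sprintf("non-numeric token in %s", what), state)
    }
    v
  }
  if (toupper(nxt(1L)) != "ASCII")
    vtk_error("only ASCII encoding is supported", state)
  h <- nxt(2L)
  if (toupper(h[1L]) != "DATASET" || toupper(h[2L]) != "UNSTRUCTURED_GRID")
    vtk_error("expected DATASET UNSTRUCTURED_GRID", state)
  h <- nxt(3L)
  if (toupper(h[1L]) != "POINTS") vtk_error("expected POINTS", state)
  nv <- as.integer(h[2L])
  verts <- matrix(num(nxt(3L * nv), "POINTS"), ncol = 3L, byrow = TRUE)
  h <- nxt(3L)
  if (toupper(h[1L]) != "CELLS") vtk_error("expected CELLS", state)
  ncell <- as.integer(h[2L]); ntok <- as.integer(h[3L])
  raw <- as.integer(num(nxt(ntok), "CELLS"))
  conn <- vector("list", ncell)
  p <- 1L
  for (i in seq_len(ncell)) {
    k <- raw[p]
    conn[[i]] <- raw[(p + 1L):(p + k)] + 1L
    p <- p + k + 1L
  }
  h <- nxt(2L)
  if (toupper(h[1L]) != "CELL_TYPES") vtk_error("expected CELL_TYPES", state)
  ctype <- as.integer(num(nxt(as.integer(h[2L])), "CELL_TYPES"))
  bad <- setdiff(unique(ctype), c(10L, 5L))
  if (length(bad))
    stop(sprintf("unsupported cell type %s: only tetrahedra (10) and triangles (5) are supported",
                 paste(bad, collapse = ",")), call. = FALSE)
  tets <- do.call(rbind, conn[ctype == 10L])
  tris_vol <- do.call(rbind, conn[ctype == 5L])
  if (is.null(tets)) stop("mesh contains no tetrahedra", call. = FALSE)
  # optional CELL_DATA labels and POINT_DATA velocity frames
  labels_code <- NULL
  frames <- list()
  while (get("pos", envir = env) <= length(state$tok)) {
    kw <- toupper(nxt(1L))
    if (kw == "CELL_DATA") {
      nxt(1L)  # count
      h <- nxt(5L)  # SCALARS name type ncomp ; LOOKUP_TABLE
      if (toupper(h[1L]) != "SCALARS") vtk_error("expected SCALARS in CELL_DATA", state)
      nxt(1L)  # table name
      vals <- as.integer(num(nxt(ncell), "CELL_DATA scalars"))
      labels_code <- vals[ctype == 5L]
    } else if (kw == "POINT_DATA") {
      nxt(1L)
      h <- nxt(3L)  # FIELD dataName numArrays
      if (toupper(h[1L]) != "FIELD") vtk_error("expected FIELD in POINT_DATA", state)
      narr <- as.integer(h[3L])
      for (a in seq_len(narr)) {
        ah <- nxt(4L)  # name ncomp ntuples type
        ncomp <- as.integer(ah[2L]); ntup <- as.integer(ah[3L])
        vals <- num(nxt(ncomp * ntup), ah[1L])
        if (grepl("^velocity_frame_", ah[1L]) && ncomp == 3L)
          frames[[ah[1L]]] <- matrix(vals, ncol = 3L, byrow = TRUE)
      }
    } else {
      vtk_error(sprintf("unexpected section `%s`", kw), state)
    }
  }
  if (is.null(labels_code) || is.null(tris_vol))
    stop("mesh file has no labeled boundary triangles", call. = FALSE)
  lab_names <- names(LABEL_CODES)[match(labels_code, LABEL_CODES)]
  if (anyNA(lab_names) || any(lab_names == "interior"))
    stop("invalid boundary label code in cell data", call. = FALSE)
  bidx <- sort(unique(as.vector(tris_vol)))
  remap <- integer(nrow(verts)); remap[bidx] <- seq_along(bidx)
  surf <- surface_mesh(verts[bidx, , drop = FALSE],
                       matrix(remap[tris_vol], ncol = 3L), lab_names)
  mesh <- volume_mesh(verts, tets, surf, boundary_map = bidx)
  field <- NULL
  if (length(frames)) {
    ord <- order(as.integer(sub("velocity_frame_", "", names(frames))))
    frames <- frames[ord]
    nf <- length(frames)
    if (is.na(period))
      stop("velocity frames present but no period= in the title line", call. = FALSE)
    ft <- period * (seq_len(nf) - 1L) / nf
    field <- velocity_field(ft, unname(frames), period)
  }
  list(mesh = mesh, field = field)
}

#' Read a volume mesh from file
#'
#' Thin wrapper over [read_mesh_vtk()] returning the mesh only.
#' @param path VTK file path.
#' @return A [volume_mesh()].
#' @export
read_mesh <- function(path) read_mesh_vtk(path)$mesh

## ---- ASCII STL surfaces ---------------------------------------------------

#' Write a surface mesh as ASCII STL
#'
#' Facet normals come from the stored outward normals. Labels go to a CSV
#' sidecar `<path>.labels.csv` (column `label`, one row per facet).
#'
#' @param surf A [surface_mesh()].
#' @param path Output STL path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(surf, path) {
  stopifnot(inherits(surf, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid bulbflow", con)
  v <- surf$vertices
  for (i in seq_len(nrow(surf$triangles))) {
    tr <- surf$triangles[i, ]
    writeLines(c(sprintf("  facet normal %s", paste(fmt_num(surf$normals[i, ]), collapse = " ")),
                 "    outer loop",
                 sprintf("      vertex %s", paste(fmt_num(v[tr[1L], ]), collapse = " ")),
                 sprintf("      vertex %s", paste(fmt_num(v[tr[2L], ]), collapse = " ")),
                 sprintf("      vertex %s", paste(fmt_num(v[tr[3L], ]), collapse = " ")),
                 "    endloop",
                 "  endfacet"), con)
  }
  writeLines("endsolid bulbflow", con)
  utils::write.csv(data.frame(label = surf$labels),
                   paste0(path, ".labels.csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ASCII STL surface
#'
#' Vertices shared between facets are merged by exact coordinate match.
#' Labels are restored from the `<path>.labels.csv` sidecar when present,
#' otherwise every facet is labeled `wall`.
#'
#' @param path STL file path.
#' @return A [surface_mesh()].
#' @export
read_stl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("STL parse error: vertex count is not a multiple of 3", call. = FALSE)
  coords <- do.call(rbind, lapply(strsplit(trimws(lines[vl]), "\\s+"),
                                  function(t) as.numeric(t[2:4])))
  if (anyNA(coords)) stop("STL parse error: non-numeric vertex", call. = FALSE)
  key <- apply(round(coords / 1e-9), 1L, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- coords[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  tris <- matrix(idx, ncol = 3L, byrow = TRUE)
  side <- paste0(path, ".labels.csv")
  labels <- if (file.exists(side)) utils::read.csv(side)$label else rep("wall", nrow(tris))
  surface_mesh(verts, tris, labels)
}
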