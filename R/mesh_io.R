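# Mesh and field output: legacy-ASCII VTK unstructured grids (hexahedra and
# triangle shells in one grid, with optional cell data) and a documented
# subset of the Abaqus .inp format (*NODE / *ELEMENT / *ELSET).

#' Write a knee model (and optional cell fields) as a VTK unstructured grid
#'
#' Legacy ASCII VTK: all bodies merged into one grid; a `body` cell field
#' encodes the body index (order of `names(model$bodies)`). Additional
#' per-cell fields can be supplied for the hex bodies via `cell_fields`
#' (named list of named-by-body numeric vectors).
#'
#' @param model a `knee_model`.
#' @param file output path (`.vtk`).
#' @param cell_fields optional list: `cell_fields$stress_max_shear$medial_meniscus`
#'   etc.; cells of other bodies get NA.
#' @return invisibly, the file path.
#' @export
write_vtk_model <- function(model, file, cell_fields = list()) {
  nodes <- NULL; cells <- list(); ctypes <- integer(0); body_id <- integer(0)
  offset <- 0L
  bnames <- names(model$bodies)
  for (bi in seq_along(bnames)) {
    b <- model$bodies[[bi]]
    if (is.null(b)) next
    nodes <- rbind(nodes, b$nodes)
    for (e in seq_len(nrow(b$elems))) {
      cells[[length(cells) + 1L]] <- b$elems[e, ] - 1L + offset
      ctypes <- c(ctypes, if (ncol(b$elems) == 8) 12L else 5L)
      body_id <- c(body_id, bi)
    }
    offset <- offset + nrow(b$nodes)
  }
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "kneegait unstructured grid", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(nodes))), con)
  writeLines(apply(nodes, 1, function(p) paste(format(p, digits = 10), collapse = " ")), con)
  sizes <- vapply(cells, length, integer(1))
  writeLines(sprintf("CELLS %d %d", length(cells), sum(sizes) + length(cells)), con)
  writeLines(vapply(cells, function(cc) paste(c(length(cc), cc), collapse = " "),
                    character(1)), con)
  writeLines(sprintf("CELL_TYPES %d", length(cells)), con)
  writeLines(as.character(ctypes), con)
  writeLines(sprintf("CELL_DATA %d", length(cells)), con)
  writeLines(c("SCALARS body int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(body_id), con)
  for (fn in names(cell_fields)) {
    vals <- rep(NA_real_, length(cells))
    for (bn in names(cell_fields[[fn]])) {
      bi <- match(bn, bnames)
      vals[body_id == bi] <- cell_fields[[fn]][[bn]]
    }
    vals[is.na(vals)] <- -1
    writeLines(c(sprintf("SCALARS %s double 1", fn), "LOOKUP_TABLE default"), con)
    writeLines(format(vals, digits = 8), con)
  }
  invisible(file)
}

#' Write a knee model as an Abaqus .inp subset
#'
#' Emits `*NODE`, `*ELEMENT` (C3D8 for hexahedra, S3 for triangle shells) and
#' one `*ELSET` per body. Node and element ids are globally numbered in body
#' order.
#'
#' @param model a `knee_model`.
#' @param file output path (`.inp`).
#' @return invisibly, the file path.
#' @export
write_inp_model <- function(model, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("*HEADING", con)
  writeLines("kneegait parametric knee model", con)
  offset <- 0L; eid <- 0L
  # nodes first (global numbering)
  writeLines("*NODE", con)
  for (b in model$bodies) {
    if (is.null(b)) next
    for (i in seq_len(nrow(b$nodes))) {
      writeLines(sprintf("%d, %.6f, %.6f, %.6f", offset + i,
                         b$nodes[i, 1], b$nodes[i, 2], b$nodes[i, 3]), con)
    }
    offset <- offset + nrow(b$nodes)
  }
  offset <- 0L
  for (bn in names(model$bodies)) {
    b <- model$bodies[[bn]]
    if (is.null(b)) next
    type <- if (ncol(b$elems) == 8) "C3D8" else "S3"
    writeLines(sprintf("*ELEMENT, TYPE=%s, ELSET=%s", type, toupper(bn)), con)
    for (e in seq_len(nrow(b$elems))) {
      eid <- eid + 1L
      writeLines(paste(c(eid, b$elems[e, ] + offset), collapse = ", "), con)
    }
    offset <- offset + nrow(b$nodes)
  }
  invisible(file)
}
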