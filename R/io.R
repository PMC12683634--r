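# Coordinate, energy-record and report I/O.  Energies are always kcal/mol,
# distances Angstrom; TSV files are tab-separated with '#' header comments.

#' Read coordinates from an XYZ or PDB file
#'
#' XYZ: atom count, comment line, then \code{element x y z} per atom, in
#' Angstrom.  PDB: fixed-column ATOM/HETATM records (parsed with bio3d;
#' occupancy/B-factor ignored).  Element symbols are normalized to
#' title case.
#'
#' @param path file path.
#' @param format "xyz" or "pdb"; default guessed from the extension.
#' @return an \code{"evb_frame"} (coords matrix in Angstrom, elements).
#' @export
read_coordinates <- function(path, format = c("auto", "xyz", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path)
    xyz <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
    elem <- pdb$atom$elesy
    if (is.null(elem) || all(!nzchar(elem)))
      elem <- substr(trimws(pdb$atom$elety), 1, 1)
    elem <- .normalize_element(elem)
    return(structure(list(coords = xyz, elements = elem, velocities = NULL),
                     class = "evb_frame"))
  }
  lines <- readLines(path)
  if (length(lines) < 2) stop("truncated XYZ file: fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ header at line 1: '", lines[1], "'")
  if (length(lines) < 2 + n)
    stop("truncated XYZ file: expected ", n, " atom lines, found ",
         max(length(lines) - 2, 0), " (ends at line ", length(lines), ")")
  coords <- matrix(NA_real_, n, 3)
  elements <- character(n)
  for (k in seq_len(n)) {
    ln <- 2 + k
    parts <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(parts) < 4)
      stop("malformed XYZ atom record at line ", ln, ": '", lines[ln], "'")
    xyz <- suppressWarnings(as.numeric(parts[2:4]))
    if (any(is.na(xyz)))
      stop("non-numeric coordinate at line ", ln, ": '", lines[ln], "'")
    elements[k] <- .normalize_element(parts[1])
    coords[k, ] <- xyz
  }
  structure(list(coords = coords, elements = elements, velocities = NULL),
            class = "evb_frame")
}

.normalize_element <- function(x) {
  x <- trimws(x)
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}

#' Write coordinates to an XYZ file
#'
#' @param frame an \code{"evb_frame"} or N x 3 coordinate matrix.
#' @param path output path.
#' @param elements element symbols (taken from the frame if present).
#' @param comment second-line comment.
#' @return \code{path}, invisibly.
#' @export
write_xyz <- function(frame, path, elements = NULL, comment = "") {
  xyz <- .frame_coords(frame)
  if (is.null(elements)) {
    elements <- if (is.list(frame) && !is.null(frame$elements)) frame$elements
                else rep("X", nrow(xyz))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(xyz)), con)
  writeLines(comment, con)
  writeLines(sprintf("%-2s %14.6f %14.6f %14.6f",
                     elements, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  invisible(path)
}

#' Write coordinates as a minimal PDB file
#'
#' Thin wrapper over bio3d's PDB writer; each atom becomes a HETATM-style
#' record with its element as the atom name.
#'
#' @inheritParams write_xyz
#' @return \code{path}, invisibly.
#' @export
write_pdb_coords <- function(frame, path, elements = NULL) {
  xyz <- .frame_coords(frame)
  if (is.null(elements)) {
    elements <- if (is.list(frame) && !is.null(frame$elements)) frame$elements
                else rep("X", nrow(xyz))
  }
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                   type = rep("ATOM", nrow(xyz)),
                   elety = elements, resid = rep("MOL", nrow(xyz)),
                   resno = rep(1L, nrow(xyz)),
                   elesy = elements)
  invisible(path)
}

#' Write lambda-window energy records as TSV
#'
#' Columns: window_index, lambda, step, eps1, eps2, V (kcal/mol), with
#' '#'-prefixed header comments.
#'
#' @param windows list of \code{"traj_window"} objects.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_energy_records <- function(windows, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# EVB lambda-window diabatic energy records",
               "# energies in kcal/mol",
               "window_index\tlambda\tstep\teps1\teps2\tV"), con)
  for (k in seq_along(windows)) {
    w <- windows[[k]]
    idx <- if (is.na(w$window_index)) k else w$window_index
    stp <- if (is.null(w$step)) seq_along(w$eps1) else w$step
    writeLines(sprintf("%d\t%.6g\t%d\t%.10g\t%.10g\t%.10g",
                       idx, w$lambda, stp, w$eps1, w$eps2, w$vmap), con)
  }
  invisible(path)
}

#' Read lambda-window energy records from TSV
#'
#' Inverse of [write_energy_records()]: records are grouped by window and
#' sorted by step within each window.
#'
#' @param path file path.
#' @return list of \code{"traj_window"} objects (possibly empty).
#' @export
read_energy_records <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("window_index", "lambda", "step", "eps1", "eps2", "V")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("energy-record file is missing column(s): ",
         paste(miss, collapse = ", "))
  for (col in need) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) | !is.finite(vals))
    if (length(bad))
      stop("non-numeric value in column '", col, "' at data row ", bad[1])
    df[[col]] <- vals
  }
  df$window_index <- as.integer(df$window_index)
  df$step <- as.integer(df$step)
  out <- list()
  for (idx in sort(unique(df$window_index))) {
    sub <- df[df$window_index == idx, , drop = FALSE]
    sub <- sub[order(sub$step), , drop = FALSE]
    out[[length(out) + 1L]] <- structure(
      list(lambda = sub$lambda[1], eps1 = sub$eps1, eps2 = sub$eps2,
           vmap = sub$V, step = sub$step, window_index = idx),
      class = "traj_window")
  }
  out
}

#' Write an analysis report as JSON (and optionally TSV tables)
#'
#' Serializes a named list of results together with provenance (package
#' version, seeds, unit system, configuration) to JSON.  Re-running with
#' identical inputs produces byte-identical output.
#'
#' @param results named list of numeric results or tables.
#' @param path output JSON path.
#' @param seeds integer seeds used to produce the results.
#' @param config optional configuration list echoed into the report.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(results, path, seeds = NULL, config = NULL) {
  payload <- list(
    package = "protolysis",
    version = as.character(utils::packageVersion("protolysis")),
    units = list(energy = "kcal/mol", distance = "Angstrom", time = "fs"),
    seeds = seeds,
    config = config,
    results = results
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
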