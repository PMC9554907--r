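# PDB parsing/writing is delegated to bio3d; this module converts units
# (PDB Angstrom <-> internal nm), splits multi-MODEL trajectories into
# frames and validates records up front so errors carry line numbers.

new_frame <- function(atoms, xyz, box = NULL, frame = 1L, time = NA_real_) {
  if (anyDuplicated(atoms$serial))
    stop("duplicate atom serials within a frame")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in frame")
  if (!is.null(box) && any(box <= 0)) stop("box vectors must be positive")
  structure(list(atoms = atoms, xyz = as.matrix(xyz), box = box,
                 frame = as.integer(frame), time = time),
            class = "interface_frame")
}

#' @export
print.interface_frame <- function(x, ...) {
  cat(sprintf("interface_frame %d: %d atoms%s\n", x$frame, nrow(x$xyz),
              if (is.null(x$box)) "" else sprintf(", box (%.3f, %.3f, %.3f) nm",
                                                  x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

#' Read a PDB structure or multi-MODEL trajectory
#'
#' Parses ATOM/HETATM/CRYST1/MODEL/ENDMDL records and returns one frame
#' per MODEL block (a single frame when no MODEL records are present).
#' Coordinates are converted to the internal nm convention at the
#' boundary (PDB Angstrom / 10) unless the file is declared to already be
#' in nm.
#'
#' @param path PDB file path.
#' @param unit unit of the coordinates in the file: `"angstrom"`
#'   (standard PDB, default) or `"nm"`.
#' @return list of `interface_frame` objects, each with an `atoms`
#'   data.frame (serial, name, resname, resid, element), an `xyz` matrix
#'   in nm and the `box` lengths in nm when a CRYST1 record is present.
#' @export
read_structure <- function(path, unit = c("angstrom", "nm")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("empty input: no ATOM/HETATM records in ", path)
  bad <- which(is_atom &
                 (nchar(lines) < 54 |
                    is.na(suppressWarnings(as.numeric(substr(lines, 31, 38)))) |
                    is.na(suppressWarnings(as.numeric(substr(lines, 39, 46)))) |
                    is.na(suppressWarnings(as.numeric(substr(lines, 47, 54))))))
  if (length(bad))
    stop(sprintf("malformed ATOM record at line %d of %s", bad[1], path))
  scale <- if (unit == "angstrom") 0.1 else 1
  box <- NULL
  cry <- grep("^CRYST1", lines, value = TRUE)
  if (length(cry)) {
    abc <- suppressWarnings(as.numeric(c(substr(cry[1], 7, 15),
                                         substr(cry[1], 16, 24),
                                         substr(cry[1], 25, 33))))
    if (anyNA(abc)) stop("malformed CRYST1 record in ", path)
    box <- abc * scale
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nf <- nrow(pdb$xyz)
  atoms <- data.frame(serial = pdb$atom$eleno, name = pdb$atom$elety,
                      resname = pdb$atom$resid, resid = pdb$atom$resno,
                      element = pdb$atom$elesy)
  lapply(seq_len(nf), function(f) {
    xyz <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE) * scale
    new_frame(atoms, xyz, box = box, frame = f)
  })
}

#' Write frames as a (multi-MODEL) PDB file
#'
#' Inverse of [read_structure()]: internal nm coordinates are written in
#' Angstrom, one MODEL block per frame (a single block for one frame),
#' with a CRYST1 record when the first frame carries box lengths.
#'
#' @param frames an `interface_frame` or a list of them (equal atom
#'   tables).
#' @param path output PDB path.
#' @export
write_structure <- function(frames, path) {
  if (inherits(frames, "interface_frame")) frames <- list(frames)
  f1 <- frames[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(f1$box))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       f1$box[1] * 10, f1$box[2] * 10, f1$box[3] * 10,
                       90, 90, 90), con)
  multi <- length(frames) > 1
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    a <- fr$atoms
    x <- fr$xyz * 10
    writeLines(sprintf("ATOM  %5d %-4s %-4sA%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       a$serial %% 100000L, substr(a$name, 1, 4),
                       substr(a$resname, 1, 4), a$resid %% 10000L,
                       x[, 1], x[, 2], x[, 3], 1, 0,
                       substr(a$element, 1, 2)), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a bracketed-group index file
#'
#' @param groups named list of integer index vectors.
#' @param path output path.
#' @export
write_index <- function(groups, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(groups)) {
    writeLines(sprintf("[ %s ]", nm), con)
    idx <- groups[[nm]]
    for (s in seq(1, length(idx), by = 15))
      writeLines(paste(idx[s:min(s + 14, length(idx))], collapse = " "), con)
  }
  invisible(path)
}

#' Read a bracketed-group index file
#'
#' GROMACS-style dialect: `[ name ]` headers followed by
#' whitespace-separated one-based atom indices matching PDB serials.
#'
#' @param path index file path.
#' @return named list of integer index vectors, group order and index
#'   order preserved.
#' @export
read_index <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, ";")]
  heads <- grep("^\\[.*\\]$", lines)
  if (!length(heads)) stop("no [ group ] headers in ", path)
  groups <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (h in seq_along(heads)) {
    name <- trimws(gsub("^\\[|\\]$", "", lines[heads[h]]))
    body <- if (heads[h] + 1L > bounds[h + 1L] - 1L) character(0)
            else lines[seq(heads[h] + 1L, bounds[h + 1L] - 1L)]
    tok <- unlist(strsplit(paste(body, collapse = " "), "\\s+"))
    tok <- tok[nzchar(tok)]
    idx <- suppressWarnings(as.integer(tok))
    if (anyNA(idx)) stop("non-integer index in group '", name, "'")
    if (any(idx <= 0)) stop("indices must be positive in group '", name, "'")
    if (anyDuplicated(idx)) stop("duplicate index in group '", name, "'")
    groups[[name]] <- idx
  }
  groups
}

#' Resolve an index group against a frame
#'
#' Matches one-based indices to PDB serials and returns the coordinate
#' rows; indices absent from the frame raise a resolution error.
#'
#' @param frame an `interface_frame`.
#' @param idx integer atom indices (PDB serials).
#' @return coordinate matrix (length(idx) x 3, nm).
#' @export
frame_coords <- function(frame, idx) {
  stopifnot(inherits(frame, "interface_frame"))
  pos <- match(idx, frame$atoms$serial)
  if (anyNA(pos))
    stop("index group refers to serial(s) absent from the structure: ",
         paste(utils::head(idx[is.na(pos)], 5), collapse = ", "))
  frame$xyz[pos, , drop = FALSE]
}

#' Write a grid surface as a color-annotated pseudo-atom PDB
#'
#' One pseudo-atom per grid node (all `(bin+1)(bin/2+1)` of them, in
#' node-major order) with the per-node scalar written to the B-factor
#' column, for 3D topographical color-map rendering.  Values outside the
#' PDB column range `[-99.99, 999.99]` are clamped with a warning.
#'
#' @param grid a `spherical_grid`.
#' @param values per-node scalars: a vector of length `n_nodes` or a
#'   matrix congruent with `grid$r`.
#' @param path output PDB path (coordinates written in Angstrom).
#' @export
write_colored_grid <- function(grid, values, path) {
  stopifnot(inherits(grid, "spherical_grid"))
  v <- as.vector(values)
  if (length(v) != grid$n_nodes)
    stop(sprintf("values length %d does not match the %d grid nodes",
                 length(v), grid$n_nodes))
  if (any(v < -99.99 | v > 999.99)) {
    warning("B-factor values clamped to [-99.99, 999.99]")
    v <- pmin(pmax(v, -99.99), 999.99)
  }
  xyz <- grid_nodes(grid)$xyz * 10              # nm -> Angstrom
  n <- nrow(xyz)
  bio3d::write.pdb(file = path, xyz = as.vector(t(xyz)),
                   type = rep("ATOM", n), eleno = seq_len(n),
                   elety = rep("GD", n), resid = rep("GRD", n),
                   resno = rep(1L, n), b = round(v, 2),
                   elesy = rep("C", n))
  invisible(path)
}

#' Write a whitespace-delimited time series file
#'
#' Header comment lines (prefixed `#`) name the columns; rows are written
#' with deterministic formatting so identical inputs give byte-identical
#' files.
#'
#' @param times time stamps (one per row).
#' @param columns named list (or data.frame) of numeric columns, all the
#'   same length as `times`.
#' @param path output path.
#' @param comments extra header comment lines.
#' @export
write_series <- function(times, columns, path, comments = character()) {
  columns <- as.list(columns)
  lens <- vapply(columns, length, 0L)
  if (length(columns) && any(lens != length(times)))
    stop("all columns must have the same length as 'times'")
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste("#", cm), con)
  writeLines(paste("#", paste(c("time", names(columns)), collapse = "  ")), con)
  if (length(times)) {
    m <- cbind(times, do.call(cbind, columns))
    writeLines(apply(m, 1, function(row)
      paste(formatC(row, format = "g", digits = 8), collapse = "  ")), con)
  }
  invisible(path)
}

#' Read a series file written by [write_series()]
#'
#' @param path series file path.
#' @return data.frame with a `time` column and one column per series.
#' @export
read_series <- function(path) {
  lines <- readLines(path, warn = FALSE)
  heads <- lines[startsWith(lines, "#")]
  nm <- strsplit(trimws(sub("^#", "", utils::tail(heads, 1))), "\\s+")[[1]]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) {
    dat <- as.data.frame(matrix(numeric(0), 0, length(nm)))
    names(dat) <- nm
    return(dat)
  }
  dat <- utils::read.table(text = body)
  names(dat) <- nm[seq_len(ncol(dat))]
  dat
}
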