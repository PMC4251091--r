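#' Read a chromatogram matrix from CSV
#'
#' Plain comma-separated numeric matrix, '.' decimal.  A single header
#' row is auto-detected (first row entirely non-numeric) and dropped.
#' The on-disk orientation must be stated; the returned chromatogram is
#' always wavelength x time and the orientation decision is logged, so
#' the loader never transposes silently.
#'
#' @param path CSV file path.
#' @param orientation \code{"wavelength-rows"} (rows are wavelength
#'   channels) or \code{"time-rows"} (rows are time points; the matrix
#'   is transposed after reading).
#' @return a \code{\link{chromatogram}}.
#' @export
read_matrix_csv <- function(path,
                            orientation = c("wavelength-rows", "time-rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  nfields <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nfields)) != 1L)
    stop("ragged CSV: rows have differing field counts (",
         paste(unique(nfields), collapse = ", "), ") in ", path)
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         strip.white = TRUE)
  first_numeric <- suppressWarnings(as.numeric(unlist(raw[1, ])))
  has_header <- all(is.na(first_numeric))
  if (has_header && nrow(raw) > 1L) raw <- raw[-1, , drop = FALSE]
  M <- matrix(NA_real_, nrow(raw), ncol(raw))
  for (j in seq_len(ncol(raw))) {
    col <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(!is.finite(col))
    if (length(bad))
      stop("non-numeric or non-finite value '", raw[bad[1], j],
           "' at data row ", bad[1], ", column ", j, " of ", path)
    M[, j] <- col
  }
  if (orientation == "time-rows") M <- t(M)
  message("read ", path, ": ", nrow(M), " wavelength channels x ",
          ncol(M), " time points (on-disk orientation: ", orientation, ")")
  chromatogram(M)
}

# ---- MATLAB v5 MAT files ---------------------------------------------
# Minimal codec for level-5 MAT files (the format used by the public
# HPLC-DAD dataset): full and small data elements, numeric 2-D arrays,
# zlib-compressed elements.  v7.3/HDF5 files are out of scope.

MI_TYPES <- c(miINT8 = 1, miUINT8 = 2, miINT16 = 3, miUINT16 = 4,
              miINT32 = 5, miUINT32 = 6, miSINGLE = 7, miDOUBLE = 9,
              miINT64 = 12, miUINT64 = 13, miMATRIX = 14,
              miCOMPRESSED = 15, miUTF8 = 16)

read_mi_numeric <- function(data, type, endian) {
  sz <- switch(as.character(type),
               "1" = 1L, "2" = 1L, "3" = 2L, "4" = 2L, "5" = 4L,
               "6" = 4L, "7" = 4L, "9" = 8L, "12" = 8L, "13" = 8L,
               stop("unsupported MAT numeric type ", type))
  what <- if (type %in% c(7, 9)) "double" else "integer"
  signed <- !(type %in% c(2, 4, 6, 13))
  n <- length(data) %/% sz
  readBin(data, what = what, n = n, size = sz, signed = signed,
          endian = endian)
}

# read one tagged data element starting at offset pos (1-based);
# returns list(type, data (raw), next_pos)
read_mat_element <- function(buf, pos, endian) {
  word <- readBin(buf[pos:(pos + 3L)], "integer", size = 4, endian = endian)
  upper <- bitwShiftR(word, 16L)
  if (upper != 0L) {                     # small data element: 4 data bytes
    type <- bitwAnd(word, 0xFFFFL)
    size <- upper
    data <- buf[(pos + 4L):(pos + 3L + size)]
    return(list(type = type, data = data, next_pos = pos + 8L))
  }
  type <- word
  size <- readBin(buf[(pos + 4L):(pos + 7L)], "integer", size = 4,
                  endian = endian)
  data <- if (size > 0) buf[(pos + 8L):(pos + 7L + size)] else raw()
  pad <- if (type == MI_TYPES[["miCOMPRESSED"]]) 0L else (8L - size %% 8L) %% 8L
  list(type = type, data = data, next_pos = pos + 8L + size + pad)
}

parse_mat_matrix <- function(data, endian) {
  pos <- 1L
  flags <- read_mat_element(data, pos, endian); pos <- flags$next_pos
  fl <- readBin(flags$data[1:4], "integer", size = 4, endian = endian)
  class_id <- bitwAnd(fl, 0xFFL)
  dims_el <- read_mat_element(data, pos, endian); pos <- dims_el$next_pos
  dims <- read_mi_numeric(dims_el$data, MI_TYPES[["miINT32"]], endian)
  name_el <- read_mat_element(data, pos, endian); pos <- name_el$next_pos
  name <- rawToChar(name_el$data[name_el$data != as.raw(0)])
  if (!(class_id %in% 6:13) || length(dims) != 2L)
    return(list(name = name, matrix = NULL,
                note = paste0("class ", class_id, ", ",
                              length(dims), "-D (unsupported)")))
  real_el <- read_mat_element(data, pos, endian)
  vals <- read_mi_numeric(real_el$data, real_el$type, endian)
  list(name = name, matrix = matrix(vals, dims[1], dims[2]), note = NULL)
}

read_mat_variables <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  buf <- readBin(path, "raw", file.size(path))
  if (length(buf) < 136L) stop(path, " is too short to be a MAT v5 file")
  magic <- rawToChar(buf[127:128])
  endian <- switch(magic, IM = "little", MI = "big",
                   stop(path, " is not a MATLAB v5 MAT-file ",
                        "(bad endian indicator; v7.3/HDF5 is unsupported)"))
  pos <- 129L
  out <- list()
  while (pos + 7L <= length(buf)) {
    el <- read_mat_element(buf, pos, endian)
    pos <- el$next_pos
    payload <- el
    if (el$type == MI_TYPES[["miCOMPRESSED"]]) {
      inner <- memDecompress(el$data, type = "gzip")
      payload <- read_mat_element(inner, 1L, endian)
    }
    if (payload$type == MI_TYPES[["miMATRIX"]]) {
      v <- parse_mat_matrix(payload$data, endian)
      out[[v$name]] <- v
    }
  }
  out
}

#' Load a chromatogram from a MATLAB v5 MAT-file
#'
#' Reads the named 2-D numeric variable.  MAT files do not record which
#' axis is elution time, so the orientation is a user decision; the
#' default heuristic assumes the longer axis is time (a diode-array
#' detector records hundreds-to-thousands of time points over at most a
#' few hundred wavelength channels).  The decision is always logged.
#'
#' @param path MAT-file path (level 5; v7.3/HDF5 is not supported).
#' @param variable_name variable to load; may be omitted when the file
#'   holds exactly one 2-D numeric variable.
#' @param orientation \code{"auto"} (longer axis = time),
#'   \code{"wavelength-rows"} or \code{"time-rows"}.
#' @return a \code{\link{chromatogram}}.
#' @export
read_mat_dataset <- function(path, variable_name = NULL,
                             orientation = c("auto", "wavelength-rows",
                                             "time-rows")) {
  orientation <- match.arg(orientation)
  vars <- read_mat_variables(path)
  numeric_vars <- names(vars)[vapply(vars, function(v)
    !is.null(v$matrix), TRUE)]
  if (is.null(variable_name)) {
    if (length(numeric_vars) != 1L)
      stop("specify variable_name; ", path, " contains: ",
           paste(names(vars), collapse = ", "))
    variable_name <- numeric_vars
  }
  if (!variable_name %in% names(vars))
    stop("variable '", variable_name, "' not in ", path,
         "; available: ", paste(names(vars), collapse = ", "))
  v <- vars[[variable_name]]
  if (is.null(v$matrix))
    stop("variable '", variable_name, "' is not a 2-D numeric array (",
         v$note, ")")
  M <- v$matrix
  if (orientation == "auto") {
    orientation <- if (nrow(M) > ncol(M)) "time-rows" else "wavelength-rows"
    message("orientation heuristic: assuming the longer axis (",
            max(dim(M)), " points) is elution time")
  }
  if (orientation == "time-rows") M <- t(M)
  message("read ", path, " variable '", variable_name, "': ",
          nrow(M), " wavelength channels x ", ncol(M),
          " time points (orientation: ", orientation, ")")
  chromatogram(M)
}

#' Write a numeric matrix to a MATLAB v5 MAT-file
#'
#' Writes one uncompressed double-precision 2-D array; the counterpart
#' of \code{\link{read_mat_dataset}}, also used to build round-trip test
#' fixtures.
#'
#' @param x numeric matrix.
#' @param path output path.
#' @param name MATLAB variable name (default \code{"X"}).
#' @return \code{path}, invisibly.
#' @export
write_mat_matrix <- function(x, path, name = "X") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- charToRaw(paste0("MATLAB 5.0 MAT-file, written by the picarc ",
                           "R package"))
  header <- c(desc, rep(charToRaw(" "), 116L - length(desc)))
  writeBin(header, con)
  writeBin(raw(8L), con)                               # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)                 # version 0x0100
  writeBin(charToRaw("IM"), con)                       # little-endian
  nm <- charToRaw(name)
  nm_pad <- (8L - length(nm) %% 8L) %% 8L
  data_bytes <- 8L * length(x)
  total <- 16L + 16L + 8L + length(nm) + nm_pad + 8L + data_bytes
  w32 <- function(...) writeBin(as.integer(c(...)), con, size = 4,
                                endian = "little")
  w32(MI_TYPES[["miMATRIX"]], total)
  w32(MI_TYPES[["miUINT32"]], 8L, 6L, 0L)              # flags: mxDOUBLE
  w32(MI_TYPES[["miINT32"]], 8L, nrow(x), ncol(x))
  w32(MI_TYPES[["miINT8"]], length(nm))
  writeBin(nm, con)
  if (nm_pad) writeBin(raw(nm_pad), con)
  w32(MI_TYPES[["miDOUBLE"]], data_bytes)
  writeBin(as.vector(x), con, size = 8, endian = "little")
  invisible(path)
}

# ---- result files -----------------------------------------------------

write_matrix_csv <- function(M, path) {
  if (is.null(M) || length(M) == 0L) {   # degenerate: no compounds found
    file.create(path)
    return(invisible(path))
  }
  utils::write.table(format(M, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

read_plain_matrix_csv <- function(path) {
  as.matrix(utils::read.csv(path, header = FALSE))
}

#' Write a separation result to a directory
#'
#' Writes \code{peaks.csv} (n x t recovered elution curves),
#' \code{spectra.csv} (m x n estimated spectra), \code{thetas.csv}
#' (mu, sigma, fitness rows), \code{history.csv} (the per-generation
#' area table) and \code{summary.json} (seed, configuration, solution
#' list, convergence).  Matrices round-trip at full double precision.
#'
#' @param result a \code{\link{separate}} result.
#' @param out_dir output directory, created if missing.
#' @return the file paths, invisibly.
#' @export
write_separation_result <- function(result, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  th <- normalize_theta_matrix(result$thetas)
  th_df <- data.frame(mu = integer(), sigma = integer(),
                      fitness = numeric())
  if (!is.null(th) && nrow(th))
    th_df <- data.frame(mu = th[, 1], sigma = th[, 2],
                        fitness = result$fitness)
  paths <- file.path(out_dir, c("peaks.csv", "spectra.csv", "thetas.csv",
                                "history.csv", "summary.json"))
  names(paths) <- c("peaks", "spectra", "thetas", "history", "summary")
  write_matrix_csv(result$peaks, paths["peaks"])
  write_matrix_csv(result$spectra, paths["spectra"])
  utils::write.csv(th_df, paths["thetas"], row.names = FALSE)
  utils::write.csv(result$run_log, paths["history"], row.names = FALSE)
  summary <- list(
    seed = result$config$seed,
    config = unclass(result$config),
    fit_options = unclass(result$fit_opts),
    solutions = if (nrow(th_df)) th_df else list(),
    generations = result$generations,
    converged = result$converged,
    n_negative_spectra = attr(result$spectra, "n_negative"))
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read back a separation result directory
#'
#' @param dir a directory written by \code{\link{write_separation_result}}.
#' @return list with \code{peaks}, \code{spectra}, \code{thetas} (matrix),
#'   \code{fitness}, \code{summary}.
#' @export
read_separation_result <- function(dir) {
  need <- file.path(dir, c("peaks.csv", "spectra.csv", "thetas.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("missing result file(s): ", paste(missing, collapse = ", "))
  th <- utils::read.csv(file.path(dir, "thetas.csv"))
  summary_path <- file.path(dir, "summary.json")
  list(peaks = read_plain_matrix_csv(need[1]),
       spectra = read_plain_matrix_csv(need[2]),
       thetas = as.matrix(th[, c("mu", "sigma"), drop = FALSE]),
       fitness = th$fitness,
       summary = if (file.exists(summary_path))
         jsonlite::read_json(summary_path) else NULL)
}
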