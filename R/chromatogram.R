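#' Construct a 3D chromatogram object
#'
#' A "3D chromatogram" is the absorbance matrix recorded by an HPLC-DAD
#' instrument: one row per detector wavelength channel, one column per
#' elution time point (the third "dimension" is the absorbance value
#' itself).  The elution-time axis is indexed 1..t; all peak-centre
#' parameters elsewhere in the package are reported on this axis.
#'
#' @param absorbance numeric matrix, wavelength channels in rows and
#'   elution time points in columns.
#' @param wavelength_axis optional labels for the rows (length m).
#' @return an object of class \code{chromatogram} with fields
#'   \code{absorbance}, \code{time_axis} (integer \code{1:t}) and
#'   \code{wavelength_axis}.
#' @export
chromatogram <- function(absorbance, wavelength_axis = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  m <- nrow(absorbance)
  t <- ncol(absorbance)
  if (m < 2L)
    stop("a chromatogram needs at least 2 wavelength channels, got ", m)
  if (t < 7L)
    stop("a chromatogram needs at least 7 time points (no admissible ",
         "peak width below that), got ", t)
  if (!all(is.finite(absorbance)))
    stop("absorbance matrix contains non-finite values")
  if (!is.null(wavelength_axis) && length(wavelength_axis) != m)
    stop("wavelength_axis has length ", length(wavelength_axis),
         ", expected ", m)
  structure(
    list(absorbance = absorbance,
         time_axis = seq_len(t),
         wavelength_axis = wavelength_axis),
    class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat("<chromatogram> ", nrow(x$absorbance), " wavelength channels x ",
      ncol(x$absorbance), " time points\n", sep = "")
  invisible(x)
}

#' @export
dim.chromatogram <- function(x) dim(x$absorbance)

n_time <- function(x) ncol(x$absorbance)
n_wavelength <- function(x) nrow(x$absorbance)

as_chromatogram <- function(x) {
  if (inherits(x, "chromatogram")) x else chromatogram(x)
}
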