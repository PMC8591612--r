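# 1-D absolute-intensity SAXS curves.
#
# All curves are held in internal units: q in 1/Angstrom, intensity in
# 1/Angstrom.  Reduced data on absolute scale are commonly reported in
# mm^-1; 1 mm^-1 == 1e-7 A^-1 and the reader applies that conversion.

#' Construct a scattering curve
#'
#' @param q Scattering vector magnitudes, 1/Angstrom; strictly increasing,
#'   positive.
#' @param intensity Absolute intensities; unit given by `unit`.
#' @param sigma Optional intensity uncertainties, same unit as `intensity`.
#' @param unit One of `"A-1"` (internal unit, default) or `"mm-1"`
#'   (converted to 1/Angstrom on construction).
#' @return Object of class `scattering_curve`: a list with elements `q`,
#'   `intensity`, `sigma` (possibly `NULL`), all in internal units.
#' @export
scattering_curve <- function(q, intensity, sigma = NULL,
                             unit = c("A-1", "mm-1")) {
  unit <- match.arg(unit)
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) != length(intensity)) {
    stop("q and intensity must have equal length")
  }
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop("sigma must match q in length")
  }
  if (any(!is.finite(q)) || any(q <= 0)) stop("q must be positive and finite")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (any(!is.finite(intensity))) stop("intensity must be finite")
  if (!is.null(sigma) && any(sigma <= 0)) stop("sigma must be positive")
  if (unit == "mm-1") {
    intensity <- intensity * 1e-7
    if (!is.null(sigma)) sigma <- sigma * 1e-7
  }
  structure(list(q = q, intensity = intensity, sigma = sigma),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("scattering_curve: %d points, q in [%.4g, %.4g] A^-1%s\n",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) "" else ", with uncertainties"))
  invisible(x)
}

#' Read a reduced SAXS curve from ASCII
#'
#' Parses the common reduced-SAXS dialect: 2-3 whitespace- or
#' comma-separated numeric columns (q, intensity, optional sigma), `#`
#' comment lines anywhere.  Column units are q in 1/Angstrom and intensity
#' in mm^-1 unless `unit = "A-1"`.
#'
#' @param path File path.
#' @param unit Intensity unit of the file, `"mm-1"` (default) or `"A-1"`.
#' @return A [scattering_curve()] in internal units.
#' @export
read_scattering_ascii <- function(path, unit = c("mm-1", "A-1")) {
  unit <- match.arg(unit)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop("no data rows in ", path)
  rows <- strsplit(trimws(lines[keep]), "[,[:space:]]+")
  ncol <- lengths(rows)
  if (any(ncol < 2 | ncol > 3)) {
    bad <- which(keep)[which(ncol < 2 | ncol > 3)[1]]
    stop("line ", bad, ": expected 2 or 3 numeric columns")
  }
  if (length(unique(ncol)) != 1) stop("inconsistent column counts in ", path)
  vals <- suppressWarnings(vapply(rows, as.numeric, numeric(ncol[1])))
  if (anyNA(vals)) {
    bad <- which(keep)[which(colSums(is.na(rbind(vals))) > 0)[1]]
    stop("line ", bad, ": non-numeric value")
  }
  vals <- matrix(vals, nrow = ncol[1])
  scattering_curve(vals[1, ], vals[2, ],
                   sigma = if (ncol[1] == 3) vals[3, ] else NULL,
                   unit = unit)
}

#' Write a scattering curve to ASCII
#'
#' Inverse of [read_scattering_ascii()]; writes q, intensity and (when
#' present) sigma at 12 significant digits with a `#` header.
#'
#' @param curve A [scattering_curve()].
#' @param path Output path.
#' @param unit Intensity unit for the file, `"mm-1"` (default) or `"A-1"`.
#' @export
write_scattering_ascii <- function(curve, path, unit = c("mm-1", "A-1")) {
  unit <- match.arg(unit)
  stopifnot(inherits(curve, "scattering_curve"))
  fac <- if (unit == "mm-1") 1e7 else 1
  cols <- list(curve$q, curve$intensity * fac)
  hdr <- "# q[A^-1]  I"
  if (!is.null(curve$sigma)) {
    cols <- c(cols, list(curve$sigma * fac))
    hdr <- paste(hdr, "sigma")
  }
  hdr <- paste0(hdr, sprintf("  [%s]", unit))
  body <- do.call(paste, c(lapply(cols, formatC, digits = 12, format = "g"),
                           list(sep = "  ")))
  writeLines(c(hdr, body), path)
}
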