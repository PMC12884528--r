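# Stick-to-curve convolution and normalization for vibrational and
# absorption spectra.

#' Stick spectrum
#'
#' Discrete per-mode spectrum: positions (cm^-1 for vibrational spectra, eV
#' for absorption) and non-negative heights, sorted by position.
#'
#' @param positions stick positions (finite).
#' @param heights stick heights (>= 0).
#' @param kind one of `"IR"`, `"Raman"`, `"absorption"`.
#' @return object of class `stick_spectrum`.
#' @export
stick_spectrum <- function(positions, heights,
                           kind = c("IR", "Raman", "absorption")) {
  kind <- match.arg(kind)
  stopifnot(length(positions) == length(heights))
  if (any(!is.finite(positions))) stop("stick positions must be finite")
  if (any(heights < 0)) stop("stick heights must be non-negative")
  o <- order(positions)
  structure(list(positions = positions[o], heights = heights[o], kind = kind),
            class = "stick_spectrum")
}

#' Lorentzian band convolution
#'
#' Replaces each stick by an area-normalized Lorentzian of full width at
#' half-maximum `fwhm`, so that the integral of each band equals its stick
#' height and the peak value of an isolated band of height `h` is
#' `2 h / (pi fwhm)`.  The default 10 cm^-1 width is the customary choice for
#' simulated vibrational spectra.
#'
#' @param sticks a [stick_spectrum()].
#' @param grid increasing output grid (same unit as the stick positions).
#' @param fwhm full width at half-maximum (same unit), default 10.
#' @param normalize scale the curve to unit maximum after convolution.
#' @return object of class `curve_spectrum` with fields `grid`, `values`,
#'   `fwhm`, `normalized`, `kind`.
#' @export
lorentzian_convolve <- function(sticks, grid, fwhm = 10, normalize = FALSE) {
  stopifnot(inherits(sticks, "stick_spectrum"))
  if (fwhm <= 0) stop("`fwhm` must be positive")
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("`grid` must be strictly increasing")
  }
  vals <- numeric(length(grid))
  if (length(sticks$positions) == 0L) {
    warning("empty stick spectrum: returning a zero curve")
  } else {
    hw <- fwhm / 2
    for (k in seq_along(sticks$positions)) {
      vals <- vals + sticks$heights[k] * (hw / pi) /
        ((grid - sticks$positions[k])^2 + hw^2)
    }
  }
  out <- structure(list(grid = grid, values = vals, fwhm = fwhm,
                        normalized = FALSE, kind = sticks$kind),
                   class = "curve_spectrum")
  if (normalize) out <- normalize_spectrum(out)
  out
}

#' Normalize a curve spectrum to unit maximum
#'
#' @param curve a `curve_spectrum` (or any list with `values`).
#' @return the curve scaled so that `max(values)` is exactly 1.
#' @export
normalize_spectrum <- function(curve) {
  m <- max(curve$values)
  if (!is.finite(m) || m <= 0) {
    stop("cannot normalize: curve maximum is not positive")
  }
  curve$values <- curve$values / m
  curve$values[which.max(curve$values)] <- 1   # exact unit maximum
  curve$normalized <- TRUE
  curve
}

#' @export
print.curve_spectrum <- function(x, ...) {
  cat(sprintf("<curve_spectrum> %s, %d points, fwhm = %g%s\n", x$kind,
              length(x$grid), x$fwhm,
              if (isTRUE(x$normalized)) ", normalized" else ""))
  invisible(x)
}

#' @export
plot.curve_spectrum <- function(x, ...) {
  graphics::plot(x$grid, x$values, type = "l",
                 xlab = if (x$kind == "absorption") "frequency (eV)" else
                   expression(tilde(nu) ~ (cm^-1)),
                 ylab = "intensity", ...)
  invisible(x)
}

#' @export
print.stick_spectrum <- function(x, ...) {
  cat(sprintf("<stick_spectrum> %s, %d sticks\n", x$kind,
              length(x$positions)))
  invisible(x)
}

#' Machine-readable run manifest
#'
#' Writes a JSON manifest (inputs, parameters, seeds, package version)
#' sufficient to reproduce a deterministic run bit for bit.  Used by the
#' command-line interface; available to scripted workflows as well.
#'
#' @param path output path.
#' @param command name of the operation.
#' @param inputs named list of input descriptions.
#' @param parameters named list of parameters.
#' @param seed integer seed or `NULL`.
#' @return the path, invisibly.
#' @export
write_run_manifest <- function(path, command, inputs = list(),
                               parameters = list(), seed = NULL) {
  obj <- list(command = command,
              package = "plasmovib",
              version = as.character(utils::packageVersion("plasmovib")),
              seed = seed, inputs = inputs, parameters = parameters,
              r_version = R.version.string)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
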