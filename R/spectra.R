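# Synthetic coelomic-fluid fluorescence scans. The M-fluorophore fingerprint
# is an excitation peak near 320 nm (window 314-320) and an emission peak
# near 380 nm (window 370-380); M-negative fluid is featureless baseline.

SPECTRUM_RANGES <- list(emission = c(340, 480), excitation = c(260, 360))
PEAK_WINDOWS <- list(emission = c(370, 380), excitation = c(314, 320))

#' Spectrum generator parameters
#'
#' Shape parameters of the synthetic fluorescence scans. Peak centers are the
#' instrument-reported maxima (emission 380 nm at 320 nm excitation;
#' excitation 320 nm monitored at 380 nm). The Gaussian peak width and the
#' baseline/peak heights are generator conventions in arbitrary fluorescence
#' units, not measured quantities.
#'
#' @param baseline Baseline intensity (a.u.).
#' @param peak_height Peak height above baseline for M-positive scans (a.u.).
#' @param peak_sd Gaussian peak SD in nm.
#' @param emission_center,excitation_center Peak centers in nm.
#' @return A list of class `spectrum_params`.
#' @export
spectrum_params <- function(baseline = 10, peak_height = 100, peak_sd = 15,
                            emission_center = 380, excitation_center = 320) {
  stopifnot(baseline > 0, peak_height > 0, peak_sd > 0)
  structure(list(baseline = baseline, peak_height = peak_height,
                 peak_sd = peak_sd, emission_center = emission_center,
                 excitation_center = excitation_center),
            class = "spectrum_params")
}

new_spectrum <- function(axis, wavelengths_nm, intensities) {
  stopifnot(length(wavelengths_nm) == length(intensities),
            all(diff(wavelengths_nm) > 0), all(intensities >= 0))
  structure(list(axis = axis, wavelength_nm = wavelengths_nm,
                 intensity = intensities),
            class = "fluor_spectrum")
}

#' @export
print.fluor_spectrum <- function(x, ...) {
  cat(sprintf("%s spectrum: %d points, %g-%g nm, argmax %g nm\n",
              x$axis, length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm),
              x$wavelength_nm[which.max(x$intensity)]))
  invisible(x)
}

#' Generate a synthetic fluorescence scan
#'
#' M-positive scans are a Gaussian peak on a low baseline, centered at the
#' fingerprint wavelength of the chosen axis (emission recorded 340-480 nm,
#' peak 380 nm; excitation recorded 260-360 nm, peak 320 nm) on a 1-nm grid.
#' M-negative scans are baseline only. Gaussian noise of SD `noise_sd` is
#' added and intensities are clipped at zero.
#'
#' @param m_status `"Mp"` or `"Mn"`.
#' @param axis `"emission"` or `"excitation"`.
#' @param noise_sd Additive noise SD (a.u.), `>= 0`.
#' @param params A [spectrum_params()] object.
#' @param seed Optional integer seed for the noise draw.
#' @return A `fluor_spectrum` object.
#' @examples
#' em <- generate_spectrum("Mp", "emission")
#' em$wavelength_nm[which.max(em$intensity)]  # 380
#' @export
generate_spectrum <- function(m_status = c("Mp", "Mn"),
                              axis = c("emission", "excitation"),
                              noise_sd = 0, params = spectrum_params(),
                              seed = NULL) {
  m_status <- match.arg(m_status)
  axis <- match.arg(axis)
  stopifnot(is.numeric(noise_sd), noise_sd >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  rng <- SPECTRUM_RANGES[[axis]]
  wl <- seq(rng[1], rng[2], by = 1)
  center <- if (axis == "emission") params$emission_center else
    params$excitation_center
  y <- rep(params$baseline, length(wl))
  if (m_status == "Mp") {
    y <- y + params$peak_height * exp(-(wl - center)^2 / (2 * params$peak_sd^2))
  }
  if (noise_sd > 0) y <- y + stats::rnorm(length(wl), 0, noise_sd)
  new_spectrum(axis, wl, pmax(y, 0))
}

check_spectrum_axis <- function(sp, axis) {
  if (!inherits(sp, "fluor_spectrum")) {
    stop("expected a 'fluor_spectrum' object for the ", axis, " axis",
         call. = FALSE)
  }
  if (sp$axis != axis) {
    stop(sprintf("spectrum labelled '%s' supplied where %s was expected",
                 sp$axis, axis), call. = FALSE)
  }
  rng <- SPECTRUM_RANGES[[axis]]
  if (min(sp$wavelength_nm) < rng[1] || max(sp$wavelength_nm) > rng[2]) {
    stop(sprintf("%s grid outside the recorded range %g-%g nm",
                 axis, rng[1], rng[2]), call. = FALSE)
  }
  win <- PEAK_WINDOWS[[axis]]
  if (min(sp$wavelength_nm) > win[1] || max(sp$wavelength_nm) < win[2]) {
    stop(sprintf("%s grid does not cover the %g-%g nm peak window",
                 axis, win[1], win[2]), call. = FALSE)
  }
  invisible(sp)
}

#' Classify a scan pair as M-positive or M-negative
#'
#' A specimen is called M-positive iff the emission argmax lies in the
#' 370-380 nm window, the excitation argmax lies in the 314-320 nm window,
#' and both peaks exceed the prominence threshold, where prominence is
#' (peak - median intensity) / median intensity. Argmax ties break toward
#' the lower wavelength. Grids outside the recorded ranges are rejected.
#'
#' @param emission,excitation `fluor_spectrum` objects of the matching axes.
#' @param prominence_threshold Minimum prominence of both peaks (default 2).
#' @return A list with `m_status`, `emission_peak_nm`, `excitation_peak_nm`,
#'   and the two prominences.
#' @examples
#' classify_spectrum(generate_spectrum("Mp", "emission"),
#'                   generate_spectrum("Mp", "excitation"))$m_status
#' @export
classify_spectrum <- function(emission, excitation,
                              prominence_threshold = 2) {
  check_spectrum_axis(emission, "emission")
  check_spectrum_axis(excitation, "excitation")
  peak_of <- function(sp) {
    i <- which.max(sp$intensity)  # ties -> lowest wavelength
    med <- stats::median(sp$intensity)
    prom <- if (med > 0) (sp$intensity[i] - med) / med else Inf
    list(nm = sp$wavelength_nm[i], prominence = prom)
  }
  em <- peak_of(emission)
  ex <- peak_of(excitation)
  in_win <- function(x, axis) {
    w <- PEAK_WINDOWS[[axis]]
    x >= w[1] && x <= w[2]
  }
  mp <- in_win(em$nm, "emission") && in_win(ex$nm, "excitation") &&
    em$prominence > prominence_threshold &&
    ex$prominence > prominence_threshold
  list(m_status = if (mp) "Mp" else "Mn",
       emission_peak_nm = em$nm, excitation_peak_nm = ex$nm,
       emission_prominence = em$prominence,
       excitation_prominence = ex$prominence)
}

#' Read and write spectra as two-column CSV
#'
#' Plain comma-separated text with header `wavelength_nm,intensity`.
#'
#' @param path File path.
#' @param axis Axis label to attach on read.
#' @param spectrum A `fluor_spectrum` object.
#' @return `read_spectrum()`: a `fluor_spectrum`; `write_spectrum()`: `path`,
#'   invisibly.
#' @export
read_spectrum <- function(path, axis = c("emission", "excitation")) {
  axis <- match.arg(axis)
  df <- utils::read.csv(path, header = TRUE)
  if (!all(c("wavelength_nm", "intensity") %in% names(df))) {
    stop("spectrum file needs columns 'wavelength_nm' and 'intensity'",
         call. = FALSE)
  }
  new_spectrum(axis, df$wavelength_nm, df$intensity)
}

#' @rdname read_spectrum
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "fluor_spectrum"))
  utils::write.csv(data.frame(wavelength_nm = spectrum$wavelength_nm,
                              intensity = spectrum$intensity),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
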