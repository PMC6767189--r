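# Powder WAXS via the Debye scattering equation.
#
# The isotropic (orientationally averaged) Debye sum is
#   I(q) = sum_k sum_j f_k(s) f_j(s) sinc(q r_kj),   sinc(x) = sin(x)/x,
# with q = 4 pi sin(theta) / lambda the physical scattering-vector magnitude
# and s = 2 sin(theta) / lambda the crystallographic scattering variable
# reported alongside. Self terms (k = j, r = 0) contribute f^2. Under a
# periodic box, pair distances use the minimum-image convention with a hard
# cutoff at half the shortest box edge.

#' Atomic X-ray form factor
#'
#' Evaluates the Cromer-Mann four-Gaussian-plus-constant parameterization
#' \eqn{f(s) = \sum_i a_i e^{-b_i (s/2)^2} + c} where `s = 2 sin(theta)/lambda`
#' in 1/Angstrom (the tabulated coefficients use `sin(theta)/lambda = s/2`).
#' At `s = 0` the form factor equals the electron count within 1%.
#'
#' @param element Element symbol (see [gel_elements()]).
#' @param s Scattering variable `2 sin(theta)/lambda` in 1/Angstrom (>= 0).
#' @return Dimensionless scattering amplitude, same length as `s`.
#' @export
form_factor <- function(element, s) {
  stopifnot(all(s >= 0))
  e <- .element(element)
  if (is.null(e$cm_a)) {
    stop("no form-factor coefficients registered for element '", element, "'",
         call. = FALSE)
  }
  q2 <- (s / 2)^2
  f <- rep(e$cm_c, length(s))
  for (i in 1:4) f <- f + e$cm_a[i] * exp(-e$cm_b[i] * q2)
  f
}

.sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)

.pair_distances <- function(frame, cutoff = NULL) {
  n <- n_atoms(frame)
  if (n < 2L) return(list(d = numeric(0), key = character(0)))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d3 <- frame$coords[idx[, 2], , drop = FALSE] -
        frame$coords[idx[, 1], , drop = FALSE]
  periodic <- !is.null(frame$box) && frame$box$periodic
  if (periodic) {
    L <- frame$box$lengths
    for (k in 1:3) d3[, k] <- d3[, k] - L[k] * round(d3[, k] / L[k])
  }
  d <- sqrt(rowSums(d3^2))
  e1 <- frame$elements[idx[, 1]]
  e2 <- frame$elements[idx[, 2]]
  key <- ifelse(e1 <= e2, paste(e1, e2), paste(e2, e1))
  if (periodic) {
    keep <- d <= (cutoff %||% (min(frame$box$lengths) / 2))
    d <- d[keep]; key <- key[keep]
  }
  list(d = d, key = key)
}

#' Powder WAXS intensity by the Debye equation
#'
#' Computes the orientationally averaged scattering intensity of a frame on a
#' `2 theta` grid: self terms plus pairwise `2 f_k f_j sinc(q r)` terms.
#' Periodic frames use minimum-image distances with a hard cutoff at half the
#' shortest box edge (finite-box termination ripples can optionally be damped
#' with a Lorch window).
#'
#' @param frame A [gel_frame] with at least one atom.
#' @param two_theta Strictly increasing grid of scattering angles in degrees,
#'   inside (0, 180).
#' @param wavelength X-ray wavelength in Angstrom (default Cu K-alpha,
#'   1.54178 A as used for gelatin WAXS).
#' @param window `"none"` (default) or `"lorch"`.
#' @return A `scattering_profile`: data frame with columns `two_theta`, `s`
#'   (`2 sin(theta)/lambda`, 1/Angstrom) and `intensity` (arbitrary units),
#'   with the wavelength as attribute.
#' @examples
#' fr <- make_lattice("sc", a = 4, n_cells = 3)
#' prof <- debye_intensity(fr, seq(5, 50, by = 0.5))
#' main_peak(prof)
#' @export
debye_intensity <- function(frame, two_theta, wavelength = 1.54178,
                            window = c("none", "lorch")) {
  window <- match.arg(window)
  stopifnot(inherits(frame, "gel_frame"), n_atoms(frame) >= 1L)
  if (!is.numeric(wavelength) || wavelength <= 0) {
    stop("wavelength must be positive", call. = FALSE)
  }
  stopifnot(all(two_theta > 0), all(two_theta < 180),
            all(diff(two_theta) > 0))
  theta <- two_theta * pi / 360               # theta in radians
  s <- 2 * sin(theta) / wavelength
  q <- 2 * pi * s                             # 4 pi sin(theta) / lambda
  els <- unique(frame$elements)
  fmat <- vapply(els, function(e) form_factor(e, s), numeric(length(s)))
  fmat <- matrix(fmat, ncol = length(els),
                 dimnames = list(NULL, els))
  counts <- table(frame$elements)
  intensity <- rowSums(sweep(fmat^2, 2, as.numeric(counts[els]), `*`))
  pd <- .pair_distances(frame)
  if (length(pd$d)) {
    r_max <- max(pd$d)
    for (k in unique(pd$key)) {
      ab <- strsplit(k, " ")[[1]]
      d <- pd$d[pd$key == k]
      w <- if (window == "lorch") .sinc(pi * d / r_max) else 1
      # sum over pairs of sinc(q r), vectorized over the angle grid in chunks
      ff <- fmat[, ab[1]] * fmat[, ab[2]]
      chunk <- max(1L, floor(5e7 / length(d)))
      sums <- numeric(length(q))
      for (i0 in seq(1L, length(q), by = chunk)) {
        ii <- i0:min(i0 + chunk - 1L, length(q))
        sums[ii] <- colSums(.sinc(outer(d, q[ii])) * w)
      }
      intensity <- intensity + 2 * ff * sums
    }
  }
  structure(data.frame(two_theta = two_theta, s = s, intensity = intensity),
            class = c("scattering_profile", "data.frame"),
            wavelength = wavelength)
}

#' Locate the principal WAXS peak
#'
#' Returns the `2 theta` position of the global intensity maximum inside a
#' window (default 5-50 degrees, the range typically scanned for gelatin).
#' Optional smoothing applies a centered running mean of the given width (in
#' grid points) before the argmax; default off.
#'
#' @param profile A `scattering_profile` from [debye_intensity()].
#' @param window Length-2 degrees interval.
#' @param smooth Odd integer smoothing width in grid points (0 = off).
#' @return Peak position in degrees.
#' @export
main_peak <- function(profile, window = c(5, 50), smooth = 0L) {
  stopifnot(inherits(profile, "data.frame"), length(window) == 2L)
  keep <- profile$two_theta >= window[1] & profile$two_theta <= window[2]
  if (!any(keep)) stop("empty peak-search window", call. = FALSE)
  tt <- profile$two_theta[keep]
  y <- profile$intensity[keep]
  if (smooth > 1L) {
    k <- as.integer(smooth)
    if (k %% 2L == 0L) k <- k + 1L
    y <- stats::filter(y, rep(1 / k, k), sides = 2)
    ok <- !is.na(y)
    tt <- tt[ok]; y <- y[ok]
  }
  tt[which.max(y)]
}

#' Bragg angle of a cubic lattice reflection
#'
#' Convenience oracle: `2 theta = 2 arcsin(lambda / (2 d))` in degrees for
#' plane spacing `d` (e.g. the (100) spacing equals the lattice constant).
#'
#' @param d_spacing Plane spacing in Angstrom.
#' @param wavelength Wavelength in Angstrom.
#' @return `2 theta` in degrees.
#' @export
bragg_angle <- function(d_spacing, wavelength = 1.54178) {
  stopifnot(d_spacing > 0, wavelength > 0, wavelength <= 2 * d_spacing)
  2 * asin(wavelength / (2 * d_spacing)) * 180 / pi
}
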