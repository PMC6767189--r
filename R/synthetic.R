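# Seeded generators for every input class the pipeline consumes: lattice and
# random-packing coordinate boxes, noisy thermodynamic series, bilinear
# specific-volume series with a planted glass transition, and cleavable
# random sequences with annotated ground-truth cut sites. Every generator is
# deterministic under a fixed seed (the seed is applied locally via withr, so
# the caller's RNG state is untouched).
#
# Generator defaults encode the simulated gelatin world the calculators are
# validated against: density 1.3248 g/cm^3, alpha_p = 6.072e-4 1/K over
# 273-318 K in ~1 K steps, delta(298 K) = 27.2 MPa^0.5 with slope
# 0.01005 MPa^0.5/K, Tg = 424.7 K from 100-600 K dilatometry in 50 K steps.
# Noise levels derive from the printed ANOVA residual variances (see the
# methods vignette).

#' Crystalline lattice frame
#'
#' Periodic simple-cubic or face-centered-cubic lattice, used as a Bragg-law
#' oracle input for the Debye scattering module.
#'
#' @param type `"sc"` (1 atom/cell) or `"fcc"` (4 atoms/cell).
#' @param a Lattice constant in Angstrom (> 0).
#' @param n_cells Number of unit cells per edge (>= 2).
#' @param element Element symbol for every site.
#' @return A [gel_frame] with a periodic box of edge `n_cells * a`.
#' @export
make_lattice <- function(type = c("sc", "fcc"), a = 4, n_cells = 5,
                         element = "C") {
  type <- match.arg(type)
  stopifnot(a > 0, n_cells >= 2)
  n_cells <- as.integer(n_cells)
  g <- as.matrix(expand.grid(i = 0:(n_cells - 1L), j = 0:(n_cells - 1L),
                             k = 0:(n_cells - 1L)))
  basis <- switch(type,
    sc  = matrix(c(0, 0, 0), 1, 3),
    fcc = matrix(c(0, 0, 0, 0.5, 0.5, 0, 0.5, 0, 0.5, 0, 0.5, 0.5),
                 4, 3, byrow = TRUE))
  coords <- do.call(rbind, lapply(seq_len(nrow(basis)), function(b) {
    sweep(g, 2, basis[b, ], `+`) * a
  }))
  gel_frame(rep(element, nrow(coords)), coords,
            box = gel_box(n_cells * a, periodic = TRUE),
            label = sprintf("%s lattice a=%g n=%d", type, a, n_cells))
}

#' Random non-overlapping atom packing
#'
#' Rejection-samples `n_atoms` positions uniformly in a periodic box subject
#' to a minimum-image pair-distance constraint. Reproducible by seed.
#'
#' @param n_atoms Number of atoms (0 allowed: empty frame).
#' @param box Box edge length(s) in Angstrom.
#' @param elements Element symbols, recycled over atoms.
#' @param min_dist Minimum pair distance in Angstrom.
#' @param seed Integer seed.
#' @param max_attempts Rejection attempts per atom before giving up.
#' @return A [gel_frame].
#' @export
make_random_box <- function(n_atoms, box = 20, elements = "C",
                            min_dist = 1.5, seed = 1L,
                            max_attempts = 10000L) {
  stopifnot(n_atoms >= 0, min_dist >= 0)
  bx <- gel_box(box, periodic = TRUE)
  L <- bx$lengths
  coords <- matrix(numeric(0), 0, 3)
  withr::with_seed(seed, {
    for (i in seq_len(n_atoms)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        p <- stats::runif(3) * L
        if (nrow(coords)) {
          d3 <- sweep(coords, 2, p)
          for (k in 1:3) d3[, k] <- d3[, k] - L[k] * round(d3[, k] / L[k])
          if (min(sqrt(rowSums(d3^2))) < min_dist) next
        }
        coords <- rbind(coords, p)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("packing failed: could not place atom ", i, " after ",
             max_attempts, " attempts", call. = FALSE)
      }
    }
  })
  gel_frame(rep_len(elements, n_atoms), coords, box = bx,
            label = sprintf("random box seed=%d", seed))
}

#' Synthetic NPT thermodynamic series
#'
#' Emulates the per-temperature equilibrium averages of an NPT gelatin run:
#' density follows \eqn{\rho(T) = \rho_0 e^{-\alpha_p T} (1 + \epsilon)} with
#' zero-mean Gaussian relative noise, on an evenly spaced temperature grid
#' (default 273-318 K at ~1 K increments, 46 points). When `mass` is given,
#' per-frame volumes are derived from the density, and a linearly drifting
#' Hansen solubility parameter \eqn{\delta(T)} (with its own noise) is
#' converted into a consistent nonbonded-energy column so that the series
#' also exercises [hansen_delta()].
#'
#' Default noise levels are taken from the printed ANOVA residual variances
#' of the reference gelatin model: sd 6.653e-3 on ln(rho) and 0.2363 MPa^0.5
#' on delta.
#'
#' @param rho0 Density prefactor; the default puts rho(298 K) at
#'   1.3248 g/cm^3.
#' @param alpha_p Planted isobaric expansion coefficient in 1/K.
#' @param T_range Length-2 temperature range in K.
#' @param n_points Number of evenly spaced temperatures (>= 3).
#' @param sigma Relative density noise sd.
#' @param seed Integer seed.
#' @param mass Total mass in g/mol (NULL: no volume/energy columns). The
#'   default cell (31.89 A cube at 1.3248 g/cm^3) weighs ~25876 g/mol.
#' @param delta298,delta_slope,delta_sigma Hansen-parameter drift used for
#'   the energy column when `mass` is given: delta(T) = delta298 +
#'   delta_slope (T - 298) + noise.
#' @return A [thermo_series] (energies in kcal/mol when present).
#' @export
make_thermo_series <- function(rho0 = 1.3248 * exp(6.072e-4 * 298),
                               alpha_p = 6.072e-4,
                               T_range = c(273, 318), n_points = 46L,
                               sigma = 6.653e-3, seed = 1L,
                               mass = NULL, delta298 = 27.2,
                               delta_slope = 0.01005,
                               delta_sigma = 0.2363) {
  stopifnot(n_points >= 3L, rho0 > 0, diff(T_range) > 0)
  temps <- seq(T_range[1], T_range[2], length.out = n_points)
  withr::with_seed(seed, {
    eps <- stats::rnorm(n_points, 0, sigma)
    rho <- rho0 * exp(-alpha_p * temps) * (1 + eps)
    if (is.null(mass)) {
      thermo_series(temperature = temps, density = rho)
    } else {
      vol <- (mass / .AVOGADRO) / rho * 1e24   # cm^3 -> Angstrom^3
      delta <- delta298 + delta_slope * (temps - 298) +
        stats::rnorm(n_points, 0, delta_sigma)
      # invert CED [MPa] = delta^2 into a kcal/mol nonbonded energy
      energy <- delta^2 * 1e6 * (vol * 1e-30) * .AVOGADRO / .KCAL_J
      thermo_series(temperature = temps, volume = vol, density = rho,
                    energy = energy, energy_unit = "kcal/mol", mass = mass)
    }
  })
}

#' Synthetic bilinear specific-volume series with a planted Tg
#'
#' Continuous two-segment line (glassy slope below `Tg`, rubbery slope above)
#' plus Gaussian noise — the dilatometric signature [glass_transition()] is
#' designed to detect. Defaults emulate the reference protocol: 100-600 K in
#' 50 K steps, knee at 424.7 K, glassy slope from alpha_p times the specific
#' volume, rubbery slope three times larger, noise sd 0.002 cm^3/g.
#'
#' @param Tg Planted breakpoint in K, strictly inside `T_range`.
#' @param slope_lo,slope_hi Segment slopes in cm^3/(g K).
#' @param v_tg Specific volume at the breakpoint (cm^3/g).
#' @param T_range Length-2 temperature range in K.
#' @param n_points Number of evenly spaced temperatures.
#' @param sigma Noise sd in cm^3/g.
#' @param seed Integer seed.
#' @return List with `temps` (K) and `specific_volume` (cm^3/g).
#' @export
make_bilinear_series <- function(Tg = 424.7, slope_lo = 4.6e-4,
                                 slope_hi = 1.38e-3, v_tg = 0.80,
                                 T_range = c(100, 600), n_points = 11L,
                                 sigma = 0.002, seed = 1L) {
  stopifnot(Tg > T_range[1], Tg < T_range[2], n_points >= 6L)
  temps <- seq(T_range[1], T_range[2], length.out = n_points)
  v <- v_tg + ifelse(temps < Tg, slope_lo, slope_hi) * (temps - Tg)
  if (sigma > 0) {
    v <- v + withr::with_seed(seed, stats::rnorm(n_points, 0, sigma))
  }
  list(temps = temps, specific_volume = v)
}

#' Random sequences with annotated true trypsin cut sites
#'
#' Generates amino-acid sequences position by position: a free position is
#' K/R with probability `kr_rate`; the residue following a K/R is P (which
#' blocks cleavage) with probability `kp_rate`, otherwise drawn from the
#' non-proline standard residues. Ground-truth cleavage positions (0-based,
#' cut after the index) are recorded from the generated residues by direct
#' application of the rule, independent of [trypsin_digest()].
#'
#' @param n Number of sequences.
#' @param length Residues per sequence.
#' @param kr_rate Probability of K/R at a free position, in \[0, 1\].
#' @param kp_rate Probability that the residue after a K/R is P.
#' @param seed Integer seed.
#' @return List of [aa_seq] objects, each with attribute `cut_sites`.
#' @export
make_cleavage_sequences <- function(n = 10L, length = 50L, kr_rate = 0.1,
                                    kp_rate = 0.2, seed = 1L) {
  stopifnot(kr_rate >= 0, kr_rate <= 1, kp_rate >= 0, kp_rate <= 1,
            length >= 1L)
  other <- setdiff(.AA_ALPHABET, c("K", "R", "P", "X"))
  withr::with_seed(seed, {
    lapply(seq_len(n), function(si) {
      res <- character(length)
      i <- 1L
      while (i <= length) {
        if (stats::runif(1) < kr_rate) {
          res[i] <- sample(c("K", "R"), 1L)
          if (i < length) {
            res[i + 1L] <- if (stats::runif(1) < kp_rate) "P" else
              sample(other, 1L)
            i <- i + 2L
            next
          }
        } else {
          res[i] <- sample(other, 1L)
        }
        i <- i + 1L
      }
      cuts <- which(res %in% c("K", "R") &
                    seq_along(res) < length &
                    c(res[-1], "") != "P") - 1L
      s <- aa_seq(paste(res, collapse = ""), id = sprintf("synth%03d", si))
      attr(s, "cut_sites") <- cuts
      s
    })
  })
}

#' Synthetic collagen-like alpha-1 chain
#'
#' A 1464-residue stand-in for the human collagen alpha-1(I) sequence, built
#' from a G-X-Y repeat body with collagen-like residue statistics flanked by
#' non-repetitive telopeptide-like ends. It is *synthetic*: it reproduces the
#' real record's length and broad composition (glycine every third residue,
#' proline-rich, K/R sprinkled at collagen-like rates), not its actual
#' residues. Deterministic under the seed.
#'
#' @param length Total chain length (default 1464).
#' @param seed Integer seed.
#' @return An [aa_seq] with id `"collagen_alpha1_synthetic"`.
#' @export
make_synthetic_collagen <- function(length = 1464L, seed = 52L) {
  stopifnot(length >= 30L)
  body_len <- length - 30L                     # two 15-residue flanks
  n_triplets <- ceiling(body_len / 3)
  other_y <- c("A", "S", "E", "Q", "L", "V", "T", "D", "N", "F", "M")
  withr::with_seed(seed, {
    flank <- function() paste(sample(c("Q", "L", "S", "Y", "D", "E", "A",
                                       "G", "V", "M", "F", "H"),
                                     15L, replace = TRUE), collapse = "")
    trip <- vapply(seq_len(n_triplets), function(i) {
      xpos <- sample(c("P", "A", "E", "L", "K", "R", "S", "D"), 1L,
                     prob = c(0.30, 0.18, 0.12, 0.10, 0.08, 0.08, 0.08, 0.06))
      ypos <- sample(c("P", other_y), 1L,
                     prob = c(0.35, rep(0.65 / length(other_y),
                                        length(other_y))))
      paste0("G", xpos, ypos)
    }, "")
    body <- substr(paste(trip, collapse = ""), 1L, body_len)
    aa_seq(paste0(flank(), body, flank()), id = "collagen_alpha1_synthetic")
  })
}
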