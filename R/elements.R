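# Physical constants used throughout; SI unless noted.
.AVOGADRO <- 6.02214076e23      # 1/mol
.R_GAS    <- 8.314462618        # J/(mol K)
.KCAL_J   <- 4184               # J per kcal (thermochemical calorie)

# Element table: atomic number, Bondi van der Waals radius (Angstrom),
# atomic mass (g/mol), and Cromer-Mann form-factor coefficients
# f(q) = sum_i a_i exp(-b_i q^2) + c with q = sin(theta)/lambda in 1/Angstrom
# (International Tables for Crystallography, Vol. C).
.element_env <- new.env(parent = emptyenv())

.register_element <- function(symbol, z, vdw, mass, a, b, c) {
  assign(symbol, list(symbol = symbol, z = z, vdw = vdw, mass = mass,
                      cm_a = a, cm_b = b, cm_c = c),
         envir = .element_env)
}

.register_element("H", 1, 1.20, 1.008,
  a = c(0.489918, 0.262003, 0.196767, 0.049879),
  b = c(20.6593, 7.74039, 49.5519, 2.20159),
  c = 0.001305)
.register_element("C", 6, 1.70, 12.011,
  a = c(2.31000, 1.02000, 1.58860, 0.865000),
  b = c(20.8439, 10.2075, 0.568700, 51.6512),
  c = 0.215600)
.register_element("N", 7, 1.55, 14.007,
  a = c(12.2126, 3.13220, 2.01250, 1.16630),
  b = c(0.005700, 9.89330, 28.9975, 0.582600),
  c = -11.529)
.register_element("O", 8, 1.52, 15.999,
  a = c(3.04850, 2.28680, 1.54630, 0.867000),
  b = c(13.2771, 5.70110, 0.323900, 32.9089),
  c = 0.250800)
.register_element("S", 16, 1.80, 32.06,
  a = c(6.90530, 5.20340, 1.43790, 1.58630),
  b = c(1.46790, 22.2151, 0.253600, 56.1720),
  c = 0.866900)

.element <- function(symbol) {
  e <- get0(symbol, envir = .element_env, inherits = FALSE)
  if (is.null(e)) {
    stop("unknown element '", symbol, "'; supported: ",
         paste(sort(ls(.element_env)), collapse = ", "), call. = FALSE)
  }
  e
}

#' Supported chemical elements
#'
#' Returns the table of elements known to the structure and scattering
#' machinery (symbol, atomic number, Bondi van der Waals radius in Angstrom,
#' atomic mass in g/mol). Additional elements can be registered with
#' [register_element()].
#'
#' @return A data frame with one row per supported element.
#' @export
gel_elements <- function() {
  syms <- sort(ls(.element_env))
  do.call(rbind, lapply(syms, function(s) {
    e <- .element(s)
    data.frame(symbol = e$symbol, z = e$z, vdw_radius = e$vdw, mass = e$mass,
               stringsAsFactors = FALSE)
  }))
}

#' Register an additional element
#'
#' Extends the supported-element table, e.g. for phosphorus-containing
#' systems. Cromer-Mann coefficients are required only if the element will be
#' used in scattering calculations.
#'
#' @param symbol Chemical symbol.
#' @param z Atomic number (electron count).
#' @param vdw_radius Van der Waals radius in Angstrom.
#' @param mass Atomic mass in g/mol.
#' @param cm_a,cm_b Length-4 Cromer-Mann Gaussian coefficients (optional).
#' @param cm_c Cromer-Mann constant term (optional).
#' @return Invisibly, the registered entry.
#' @export
register_element <- function(symbol, z, vdw_radius, mass,
                             cm_a = NULL, cm_b = NULL, cm_c = NULL) {
  stopifnot(is.character(symbol), length(symbol) == 1L, z > 0,
            vdw_radius > 0, mass > 0)
  if (!is.null(cm_a)) stopifnot(length(cm_a) == 4L, length(cm_b) == 4L,
                                length(cm_c) == 1L)
  .register_element(symbol, z, vdw_radius, mass, cm_a, cm_b, cm_c)
  invisible(get(symbol, envir = .element_env))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
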