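# Atomic-structure containers and plain-text readers/writers (PDB, XYZ,
# LAMMPS-dump dialect, delimited thermodynamic tables).

#' Periodic simulation box
#'
#' @param lengths Edge lengths in Angstrom (length 1 recycled to 3).
#' @param periodic Logical flag.
#' @return Object of class `gel_box`.
#' @export
gel_box <- function(lengths, periodic = TRUE) {
  if (length(lengths) == 1L) lengths <- rep(lengths, 3L)
  stopifnot(length(lengths) == 3L, all(is.finite(lengths)), all(lengths > 0))
  structure(list(lengths = as.numeric(lengths), periodic = isTRUE(periodic)),
            class = "gel_box")
}

#' Atomic frame
#'
#' A set of atoms (element symbols and Cartesian coordinates in Angstrom) in
#' an optional periodic box — one snapshot of a trajectory.
#'
#' @param elements Character vector of element symbols (must be in
#'   [gel_elements()], extensible via [register_element()]).
#' @param coords Numeric n-by-3 matrix of coordinates in Angstrom.
#' @param box A [gel_box] or `NULL` for non-periodic.
#' @param label Free-text label (e.g. timestep).
#' @return Object of class `gel_frame`.
#' @export
gel_frame <- function(elements, coords, box = NULL, label = "") {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  stopifnot(length(elements) == nrow(coords))
  if (length(elements)) {
    stopifnot(all(is.finite(coords)))
    for (el in unique(elements)) .element(el)   # errors on unknown symbol
  }
  if (!is.null(box)) stopifnot(inherits(box, "gel_box"))
  structure(list(elements = as.character(elements), coords = coords,
                 box = box, label = as.character(label)),
            class = "gel_frame")
}

#' @export
print.gel_frame <- function(x, ...) {
  cat(sprintf("<gel_frame%s> %d atoms", if (nzchar(x$label))
      paste0(" '", x$label, "'") else "", nrow(x$coords)))
  if (!is.null(x$box)) {
    cat(sprintf(", %s box %.2f x %.2f x %.2f A",
                if (x$box$periodic) "periodic" else "open",
                x$box$lengths[1], x$box$lengths[2], x$box$lengths[3]))
  }
  cat("\n")
  invisible(x)
}

n_atoms <- function(frame) nrow(frame$coords)

#' Total mass of a frame in g/mol
#' @param frame A [gel_frame].
#' @return Sum of atomic masses (g/mol).
#' @export
frame_mass <- function(frame) {
  if (!n_atoms(frame)) return(0)
  sum(vapply(frame$elements, function(e) .element(e)$mass, 1.0))
}

.num_field <- function(s, what, lineno) {
  v <- suppressWarnings(as.numeric(s))
  if (any(is.na(v))) {
    stop("unparseable ", what, " field on line ", lineno, ": '",
         trimws(s[is.na(v)][1]), "'", call. = FALSE)
  }
  v
}

#' Read a PDB structure into a frame
#'
#' Parses `ATOM`/`HETATM` records (fixed columns). The element is taken from
#' columns 77-78 when present, otherwise inferred from the first alphabetic
#' character of the atom name. A `CRYST1` record becomes a periodic [gel_box];
#' without one the frame is non-periodic. Atom order is preserved.
#'
#' @param text PDB text (string or vector of lines) or a file path.
#' @return A [gel_frame].
#' @export
read_pdb <- function(text) {
  lines <- .input_lines(text)
  box <- NULL
  cr <- grep("^CRYST1", lines)
  if (length(cr)) {
    l <- lines[cr[1]]
    abc <- .num_field(c(substr(l, 7, 15), substr(l, 16, 24), substr(l, 25, 33)),
                      "CRYST1", cr[1])
    box <- gel_box(abc, periodic = TRUE)
  }
  at <- grep("^(ATOM  |HETATM)", lines)
  if (!length(at)) stop("no ATOM/HETATM records found", call. = FALSE)
  elements <- character(length(at))
  coords <- matrix(0, length(at), 3L)
  for (i in seq_along(at)) {
    l <- lines[at[i]]
    coords[i, ] <- .num_field(c(substr(l, 31, 38), substr(l, 39, 46),
                                substr(l, 47, 54)), "coordinate", at[i])
    el <- trimws(substr(l, 77, 78))
    if (!nzchar(el)) {
      name <- trimws(substr(l, 13, 16))
      el <- regmatches(name, regexpr("[A-Za-z]", name))
    }
    el <- paste0(toupper(substr(el, 1, 1)),
                 tolower(substr(el, 2, nchar(el))))
    elements[i] <- el
  }
  gel_frame(elements, coords, box = box, label = "pdb")
}

#' Write a frame as PDB text
#' @param frame A [gel_frame].
#' @param path Optional output path.
#' @return PDB text (invisibly when `path` given).
#' @export
write_pdb <- function(frame, path = NULL) {
  lines <- character(0)
  if (!is.null(frame$box)) {
    lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     frame$box$lengths[1], frame$box$lengths[2],
                     frame$box$lengths[3], 90, 90, 90)
  }
  for (i in seq_len(n_atoms(frame))) {
    lines <- c(lines, sprintf(
      "ATOM  %5d %-4s UNK A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      i, frame$elements[i], frame$coords[i, 1], frame$coords[i, 2],
      frame$coords[i, 3], frame$elements[i]))
  }
  lines <- c(lines, "END")
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) { cat(text, file = path); return(invisible(text)) }
  text
}

.input_lines <- function(text) {
  stopifnot(is.character(text), length(text) >= 1L)
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    readLines(text)
  } else {
    strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
}

#' Read trajectory frames from XYZ or LAMMPS-dump text
#'
#' XYZ: standard multi-frame `n / comment / element x y z` blocks. An
#' extended-XYZ `Lattice="ax 0 0 0 by 0 0 0 cz"` comment becomes a periodic
#' box. All XYZ frames must contain the same atom count. LAMMPS dump: `ITEM:`
#' blocks; `BOX BOUNDS` lo/hi pairs are converted to edge lengths and the
#' `ATOMS` header row names the columns (needs `element` or `type`, and
#' `x y z`).
#'
#' @param text Input text or file path.
#' @param format `"xyz"` or `"dump"`.
#' @return List of [gel_frame]s, in file order.
#' @export
read_frames <- function(text, format = c("xyz", "dump")) {
  format <- match.arg(format)
  lines <- .input_lines(text)
  if (format == "xyz") .read_xyz(lines) else .read_dump(lines)
}

.read_xyz <- function(lines) {
  frames <- list()
  i <- 1L
  n_ref <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("expected atom count on line ", i, call. = FALSE)
    if (is.null(n_ref)) n_ref <- n
    if (n != n_ref) stop("inconsistent atom count across XYZ frames (", n_ref,
                         " vs ", n, " at line ", i, ")", call. = FALSE)
    comment <- lines[i + 1L]
    box <- NULL
    m <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
    if (length(m)) {
      v <- .num_field(strsplit(trimws(gsub('Lattice="|"', "", m)),
                               "[[:space:]]+")[[1]], "Lattice", i + 1L)
      box <- gel_box(c(v[1], v[5], v[9]), periodic = TRUE)
    }
    block <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(block), "[[:space:]]+")
    elements <- vapply(toks, `[`, "", 1L)
    coords <- t(vapply(seq_along(toks), function(k)
      .num_field(toks[[k]][2:4], "coordinate", i + 1L + k), numeric(3)))
    frames[[length(frames) + 1L]] <-
      gel_frame(elements, coords, box = box, label = trimws(comment))
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no XYZ frames found", call. = FALSE)
  frames
}

.read_dump <- function(lines) {
  starts <- grep("^ITEM: TIMESTEP", lines)
  if (!length(starts)) stop("no 'ITEM: TIMESTEP' blocks found", call. = FALSE)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(b) {
    blk <- lines[starts[b]:ends[b]]
    ts <- trimws(blk[2])
    nat <- as.integer(trimws(blk[grep("^ITEM: NUMBER OF ATOMS", blk) + 1L]))
    bb <- grep("^ITEM: BOX BOUNDS", blk)
    bounds <- t(vapply(1:3, function(k)
      .num_field(strsplit(trimws(blk[bb + k]), "[[:space:]]+")[[1]][1:2],
                 "box bound", starts[b] + bb + k - 1L), numeric(2)))
    box <- gel_box(bounds[, 2] - bounds[, 1], periodic = TRUE)
    ai <- grep("^ITEM: ATOMS", blk)
    cols <- strsplit(trimws(sub("^ITEM: ATOMS", "", blk[ai])),
                     "[[:space:]]+")[[1]]
    ecol <- match("element", cols)
    if (is.na(ecol)) ecol <- match("type", cols)
    xc <- match(c("x", "y", "z"), cols)
    if (is.na(ecol) || any(is.na(xc))) {
      stop("dump ATOMS header must name element/type and x y z", call. = FALSE)
    }
    rows <- strsplit(trimws(blk[(ai + 1L):(ai + nat)]), "[[:space:]]+")
    elements <- vapply(rows, `[`, "", ecol)
    coords <- t(vapply(seq_along(rows), function(k)
      .num_field(rows[[k]][xc], "coordinate", starts[b] + ai + k - 1L),
      numeric(3)))
    gel_frame(elements, coords, box = box, label = paste0("timestep ", ts))
  })
}

#' Write frames as (extended) XYZ text
#' @param frames A [gel_frame] or list of frames.
#' @param path Optional output path.
#' @return XYZ text (invisibly when `path` given).
#' @export
write_frames <- function(frames, path = NULL) {
  if (inherits(frames, "gel_frame")) frames <- list(frames)
  out <- character(0)
  for (f in frames) {
    comment <- if (!is.null(f$box) && f$box$periodic) {
      L <- f$box$lengths
      sprintf('Lattice="%g 0 0 0 %g 0 0 0 %g"', L[1], L[2], L[3])
    } else f$label
    out <- c(out, as.character(n_atoms(f)), comment,
             sprintf("%s %.8f %.8f %.8f", f$elements,
                     f$coords[, 1], f$coords[, 2], f$coords[, 3]))
  }
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) { cat(text, file = path); return(invisible(text)) }
  text
}

#' Thermodynamic per-frame series
#'
#' Ordered records of per-frame/per-run state: temperature (K) and any of
#' volume (Angstrom^3), density (g/cm^3) and nonbonded energy (declared unit).
#' When density is absent but a total mass (g/mol) and volume are declared it
#' is derived as rho = M/V.
#'
#' @param temperature Temperatures in K (> 0).
#' @param volume,density,energy Optional per-record columns.
#' @param energy_unit Declared energy unit: `"kcal/mol"`, `"kJ/mol"` or
#'   `"J/mol"`.
#' @param mass Optional total mass in g/mol (enables rho = M/V).
#' @param label Optional per-record labels.
#' @return A data frame of class `thermo_series` with a `units` attribute.
#' @export
thermo_series <- function(temperature, volume = NULL, density = NULL,
                          energy = NULL, energy_unit = "kcal/mol",
                          mass = NULL, label = NULL) {
  stopifnot(all(temperature > 0))
  n <- length(temperature)
  if (is.null(density) && !is.null(mass) && !is.null(volume)) {
    # rho [g/cm^3] = (M/N_A) [g] / (V * 1e-24 [cm^3])
    density <- (mass / .AVOGADRO) / (volume * 1e-24)
  }
  if (!is.null(density)) stopifnot(all(density > 0))
  df <- data.frame(temperature = as.numeric(temperature))
  if (!is.null(volume)) df$volume <- as.numeric(volume)
  if (!is.null(density)) df$density <- as.numeric(density)
  if (!is.null(energy)) df$energy <- as.numeric(energy)
  df$label <- if (is.null(label)) as.character(seq_len(n)) else
    as.character(label)
  structure(df, class = c("thermo_series", "data.frame"),
            units = list(temperature = "K", volume = "A3", density = "g/cm3",
                         energy = energy_unit),
            mass = mass)
}

#' Read a delimited thermodynamic table
#'
#' @param text CSV/TSV text or file path (header row required).
#' @param column_map Named list mapping any of `temperature`, `volume`,
#'   `density`, `energy` to column names in the table.
#' @param sep Field separator (default auto: comma, falling back to tab).
#' @param energy_unit Declared unit of the energy column.
#' @param mass Optional total mass in g/mol.
#' @return A [thermo_series].
#' @export
read_thermo <- function(text, column_map = list(temperature = "temperature",
                                                density = "density"),
                        sep = NULL, energy_unit = "kcal/mol", mass = NULL) {
  lines <- .input_lines(text)
  if (is.null(sep)) sep <- if (grepl(",", lines[1])) "," else "\t"
  df <- utils::read.table(text = paste(lines, collapse = "\n"), sep = sep,
                          header = TRUE, colClasses = "character",
                          check.names = FALSE, strip.white = TRUE)
  get_col <- function(role) {
    nm <- column_map[[role]]
    if (is.null(nm)) return(NULL)
    if (!nm %in% names(df)) {
      stop("mapped column '", nm, "' (", role, ") not found in table",
           call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(df[[nm]]))
    if (any(is.na(v))) {
      stop("malformed numeric cell in column '", nm, "', row ",
           which(is.na(v))[1], call. = FALSE)
    }
    v
  }
  thermo_series(temperature = get_col("temperature"),
                volume = get_col("volume"), density = get_col("density"),
                energy = get_col("energy"), energy_unit = energy_unit,
                mass = mass)
}

#' Write a thermo series as CSV
#' @param series A [thermo_series].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_thermo <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
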