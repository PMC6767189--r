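# Gelatin sequence construction: FASTA import, hydroxyproline substitution,
# simulated trypsin digestion and chain assembly.

.AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Amino-acid sequence with hydroxyproline
#'
#' A one-letter amino-acid sequence over the 20 standard residues plus `X`,
#' the code used here for hydroxyproline (collagen/gelatin's characteristic
#' post-translationally modified proline, absent from plain FASTA alphabets).
#'
#' @param residues Single string (or character vector of single letters) of
#'   one-letter residue codes; lowercase accepted and uppercased.
#' @param id Free-text sequence label.
#' @return An object of class `aa_seq`.
#' @examples
#' aa_seq("GPXGAK", id = "toy")
#' @export
aa_seq <- function(residues, id = "seq") {
  if (length(residues) > 1L) residues <- paste(residues, collapse = "")
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(gsub("[[:space:]]", "", residues))
  bad <- which(!strsplit(residues, "")[[1]] %in% .AA_ALPHABET)
  if (length(bad)) {
    stop("illegal residue symbol '",
         substr(residues, bad[1], bad[1]), "' at position ", bad[1],
         " of sequence '", id, "'", call. = FALSE)
  }
  structure(list(id = as.character(id), residues = residues),
            class = "aa_seq")
}

#' @export
as.character.aa_seq <- function(x, ...) x$residues

#' @export
length.aa_seq <- function(x) nchar(x$residues)

#' @export
print.aa_seq <- function(x, ...) {
  cat(sprintf("<aa_seq '%s'> %d residues\n", x$id, length(x)))
  res <- x$residues
  if (nchar(res) > 60) res <- paste0(substr(res, 1, 57), "...")
  cat(" ", res, "\n")
  invisible(x)
}

.as_aa_seq <- function(x, id = "seq") {
  if (inherits(x, "aa_seq")) x else aa_seq(x, id = id)
}

.residue_vector <- function(seq) strsplit(.as_aa_seq(seq)$residues, "")[[1]]

#' Parse FASTA text into amino-acid sequences
#'
#' Accepts multi-record FASTA text (wrapped or unwrapped, any case). Record
#' order is preserved, sequences are uppercased and whitespace-stripped, and
#' every residue must belong to the 21-letter alphabet (20 standard amino
#' acids plus `X` for hydroxyproline); an offending symbol raises an error
#' naming its position.
#'
#' @param text FASTA text (single string or character vector of lines), or the
#'   path of an existing FASTA file.
#' @return List of [aa_seq] objects.
#' @seealso [write_fasta()] for the inverse.
#' @export
parse_fasta <- function(text) {
  stopifnot(is.character(text), length(text) >= 1L)
  path <- NULL
  if (length(text) == 1L && !grepl("[\n>]", text) && file.exists(text)) {
    path <- text
  } else {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path), add = TRUE)
    writeLines(paste(text, collapse = "\n"), path)
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA input: ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA input: no records found",
                              call. = FALSE)
  ids <- names(set)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- aa_seq(as.character(set[[i]]), id = ids[i] %||% paste0("seq", i))
  }
  out
}

#' Write amino-acid sequences as FASTA text
#'
#' Round-trip guarantee: `parse_fasta(write_fasta(s))` reproduces `s`.
#'
#' @param seqs An [aa_seq] or list of them (plain strings accepted).
#' @param path Optional file path; when given, text is also written there.
#' @param width Line-wrap width in residues.
#' @return FASTA text as a single string (invisibly when `path` is given).
#' @export
write_fasta <- function(seqs, path = NULL, width = 60L) {
  if (inherits(seqs, "aa_seq") || is.character(seqs)) seqs <- list(seqs)
  lines <- character(0)
  for (s in seqs) {
    s <- .as_aa_seq(s)
    body <- if (length(s) == 0L) character(0) else {
      starts <- seq(1L, nchar(s$residues), by = width)
      substring(s$residues, starts, pmin(starts + width - 1L, nchar(s$residues)))
    }
    lines <- c(lines, paste0(">", s$id), body)
  }
  text <- if (length(lines)) paste0(paste(lines, collapse = "\n"), "\n") else ""
  if (!is.null(path)) {
    cat(text, file = path)
    return(invisible(text))
  }
  text
}

#' Substitute hydroxyproline into a collagen-like sequence
#'
#' Collagen's repeating unit is the G-X-Y triplet in which the Y-position
#' proline is typically hydroxylated. The default rule scans the sequence
#' greedily: at each glycine a triplet is consumed, and a proline in its third
#' (Y) position becomes `X`. The scan anchors only on G, so sequences without
#' the collagen repeat are left mostly untouched. Alternatives: `"all"`
#' replaces every proline, `"none"` returns the input unchanged.
#'
#' The operation preserves length and is idempotent (X is never re-substituted
#' and glycine anchors are untouched).
#'
#' @param seq An [aa_seq] (or string).
#' @param rule One of `"gxy"` (default), `"all"`, `"none"`.
#' @return An [aa_seq] of identical length.
#' @examples
#' as.character(hydroxylate_prolines("GAPGPA"))  # "GAXGPA"
#' @export
hydroxylate_prolines <- function(seq, rule = c("gxy", "all", "none")) {
  seq <- .as_aa_seq(seq)
  rule <- match.arg(rule)
  if (length(seq) == 0L) stop("sequence is empty", call. = FALSE)
  if (rule == "none") return(seq)
  res <- .residue_vector(seq)
  if (rule == "all") {
    res[res == "P"] <- "X"
  } else {
    n <- length(res)
    i <- 1L
    while (i <= n - 2L) {
      if (res[i] == "G") {
        if (res[i + 2L] == "P") res[i + 2L] <- "X"
        i <- i + 3L
      } else {
        i <- i + 1L
      }
    }
  }
  aa_seq(paste(res, collapse = ""), id = seq$id)
}

#' @rdname trypsin_digest
#' @param residues,start,end Fragment slice and its 0-based, end-exclusive
#'   coordinates in the parent sequence.
#' @export
peptide_fragment <- function(residues, start, end) {
  stopifnot(end > start, start >= 0)
  structure(list(residues = .as_aa_seq(residues,
                                       id = sprintf("frag_%d_%d", start, end)),
                 start = as.integer(start), end = as.integer(end)),
            class = "peptide_fragment")
}

#' Simulated trypsin digestion
#'
#' Trypsin cleaves on the C-terminal side of lysine (K) and arginine (R),
#' except when the following residue is proline (P), which blocks cleavage.
#' Hydroxyproline (`X`) does not block. A terminal K/R produces no cut
#' (nothing on its carboxyl side). Fragments partition the parent: their
#' concatenation in order reproduces it exactly.
#'
#' @param seq An [aa_seq] (or string).
#' @return A `digest_result`: list with `parent`, ordered `fragments`
#'   (each a `peptide_fragment` with 0-based `start`/`end`), and
#'   `cleavage_sites` (0-based positions; the cut falls after that index).
#' @examples
#' d <- trypsin_digest("GAKGPR")
#' vapply(d$fragments, function(f) as.character(f$residues), "")
#' @export
trypsin_digest <- function(seq) {
  seq <- .as_aa_seq(seq)
  if (length(seq) == 0L) stop("sequence is empty", call. = FALSE)
  res <- .residue_vector(seq)
  n <- length(res)
  is_site <- res %in% c("K", "R") &
    seq_len(n) < n &
    c(res[-1], "") != "P"
  sites0 <- which(is_site) - 1L              # 0-based, cut after this index
  bounds <- c(0L, sites0 + 1L, n)            # fragment boundaries, 0-based
  frags <- lapply(seq_len(length(bounds) - 1L), function(i) {
    s <- bounds[i]; e <- bounds[i + 1L]
    peptide_fragment(substr(seq$residues, s + 1L, e), s, e)
  })
  structure(list(parent = seq, fragments = frags, cleavage_sites = sites0),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("<digest_result> parent '%s' (%d aa), %d fragments, %d cuts\n",
              x$parent$id, length(x$parent), length(x$fragments),
              length(x$cleavage_sites)))
  invisible(x)
}

#' Assemble a gelatin chain of a target length from digest fragments
#'
#' The default `"ordered"` policy concatenates fragments in parent order until
#' the cumulative length first reaches or exceeds `target_length`; if the
#' target cannot be hit exactly it truncates at the last whole-fragment
#' boundary not exceeding the target and reports the achieved length (attribute
#' `achieved_length`, with a warning when it differs from the target). Every
#' residue of the output occurs in the digest fragments, in order. A custom
#' policy may be supplied as a function `(digest, target_length) ->` list of
#' fragment indices.
#'
#' @param digest A `digest_result` from [trypsin_digest()].
#' @param target_length Desired chain length in residues (> 0, at most the
#'   parent length).
#' @param policy `"ordered"` or a function as described.
#' @return An [aa_seq] with attribute `achieved_length`.
#' @export
assemble_chain <- function(digest, target_length, policy = "ordered") {
  stopifnot(inherits(digest, "digest_result"))
  if (!is.numeric(target_length) || target_length <= 0) {
    stop("target_length must be a positive residue count", call. = FALSE)
  }
  target_length <- as.integer(target_length)
  if (target_length > length(digest$parent)) {
    stop("target_length (", target_length, ") exceeds parent length (",
         length(digest$parent), ")", call. = FALSE)
  }
  if (is.function(policy)) {
    idx <- policy(digest, target_length)
  } else if (identical(policy, "ordered")) {
    lens <- vapply(digest$fragments, function(f) f$end - f$start, 1L)
    cum <- cumsum(lens)
    k <- which(cum >= target_length)[1]
    if (!is.na(k) && cum[k] > target_length) k <- k - 1L  # last boundary <= target
    idx <- seq_len(max(k, 0L))
  } else {
    stop("unknown assembly policy '", policy, "'", call. = FALSE)
  }
  chain <- paste(vapply(digest$fragments[idx],
                        function(f) as.character(f$residues), ""),
                 collapse = "")
  achieved <- nchar(chain)
  if (achieved != target_length) {
    warning("no fragment combination reaches target length ", target_length,
            " under this policy; achieved ", achieved, call. = FALSE)
  }
  out <- aa_seq(chain, id = sprintf("%s_chain%d", digest$parent$id, achieved))
  attr(out, "achieved_length") <- achieved
  out
}
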