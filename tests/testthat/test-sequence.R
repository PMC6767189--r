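test_that("parse_fasta handles records, normalization and bad input", {
  seqs <- parse_fasta(">a\nGPX\n")
  expect_length(seqs, 1L)
  expect_equal(as.character(seqs[[1]]), "GPX")
  expect_equal(length(seqs[[1]]), 3L)

  # lowercase + line wraps normalize to the unwrapped uppercase sequence
  wrapped <- ">s1\ngak\ngpr\naa\n>s2\nGPX\n"
  seqs <- parse_fasta(wrapped)
  expect_equal(vapply(seqs, as.character, ""), c("GAKGPRAA", "GPX"))
  expect_equal(vapply(seqs, function(s) s$id, ""), c("s1", "s2"))

  expect_error(parse_fasta(""), "empty|parse")
  expect_error(parse_fasta(">a\nGP1X\n"), "position 3")
  expect_error(parse_fasta(">a\nGAB\n"), "illegal residue")
})

test_that("packaged synthetic collagen record has the collagen length", {
  path <- system.file("extdata", "collagen_alpha1_synthetic.fasta",
                      package = "gelsim")
  col <- parse_fasta(path)[[1]]
  expect_equal(length(col), 1464L)
  # deterministic generator reproduces the packaged file
  expect_equal(as.character(make_synthetic_collagen()), as.character(col))
  # round-trip identity on the full-length record
  rt <- parse_fasta(write_fasta(col))[[1]]
  expect_equal(as.character(rt), as.character(col))
  expect_equal(rt$id, col$id)
})

test_that("write_fasta round-trips and handles the empty list", {
  expect_equal(write_fasta(list()), "")
  s <- aa_seq("GPX", id = "x")
  expect_match(write_fasta(s), ">x\nGPX\n", fixed = TRUE)
  for (seed in 1:5) {
    str <- random_aa_string(137, seed)
    rt <- parse_fasta(write_fasta(aa_seq(str, id = "r")))[[1]]
    expect_equal(as.character(rt), str)
  }
})

test_that("hydroxylation follows the G-X-Y rule and is idempotent", {
  expect_equal(as.character(hydroxylate_prolines("GAPGPA")), "GAXGPA")
  expect_equal(as.character(hydroxylate_prolines("AAAAAA")), "AAAAAA")
  expect_equal(as.character(hydroxylate_prolines("GGPP")), "GGXP")
  expect_equal(as.character(hydroxylate_prolines("GAPGAP", rule = "all")),
               "GAXGAX")
  expect_equal(as.character(hydroxylate_prolines("GAPGAP", rule = "none")),
               "GAPGAP")
  for (seed in 1:20) {
    s <- random_aa_string(60, seed)
    h <- hydroxylate_prolines(s)
    expect_equal(length(h), nchar(s))                       # length preserved
    hh <- hydroxylate_prolines(h)
    expect_equal(as.character(hh), as.character(h))         # idempotent
    # only P -> X substitutions
    a <- strsplit(s, "")[[1]]; b <- strsplit(as.character(h), "")[[1]]
    changed <- which(a != b)
    expect_true(all(a[changed] == "P" & b[changed] == "X"))
  }
})

test_that("trypsin digestion applies the K/R rule with proline blocking", {
  expect_equal(frag_strings(trypsin_digest("GAKGPR")), c("GAK", "GPR"))
  expect_equal(frag_strings(trypsin_digest("GAKPGR")), "GAKPGR")
  expect_equal(frag_strings(trypsin_digest("AAAA")), "AAAA")
  # hydroxyproline does not block cleavage; consecutive K/R cut independently
  expect_equal(frag_strings(trypsin_digest("AKXA")), c("AK", "XA"))
  expect_equal(frag_strings(trypsin_digest("AKRA")), c("AK", "R", "A"))
  # terminal K produces no cut
  expect_equal(frag_strings(trypsin_digest("AAK")), "AAK")
})

test_that("digest fragments partition the parent and match the scan oracle", {
  for (seed in 1:50) {
    s <- random_aa_string(50, seed)
    d <- trypsin_digest(s)
    expect_equal(paste(frag_strings(d), collapse = ""), s)
    expect_equal(d$cleavage_sites, oracle_cut_sites(s))
    expect_equal(length(d$fragments), length(d$cleavage_sites) + 1L)
    expect_true(all(diff(d$cleavage_sites) > 0) ||
                  length(d$cleavage_sites) < 2L)
    # fragment coordinates tile [0, n)
    starts <- vapply(d$fragments, `[[`, 1L, "start")
    ends <- vapply(d$fragments, `[[`, 1L, "end")
    expect_equal(starts, c(0L, ends[-length(ends)]))
    expect_equal(ends[length(ends)], nchar(s))
  }
})

test_that("assemble_chain follows the ordered policy and reports length", {
  d <- trypsin_digest("GAKGPRAA")
  expect_equal(as.character(assemble_chain(d, 6)), "GAKGPR")
  expect_equal(as.character(assemble_chain(d, 8)), "GAKGPRAA")  # identity
  expect_equal(as.character(assemble_chain(d, 3)), "GAK")
  # exact target unreachable: truncate at last whole fragment, warn, report
  expect_warning(ch <- assemble_chain(d, 5), "achieved 3")
  expect_equal(attr(ch, "achieved_length"), 3L)
  expect_error(assemble_chain(d, 0), "positive")
  expect_error(assemble_chain(d, 9), "exceeds parent")
  # custom policy function
  pick_last <- function(digest, target) length(digest$fragments)
  expect_equal(as.character(assemble_chain(d, 2, policy = pick_last)), "AA")
})
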