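test_that("default library has 16 templates of one length, 14 motif-bearing", {
  lib <- default_library()
  expect_s3_class(lib, "nuc_library")
  expect_equal(nrow(lib), 16L)
  expect_equal(sum(lib$motif_kind != "none"), 14L)
  expect_setequal(lib$id[lib$motif_kind == "none"], c("601", "601M"))
  expect_equal(unique(nchar(lib$sequence)), 217L)
  expect_false(anyDuplicated(lib$id) > 0)
  # (kind, offset) design grid is the full cross of kinds and offsets
  motif <- lib[lib$motif_kind != "none", ]
  expect_setequal(
    paste(motif$motif_kind, motif$dyad_offset),
    paste(rep(c("high", "intermediate"), each = 7),
          c(0, 5, 41, 46, 66, 71, 81)))
  # deterministic: rebuilding is bit-identical
  expect_identical(lib, build_library())
})

test_that("motif placement is centered at dyad + offset and length-preserving", {
  bb <- default_backbone()
  motif <- "GGGCATGTCCGGGCATGTCC"
  t0 <- build_template(bb, motif, 0, "high")
  # motif center coincides with the dyad (0-based index 108): 0-based
  # window [98, 118) is 1-based substring 99..118
  expect_equal(substr(t0$sequence, 99, 118), motif)
  expect_equal(nchar(t0$sequence), nchar(bb))
  # mismatches confined to the placement window, Hamming distance <= 20
  for (off in c(0L, 41L, 81L)) {
    tp <- build_template(bb, motif, off, "high")
    a <- strsplit(tp$sequence, "")[[1]]
    b <- strsplit(bb, "")[[1]]
    mism <- which(a != b)
    expect_lte(length(mism), 20L)
    w0 <- 108L + off - 10L  # 0-based window start
    expect_true(all(mism >= w0 + 1L & mism <= w0 + 20L))
    # motif occurs verbatim at the designed coordinates
    expect_equal(substr(tp$sequence, w0 + 1L, w0 + 20L), motif)
  }
  expect_error(build_template(bb, motif, 200, "high"), "bounds")
  expect_error(build_template("ACGTN", motif, 0, "high"), "non-ACGT")
})

test_that("SHL labels follow half-turn rounding with a linker flag", {
  expect_equal(assign_shl(66, 10.2, 73)$shl, 6.5)
  expect_equal(assign_shl(71, 10.2, 73)$shl, 7)
  s81 <- assign_shl(81, 10.2, 73)
  expect_equal(s81$shl, 8)
  expect_true(s81$linker)
  expect_match(s81$label, "linker")
  expect_equal(assign_shl(0, 10.2, 73)$shl, 0)
  expect_false(assign_shl(0, 10.2, 73)$linker)
  expect_equal(assign_shl(41, 10.2, 73)$shl, 4)  # 41/10.2 = 4.02
  expect_error(assign_shl(66, -1), "positive")
  # non-decreasing in offset for fixed period
  offs <- 0:90
  shls <- assign_shl(offs, 10.2, 73)$shl
  expect_true(all(diff(shls) >= 0))
  # paired offsets 5 bp apart sit about half a helical turn apart
  for (pair in list(c(0, 5), c(41, 46), c(66, 71)))
    expect_lt(abs(diff(pair) / 10.2 - 0.5), 0.1)
})

test_that("modified control strips CATG only outside the positioning core", {
  bb <- default_backbone()
  mod <- make_modified_control(bb)
  expect_equal(nchar(mod), nchar(bb))
  # the designed flank CATG (0-based 189) is replaced by AGGT
  expect_equal(substr(bb, 190, 193), "CATG")
  expect_equal(substr(mod, 190, 193), "AGGT")
  # no CATG remains outside the core span [35, 182)
  hits <- gregexpr("CATG", mod, fixed = TRUE)[[1]]
  if (hits[1] != -1)
    expect_true(all(hits - 1 + 4 > 35 & hits - 1 < 182))
  # identity on sequences without CATG outside the core
  expect_equal(make_modified_control("ACGTACGT", c(0, 8)), "ACGTACGT")
  expect_equal(make_modified_control("AAACATGAAA", c(0, 10)), "AAACATGAAA")
  # CATG straddling the core boundary is untouched
  straddle <- paste0(strrep("A", 10), "CATG", strrep("A", 10))
  expect_equal(make_modified_control(straddle, c(12, 24)), straddle)
})

test_that("controls contain neither motif and offsets=[] yields controls only", {
  lib <- default_library()
  ctl <- lib$sequence[lib$motif_kind == "none"]
  for (m in c("GGGCATGTCCGGGCATGTCC", "AGACTGGGCATGTCTGGGCA")) {
    expect_false(any(grepl(m, ctl, fixed = TRUE)))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))
    expect_false(any(grepl(rc, ctl, fixed = TRUE)))
  }
  lib0 <- build_library(library_config(offsets = integer()))
  expect_equal(nrow(lib0), 2L)
  expect_setequal(lib0$id, c("601", "601M"))
  expect_error(library_config(offsets = c(5, 5)), "duplicate")
})

test_that("library FASTA round trip preserves all design metadata", {
  lib <- default_library()
  f <- withr::local_tempfile(fileext = ".fa")
  write_library_fasta(lib, f)
  expect_equal(as.data.frame(read_library_fasta(f)), as.data.frame(lib))
  # empty library -> empty file -> empty library
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_library_fasta(lib[0, ], f2)
  expect_equal(nrow(read_library_fasta(f2)), 0L)
  # header without metadata parses leniently with a warning
  f3 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">plain", "ACGTACGT"), f3)
  expect_warning(lib3 <- read_library_fasta(f3), "metadata")
  expect_equal(lib3$motif_kind, "none")
})
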