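# Nucleosome template library design ------------------------------------
#
# Templates are built on a Widom 601 positioning backbone: a 147-bp core
# flanked symmetrically so that the dyad (SHL 0) sits at the template
# center. A 20-bp binding motif is substituted into the backbone with its
# center a chosen number of base pairs 3' of the dyad; the superhelix
# location (SHL) of each placement is the dyad offset in helical turns.

# Canonical 147-bp Widom 601 nucleosome positioning core.
WIDOM601_CORE <- paste0(
  "CTGGAGAATCCCGGTGCCGAGGCCGCTCAATTGGTCGTAGACAGCTCTAGCACCGCTTAAACGCACG",
  "TACGCGCTGTCCCCCGCGTTTTAACCGCCAAGGGGATTACTCCCTAGTCTCCAGGCACGTGTCAGAT",
  "ATATACATCCTGT")

# Synthetic 35-bp flanks for the default 217-bp construct. The 3' flank
# carries one CATG half-site core just outside the positioning core,
# reproducing the feature of the original construct that motivates the
# modified ("601M") control. Neither flank matches either default motif.
FLANK5_DEFAULT <- "ACCTAGTTCGATCTGAACGTGTCCTAGATCCGGTA"
FLANK3_DEFAULT <- "TCGGATCCATGATCAAGCTTGACCTGGAGTCCTAA"

MOTIF_HIGH <- "GGGCATGTCCGGGCATGTCC"          # adapted high-affinity ideal site
MOTIF_INTERMEDIATE <- "AGACTGGGCATGTCTGGGCA" # natural CDKN1A promoter site

#' Widom 601 positioning core sequence
#'
#' @return The canonical 147-bp Widom 601 core as a character string.
#' @export
widom601_core <- function() WIDOM601_CORE

#' Default 217-bp assay backbone
#'
#' The 147-bp Widom 601 core with synthetic 35-bp flanks on each side, so
#' the dyad sits at 0-based index 108. The 3' flank contains a single CATG
#' half-site core outside the positioning core (the sequence feature the
#' modified control removes).
#'
#' @param flank5,flank3 Flank sequences; defaults are the shipped synthetic
#'   35-bp flanks.
#' @return Backbone DNA string.
#' @export
default_backbone <- function(flank5 = FLANK5_DEFAULT, flank3 = FLANK3_DEFAULT) {
  check_dna(flank5, "flank5"); check_dna(flank3, "flank3")
  if (nchar(flank5) != nchar(flank3))
    stop("flanks must have equal length so the core stays centered",
         call. = FALSE)
  paste0(flank5, WIDOM601_CORE, flank3)
}

#' Library design configuration
#'
#' @param backbone Backbone DNA string with the 147-bp positioning core
#'   centered; default [default_backbone()].
#' @param motif_high,motif_intermediate 20-bp binding-site sequences.
#' @param offsets Integer dyad offsets (bp from dyad to motif center).
#' @param helical_period DNA helical periodicity in bp/turn used for SHL
#'   labels (default 10.2).
#' @param core_half_width Half-width of the positioning core in bp
#'   (default 73; offsets beyond it lie in the linker).
#' @return A `library_config` list.
#' @export
library_config <- function(backbone = default_backbone(),
                           motif_high = MOTIF_HIGH,
                           motif_intermediate = MOTIF_INTERMEDIATE,
                           offsets = c(0L, 5L, 41L, 46L, 66L, 71L, 81L),
                           helical_period = 10.2,
                           core_half_width = 73L) {
  check_dna(backbone, "backbone")
  check_dna(motif_high, "motif_high")
  check_dna(motif_intermediate, "motif_intermediate")
  if (nchar(motif_high) != nchar(motif_intermediate))
    stop("motifs must have equal length", call. = FALSE)
  offsets <- as.integer(offsets)
  if (anyDuplicated(offsets)) stop("duplicate offsets", call. = FALSE)
  if (any(offsets < 0)) stop("offsets must be non-negative", call. = FALSE)
  max_off <- (nchar(backbone) - nchar(motif_high)) / 2
  if (any(offsets > max_off))
    stop("offset places motif outside the backbone", call. = FALSE)
  structure(list(backbone = backbone, motif_high = motif_high,
                 motif_intermediate = motif_intermediate, offsets = offsets,
                 helical_period = helical_period,
                 core_half_width = as.integer(core_half_width)),
            class = "library_config")
}

# 0-based core span [start, end) for a backbone with the 147-bp core
# centered; dyad is the central core position.
core_span <- function(backbone_len) {
  start <- (backbone_len - 147L) %/% 2L
  c(start = start, end = start + 147L)
}

dyad_index <- function(backbone_len) {
  unname(core_span(backbone_len)["start"]) + 73L  # 0-based
}

#' Place a motif at a dyad offset on a nucleosome backbone
#'
#' Substitutes `motif` into `backbone` so that the motif center lies
#' `dyad_offset` bp 3' of the nucleosome dyad (the central position of the
#' 147-bp positioning core). Length is preserved. For the default 217-bp
#' backbone the dyad is 0-based index 108.
#'
#' @param backbone Backbone DNA string (positioning core centered).
#' @param motif Motif DNA string.
#' @param dyad_offset Non-negative integer bp from dyad to motif center.
#' @param motif_kind Label, `"high"` or `"intermediate"`.
#' @param helical_period,core_half_width Passed to [assign_shl()].
#' @return A one-row `nuc_library` data frame (see [build_library()]).
#' @export
build_template <- function(backbone, motif, dyad_offset,
                           motif_kind = c("high", "intermediate"),
                           helical_period = 10.2, core_half_width = 73L) {
  check_dna(backbone, "backbone"); check_dna(motif, "motif")
  motif_kind <- match.arg(motif_kind)
  dyad_offset <- as.integer(dyad_offset)
  if (is.na(dyad_offset) || dyad_offset < 0)
    stop("dyad_offset must be a non-negative integer", call. = FALSE)
  L <- nchar(backbone); m <- nchar(motif)
  dyad <- dyad_index(L)
  # 0-based half-open placement window centered at dyad + offset
  w0 <- dyad + dyad_offset - m %/% 2L
  w1 <- w0 + m
  if (w0 < 0L || w1 > L)
    stop("motif placement window [", w0, ",", w1, ") exceeds template bounds",
         call. = FALSE)
  seq <- paste0(substr(backbone, 1L, w0), motif,
                substr(backbone, w1 + 1L, L))
  stopifnot(nchar(seq) == L)
  shl <- assign_shl(dyad_offset, helical_period, core_half_width)
  cs <- core_span(L)
  kind_tag <- if (motif_kind == "high") "H" else "I"
  new_nuc_library(data.frame(
    id = sprintf("%s%02d", kind_tag, dyad_offset),
    sequence = seq, motif_kind = motif_kind, dyad_offset = dyad_offset,
    shl = shl$shl, shl_label = shl$label, linker = shl$linker,
    core_start = unname(cs["start"]), core_end = unname(cs["end"]),
    stringsAsFactors = FALSE))
}

#' Superhelix location (SHL) label for a dyad offset
#'
#' SHL is the dyad offset expressed in helical turns, rounded to the
#' nearest half turn (ties away from zero). Offsets beyond the core
#' half-width lie in the linker DNA and carry a linker flag, so that with
#' the default 10.2 bp/turn period, offsets 66, 71 and 81 bp map to SHL
#' 6.5, 7 and 8-in-the-linker.
#'
#' @param dyad_offset Non-negative distance from the dyad in bp.
#' @param helical_period Helical periodicity in bp/turn (> 0).
#' @param core_half_width Core half-width in bp (positions beyond it are
#'   linker).
#' @return List with `shl` (numeric half-integer), `linker` (logical) and
#'   `label` (e.g. `"6.5"`, `"8 (linker)"`).
#' @examples
#' assign_shl(66)  # SHL 6.5
#' assign_shl(81)  # SHL 8, linker
#' @export
assign_shl <- function(dyad_offset, helical_period = 10.2,
                       core_half_width = 73L) {
  if (!is.numeric(helical_period) || helical_period <= 0)
    stop("helical_period must be positive", call. = FALSE)
  if (any(dyad_offset < 0)) stop("dyad_offset must be >= 0", call. = FALSE)
  shl <- round_half(dyad_offset / helical_period)
  linker <- dyad_offset > core_half_width
  label <- ifelse(linker, paste0(as.character(shl), " (linker)"),
                  as.character(shl))
  list(shl = shl, linker = linker, label = label)
}

#' Strip CATG half-site cores from outside the positioning core
#'
#' Builds the modified-control backbone: every CATG occurrence lying
#' entirely outside the 147-bp positioning core is replaced by AGGT;
#' occurrences inside (or straddling) the core are untouched. Length is
#' preserved.
#'
#' @param backbone Backbone DNA string.
#' @param core_span Integer vector `c(start, end)`, the 0-based half-open
#'   span of the positioning core; default centered.
#' @return Modified DNA string.
#' @export
make_modified_control <- function(backbone,
                                  core_span = NULL) {
  check_dna(backbone, "backbone")
  L <- nchar(backbone)
  if (is.null(core_span)) {
    cs <- (L - 147L) %/% 2L
    core_span <- c(cs, cs + 147L)
  }
  hits <- gregexpr("CATG", backbone, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(backbone)
  out <- strsplit(backbone, "", fixed = TRUE)[[1L]]
  for (h in hits) {         # h is 1-based start; 0-based window [h-1, h+3)
    if (h - 1L + 4L <= core_span[1L] || h - 1L >= core_span[2L]) {
      out[h:(h + 3L)] <- c("A", "G", "G", "T")
    }
  }
  paste(out, collapse = "")
}

new_nuc_library <- function(df) {
  class(df) <- c("nuc_library", "data.frame")
  df
}

#' Build the full nucleosome template library
#'
#' One template per (motif kind, dyad offset) pair plus two motif-free
#' controls: the unmodified backbone (`"601"`) and the CATG-stripped
#' modified control (`"601M"`). With the default seven offsets this yields
#' 16 templates, 14 of them motif-bearing.
#'
#' @param config A [library_config()].
#' @return A `nuc_library` data frame with columns `id`, `sequence`,
#'   `motif_kind`, `dyad_offset`, `shl`, `shl_label`, `linker`,
#'   `core_start`, `core_end` (core span 0-based half-open).
#' @examples
#' lib <- build_library(library_config())
#' table(lib$motif_kind)
#' @export
build_library <- function(config = library_config()) {
  stopifnot(inherits(config, "library_config"))
  L <- nchar(config$backbone)
  cs <- core_span(L)
  rows <- list()
  for (kind in c("high", "intermediate")) {
    motif <- if (kind == "high") config$motif_high else config$motif_intermediate
    for (off in config$offsets) {
      rows[[length(rows) + 1L]] <- build_template(
        config$backbone, motif, off, kind,
        config$helical_period, config$core_half_width)
    }
  }
  controls <- data.frame(
    id = c("601", "601M"),
    sequence = c(config$backbone,
                 make_modified_control(config$backbone,
                                       c(cs["start"], cs["end"]))),
    motif_kind = "none", dyad_offset = NA_integer_,
    shl = NA_real_, shl_label = NA_character_, linker = NA,
    core_start = unname(cs["start"]), core_end = unname(cs["end"]),
    stringsAsFactors = FALSE)
  lib <- rbind(do.call(rbind, rows), controls)
  rownames(lib) <- NULL
  if (anyDuplicated(lib$id)) stop("duplicate template ids", call. = FALSE)
  new_nuc_library(lib)
}

#' Write a template library to FASTA
#'
#' Headers encode the design metadata in the dialect
#' `>id kind=<high|intermediate|none> offset=<int> shl=<label>`.
#'
#' @param library A `nuc_library`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_library_fasta <- function(library, path) {
  stopifnot(inherits(library, "nuc_library") || is.data.frame(library))
  seqs <- Biostrings::DNAStringSet(library$sequence)
  if (length(seqs) > 0L) names(seqs) <- with(library, paste0(
    id, " kind=", motif_kind,
    ifelse(is.na(dyad_offset), "", paste0(" offset=", dyad_offset)),
    ifelse(is.na(shl), "",
           paste0(" shl=", shl, ifelse(linker, "L", "")))))
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read a template library from FASTA
#'
#' Inverse of [write_library_fasta()]. Headers without metadata fields are
#' parsed leniently as motif-free templates with a warning.
#'
#' @param path FASTA path.
#' @return A `nuc_library` data frame.
#' @export
read_library_fasta <- function(path) {
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) stop("malformed FASTA: ",
                                            conditionMessage(e), call. = FALSE))
  if (length(seqs) == 0L)
    return(new_nuc_library(data.frame(
      id = character(), sequence = character(), motif_kind = character(),
      dyad_offset = integer(), shl = numeric(), shl_label = character(),
      linker = logical(), core_start = integer(), core_end = integer(),
      stringsAsFactors = FALSE)))
  hdr <- names(seqs)
  id <- sub("\\s.*$", "", hdr)
  grab <- function(field) {
    m <- regmatches(hdr, regexpr(paste0(field, "=\\S+"), hdr))
    out <- rep(NA_character_, length(hdr))
    out[grepl(paste0(field, "="), hdr)] <- sub(paste0(field, "="), "", m)
    out
  }
  kind <- grab("kind")
  if (anyNA(kind)) {
    warning("FASTA headers without kind= metadata; treating as motif-free")
    kind[is.na(kind)] <- "none"
  }
  off <- suppressWarnings(as.integer(grab("offset")))
  shl_raw <- grab("shl")
  linker <- grepl("L$", shl_raw)
  shl <- suppressWarnings(as.numeric(sub("L$", "", shl_raw)))
  L <- unique(nchar(as.character(seqs)))
  if (length(L) != 1L)
    warning("templates have differing lengths")
  cs <- core_span(max(nchar(as.character(seqs))))
  out <- data.frame(
    id = unname(id), sequence = unname(as.character(seqs)),
    motif_kind = unname(kind), dyad_offset = off, shl = shl,
    shl_label = ifelse(is.na(shl), NA_character_,
                       ifelse(linker, paste0(as.character(shl), " (linker)"),
                              as.character(shl))),
    linker = ifelse(is.na(shl), NA, linker),
    core_start = unname(cs["start"]), core_end = unname(cs["end"]),
    stringsAsFactors = FALSE, row.names = NULL)
  new_nuc_library(out)
}
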