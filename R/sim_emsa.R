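# Synthetic EMSA-seq data -----------------------------------------------
#
# Emulates the competitive nucleosome-binding assay: a pool of 16 template
# nucleosomes at configurable input frequencies is titrated with factor at
# the assay's five concentrations (18, 36, 71, 142, 286 nM); per lane,
# each template partitions between the unshifted nucleosome band and the
# supershift band according to its model occupancy, and band sequencing
# counts are drawn multinomially at a configured depth.

#' EMSA simulation configuration
#'
#' @param library A `nuc_library` (default [build_library()]).
#' @param model Ground-truth [binding_model()].
#' @param concentrations Factor concentrations, molar (default the assay's
#'   18, 36, 71, 142, 286 nM).
#' @param input_freqs Named per-template input frequencies (default
#'   uniform).
#' @param reads_per_band Sequencing depth per band (default 1e6).
#' @param read_len Read length in bp (default 150, paired).
#' @param error_rate Per-base substitution error rate (default 0.001).
#' @param seed RNG seed.
#' @return An `emsa_sim_config` list.
#' @export
emsa_sim_config <- function(library = build_library(),
                            model = binding_model(),
                            concentrations = c(18, 36, 71, 142, 286) * 1e-9,
                            input_freqs = NULL,
                            reads_per_band = 1e6,
                            read_len = 150L,
                            error_rate = 0.001,
                            seed = 1L) {
  if (is.null(input_freqs))
    input_freqs <- setNames(rep(1 / nrow(library), nrow(library)),
                            library$id)
  if (!isTRUE(all.equal(sum(input_freqs), 1)))
    stop("input frequencies must sum to 1", call. = FALSE)
  if (!setequal(names(input_freqs), library$id))
    stop("input frequencies must cover the library", call. = FALSE)
  if (reads_per_band <= 0) stop("depth must be positive", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.25)
    stop("error rate must be in [0, 0.25)", call. = FALSE)
  structure(list(library = library, model = model,
                 concentrations = concentrations,
                 input_freqs = input_freqs[library$id],
                 reads_per_band = reads_per_band,
                 read_len = as.integer(read_len),
                 error_rate = error_rate, seed = seed),
            class = "emsa_sim_config")
}

#' Simulate a titration series of band counts
#'
#' For each lane at concentration c, template occupancies come from
#' [expected_occupancy()]; the unshifted nucleosome band draws counts with
#' weights proportional to f_N (1 - theta_N), the supershift band with
#' weights f_N theta_N, and the input lane with weights f_N, each
#' multinomially at `reads_per_band`. Reproducible given the config seed.
#'
#' @param config An [emsa_sim_config()].
#' @return A [band_count_table()] with one protein lane per concentration
#'   (named e.g. `"18nM"`) plus the input lane.
#' @export
simulate_titration <- function(config) {
  stopifnot(inherits(config, "emsa_sim_config"))
  lib <- config$library
  f <- config$input_freqs
  depth <- config$reads_per_band
  draw <- function(w) {
    if (sum(w) == 0) return(setNames(integer(length(w)), names(w)))
    setNames(as.integer(rmultinom(1L, depth, w)), names(w))
  }
  with_seed(config$seed, {
    input <- draw(f)
    lanes <- list()
    for (ci in seq_along(config$concentrations)) {
      cc <- config$concentrations[ci]
      theta <- vapply(seq_len(nrow(lib)), function(i)
        expected_occupancy(config$model, lib$motif_kind[i],
                           lib$dyad_offset[i], cc), numeric(1L))
      lanes[[sprintf("%gnM", cc * 1e9)]] <- list(
        nucleosome = draw(f * (1 - theta)),
        supershift = draw(f * theta))
    }
    band_count_table(input, lanes, config$concentrations)
  })
}

#' Simulate band FASTQ reads from a count table
#'
#' Gel bands contain the intact template constructs, so paired mode (the
#' default, matching 2 x 150 paired-end sequencing of 217-bp fragments)
#' reads both ends of the full-length fragment: mate 1 is the 5' prefix
#' and mate 2 the reverse complement of the 3' suffix, jointly covering
#' every position. Single-end mode samples a uniform fragment start and a
#' random strand. I.i.d. substitution errors are applied at `error_rate`.
#'
#' @param counts A [band_count_table()].
#' @param library The `nuc_library` the counts refer to.
#' @param read_len Read length in bp.
#' @param error_rate Per-base substitution probability.
#' @param seed RNG seed.
#' @param paired Paired-end mode (default `TRUE`).
#' @return Nested list mirroring the count table: `$input` and
#'   `$lanes[[lane]][[band]]`, each a list with character vectors `r1`
#'   (and `r2` when paired) and `template` (truth labels).
#' @export
simulate_reads <- function(counts, library, read_len = 150L,
                           error_rate = 0.001, seed = 1L, paired = TRUE) {
  stopifnot(inherits(counts, "band_count_table"))
  L <- unique(nchar(library$sequence))
  if (length(L) != 1L)
    stop("library templates must share one length", call. = FALSE)
  if (read_len > L)
    stop("read_len exceeds template length", call. = FALSE)
  seqs <- setNames(library$sequence, library$id)
  band_reads <- function(cts) {
    cts <- cts[cts > 0]
    tpl <- rep(names(cts), cts)
    n <- length(tpl)
    if (n == 0L)
      return(list(r1 = character(), r2 = if (paired) character(),
                  template = character()))
    if (paired) {
      r1 <- substr(seqs[tpl], 1L, read_len)
      r2_by_tpl <- setNames(revcomp_many(substr(seqs, L - read_len + 1L, L)),
                            names(seqs))
      r2 <- r2_by_tpl[tpl]
    } else {
      st <- sample.int(L - read_len + 1L, n, replace = TRUE)
      r1 <- substr(seqs[tpl], st, st + read_len - 1L)
      flip <- runif(n) < 0.5
      r1[flip] <- revcomp_many(r1[flip])
      r2 <- NULL
    }
    list(r1 = add_seq_errors(unname(r1), error_rate),
         r2 = if (paired) add_seq_errors(unname(r2), error_rate),
         template = tpl)
  }
  with_seed(seed, {
    out <- list(input = band_reads(counts$input), lanes = list())
    for (ln in names(counts$lanes))
      out$lanes[[ln]] <- lapply(counts$lanes[[ln]], band_reads)
    out
  })
}

# i.i.d. substitution errors on a character vector of reads
add_seq_errors <- function(reads, error_rate) {
  if (error_rate == 0 || length(reads) == 0L) return(reads)
  len <- nchar(reads[1L])
  nerr <- stats::rbinom(length(reads), len, error_rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(nerr > 0L)) {
    pos <- sample.int(len, nerr[i])
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
    for (p in pos) chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Count simulated band reads back through the assigner
#'
#' Runs [assign_reads()] on every band of a [simulate_reads()] result,
#' reconstructing a [band_count_table()].
#'
#' @param reads Result of [simulate_reads()].
#' @param library The `nuc_library`.
#' @param max_mismatch_frac Passed to [assign_reads()].
#' @return A [band_count_table()] (plus `unassigned` attribute per band in
#'   `attr(, "unassigned")`).
#' @export
reads_to_counts <- function(reads, library, max_mismatch_frac = 0.1) {
  una <- list()
  count_band <- function(b, key) {
    a <- assign_reads(b$r1, library, mates = b$r2,
                      max_mismatch_frac = max_mismatch_frac)
    una[[key]] <<- a$unassigned
    a$counts
  }
  input <- count_band(reads$input, "input")
  lanes <- list()
  for (ln in names(reads$lanes))
    lanes[[ln]] <- lapply(setNames(names(reads$lanes[[ln]]),
                                   names(reads$lanes[[ln]])),
                          function(bn) count_band(reads$lanes[[ln]][[bn]],
                                                  paste(ln, bn)))
  out <- band_count_table(input, lanes)
  attr(out, "unassigned") <- una
  out
}

#' Write simulated band reads as FASTQ
#'
#' One file per band (and mate): `<prefix>_<lane>_<band>_R1.fastq` etc.,
#' with constant Phred-40 qualities.
#'
#' @param reads Result of [simulate_reads()].
#' @param dir Output directory.
#' @param prefix File-name prefix (default `"band"`).
#' @return Character vector of written paths, invisibly.
#' @export
write_band_fastq <- function(reads, dir, prefix = "band") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wr <- function(v, path) {
    if (!length(v)) return()
    x <- Biostrings::DNAStringSet(v)
    names(x) <- paste0("read", seq_along(v))
    q <- Biostrings::PhredQuality(
      vapply(nchar(v), function(n) strrep("I", n), character(1L)))
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(q))
    paths <<- c(paths, path)
  }
  emit <- function(b, tag) {
    wr(b$r1, file.path(dir, paste0(prefix, "_", tag, "_R1.fastq")))
    if (!is.null(b$r2))
      wr(b$r2, file.path(dir, paste0(prefix, "_", tag, "_R2.fastq")))
  }
  emit(reads$input, "input")
  for (ln in names(reads$lanes))
    for (bn in names(reads$lanes[[ln]]))
      emit(reads$lanes[[ln]][[bn]], paste0(gsub("[^A-Za-z0-9]", "", ln),
                                           "_", bn))
  invisible(paths)
}
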