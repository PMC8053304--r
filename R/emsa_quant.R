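# EMSA-seq quantification -----------------------------------------------
#
# Reads excised from each gel band are assigned back to the template they
# came from; per-template counts in the unshifted nucleosome band are then
# compared against a non-specific control template and normalized to the
# input lane, giving the relative-shift statistic (log2 units): templates
# preferentially bound by the factor are depleted from the nucleosome band
# and score positive.

#' Assign band reads to library templates
#'
#' Each read (or read pair) is assigned to the template minimizing the
#' Hamming distance over the best ungapped placement, on either strand.
#' Reads whose best distance exceeds `max_mismatch_frac` of the read
#' length, or that tie between two templates, are counted as unassigned.
#' For pairs the mate distances are summed and the threshold applies to the
#' combined length.
#'
#' Ungapped matching suffices here because templates differ by at least a
#' 20-bp motif block (or flank substitutions), not by indels.
#'
#' @param reads Character vector or [Biostrings::DNAStringSet] of reads.
#' @param library A `nuc_library` (see [build_library()]).
#' @param mates Optional second mates, same length as `reads`.
#' @param max_mismatch_frac Maximum tolerated mismatch fraction
#'   (default 0.1).
#' @return Named integer counts per template id plus an `unassigned` count,
#'   as a list with elements `counts` and `unassigned`.
#' @export
assign_reads <- function(reads, library, mates = NULL,
                         max_mismatch_frac = 0.1) {
  if (nrow(library) == 0L) stop("empty template library", call. = FALSE)
  reads <- as.character(reads)
  counts <- setNames(integer(nrow(library)), library$id)
  if (length(reads) == 0L) return(list(counts = counts, unassigned = 0L))
  tpl <- library$sequence
  score <- function(rd) {
    pmin(hamming_scan(rd, tpl), hamming_scan(revcomp_many(rd), tpl))
  }
  d <- score(reads)
  tot_len <- nchar(reads)
  if (!is.null(mates)) {
    mates <- as.character(mates)
    stopifnot(length(mates) == length(reads))
    d <- d + score(mates)
    tot_len <- tot_len + nchar(mates)
  }
  best <- apply(d, 1L, min)
  nbest <- rowSums(d == best)
  hit <- max.col(-d, ties.method = "first")
  ok <- best <= max_mismatch_frac * tot_len & nbest == 1L
  tab <- tabulate(hit[ok], nbins = nrow(library))
  list(counts = counts + tab, unassigned = sum(!ok))
}

#' Relative shift of each template from the unshifted nucleosome band
#'
#' For template N with nucleosome-band count c_N and input-lane count i_N,
#' relative to a non-specific reference template,
#' \deqn{RS_N = -\log_2\left(\frac{c_N / c_{ref}}{i_N / i_{ref}}\right).}
#' Bound templates are depleted from the unshifted band and score positive.
#' The reference template scores exactly 0, and the statistic is invariant
#' to independent depth rescaling of either band.
#'
#' @param band_counts Named numeric vector: per-template counts in the
#'   unshifted nucleosome band of one lane.
#' @param input_counts Named numeric vector: per-template counts in the
#'   input (no-protein) lane.
#' @param ref_id Reference template id (default `"601"`; the modified
#'   control `"601M"` is the supported alternative).
#' @param pseudocount Added to every count before forming ratios
#'   (default 0.5); with 0, zero reference counts are an error.
#' @return Named numeric vector of relative shifts (log2 units).
#' @export
relative_shift <- function(band_counts, input_counts, ref_id = "601",
                           pseudocount = 0.5) {
  ids <- names(band_counts)
  if (is.null(ids) || is.null(names(input_counts)))
    stop("counts must be named by template id", call. = FALSE)
  if (!ref_id %in% ids || !ref_id %in% names(input_counts))
    stop("reference template '", ref_id, "' absent from counts",
         call. = FALSE)
  input_counts <- input_counts[ids]
  if (anyNA(input_counts))
    stop("input counts missing for some templates", call. = FALSE)
  c_ <- band_counts + pseudocount
  i_ <- input_counts + pseudocount
  if (c_[[ref_id]] == 0 || i_[[ref_id]] == 0)
    stop("zero reference count with zero pseudocount", call. = FALSE)
  rs <- -log2((c_ / c_[[ref_id]]) / (i_ / i_[[ref_id]]))
  rs[ref_id] <- 0
  rs
}

#' Enrichment of each template in the supershifted band
#'
#' Same ratio-of-ratios as [relative_shift()] without the leading minus
#' sign: templates enriched in the shifted (bound) band score positive.
#' Multiple supershift bands should be pooled into one shifted class first
#' (see [pool_supershifts()]).
#'
#' @inheritParams relative_shift
#' @param band_counts Per-template counts in the (pooled) supershift band.
#' @return Named numeric vector of log2 enrichments.
#' @export
supershift_enrichment <- function(band_counts, input_counts, ref_id = "601",
                                  pseudocount = 0.5) {
  -relative_shift(band_counts, input_counts, ref_id, pseudocount)
}

#' Pool multiple supershift bands into one shifted class
#'
#' @param ... Named per-template count vectors (one per supershift band),
#'   or a single list of them.
#' @return Element-wise sum, a named vector.
#' @export
pool_supershifts <- function(...) {
  bands <- list(...)
  if (length(bands) == 1L && is.list(bands[[1L]]) && !is.numeric(bands[[1L]]))
    bands <- bands[[1L]]
  ids <- names(bands[[1L]])
  out <- setNames(numeric(length(ids)), ids)
  for (b in bands) {
    if (!identical(names(b), ids))
      stop("supershift bands have mismatched template sets", call. = FALSE)
    out <- out + b
  }
  out
}

#' Aggregate relative-shift replicates
#'
#' @param results List of per-replicate shift tables: each a data frame
#'   with columns `lane`, `template`, `relative_shift` (as produced by
#'   [shift_table()]).
#' @return Data frame with per (lane, template) `mean` and, when at least
#'   two replicates are present, `range` (max minus min).
#' @export
aggregate_replicates <- function(results) {
  if (length(results) < 1L) stop("need at least one replicate", call. = FALSE)
  key0 <- with(results[[1L]], paste(lane, template))
  for (r in results[-1L]) {
    if (!setequal(with(r, paste(lane, template)), key0))
      stop("replicates cover different (lane, template) sets", call. = FALSE)
  }
  all <- do.call(rbind, Map(function(r, i) transform(r, .rep = i),
                            results, seq_along(results)))
  sp <- split(all$relative_shift, paste(all$lane, all$template, sep = "\r"))
  keys <- do.call(rbind, strsplit(names(sp), "\r", fixed = TRUE))
  out <- data.frame(lane = keys[, 1L], template = keys[, 2L],
                    mean = vapply(sp, mean, numeric(1L)),
                    range = if (length(results) >= 2L)
                      vapply(sp, function(x) diff(range(x)), numeric(1L))
                    else NA_real_,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$lane, out$template), , drop = FALSE]
}

#' Per-lane shift table from a band count table
#'
#' Convenience wrapper applying [relative_shift()] (and, when supershift
#' bands are present, [supershift_enrichment()] on their pooled counts) to
#' every protein-containing lane of a [band_count_table()].
#'
#' @param bct A `band_count_table`.
#' @param ref_id,pseudocount Passed to [relative_shift()].
#' @return Data frame with columns `lane` (concentration label),
#'   `template`, `relative_shift`, and `supershift_enrichment` (NA when no
#'   supershift band).
#' @export
shift_table <- function(bct, ref_id = "601", pseudocount = 0.5) {
  stopifnot(inherits(bct, "band_count_table"))
  input <- bct$input
  out <- list()
  for (ln in names(bct$lanes)) {
    lane <- bct$lanes[[ln]]
    rs <- relative_shift(lane$nucleosome, input, ref_id, pseudocount)
    ss <- rep(NA_real_, length(rs))
    ss_bands <- lane[grepl("^supershift", names(lane))]
    if (length(ss_bands))
      ss <- supershift_enrichment(pool_supershifts(ss_bands), input,
                                  ref_id, pseudocount)
    out[[ln]] <- data.frame(lane = ln, template = names(rs),
                            relative_shift = unname(rs),
                            supershift_enrichment = unname(ss),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Band count table container
#'
#' @param input Named per-template counts of the input (no-protein) lane.
#' @param lanes Named list (one element per protein lane, named by
#'   concentration label) of lists of named per-template count vectors,
#'   with elements `nucleosome` and optionally `supershift`,
#'   `supershift_2`, ...
#' @param concentrations Numeric molar concentrations, parallel to `lanes`.
#' @return A `band_count_table`.
#' @export
band_count_table <- function(input, lanes, concentrations = NULL) {
  ids <- names(input)
  if (is.null(ids)) stop("input counts must be named", call. = FALSE)
  for (lane in lanes) {
    for (b in lane)
      if (!identical(names(b), ids))
        stop("lane band template ids differ from input", call. = FALSE)
  }
  if (any(unlist(lanes) < 0) || any(input < 0))
    stop("counts must be non-negative", call. = FALSE)
  structure(list(input = input, lanes = lanes,
                 concentrations = concentrations),
            class = "band_count_table")
}

#' Write / read a band count table as TSV
#'
#' Long format with columns `lane`, `band`, `template`, `count`; the input
#' lane is stored with `lane = "input"`. Concentrations (molar) are kept in
#' a `# concentrations:` comment line.
#'
#' @param bct A `band_count_table`.
#' @param path TSV path.
#' @return `path` invisibly / the re-read `band_count_table`.
#' @export
write_band_counts <- function(bct, path) {
  stopifnot(inherits(bct, "band_count_table"))
  rows <- data.frame(lane = "input", band = "input",
                     template = names(bct$input),
                     count = unname(bct$input), stringsAsFactors = FALSE)
  for (ln in names(bct$lanes)) {
    for (bn in names(bct$lanes[[ln]])) {
      b <- bct$lanes[[ln]][[bn]]
      rows <- rbind(rows, data.frame(lane = ln, band = bn,
                                     template = names(b),
                                     count = unname(b),
                                     stringsAsFactors = FALSE))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(bct$concentrations))
    writeLines(paste0("# concentrations: ",
                      paste(bct$concentrations, collapse = ",")), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_band_counts
#' @export
read_band_counts <- function(path) {
  first <- readLines(path, n = 1L)
  conc <- NULL
  if (startsWith(first, "# concentrations:"))
    conc <- as.numeric(strsplit(sub("# concentrations: *", "", first),
                                ",")[[1L]])
  rows <- utils::read.table(path, sep = "\t", header = TRUE,
                            comment.char = "#", stringsAsFactors = FALSE,
                            colClasses = c("character", "character",
                                           "character", "numeric"))
  inp <- rows[rows$lane == "input", ]
  input <- setNames(inp$count, inp$template)
  lanes <- list()
  for (ln in unique(rows$lane[rows$lane != "input"])) {
    sub <- rows[rows$lane == ln, ]
    lanes[[ln]] <- lapply(split(sub, sub$band), function(s)
      setNames(s$count, s$template)[names(input)])
  }
  band_count_table(input, lanes, conc)
}
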