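# Genomic signal tracks and summit-anchored sites -----------------------

#' Construct a signal track
#'
#' A thin wrapper around a per-chromosome [IRanges::RleList] of
#' non-negative per-base coverage, carrying the genome-wide tag total used
#' for depth standardization.
#'
#' @param coverage Named list of numeric vectors, or an `RleList`.
#' @return A `signal_track` with elements `coverage` (RleList) and
#'   `total_tags`.
#' @export
signal_track <- function(coverage) {
  if (is.list(coverage) && !is(coverage, "RleList"))
    coverage <- IRanges::RleList(lapply(coverage, S4Vectors::Rle))
  vals <- unlist(lapply(coverage, function(x) min(S4Vectors::runValue(x))))
  if (length(vals) && min(vals) < 0)
    stop("coverage must be non-negative", call. = FALSE)
  structure(list(coverage = coverage,
                 total_tags = sum(vapply(coverage, function(x)
                   sum(as.numeric(S4Vectors::runValue(x)) *
                         S4Vectors::runLength(x)), numeric(1L)))),
            class = "signal_track")
}

#' Read a bedGraph (or fixed-step wiggle) file as a signal track
#'
#' Interval scores are treated as per-base coverage.
#'
#' @param path bedGraph/wig path.
#' @param seqlengths Optional named chromosome lengths; defaults to the
#'   furthest covered position per chromosome.
#' @return A `signal_track`.
#' @export
read_signal_track <- function(path, seqlengths = NULL) {
  gr <- rtracklayer::import(path)
  if (!is.null(seqlengths))
    GenomeInfoDb::seqlengths(gr) <- seqlengths[GenomeInfoDb::seqlevels(gr)]
  cov <- GenomicRanges::coverage(gr, weight = "score")
  signal_track(cov)
}

#' Write a signal track as bedGraph
#'
#' @param track A `signal_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_track <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  gr <- GenomicRanges::bindAsGRanges(score = track$coverage)
  gr <- gr[gr$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Summit-anchored genomic sites
#'
#' @param chrom Chromosome names.
#' @param summit 1-based summit positions (single-base ChIP maxima).
#' @param start,end Optional 1-based closed site intervals containing the
#'   summit; default a 1-bp interval at the summit.
#' @param id Site identifiers.
#' @return A [GenomicRanges::GRanges] with metadata columns `summit` and
#'   `id`.
#' @export
genomic_sites <- function(chrom, summit, start = summit, end = summit,
                          id = NULL) {
  if (any(start > summit | summit > end))
    stop("summit must lie inside the site interval", call. = FALSE)
  id <- id %||% paste0("site_", seq_along(summit))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         summit = as.integer(summit), id = id)
}

#' Read summit sites from BED
#'
#' 0-based half-open BED records become 1-based sites; single-base records
#' anchor the summit directly, wider records use the interval midpoint.
#'
#' @param path BED path.
#' @return A `GRanges` as from [genomic_sites()].
#' @export
read_sites_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  summit <- as.integer(floor((GenomicRanges::start(gr) +
                                GenomicRanges::end(gr)) / 2))
  id <- if (!is.null(gr$name) && !anyNA(gr$name)) gr$name else
    paste0("site_", seq_along(gr))
  genomic_sites(as.character(GenomicRanges::seqnames(gr)), summit,
                GenomicRanges::start(gr), GenomicRanges::end(gr), id)
}

#' Write summit sites as BED
#'
#' @param sites Sites from [genomic_sites()].
#' @param path Output path.
#' @param summit_only Write 1-bp summit records (default) rather than the
#'   full intervals.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path, summit_only = TRUE) {
  gr <- if (summit_only)
    GenomicRanges::GRanges(GenomicRanges::seqnames(sites),
                           IRanges::IRanges(sites$summit, sites$summit),
                           name = sites$id)
  else {
    out <- sites; out$name <- sites$id; out
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
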