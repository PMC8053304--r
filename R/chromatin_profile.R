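# Summit-centered chromatin profiling -----------------------------------
#
# Signal around ChIP-seq summits is summarized as a sites x bins matrix of
# depth-standardized tag counts (2-kb window, 10-bp bins by default,
# standardized to 1e8 tags for histone marks or 1e9 for nucleosome
# occupancy), then grouped, annotated and compared.

#' Binned, depth-standardized profile matrix around summits
#'
#' Entry (site, bin) is the coverage summed over that bin of the window
#' centered on the site summit, rescaled by `standard_total / total_tags`.
#' Sites whose window runs past a chromosome end (or whose chromosome is
#' absent from the track) are dropped with a warning; dropped ids are kept
#' in `attr(, "dropped")`.
#'
#' @param track A [signal_track()].
#' @param sites Sites from [genomic_sites()].
#' @param window_half Half-window in bp (default 1000).
#' @param bin_size Bin width in bp (default 10; must divide the window).
#' @param standard_total Standardized tag total (default 1e8).
#' @return Numeric matrix (sites x bins) with site ids as rownames and
#'   attributes `window_half`, `bin_size`, `standard_total`.
#' @export
binned_profile <- function(track, sites, window_half = 1000L,
                           bin_size = 10L, standard_total = 1e8) {
  stopifnot(inherits(track, "signal_track"))
  window_half <- as.integer(window_half); bin_size <- as.integer(bin_size)
  if ((2L * window_half) %% bin_size != 0L)
    stop("bin_size must divide the window", call. = FALSE)
  if (track$total_tags == 0)
    stop("track has zero total tags", call. = FALSE)
  nbin <- 2L * window_half %/% bin_size
  chroms <- as.character(GenomicRanges::seqnames(sites))
  summit <- sites$summit
  ids <- sites$id
  scale <- standard_total / track$total_tags
  out <- matrix(NA_real_, length(sites), nbin, dimnames = list(ids, NULL))
  for (ch in unique(chroms)) {
    sel <- which(chroms == ch)
    if (!ch %in% names(track$coverage)) next
    cov <- track$coverage[[ch]]
    len <- length(cov)
    # window covers [summit - window_half, summit + window_half - 1]
    wstart <- summit[sel] - window_half
    ok <- wstart >= 1L & summit[sel] + window_half - 1L <= len
    for (i in sel[ok]) {
      s <- summit[i] - window_half
      bins <- IRanges::IRanges(start = s + bin_size * (0:(nbin - 1L)),
                               width = bin_size)
      out[i, ] <- IRanges::viewSums(IRanges::Views(cov, bins)) * scale
    }
  }
  dropped <- ids[!stats::complete.cases(out)]
  if (length(dropped))
    warning(length(dropped), " site(s) dropped: window out of range")
  out <- out[stats::complete.cases(out), , drop = FALSE]
  attr(out, "window_half") <- window_half
  attr(out, "bin_size") <- bin_size
  attr(out, "standard_total") <- standard_total
  attr(out, "dropped") <- dropped
  out
}

#' Average profile over sites
#'
#' @param matrix A profile matrix from [binned_profile()].
#' @return Per-bin column means (attributes preserved).
#' @export
average_profile <- function(matrix) {
  if (nrow(matrix) < 1L) stop("empty profile matrix", call. = FALSE)
  out <- colMeans(matrix)
  attr(out, "window_half") <- attr(matrix, "window_half")
  attr(out, "bin_size") <- attr(matrix, "bin_size")
  out
}

#' Relative bin-center coordinates of a profile
#' @noRd
bin_centers <- function(window_half, bin_size, nbin) {
  -window_half + (seq_len(nbin) - 0.5) * bin_size
}

#' Per-site chromatin feature matrix across marks
#'
#' One feature per mark: `log2(1 + mean standardized window signal)`,
#' z-scored per mark across sites. Depth standardization makes features
#' invariant to sequencing depth; zero-variance marks are left un-scored
#' with a warning. With a single site all z-scores are 0 by convention.
#'
#' @param tracks Named list of [signal_track()]s.
#' @param sites Sites from [genomic_sites()].
#' @param window_half,bin_size,standard_total Passed to [binned_profile()].
#' @return Sites x marks numeric matrix.
#' @export
site_feature_matrix <- function(tracks, sites, window_half = 1000L,
                                bin_size = 10L, standard_total = 1e8) {
  if (length(tracks) < 1L) stop("need at least one track", call. = FALSE)
  if (is.null(names(tracks))) stop("tracks must be named", call. = FALSE)
  cols <- lapply(tracks, function(tr) {
    pm <- binned_profile(tr, sites, window_half, bin_size, standard_total)
    rowMeans(pm)
  })
  common <- Reduce(intersect, lapply(cols, names))
  feat <- vapply(cols, function(x) log2(1 + x[common]),
                 numeric(length(common)))
  feat <- matrix(feat, nrow = length(common),
                 dimnames = list(common, names(tracks)))
  for (j in seq_len(ncol(feat))) {
    if (nrow(feat) == 1L) { feat[, j] <- 0; next }
    s <- stats::sd(feat[, j])
    if (s == 0) {
      warning("zero-variance mark '", colnames(feat)[j],
              "': z-score skipped")
      next
    }
    feat[, j] <- (feat[, j] - mean(feat[, j])) / s
  }
  feat
}

#' Seeded k-means chromatin grouping
#'
#' Euclidean k-means over the feature matrix, best of `n_restarts` random
#' starts by within-cluster sum of squares; deterministic given `seed`.
#' Group labels are relabeled in order of descending cluster size (group 1
#' is the largest).
#'
#' @param features Sites x features numeric matrix.
#' @param k Number of groups (default 4).
#' @param seed RNG seed.
#' @param n_restarts Random restarts (default 100).
#' @return List with `labels` (named integer vector), `centers`,
#'   `objective` (best total within-cluster SS), `restart_objectives`, and
#'   `seed`.
#' @export
kmeans_cluster <- function(features, k = 4L, seed = 1L, n_restarts = 100L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > nrow(features))
    stop("k exceeds the number of sites", call. = FALSE)
  with_seed(seed, {
    objs <- numeric(n_restarts)
    best <- NULL
    for (r in seq_len(n_restarts)) {
      km <- suppressWarnings(
        stats::kmeans(features, centers = k, iter.max = 100L, nstart = 1L))
      objs[r] <- km$tot.withinss
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    ord <- order(-best$size, seq_len(k))
    relab <- integer(k); relab[ord] <- seq_len(k)
    labels <- setNames(relab[best$cluster], rownames(features))
    list(labels = labels, centers = best$centers[ord, , drop = FALSE],
         objective = best$tot.withinss, restart_objectives = objs,
         seed = seed)
  })
}

#' Classify site accessibility against accessible intervals
#'
#' A site is accessible iff its summit lies inside an accessible interval
#' (half-open on disk; containment in 1-based coordinates internally).
#' Sites on chromosomes absent from the interval set are inaccessible, with
#' a warning.
#'
#' @param sites Sites from [genomic_sites()].
#' @param accessible_intervals `GRanges` of accessible regions (e.g. read
#'   from a DNase/FAIRE synthesis BED).
#' @return List with `accessible` (named logical), `n_accessible`,
#'   `n_sites`, `fraction`.
#' @export
classify_accessibility <- function(sites, accessible_intervals) {
  summits <- GenomicRanges::GRanges(GenomicRanges::seqnames(sites),
                                    IRanges::IRanges(sites$summit,
                                                     sites$summit))
  missing_chr <- setdiff(unique(as.character(GenomicRanges::seqnames(sites))),
                         unique(as.character(
                           GenomicRanges::seqnames(accessible_intervals))))
  if (length(missing_chr) && length(accessible_intervals))
    warning("chromosome(s) absent from interval set: ",
            paste(missing_chr, collapse = ", "))
  # disjoint seqlevels are a legitimate no-overlap case, not a warning
  acc <- suppressWarnings(IRanges::overlapsAny(summits,
                                               accessible_intervals))
  names(acc) <- sites$id
  list(accessible = acc, n_accessible = sum(acc), n_sites = length(acc),
       fraction = if (length(acc)) mean(acc) else 0)
}

#' Gene model container
#'
#' @param transcripts `GRanges` of transcript spans with metadata column
#'   `tx_id` (strand used for TSS orientation).
#' @param exons `GRanges` of exons with metadata column `tx_id`.
#'   Transcripts with an exon outside their span are skipped with a
#'   warning.
#' @return A `gene_model` list.
#' @export
gene_model <- function(transcripts, exons) {
  bad <- character()
  for (tx in unique(exons$tx_id)) {
    i <- which(transcripts$tx_id == tx)
    if (!length(i)) { bad <- c(bad, tx); next }
    ex <- exons[exons$tx_id == tx]
    span <- transcripts[i]
    if (any(GenomicRanges::start(ex) < GenomicRanges::start(span) |
            GenomicRanges::end(ex) > GenomicRanges::end(span)) ||
        any(as.character(GenomicRanges::seqnames(ex)) !=
            as.character(GenomicRanges::seqnames(span))))
      bad <- c(bad, tx)
  }
  if (length(bad)) {
    warning("skipping malformed transcript(s): ",
            paste(bad, collapse = ", "))
    transcripts <- transcripts[!transcripts$tx_id %in% bad]
    exons <- exons[!exons$tx_id %in% bad]
  }
  structure(list(transcripts = transcripts, exons = exons),
            class = "gene_model")
}

#' Read a GFF3-subset gene model
#'
#' Expects `mRNA`/`transcript` records (used as transcript spans) and
#' `exon` records with `Parent` attributes.
#'
#' @param path GFF3 path.
#' @return A [gene_model()].
#' @export
read_gene_model <- function(path) {
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  tx <- gr[type %in% c("mRNA", "transcript")]
  tx$tx_id <- as.character(tx$ID)
  ex <- gr[type == "exon"]
  ex$tx_id <- vapply(ex$Parent, function(p) as.character(p)[1L],
                     character(1L))
  gene_model(tx[, "tx_id"], ex[, "tx_id"])
}

#' Annotate summits against a gene model
#'
#' Category precedence: promoter (stranded, TSS -1000/+100) > exon >
#' intron > intergenic. Fractions over the four categories sum to 1.
#'
#' @param sites Sites from [genomic_sites()].
#' @param model A [gene_model()].
#' @param promoter_up,promoter_down Promoter window around the TSS in bp
#'   (defaults 1000 upstream, 100 downstream).
#' @return List with `category` (named character) and `fractions`.
#' @export
annotate_sites <- function(sites, model, promoter_up = 1000L,
                           promoter_down = 100L) {
  stopifnot(inherits(model, "gene_model"))
  summits <- GenomicRanges::GRanges(GenomicRanges::seqnames(sites),
                                    IRanges::IRanges(sites$summit,
                                                     sites$summit))
  tx <- model$transcripts
  plus <- as.character(GenomicRanges::strand(tx)) != "-"
  tss <- ifelse(plus, GenomicRanges::start(tx), GenomicRanges::end(tx))
  prom <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(tx),
    IRanges::IRanges(pmax(1L, ifelse(plus, tss - promoter_up,
                                     tss - promoter_down)),
                     ifelse(plus, tss + promoter_down, tss + promoter_up)))
  cat <- rep("intergenic", length(sites))
  cat[IRanges::overlapsAny(summits, tx)] <- "intronic"
  cat[IRanges::overlapsAny(summits, model$exons)] <- "exonic"
  cat[IRanges::overlapsAny(summits, prom)] <- "promoter"
  names(cat) <- sites$id
  lev <- c("promoter", "exonic", "intronic", "intergenic")
  fr <- table(factor(cat, levels = lev)) / length(cat)
  list(category = cat, fractions = setNames(as.numeric(fr), lev))
}

#' Compare two summit site sets
#'
#' A site is shared iff some summit in the other set on the same chromosome
#' lies within `match_dist` bp of its summit. The partition covers each
#' input set exactly once: `a_shared` + `a_only` = |A| and `b_shared` +
#' `b_only` = |B|.
#'
#' @param sites_a,sites_b Sites from [genomic_sites()].
#' @param match_dist Maximum summit distance in bp (default 100).
#' @return List with logical vectors `a_shared`, `b_shared` and counts
#'   `n_shared_a`, `n_a_only`, `n_shared_b`, `n_b_only`.
#' @export
compare_site_sets <- function(sites_a, sites_b, match_dist = 100L) {
  if (match_dist < 0) stop("match_dist must be >= 0", call. = FALSE)
  pt <- function(s) GenomicRanges::GRanges(
    GenomicRanges::seqnames(s), IRanges::IRanges(s$summit, s$summit))
  a <- pt(sites_a); b <- pt(sites_b)
  a_shared <- suppressWarnings(IRanges::overlapsAny(a, b + match_dist))
  b_shared <- suppressWarnings(IRanges::overlapsAny(b, a + match_dist))
  names(a_shared) <- sites_a$id; names(b_shared) <- sites_b$id
  list(a_shared = a_shared, b_shared = b_shared,
       n_shared_a = sum(a_shared), n_a_only = sum(!a_shared),
       n_shared_b = sum(b_shared), n_b_only = sum(!b_shared))
}

#' Average signal change and peak-valley-peak call
#'
#' Computes the per-bin difference of average profiles (after minus before)
#' and flags the characteristic peak-valley-peak shape of the after
#' profile: the central +/-100 bp holds the local minimum (valley) and both
#' flanks carry a maximum within +/-500 bp exceeding the valley by
#' `peak_ratio`.
#'
#' @param before,after Profile matrices from [binned_profile()] with
#'   identical geometry.
#' @param peak_ratio Required flank-peak to valley ratio (default 1.25).
#' @param valley_half Central half-width in bp holding the valley
#'   (default 100).
#' @param flank_max Flank search limit in bp (default 500).
#' @return List with `delta` (per-bin average change), `pvp` (logical
#'   flag), `avg_before`, `avg_after`.
#' @export
signal_delta <- function(before, after, peak_ratio = 1.25,
                         valley_half = 100, flank_max = 500) {
  geom <- function(m) as.numeric(c(ncol(m), attr(m, "window_half"),
                                   attr(m, "bin_size")))
  if (!isTRUE(all.equal(geom(before), geom(after))))
    stop("profile matrices have mismatched geometry", call. = FALSE)
  avg_b <- average_profile(before)
  avg_a <- average_profile(after)
  delta <- as.vector(avg_a) - as.vector(avg_b)
  ctr <- bin_centers(attr(before, "window_half"), attr(before, "bin_size"),
                     ncol(before))
  central <- abs(ctr) <= valley_half
  left <- ctr < -valley_half & ctr >= -flank_max
  right <- ctr > valley_half & ctr <= flank_max
  valley <- min(avg_a[central])
  lp <- if (any(left)) max(avg_a[left]) else -Inf
  rp <- if (any(right)) max(avg_a[right]) else -Inf
  pvp <- if (valley == 0) lp > 0 && rp > 0 else
    lp >= peak_ratio * valley && rp >= peak_ratio * valley
  list(delta = delta, pvp = pvp, avg_before = avg_b, avg_after = avg_a)
}

#' Write / read a profile matrix as TSV
#'
#' Geometry is kept in `#` comment lines so the round trip preserves
#' attributes.
#'
#' @param matrix Profile matrix from [binned_profile()].
#' @param path TSV path.
#' @return `path` invisibly / the re-read matrix.
#' @export
write_profile_matrix <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# window_half: %d\n# bin_size: %d\n# standard_total: %g",
                     attr(matrix, "window_half"), attr(matrix, "bin_size"),
                     attr(matrix, "standard_total") %||% NA), con)
  utils::write.table(matrix, con, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_matrix
#' @export
read_profile_matrix <- function(path) {
  hdr <- readLines(path, n = 3L)
  val <- function(k) as.numeric(sub(paste0("# ", k, ": "), "",
                                    hdr[startsWith(hdr, paste0("# ", k))]))
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          row.names = 1L)
  m <- as.matrix(df)
  dimnames(m) <- list(rownames(df), NULL)
  attr(m, "window_half") <- as.integer(val("window_half"))
  attr(m, "bin_size") <- as.integer(val("bin_size"))
  st <- val("standard_total")
  if (!is.na(st)) attr(m, "standard_total") <- st
  m
}
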