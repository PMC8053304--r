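# Synthetic chromatin landscape ------------------------------------------
#
# Generates a small genome with planted binding-site groups that mirror the
# chromatin classes observed around pioneer-factor summits: three active
# classes (promoter-like, enhancer-like, repressive-mark) and a majority
# class bereft of any histone-mark signal and inaccessible. Each site
# carries a positioned nucleosome whose dyad is displaced 50-60 bp from the
# summit on a random side, and the "after" H3K27ac track adds flanking
# acetylation gains with a central valley at bound sites.

#' Chromatin simulation configuration
#'
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param n_sites Named counts of planted sites per group: `a`
#'   (promoter-like active), `b` (enhancer-like active), `c`
#'   (repressive-mark), `d` (unmodified; the majority class).
#' @param accessible_fraction Fraction of sites (taken in group order
#'   a, b, c, d) lying inside accessible intervals (default 0.28).
#' @param nuc_offset_range Integer range (bp) of the positioned-nucleosome
#'   dyad displacement from the summit (default 50-60, random side).
#' @param h3k27ac_gain Amplitude of the planted flanking acetylation gain
#'   (expected per-base tags; default 1.2).
#' @param n_shared Number of cell-line-A sites also bound in cell line B.
#' @param n_b_only Number of extra B-only sites.
#' @param n_genes Number of genes in the synthetic gene model.
#' @param noise Fractional Poisson perturbation of track bins; 0 gives
#'   exact expected coverage (default 0.2).
#' @param seed RNG seed.
#' @return A `chromatin_sim_config` list.
#' @export
chromatin_sim_config <- function(chrom_lengths = c(chrS1 = 500000L,
                                                   chrS2 = 350000L),
                                 n_sites = c(a = 30L, b = 30L, c = 30L,
                                             d = 160L),
                                 accessible_fraction = 0.28,
                                 nuc_offset_range = c(50L, 60L),
                                 h3k27ac_gain = 1.2,
                                 n_shared = 120L,
                                 n_b_only = 40L,
                                 n_genes = 40L,
                                 noise = 0.2,
                                 seed = 1L) {
  if (accessible_fraction < 0 || accessible_fraction > 1)
    stop("accessible_fraction must be in [0, 1]", call. = FALSE)
  if (any(chrom_lengths <= 4000L))
    stop("chromosomes must exceed twice the profile window", call. = FALSE)
  if (noise < 0) stop("noise must be >= 0", call. = FALSE)
  structure(list(chrom_lengths = chrom_lengths, n_sites = n_sites,
                 accessible_fraction = accessible_fraction,
                 nuc_offset_range = as.integer(nuc_offset_range),
                 h3k27ac_gain = h3k27ac_gain,
                 n_shared = as.integer(n_shared),
                 n_b_only = as.integer(n_b_only),
                 n_genes = as.integer(n_genes),
                 noise = noise, seed = seed),
            class = "chromatin_sim_config")
}

# Marks emitted for the synthetic genome.
ACTIVE_MARKS <- c("H3K4me1", "H3K4me2", "H3K4me3", "H3K9ac", "H3K27ac")
REPRESSIVE_MARKS <- c("H3K9me3", "H3K27me3")

# Peak amplitudes (expected per-base tags at the flanking-peak maxima) per
# group for each histone mark; group d is baseline-only by construction.
mark_amplitudes <- function() {
  amp <- matrix(0, nrow = 7, ncol = 3,
                dimnames = list(c(ACTIVE_MARKS, REPRESSIVE_MARKS),
                                c("a", "b", "c")))
  amp["H3K4me3", ] <- c(2.0, 0.2, 0.1)
  amp["H3K4me2", ] <- c(1.5, 1.0, 0.1)
  amp["H3K4me1", ] <- c(0.3, 1.5, 0.1)
  amp["H3K9ac", ] <- c(1.5, 0.8, 0.0)
  amp["H3K27ac", ] <- c(1.5, 1.2, 0.0)
  amp["H3K9me3", ] <- c(0, 0, 1.2)
  amp["H3K27me3", ] <- c(0, 0, 1.5)
  amp
}

#' Simulate the chromatin landscape
#'
#' @param config A [chromatin_sim_config()].
#' @param out_dir Optional directory; when given, site BEDs, the
#'   accessible-interval BED, the gene-model GFF3 and all tracks
#'   (bedGraph) are written there.
#' @return List with `sites` (cell line A, metadata columns `group`,
#'   `effect`, `nuc_offset`), `sites_b` (cell line B), `accessible`
#'   (`GRanges`), `genes` ([gene_model()]), `tracks` (named
#'   [signal_track()] list: the seven marks, `DNase`, `MNase`,
#'   `H3K27ac_after`), `truth` (planted group labels, accessible fraction,
#'   shared-site counts), and `paths` when `out_dir` is used.
#' @export
simulate_chromatin <- function(config = chromatin_sim_config(),
                               out_dir = NULL) {
  stopifnot(inherits(config, "chromatin_sim_config"))
  with_seed(config$seed, {
    lens <- config$chrom_lengths
    n_tot <- sum(config$n_sites)
    # non-overlapping anchor slots, 2.2 kb apart, 2.2 kb margins
    slots <- do.call(rbind, lapply(names(lens), function(ch) {
      pos <- seq(2200L, lens[[ch]] - 2200L, by = 2200L)
      data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
    }))
    need <- n_tot + config$n_b_only + config$n_genes
    if (need > nrow(slots))
      stop("genome too small for the requested sites and genes",
           call. = FALSE)
    take <- slots[sample.int(nrow(slots), need), ]
    site_slots <- take[seq_len(n_tot), ]
    b_slots <- take[n_tot + seq_len(config$n_b_only), ]
    gene_slots <- take[n_tot + config$n_b_only + seq_len(config$n_genes), ]

    group <- rep(names(config$n_sites), config$n_sites)
    ord <- order(site_slots$chrom, site_slots$pos)
    site_slots <- site_slots[ord, ]  # group stays aligned to slot draw order
    group <- group[ord]
    sites <- genomic_sites(site_slots$chrom, site_slots$pos,
                           id = sprintf("A_%03d", seq_len(n_tot)))
    sites$group <- group
    sites$effect <- TRUE  # every bound site gains flanking acetylation
    delta <- sample(seq(config$nuc_offset_range[1L],
                        config$nuc_offset_range[2L]), n_tot,
                    replace = TRUE)
    side <- sample(c(-1L, 1L), n_tot, replace = TRUE)
    sites$nuc_offset <- as.integer(side * delta)

    # accessibility: first round(frac * n) sites in group order a,b,c,d
    by_group <- order(match(group, c("a", "b", "c", "d")))
    n_acc <- round(config$accessible_fraction * n_tot)
    acc_idx <- by_group[seq_len(n_acc)]
    accessible_sites <- rep(FALSE, n_tot); accessible_sites[acc_idx] <- TRUE
    accessible <- if (n_acc > 0)
      GenomicRanges::reduce(GenomicRanges::GRanges(
        GenomicRanges::seqnames(sites)[acc_idx],
        IRanges::IRanges(sites$summit[acc_idx] - 150L,
                         sites$summit[acc_idx] + 150L)))
    else GenomicRanges::GRanges()

    # cell line B: first n_shared A sites (jittered summits) + B-only sites
    sh_idx <- seq_len(min(config$n_shared, n_tot))
    jitter <- sample(-20:20, length(sh_idx), replace = TRUE)
    sites_b <- genomic_sites(
      c(as.character(GenomicRanges::seqnames(sites))[sh_idx],
        b_slots$chrom),
      c(sites$summit[sh_idx] + jitter, b_slots$pos),
      id = sprintf("B_%03d", seq_len(length(sh_idx) + nrow(b_slots))))

    genes <- make_gene_model(gene_slots, lens)

    # expected per-base coverage ------------------------------------------
    bg <- 0.1
    gauss <- function(x, mu, sd) exp(-(x - mu)^2 / (2 * sd^2))
    new_lambda <- function() lapply(lens, function(l) rep(bg, l))
    add_shape <- function(lam, chrom, center, amp, mus, sd) {
      l <- length(lam[[chrom]])
      xs <- max(1L, center - 1000L):min(l, center + 1000L)
      v <- 0
      for (mu in mus) v <- v + amp * gauss(xs, center + mu, sd)
      lam[[chrom]][xs] <- lam[[chrom]][xs] + v
      lam
    }
    amp <- mark_amplitudes()
    chroms <- as.character(GenomicRanges::seqnames(sites))
    lambdas <- list()
    for (mk in rownames(amp)) {
      lam <- new_lambda()
      for (i in seq_len(n_tot)) {
        g <- group[i]
        if (g == "d" || amp[mk, g] == 0) next
        lam <- add_shape(lam, chroms[i], sites$summit[i], amp[mk, g],
                         c(-150L, 150L), 75)
      }
      lambdas[[mk]] <- lam
    }
    lam <- new_lambda()  # DNase: central peak at accessible sites
    for (i in which(accessible_sites))
      lam <- add_shape(lam, chroms[i], sites$summit[i], 2.0, 0L, 100)
    lambdas[["DNase"]] <- lam
    lam <- new_lambda()  # MNase: positioned nucleosome, displaced dyad
    for (i in seq_len(n_tot))
      lam <- add_shape(lam, chroms[i], sites$summit[i], 3.0,
                       sites$nuc_offset[i], 45)
    lambdas[["MNase"]] <- lam
    lam <- lambdas[["H3K27ac"]]  # after induction: flanking gains + valley
    for (i in which(sites$effect))
      lam <- add_shape(lam, chroms[i], sites$summit[i],
                       config$h3k27ac_gain, c(-200L, 200L), 80)
    lambdas[["H3K27ac_after"]] <- lam

    tracks <- lapply(lambdas, lambda_to_track, noise = config$noise)

    out <- list(sites = sites, sites_b = sites_b, accessible = accessible,
                genes = genes, tracks = tracks,
                truth = list(group = setNames(group, sites$id),
                             accessible = setNames(accessible_sites,
                                                   sites$id),
                             accessible_fraction = n_acc / n_tot,
                             nuc_offset = setNames(sites$nuc_offset,
                                                   sites$id),
                             n_shared = length(sh_idx),
                             n_b_only = nrow(b_slots)),
                config = config)
    if (!is.null(out_dir)) out$paths <- write_chromatin_sim(out, out_dir)
    out
  })
}

# Draw per-10bp-bin coverage around the expected lambda: noise = 0 gives
# the expectation exactly; otherwise bins are perturbed toward a Poisson
# draw of their expected tag sum, scaled by the noise fraction.
lambda_to_track <- function(lam, noise, bin = 10L) {
  cov <- lapply(lam, function(v) {
    if (noise == 0) return(v)
    nb <- length(v) %/% bin
    head_v <- v[seq_len(nb * bin)]
    m <- matrix(head_v, nrow = bin)
    mu <- colSums(m)
    drawn <- rpois(nb, mu) / bin
    binned <- (1 - noise) * (mu / bin) + noise * drawn
    out <- rep(binned, each = bin)
    c(out, v[-seq_len(nb * bin)])
  })
  signal_track(cov)
}

# Random gene model on the remaining anchor slots.
make_gene_model <- function(gene_slots, lens) {
  n <- nrow(gene_slots)
  if (n == 0L) {
    empty <- GenomicRanges::GRanges()
    empty$tx_id <- character()
    return(gene_model(empty, empty))
  }
  width <- sample(3000:12000, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  start <- pmax(1L, gene_slots$pos - width %/% 2L)
  end <- pmin(lens[gene_slots$chrom], start + width)
  tx_id <- sprintf("tx_%03d", seq_len(n))
  tx <- GenomicRanges::GRanges(gene_slots$chrom,
                               IRanges::IRanges(start, end),
                               strand = strand, tx_id = tx_id)
  ex_list <- lapply(seq_len(n), function(i) {
    nex <- sample(2:5, 1L)
    w <- end[i] - start[i] + 1L
    bounds <- sort(sample.int(w - 2L, 2L * nex - 2L)) + start[i] - 1L
    es <- c(start[i], bounds[seq(2L, length(bounds), by = 2L)] + 1L)
    ee <- c(bounds[seq(1L, length(bounds), by = 2L)], end[i])
    GenomicRanges::GRanges(gene_slots$chrom[i],
                           IRanges::IRanges(es, pmax(es, ee)),
                           strand = strand[i], tx_id = tx_id[i])
  })
  gene_model(tx, suppressWarnings(do.call(c, ex_list)))
}

#' Write a simulated chromatin landscape to disk
#'
#' @param sim Result of [simulate_chromatin()].
#' @param dir Output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
write_chromatin_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    sites_a = write_sites_bed(sim$sites, file.path(dir, "sites_A.bed")),
    sites_b = write_sites_bed(sim$sites_b, file.path(dir, "sites_B.bed")))
  acc_path <- file.path(dir, "accessible.bed")
  rtracklayer::export(sim$accessible, acc_path, format = "BED")
  paths["accessible"] <- acc_path
  gff_path <- file.path(dir, "genes.gff3")
  write_gene_model_gff(sim$genes, gff_path)
  paths["genes"] <- gff_path
  for (mk in names(sim$tracks)) {
    p <- file.path(dir, paste0(mk, ".bedGraph"))
    write_signal_track(sim$tracks[[mk]], p)
    paths[mk] <- p
  }
  invisible(paths)
}

#' Write a gene model as GFF3
#'
#' @param model A [gene_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_model_gff <- function(model, path) {
  tx <- model$transcripts
  ex <- model$exons
  tx_gr <- tx
  tx_gr$type <- "mRNA"
  tx_gr$ID <- tx$tx_id
  ex_gr <- ex
  ex_gr$type <- "exon"
  ex_gr$Parent <- ex$tx_id
  lines <- c("##gff-version 3")
  fmt <- function(gr, attrs) sprintf(
    "%s\tnucpioneer\t%s\t%d\t%d\t.\t%s\t.\t%s",
    as.character(GenomicRanges::seqnames(gr)), gr$type,
    GenomicRanges::start(gr), GenomicRanges::end(gr),
    as.character(GenomicRanges::strand(gr)), attrs)
  if (length(tx_gr))
    lines <- c(lines, fmt(tx_gr, paste0("ID=", tx_gr$ID)))
  if (length(ex_gr))
    lines <- c(lines, fmt(ex_gr, paste0("Parent=", ex_gr$Parent)))
  writeLines(lines, path)
  invisible(path)
}
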