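# End-to-end workflows ---------------------------------------------------
#
# Two orchestrated arms with YAML configuration, stage-tagged logging to
# stderr, and JSON run reports: the in vitro arm (template library ->
# simulated titration -> relative shifts -> positional-model fit) and the
# in vivo arm (synthetic chromatin -> summit profiles -> clustering,
# accessibility, annotation, set comparison, symmetry, acetylation delta).

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

read_run_config <- function(config) {
  if (is.character(config)) yaml::read_yaml(config) else config
}

pkg_version <- function() {
  as.character(utils::packageVersion("nucpioneer"))
}

#' Run the in vitro arm end to end
#'
#' Builds the template library, simulates (or loads) band counts,
#' computes per-lane relative shifts, and fits the positional binding
#' model. With `offsets: []` only the two controls exist and the fit is
#' skipped with a `controls only, fit skipped` flag.
#'
#' @param config YAML path or list. Recognized fields (all optional):
#'   `seed`, `offsets`, `concentrations_nM`, `reads_per_band`,
#'   `pseudocount`, `ref_id`, `model` (list: `kd_high_nM`,
#'   `kd_intermediate_nM`, `theta0`, `d_star`, `s`), `out_dir`.
#' @return A run report list (config echo, output paths, headline
#'   numbers, package version, seed registry), invisibly written as JSON
#'   to `out_dir/report_invitro.json` when `out_dir` is set.
#' @export
run_invitro <- function(config = list()) {
  cfg <- read_run_config(config)
  seed <- cfg$seed %||% 1L
  offsets <- if (!is.null(cfg$offsets)) as.integer(unlist(cfg$offsets))
  else c(0L, 5L, 41L, 46L, 66L, 71L, 81L)
  conc <- (cfg$concentrations_nM %||% c(18, 36, 71, 142, 286)) * 1e-9
  depth <- cfg$reads_per_band %||% 2e5
  ref_id <- cfg$ref_id %||% "601"
  pseudocount <- cfg$pseudocount %||% 0.5
  m <- cfg$model %||% list()
  truth <- binding_model(
    kd_high = (m$kd_high_nM %||% 25) * 1e-9,
    kd_intermediate = (m$kd_intermediate_nM %||% 100) * 1e-9,
    theta0 = m$theta0 %||% 0.02,
    d_star = m$d_star %||% 50, s = m$s %||% 2)
  out_dir <- cfg$out_dir
  paths <- list()

  log_stage("library", "building template library")
  lib <- run_stage("library", build_library(
    library_config(offsets = offsets)))
  controls_only <- length(offsets) == 0L
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths$library_fasta <- write_library_fasta(
      lib, file.path(out_dir, "library.fa"))
  }

  log_stage("simulate", "titration at ", length(conc), " concentrations, ",
            "depth ", depth)
  sim_cfg <- run_stage("simulate", emsa_sim_config(
    library = lib, model = truth, concentrations = conc,
    reads_per_band = depth, seed = seed))
  bct <- run_stage("simulate", simulate_titration(sim_cfg))
  if (!is.null(out_dir))
    paths$counts_tsv <- write_band_counts(
      bct, file.path(out_dir, "band_counts.tsv"))

  log_stage("shift", "computing relative shifts vs ", ref_id)
  shifts <- run_stage("shift", shift_table(bct, ref_id, pseudocount))
  if (!is.null(out_dir)) {
    paths$shifts_tsv <- file.path(out_dir, "shifts.tsv")
    utils::write.table(shifts, paths$shifts_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  fit <- NULL
  if (controls_only) {
    log_stage("fit", "controls only, fit skipped")
  } else {
    log_stage("fit", "fitting positional binding model")
    shifts$concentration <- conc[match(shifts$lane,
                                       sprintf("%gnM", conc * 1e9))]
    fit <- run_stage("fit", fit_positional_model(shifts, lib))
  }

  report <- list(
    arm = "invitro", version = pkg_version(),
    config = cfg, seed = seed, paths = paths,
    library = list(n_templates = nrow(lib),
                   n_motif = sum(lib$motif_kind != "none"),
                   template_length = unique(nchar(lib$sequence))),
    flags = if (controls_only) "controls only, fit skipped" else character(),
    shift_table = shifts,
    fit = if (!is.null(fit) && !fit$no_binding)
      list(d_star = fit$model$d_star, s = fit$model$s,
           kd_high = fit$model$kd_high,
           kd_intermediate = fit$model$kd_intermediate,
           objective = fit$objective)
    else if (!is.null(fit)) list(no_binding = TRUE))
  if (!is.null(out_dir)) {
    rp <- file.path(out_dir, "report_invitro.json")
    jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA,
                         force = TRUE, pretty = TRUE)
    report$paths$report <- rp
  }
  report
}

#' Run the in vivo arm end to end
#'
#' Simulates (or loads) the chromatin landscape, profiles all marks around
#' the summits, k-means-groups the sites, calls accessibility, annotates
#' against the gene model, compares the two cell-line site sets, orients
#' and clusters nucleosome occupancy, and computes the H3K27ac change with
#' its peak-valley-peak call.
#'
#' @param config YAML path or list. Recognized fields (all optional):
#'   `seed`, `k`, `n_restarts`, `noise`, `accessible_fraction`,
#'   `match_dist`, `out_dir`, plus any [chromatin_sim_config()] override
#'   under `sim`.
#' @return A run report list, written as JSON to
#'   `out_dir/report_invivo.json` when `out_dir` is set.
#' @export
run_invivo <- function(config = list()) {
  cfg <- read_run_config(config)
  seed <- cfg$seed %||% 1L
  k <- cfg$k %||% 4L
  n_restarts <- cfg$n_restarts %||% 100L
  match_dist <- cfg$match_dist %||% 100L
  out_dir <- cfg$out_dir
  sim_over <- cfg$sim %||% list()
  sim_args <- utils::modifyList(
    list(noise = cfg$noise %||% 0.2,
         accessible_fraction = cfg$accessible_fraction %||% 0.28,
         seed = seed),
    sim_over)
  if (!is.null(cfg$tracks)) {
    # real-data mode: named bedGraph paths plus site/interval/gene files
    sim <- run_stage("load", {
      missing <- unlist(cfg$tracks)[!file.exists(unlist(cfg$tracks))]
      if (length(missing))
        stop("missing track file(s): ", paste(missing, collapse = ", "))
      list(sites = read_sites_bed(cfg$sites_bed),
           sites_b = if (!is.null(cfg$sites_b_bed))
             read_sites_bed(cfg$sites_b_bed),
           accessible = rtracklayer::import(cfg$accessible_bed,
                                            format = "BED"),
           genes = read_gene_model(cfg$genes_gff),
           tracks = lapply(cfg$tracks, read_signal_track),
           paths = NULL)
    })
  } else {
    log_stage("simulate", "generating synthetic chromatin landscape")
    sim <- run_stage("simulate",
                     simulate_chromatin(do.call(chromatin_sim_config,
                                                sim_args),
                                        out_dir = out_dir))
  }

  log_stage("profile", "binned profiles for ",
            length(sim$tracks), " tracks")
  marks <- c(ACTIVE_MARKS, REPRESSIVE_MARKS, "DNase")
  feat <- run_stage("profile",
                    site_feature_matrix(sim$tracks[marks], sim$sites))

  log_stage("cluster", "k-means, k = ", k)
  km <- run_stage("cluster",
                  kmeans_cluster(feat, k = k, seed = seed,
                                 n_restarts = n_restarts))

  log_stage("accessibility", "summit-in-interval calls")
  acc <- run_stage("accessibility",
                   classify_accessibility(sim$sites, sim$accessible))

  log_stage("annotate", "gene-model annotation")
  ann <- run_stage("annotate", annotate_sites(sim$sites, sim$genes))

  cmp <- NULL
  if (!is.null(sim$sites_b)) {
    log_stage("compare", "site-set comparison at ", match_dist, " bp")
    cmp <- run_stage("compare",
                     compare_site_sets(sim$sites, sim$sites_b, match_dist))
  }

  log_stage("symmetry", "orienting nucleosome occupancy")
  mnase <- run_stage("symmetry",
                     binned_profile(sim$tracks$MNase, sim$sites,
                                    standard_total = 1e9))
  oc <- run_stage("symmetry",
                  orient_cluster(mnase, k = 2L, seed = seed))
  peaks <- run_stage("symmetry", vapply(seq_len(nrow(oc$means)), function(j)
    occupancy_peak_offset(oc$means[j, ], attr(mnase, "window_half"),
                          attr(mnase, "bin_size"))$offset, numeric(1L)))
  main_cl <- which.max(tabulate(oc$cluster, nbins = nrow(oc$means)))
  peak <- list(offset = peaks[main_cl], per_cluster = peaks)

  log_stage("delta", "H3K27ac before/after")
  before <- run_stage("delta",
                      binned_profile(sim$tracks$H3K27ac, sim$sites))
  after <- run_stage("delta",
                     binned_profile(sim$tracks$H3K27ac_after, sim$sites))
  dl <- run_stage("delta", signal_delta(before, after))

  report <- list(
    arm = "invivo", version = pkg_version(),
    config = cfg, seed = seed,
    paths = as.list(sim$paths %||% list()),
    n_sites = length(sim$sites),
    cluster_sizes = as.list(table(km$labels)),
    kmeans_objective = km$objective,
    accessible_fraction = acc$fraction,
    annotation_fractions = as.list(ann$fractions),
    set_comparison = if (!is.null(cmp))
      cmp[c("n_shared_a", "n_a_only", "n_shared_b", "n_b_only")],
    occupancy_peak_offset = peak$offset,
    occupancy_peak_per_cluster = peak$per_cluster,
    pvp = dl$pvp)
  if (!is.null(out_dir)) {
    rp <- file.path(out_dir, "report_invivo.json")
    jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA,
                         force = TRUE, pretty = TRUE)
    report$paths$report <- rp
  }
  report
}
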