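# Positional-accessibility binding model --------------------------------
#
# Binding of the factor to a nucleosomal motif is modelled as a simple
# occupancy isotherm whose effective affinity is attenuated by how far the
# motif sits from the nucleosome dyad: sites near the dyad are sterically
# occluded, sites near the entry/exit edge are accessible through partial
# DNA unwrapping. Accessibility follows a logistic switch
#   a(d) = 1 / (1 + exp(-(d - d_star)/s))
# with boundary d_star (bp from the dyad) and steepness s, so a(d_star) is
# exactly 1/2. Occupancy at factor concentration c is
#   theta = theta0 + (1 - theta0) * c / (c + Kd / a(d)),
# with theta0 a non-specific (position- and motif-independent) bound
# fraction; motif-free controls sit at theta0.
#
# Under this model the expected relative shift of template N against a
# control reference is
#   E[RS] = -log2((1 - theta_N) / (1 - theta_ref)) = log2(1 + c * a(d)/Kd),
# independent of theta0.

#' Construct a positional binding model
#'
#' @param kd_high,kd_intermediate Dissociation constants (molar) of the
#'   high- and intermediate-affinity motifs on accessible DNA.
#' @param theta0 Non-specific bound fraction in `[0, 1)`.
#' @param d_star Inhibition boundary, bp from the dyad.
#' @param s Boundary steepness, bp.
#' @return A `binding_model` list.
#' @export
binding_model <- function(kd_high = 25e-9, kd_intermediate = 100e-9,
                          theta0 = 0.02, d_star = 50, s = 2) {
  if (kd_high <= 0 || kd_intermediate <= 0)
    stop("dissociation constants must be positive", call. = FALSE)
  if (theta0 < 0 || theta0 >= 1)
    stop("theta0 must be in [0, 1)", call. = FALSE)
  if (d_star < 0) stop("d_star must be >= 0", call. = FALSE)
  if (s <= 0) stop("s must be positive", call. = FALSE)
  structure(list(kd_high = kd_high, kd_intermediate = kd_intermediate,
                 theta0 = theta0, d_star = d_star, s = s),
            class = "binding_model")
}

#' Positional accessibility a(d)
#'
#' Logistic accessibility of a motif centered `d` bp from the dyad;
#' `a(d_star) = 1/2` exactly.
#'
#' @param d Distance from dyad (bp), vectorized.
#' @param d_star,s Boundary location and steepness (bp).
#' @return Accessibility in (0, 1).
#' @export
accessibility <- function(d, d_star, s) {
  1 / (1 + exp(-(d - d_star) / s))
}

#' Expected occupancy of a template at a factor concentration
#'
#' @param model A [binding_model()].
#' @param motif_kind `"high"`, `"intermediate"` or `"none"` (controls).
#' @param dyad_offset Motif-center distance from the dyad (bp); ignored for
#'   controls.
#' @param concentration Factor concentration, molar (>= 0).
#' @return Occupancy theta in `[0, 1]`.
#' @export
expected_occupancy <- function(model, motif_kind, dyad_offset,
                               concentration) {
  stopifnot(inherits(model, "binding_model"))
  if (any(concentration < 0))
    stop("concentration must be non-negative", call. = FALSE)
  if (motif_kind == "none") return(rep(model$theta0,
                                       length(concentration)))
  kd <- switch(motif_kind, high = model$kd_high,
               intermediate = model$kd_intermediate,
               stop("unknown motif_kind '", motif_kind, "'", call. = FALSE))
  a <- accessibility(dyad_offset, model$d_star, model$s)
  model$theta0 + (1 - model$theta0) *
    concentration / (concentration + kd / a)
}

#' Closed-form expected relative shift
#'
#' `E[RS] = log2(1 + c * a(d) / Kd)` for motif templates; 0 for controls.
#'
#' @inheritParams expected_occupancy
#' @return Expected relative shift (log2 units).
#' @export
expected_relative_shift <- function(model, motif_kind, dyad_offset,
                                    concentration) {
  stopifnot(inherits(model, "binding_model"))
  if (motif_kind == "none") return(rep(0, length(concentration)))
  kd <- switch(motif_kind, high = model$kd_high,
               intermediate = model$kd_intermediate)
  a <- accessibility(dyad_offset, model$d_star, model$s)
  log2(1 + concentration * a / kd)
}

#' Fit the positional binding model to observed relative shifts
#'
#' Least-squares fit of the closed-form expected relative shift to the
#' observed per-lane, per-template values. A coarse grid over the boundary
#' `d_star` (0..90 bp, 2-bp step), steepness `s` in \{1, 2, 4, 8\} bp and
#' log-spaced dissociation constants is refined by Nelder-Mead. For fixed
#' (d_star, s) the residual sum of squares separates by motif kind, so the
#' grid stage optimizes each Kd independently.
#'
#' @param shifts Data frame with columns `template`, `relative_shift` and
#'   `concentration` (molar); typically [shift_table()] joined with lane
#'   concentrations, replicate-averaged.
#' @param library The `nuc_library` the templates come from.
#' @param noise_floor Maximum absolute mean shift regarded as "no signal"
#'   (default 0.1 log2 units).
#' @return A list with `model` (the fitted [binding_model()]; theta0 is not
#'   identifiable from relative shifts and is reported as 0), `objective`
#'   (residual sum of squares) and `no_binding` flag. When no specific
#'   binding is detected the estimates are `NA` and `no_binding` is `TRUE`.
#' @export
fit_positional_model <- function(shifts, library, noise_floor = 0.1) {
  need <- c("template", "relative_shift", "concentration")
  if (!all(need %in% names(shifts)))
    stop("shifts must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (length(unique(shifts$concentration[shifts$concentration > 0])) < 2L)
    stop("need at least two lanes with nonzero protein", call. = FALSE)
  meta <- library[match(shifts$template, library$id), ]
  if (anyNA(meta$id))
    stop("shift table contains templates absent from the library",
         call. = FALSE)
  keep <- meta$motif_kind != "none"
  obs <- shifts$relative_shift
  if (max(abs(tapply(obs[keep], paste(meta$dyad_offset[keep],
                                      meta$motif_kind[keep]), mean))) <
      noise_floor) {
    return(list(model = NULL, objective = NA_real_, no_binding = TRUE))
  }
  d <- meta$dyad_offset[keep]
  kind <- meta$motif_kind[keep]
  conc <- shifts$concentration[keep]
  y <- obs[keep]
  # residual SS for one motif kind given accessibility and log10 Kd
  sse_kind <- function(a, cc, yy, lkd) {
    pred <- log2(1 + cc * a / 10^lkd)
    sum((yy - pred)^2)
  }
  lkd_grid <- seq(-10, -5.5, by = 0.25)
  d_grid <- seq(0, 90, by = 2)
  s_grid <- c(1, 2, 4, 8)
  best <- list(obj = Inf)
  for (dd in d_grid) for (ss in s_grid) {
    a <- accessibility(d, dd, ss)
    tot <- 0; lkds <- c(high = NA_real_, intermediate = NA_real_)
    for (kk in c("high", "intermediate")) {
      m <- kind == kk
      if (!any(m)) next
      v <- vapply(lkd_grid, function(l) sse_kind(a[m], conc[m], y[m], l),
                  numeric(1L))
      lkds[kk] <- lkd_grid[which.min(v)]
      tot <- tot + min(v)
    }
    if (tot < best$obj)
      best <- list(obj = tot, d_star = dd, s = ss, lkds = lkds)
  }
  # local refinement on (d_star, log s, log10 Kd_high, log10 Kd_int)
  par0 <- c(best$d_star, log(best$s),
            best$lkds["high"], best$lkds["intermediate"])
  par0[is.na(par0)] <- -8
  objfun <- function(p) {
    a <- accessibility(d, p[1L], exp(p[2L]))
    kd <- ifelse(kind == "high", 10^p[3L], 10^p[4L])
    if (p[1L] < 0 || p[1L] > 110) return(1e9)
    sum((y - log2(1 + conc * a / kd))^2)
  }
  fit <- stats::optim(par0, objfun, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  mdl <- binding_model(kd_high = unname(10^fit$par[3L]),
                       kd_intermediate = unname(10^fit$par[4L]),
                       theta0 = 0, d_star = unname(fit$par[1L]),
                       s = unname(exp(fit$par[2L])))
  list(model = mdl, objective = fit$value, no_binding = FALSE)
}
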