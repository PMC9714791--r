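## Synthetic-data generators with recorded ground truth for all three
## readouts: per-gene DE summary tables, behavioral feature matrices, and
## two-channel fluorescence images.  Fixed seeds give byte-identical
## output, so every downstream stage is testable offline.

#' Configuration for the DE-table generator
#'
#' @param n_genes number of genes per contrast.
#' @param frac_dysregulated fraction of genes with a true disease effect.
#' @param effect_mean,effect_sd mean and SD of the magnitude of true
#'   disease log2 fold changes (signs are random); defaults 0.6 / 0.25
#'   put typical effects a little above a 20% fold-change threshold,
#'   which is where a realistic bulk contrast concentrates.
#' @param se_low,se_high per-gene standard errors are drawn uniformly on
#'   this range (`se_low > 0`).
#' @param alpha_by_scenario named list mapping each lowering scenario to
#'   its true reversal multiplier: a scalar, a vector recycled over the
#'   dysregulated genes, or a `function(n)` drawing n multipliers.
#' @param seed integer RNG seed.
#' @return validated config (class `"de_sim_config"`).
#' @export
de_sim_config <- function(n_genes = 5000, frac_dysregulated = 0.2,
                          effect_mean = 0.6, effect_sd = 0.25,
                          se_low = 0.05, se_high = 0.25,
                          alpha_by_scenario = list(early = -1,
                                                   late = -0.2,
                                                   none = 0),
                          seed = 1L) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (frac_dysregulated < 0 || frac_dysregulated > 1)
    stop("frac_dysregulated must lie in [0, 1]")
  if (se_low <= 0 || se_high < se_low) stop("need 0 < se_low <= se_high")
  if (length(alpha_by_scenario) == 0L || is.null(names(alpha_by_scenario)))
    stop("alpha_by_scenario must be a nonempty named list")
  structure(list(n_genes = as.integer(n_genes),
                 frac_dysregulated = frac_dysregulated,
                 effect_mean = effect_mean, effect_sd = effect_sd,
                 se_low = se_low, se_high = se_high,
                 alpha_by_scenario = alpha_by_scenario,
                 seed = as.integer(seed)),
            class = "de_sim_config")
}

#' Simulate disease and treatment DE summary tables with known truth
#'
#' Dysregulated genes receive a true disease effect whose magnitude is
#' drawn from `N(effect_mean, effect_sd)` (folded at zero) with a random
#' sign; other genes have true effect 0.  Observed log2 fold changes are
#' the truth plus normal noise at a per-gene SE drawn uniformly on
#' `[se_low, se_high]`; p-values are two-sided normal tail probabilities
#' of estimate/SE.  For each scenario the treatment contrast is the
#' lowered group versus the *disease* group, so a multiplier of −1 means
#' exact return to control; its observed effect is centred on
#' `alpha * delta`.
#'
#' @param cfg a [de_sim_config()].
#' @return list: `disease` (data frame `gene_id`, `log2fc`, `lfc_se`,
#'   `pvalue`), `scenarios` (named list of such data frames), `truth`
#'   (data frame `gene_id`, `dysregulated`, `true_delta`, one
#'   `alpha_<scenario>` column per scenario).  The treatment-contrast
#'   convention is recorded in `attr(, "contrast")`.
#' @export
simulate_de_tables <- function(cfg) {
  stopifnot(inherits(cfg, "de_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  ids <- sprintf("gene_%05d", seq_len(n))
  n_dys <- round(cfg$frac_dysregulated * n)
  dys <- sort(sample.int(n, n_dys))
  delta <- numeric(n)
  if (n_dys > 0) {
    mag <- abs(stats::rnorm(n_dys, cfg$effect_mean, cfg$effect_sd))
    delta[dys] <- mag * sample(c(-1, 1), n_dys, replace = TRUE)
  }
  make_table <- function(true_effect) {
    se <- stats::runif(n, cfg$se_low, cfg$se_high)
    est <- true_effect + stats::rnorm(n, 0, se)
    data.frame(gene_id = ids, log2fc = est, lfc_se = se,
               pvalue = 2 * stats::pnorm(-abs(est / se)))
  }
  disease <- make_table(delta)
  truth <- data.frame(gene_id = ids,
                      dysregulated = seq_len(n) %in% dys,
                      true_delta = delta)
  scenarios <- list()
  for (nm in names(cfg$alpha_by_scenario)) {
    spec <- cfg$alpha_by_scenario[[nm]]
    alpha <- numeric(n)
    a_dys <- if (is.function(spec)) spec(n_dys) else rep_len(spec, n_dys)
    alpha[dys] <- a_dys
    scenarios[[nm]] <- make_table(alpha * delta)
    truth[[paste0("alpha_", nm)]] <- alpha
  }
  out <- list(disease = disease, scenarios = scenarios, truth = truth)
  attr(out, "contrast") <-
    "treatment = lowered vs disease group; alpha = -1 is exact return to control"
  out
}

#' Configuration for the behavioral-feature generator
#'
#' @param groups named integer vector: subjects per group (each >= 3).
#' @param n_features feature count.
#' @param mean_shift named list (one entry per group) of standardized
#'   mean offsets — a scalar or a length-`n_features` vector.  Missing
#'   groups default to zero offset.
#' @param feature_correlation common pairwise correlation in `[0, 1)`
#'   of the equicorrelated covariance shared by every group.
#' @param seed integer RNG seed.
#' @return validated config (class `"behavior_sim_config"`).
#' @export
behavior_sim_config <- function(groups = c(control = 30, disease = 30),
                                n_features = 20,
                                mean_shift = list(),
                                feature_correlation = 0.3,
                                seed = 1L) {
  if (length(groups) < 2L || is.null(names(groups)))
    stop("groups must be a named vector of at least two groups")
  if (any(groups < 3)) stop("every group needs >= 3 subjects")
  if (feature_correlation < 0 || feature_correlation >= 1)
    stop("feature_correlation must lie in [0, 1)")
  bad <- setdiff(names(mean_shift), names(groups))
  if (length(bad)) stop("mean_shift for unknown group(s): ",
                        paste(bad, collapse = ", "))
  structure(list(groups = groups, n_features = as.integer(n_features),
                 mean_shift = mean_shift,
                 feature_correlation = feature_correlation,
                 seed = as.integer(seed)),
            class = "behavior_sim_config")
}

#' Simulate a behavioral feature matrix
#'
#' Each group's subjects are drawn from a multivariate normal with the
#' group's configured mean offset and a shared equicorrelated covariance
#' (unit variances, common correlation).  A stand-in for proprietary
#' high-content behavioral platforms: an explicit Gaussian model, not a
#' claim about real feature distributions.
#'
#' @param cfg a [behavior_sim_config()].
#' @return list: `values` (subjects x features matrix), `groups`
#'   (factor), `feature_names`.
#' @export
simulate_behavior <- function(cfg) {
  stopifnot(inherits(cfg, "behavior_sim_config"))
  set.seed(cfg$seed)
  p <- cfg$n_features
  rho <- cfg$feature_correlation
  sigma <- matrix(rho, p, p); diag(sigma) <- 1
  R <- tryCatch(chol(sigma),
                error = function(e) stop("covariance is not positive definite"))
  rows <- list(); labels <- character(0)
  for (g in names(cfg$groups)) {
    ng <- cfg$groups[[g]]
    mu <- rep(0, p)
    if (!is.null(cfg$mean_shift[[g]])) mu <- mu + rep_len(cfg$mean_shift[[g]], p)
    z <- matrix(stats::rnorm(ng * p), ng, p) %*% R
    rows[[g]] <- sweep(z, 2L, mu, "+")
    labels <- c(labels, rep(g, ng))
  }
  values <- do.call(rbind, rows)
  fn <- sprintf("feature_%02d", seq_len(p))
  colnames(values) <- fn
  rownames(values) <- NULL
  list(values = values, groups = factor(labels, levels = names(cfg$groups)),
       feature_names = fn)
}

#' Configuration for the two-channel image generator
#'
#' @param image_shape image size in pixels, `c(rows, cols)`.
#' @param pixel_size_um physical pixel size (default 0.32 um).
#' @param n_nuclei nuclei to place.
#' @param nucleus_radius_px mean nucleus radius; default 14 px gives an
#'   area of about 600 px, comfortably above a 200-px floor.
#' @param radius_jitter fractional radius jitter per nucleus.
#' @param nuclear_spot_rate expected spots per nucleus (Poisson).
#' @param extranuclear_spot_rate expected spots per mm^2 of
#'   non-nuclear area (Poisson).
#' @param spot_sigma_px Gaussian spot SD in px; the default equals the
#'   3-px texture scale of the segmentation recipe, the spot size the
#'   scripted filters are tuned to.
#' @param spot_amplitude spot peak amplitude above background (on the
#'   `[0, 1]` scale); with the default `noise_sd` 0.01 this is SNR 50.
#' @param nuclear_intensity DAPI amplitude of a nucleus.
#' @param background_level constant baseline in both channels.
#' @param noise_sd Gaussian read-noise SD.
#' @param photon_gain counts per intensity unit for the Poisson shot
#'   noise component.
#' @param seed integer RNG seed.
#' @return validated config (class `"image_sim_config"`).
#' @export
image_sim_config <- function(image_shape = c(256L, 256L),
                             pixel_size_um = 0.32,
                             n_nuclei = 12L,
                             nucleus_radius_px = 14,
                             radius_jitter = 0.1,
                             nuclear_spot_rate = 1,
                             extranuclear_spot_rate = 2000,
                             spot_sigma_px = 3,
                             spot_amplitude = 0.5,
                             nuclear_intensity = 0.45,
                             background_level = 0.05,
                             noise_sd = 0.01,
                             photon_gain = 2000,
                             seed = 1L) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (nuclear_spot_rate < 0 || extranuclear_spot_rate < 0)
    stop("spot rates must be >= 0")
  if (length(image_shape) != 2L || any(image_shape < 16))
    stop("image_shape must be two dimensions of at least 16 px")
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size_um = pixel_size_um,
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius_px = nucleus_radius_px,
                 radius_jitter = radius_jitter,
                 nuclear_spot_rate = nuclear_spot_rate,
                 extranuclear_spot_rate = extranuclear_spot_rate,
                 spot_sigma_px = spot_sigma_px,
                 spot_amplitude = spot_amplitude,
                 nuclear_intensity = nuclear_intensity,
                 background_level = background_level,
                 noise_sd = noise_sd, photon_gain = photon_gain,
                 seed = as.integer(seed)),
            class = "image_sim_config")
}

#' Simulate a two-channel image with nucleus and spot ground truth
#'
#' Nuclei are rendered as non-overlapping soft-edged disks on the DAPI
#' channel; spots as isotropic Gaussian peaks on the spot channel, at
#' recorded truth coordinates with a minimum mutual spacing of
#' `6 * spot_sigma_px` px so truth matching is unambiguous.  A spot
#' is flagged nuclear iff its centre lies inside a nucleus.  Both
#' channels receive Poisson shot noise (at `photon_gain`) plus Gaussian
#' read noise and are clipped to `[0, 1]`.
#'
#' @param cfg an [image_sim_config()].
#' @return list: `dapi` and `spot_channel` (matrices in `[0, 1]`),
#'   `nuclei_mask` (integer label matrix), `spot_truth` (data frame
#'   `row`, `col`, `amplitude`, `sigma_px`, `is_nuclear`).
#' @export
simulate_images <- function(cfg) {
  stopifnot(inherits(cfg, "image_sim_config"))
  set.seed(cfg$seed)
  nr <- cfg$image_shape[1L]; nc <- cfg$image_shape[2L]
  rmax <- cfg$nucleus_radius_px * (1 + cfg$radius_jitter)
  margin <- ceiling(rmax) + 2L
  if (2 * margin >= min(nr, nc))
    stop("image too small for the configured nuclei")

  ## --- place non-overlapping nuclei by bounded rejection sampling
  centres <- matrix(numeric(0), 0L, 2L)
  radii <- numeric(0)
  for (i in seq_len(cfg$n_nuclei)) {
    placed <- FALSE
    for (try in seq_len(500L)) {
      ctr <- c(stats::runif(1, margin, nr - margin),
               stats::runif(1, margin, nc - margin))
      rad <- cfg$nucleus_radius_px *
        (1 + stats::runif(1, -cfg$radius_jitter, cfg$radius_jitter))
      if (nrow(centres) == 0L ||
          all(sqrt(rowSums(sweep(centres, 2L, ctr)^2)) > radii + rad + 6)) {
        centres <- rbind(centres, ctr); radii <- c(radii, rad)
        placed <- TRUE; break
      }
    }
    if (!placed)
      stop("could not place ", cfg$n_nuclei,
           " non-overlapping nuclei; enlarge the image")
  }

  rowg <- matrix(seq_len(nr), nr, nc)
  colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dapi <- matrix(cfg$background_level, nr, nc)
  mask <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(centres))) {
    d <- sqrt((rowg - centres[i, 1L])^2 + (colg - centres[i, 2L])^2)
    dapi <- dapi + cfg$nuclear_intensity * stats::plogis((radii[i] - d) / 1.0)
    mask[d <= radii[i]] <- i
  }

  ## --- spot truth: nuclear (per nucleus) + extranuclear (per mm^2)
  min_sep <- 6 * cfg$spot_sigma_px
  truth <- data.frame(row = numeric(), col = numeric(),
                      amplitude = numeric(), sigma_px = numeric(),
                      is_nuclear = logical())
  ok_spot <- function(pt) nrow(truth) == 0L ||
    all(sqrt((truth$row - pt[1L])^2 + (truth$col - pt[2L])^2) >= min_sep)
  add_spot <- function(pt, nuclear) {
    truth[nrow(truth) + 1L, ] <<- list(pt[1L], pt[2L], cfg$spot_amplitude,
                                       cfg$spot_sigma_px, nuclear)
  }
  for (i in seq_len(nrow(centres))) {
    n_sp <- stats::rpois(1L, cfg$nuclear_spot_rate)
    for (s in seq_len(n_sp)) {
      for (try in seq_len(200L)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rr <- radii[i] * 0.7 * sqrt(stats::runif(1))
        pt <- centres[i, ] + rr * c(cos(ang), sin(ang))
        if (ok_spot(pt)) { add_spot(pt, TRUE); break }
      }
    }
  }
  ext_area_mm2 <- sum(mask == 0L) * (cfg$pixel_size_um * 1e-3)^2
  n_ext <- stats::rpois(1L, cfg$extranuclear_spot_rate * ext_area_mm2)
  for (s in seq_len(n_ext)) {
    for (try in seq_len(200L)) {
      pt <- c(stats::runif(1, margin, nr - margin),
              stats::runif(1, margin, nc - margin))
      if (mask[round(pt[1L]), round(pt[2L])] == 0L && ok_spot(pt)) {
        add_spot(pt, FALSE); break
      }
    }
  }

  ## --- render spot channel
  spot_img <- matrix(cfg$background_level, nr, nc)
  half <- ceiling(4 * cfg$spot_sigma_px)
  for (s in seq_len(nrow(truth))) {
    r0 <- max(1L, floor(truth$row[s]) - half)
    r1 <- min(nr, ceiling(truth$row[s]) + half)
    c0 <- max(1L, floor(truth$col[s]) - half)
    c1 <- min(nc, ceiling(truth$col[s]) + half)
    rs <- r0:r1; cs <- c0:c1
    d2 <- outer((rs - truth$row[s])^2, (cs - truth$col[s])^2, "+")
    spot_img[rs, cs] <- spot_img[rs, cs] +
      truth$amplitude[s] * exp(-d2 / (2 * truth$sigma_px[s]^2))
  }

  noisy <- function(clean) {
    shot <- stats::rpois(length(clean), pmax(clean, 0) * cfg$photon_gain) /
      cfg$photon_gain
    img <- matrix(shot, nr, nc) +
      matrix(stats::rnorm(length(clean), 0, cfg$noise_sd), nr, nc)
    pmin(pmax(img, 0), 1)
  }
  list(dapi = noisy(dapi), spot_channel = noisy(spot_img),
       nuclei_mask = mask, spot_truth = truth)
}
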