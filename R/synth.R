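# Synthetic study generator: clinical covariates with calibrated marginals,
# a logistic outcome model on the multivariate-significant variables, and
# ellipsoidal nodule / ablation-zone CT phantoms whose ablation-zone texture
# differs by outcome class when a signal preset is active.

# Cohort marginals (counts out of 479 lesions / mean+-sd) used as sampling
# distributions. Continuous tumour markers are truncated-normal at zero with
# the *underlying* mean calibrated so the truncated mean matches the target.
default_marginals <- function() {
  list(
    gender          = c(male = 269, female = 210),
    age             = c(mean = 57.9, sd = 10.3),
    cea             = c(mean = 4.6, sd = 4.1),
    ca19_9          = c(mean = 10.8, sd = 6.2),
    nodule_size_cat = c("<10" = 227, "10-19" = 178, "20-30" = 74),
    location        = c(RUL = 112, RML = 52, RLL = 88, LUL = 108, LLL = 119),
    distance1       = c(">1cm" = 399, "<1cm" = 80),
    distance2       = c(">1cm" = 192, "<1cm" = 287),
    pneumothorax    = c(yes = 115, no = 364),
    iah             = c(yes = 124, no = 355)
  )
}

# Texture presets: correlation length (mm) of the ablation-zone texture per
# class and the hyperdense-remnant parameters planted in non-CR lesions.
# Frozen after a one-off calibration simulation; the signal knob is the
# non-CR correlation length plus the remnant.
texture_presets <- function() {
  list(
    none   = list(corr_cr = 1.5, corr_noncr = 1.5, remnant_contrast = 0,   remnant_frac = 0),
    weak   = list(corr_cr = 1.3, corr_noncr = 1.7, remnant_contrast = 40,  remnant_frac = 0.25),
    strong = list(corr_cr = 1.0, corr_noncr = 3.0, remnant_contrast = 120, remnant_frac = 0.40)
  )
}

#' Configuration of the synthetic study generator
#'
#' Defaults emulate the published cohort: 479 lesions, covariate marginals
#' from the cohort characteristics table, outcome log-odds equal to the
#' natural logs of the multivariate odds ratios (CA19-9 per U/ml and the
#' lower-lobe locations, non-CR as the event), intercept calibrated so the
#' marginal non-CR prevalence is 100/479, and anisotropic voxel spacing
#' (0.7 x 0.7 x 1.25 mm) to force resampling.
#'
#' @param n_lesions number of lesions (>= 10).
#' @param seed master seed for all generator randomness.
#' @param covariate_marginals named list of per-variable parameters
#'   (counts for categoricals, `c(mean=, sd=)` for continuous).
#' @param log_odds named coefficients of the outcome model; names are either
#'   a continuous column (`ca19_9`) or `<column><level>` for a categorical
#'   level (`locationRLL`).
#' @param effect_scale multiplier applied to `log_odds` (0 gives a pure-noise
#'   outcome); the intercept is recalibrated for the scaled model.
#' @param target_prevalence marginal non-CR probability the intercept is
#'   calibrated to.
#' @param image_shape voxels per axis (length 1 or 3, each >= 32).
#' @param spacing_mm voxel size in mm per axis.
#' @param texture_signal `"none"`, `"weak"` or `"strong"` class-texture preset.
#' @return a `generator_config` list, with the calibrated truncated-normal
#'   parameters and intercept attached.
#' @export
generator_config <- function(n_lesions = 479, seed = 17,
                             covariate_marginals = default_marginals(),
                             log_odds = c(ca19_9 = log(1.007),
                                          locationRLL = log(2.997),
                                          locationLLL = log(2.498)),
                             effect_scale = 1,
                             target_prevalence = 100 / 479,
                             image_shape = c(64, 64, 64),
                             spacing_mm = c(0.7, 0.7, 1.25),
                             texture_signal = c("strong", "weak", "none")) {
  texture_signal <- match.arg(texture_signal)
  if (!is_count(n_lesions) || n_lesions < 10) stopf("n_lesions must be a count >= 10")
  if (length(image_shape) == 1L) image_shape <- rep(image_shape, 3)
  if (any(image_shape < 32)) stopf("image_shape must be >= 32 per axis")
  if (any(spacing_mm <= 0)) stopf("spacing_mm must be strictly positive")
  m <- covariate_marginals
  for (v in c("cea", "ca19_9")) {
    if (m[[v]]["sd"] < 0) stopf("invalid marginal sd for %s", v)
    m[[v]]["mu0"] <- calibrate_truncnorm_mu(m[[v]]["mean"], m[[v]]["sd"])
  }
  cfg <- structure(list(
    n_lesions = as.integer(n_lesions), seed = as.integer(seed),
    covariate_marginals = m, log_odds = log_odds,
    effect_scale = effect_scale, target_prevalence = target_prevalence,
    image_shape = as.integer(image_shape), spacing_mm = as.numeric(spacing_mm),
    texture_signal = texture_signal,
    preset = texture_presets()[[texture_signal]]
  ), class = "generator_config")
  cfg$intercept <- calibrate_intercept(cfg)
  cfg
}

# underlying normal mean whose zero-truncated mean equals `target`
calibrate_truncnorm_mu <- function(target, sd) {
  if (sd == 0) return(unname(target))
  f <- function(mu) {
    a <- -mu / sd
    mu + sd * dnorm(a) / (1 - pnorm(a)) - target
  }
  uniroot(f, c(target - 6 * sd, target + sd), tol = 1e-10)$root
}

rtrunc0 <- function(n, mu0, sd) {
  if (sd == 0) return(rep(mu0, n))
  a <- pnorm(-mu0 / sd)
  mu0 + sd * qnorm(runif(n, a, 1))
}

#' Sample clinical records from the configured marginals
#'
#' Covariates are drawn independently: age normal, CEA and CA19-9
#' truncated-normal at zero (calibrated so the truncated mean matches the
#' configured target), categoricals from the configured frequencies. Uses the
#' current RNG state; seed externally for reproducibility.
#'
#' @param config a [generator_config()].
#' @param n number of records.
#' @return data.frame with one row per record.
#' @export
sample_clinical <- function(config, n = 1) {
  stopifnot(inherits(config, "generator_config"))
  m <- config$covariate_marginals
  scat <- function(tab) {
    if (any(tab < 0) || sum(tab) <= 0) stopf("invalid categorical marginal")
    factor(sample(names(tab), n, replace = TRUE, prob = tab / sum(tab)),
           levels = names(tab))
  }
  if (m$age["sd"] < 0) stopf("invalid marginal sd for age")
  data.frame(
    gender = scat(m$gender),
    age = rnorm(n, m$age["mean"], m$age["sd"]),
    cea = rtrunc0(n, m$cea["mu0"], m$cea["sd"]),
    ca19_9 = rtrunc0(n, m$ca19_9["mu0"], m$ca19_9["sd"]),
    nodule_size_cat = scat(m$nodule_size_cat),
    location = scat(m$location),
    distance1 = scat(m$distance1),
    distance2 = scat(m$distance2),
    pneumothorax = scat(m$pneumothorax),
    iah = scat(m$iah)
  )
}

# raw (unscaled) linear predictor of the outcome model for each record
outcome_linpred <- function(records, log_odds) {
  eta <- numeric(nrow(records))
  for (nm in names(log_odds)) {
    if (nm %in% names(records) && is.numeric(records[[nm]])) {
      eta <- eta + log_odds[[nm]] * records[[nm]]
    } else {
      hit <- FALSE
      for (col in names(records)) {
        if (is.factor(records[[col]]) && startsWith(nm, col)) {
          lev <- substring(nm, nchar(col) + 1)
          if (lev %in% levels(records[[col]])) {
            eta <- eta + log_odds[[nm]] * (records[[col]] == lev)
            hit <- TRUE
            break
          }
        }
      }
      if (!hit) stopf("log_odds name '%s' matches no covariate or level", nm)
    }
  }
  eta
}

# intercept such that the marginal non-CR prevalence hits the target, by
# bisection over a fixed deterministic Monte-Carlo draw of covariates
calibrate_intercept <- function(config, n_mc = 50000) {
  eta <- withr::with_seed(987654321, {
    rec <- sample_clinical(config, n_mc)
    config$effect_scale * outcome_linpred(rec, config$log_odds)
  })
  p <- config$target_prevalence
  if (config$effect_scale == 0 || all(eta == 0)) return(qlogis(p))
  uniroot(function(b0) mean(plogis(b0 + eta)) - p,
          c(qlogis(p) - 20, qlogis(p) + 20), tol = 1e-9)$root
}

#' Sample outcome labels for clinical records
#'
#' `P(nonCR) = logistic(intercept + effect_scale * sum(log_odds * covariates))`.
#'
#' @param records data.frame from [sample_clinical()].
#' @param config a [generator_config()].
#' @return factor with levels `CR`, `nonCR`.
#' @export
sample_outcome <- function(records, config) {
  stopifnot(inherits(config, "generator_config"))
  p <- plogis(config$intercept +
                config$effect_scale * outcome_linpred(records, config$log_odds))
  factor(ifelse(rbinom(nrow(records), 1, p) == 1, "nonCR", "CR"),
         levels = c("CR", "nonCR"))
}

# separable Gaussian smoothing with edge replication; sigma in voxels per axis
gauss_smooth3d <- function(a, sigma_vox) {
  d <- dim(a)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0.05) next
    h <- ceiling(3 * s)
    w <- dnorm(-h:h, sd = s)
    w <- w / sum(w)
    a <- array(.smooth_axis_cpp(as.numeric(a), d, axis - 1L, w), d)
  }
  a
}

# correlated Gaussian texture field with unit marginal sd
texture_field <- function(dims, corr_mm, spacing) {
  f <- gauss_smooth3d(array(rnorm(prod(dims)), dims), corr_mm / spacing)
  s <- sd(f)
  if (s == 0) return(f)
  f / s
}

nodule_diameter_mm <- function(size_cat) {
  switch(as.character(size_cat),
         "<10" = runif(1, 5, 9),
         "10-19" = runif(1, 10, 19),
         "20-30" = runif(1, 20, 30),
         stopf("unknown nodule size category '%s'", size_cat))
}

soft_inside <- function(r, width = 0.06) plogis(-(r - 1) / width)

#' Generate one pre/post phantom image pair
#'
#' Pre-ablation: an ellipsoidal soft-tissue nodule (diameter set by the
#' nodule size category) over an aerated-lung background near -800 HU, with
#' correlated Gaussian texture. Post-ablation: a concentric, larger ablation
#' zone whose periphery carries a ground-glass-like rim; for non-CR lesions
#' under an active texture preset, the zone texture has a longer correlation
#' length and an off-centre hyperdense remnant. Uses the current RNG state.
#'
#' @param record one-row clinical data.frame.
#' @param label `"CR"` or `"nonCR"`.
#' @param config a [generator_config()].
#' @return list with `pre_volume`, `pre_mask`, `post_volume`, `post_mask`
#'   ([volume3d()] each).
#' @export
generate_phantom_pair <- function(record, label, config) {
  label <- as.character(label)
  dims <- config$image_shape
  sp <- config$spacing_mm
  extent <- dims * sp
  preset <- config$preset

  d_nod <- nodule_diameter_mm(record$nodule_size_cat)
  margin <- runif(1, 5, 7)
  d_zone <- d_nod + 2 * margin
  if (d_zone > min(extent) - 2)
    stopf("nodule (%.1f mm zone) larger than grid (%.1f mm)", d_zone, min(extent))

  ctr <- extent / 2 + runif(3, -1.5, 1.5)
  semi_nod <- d_nod / 2 * sample(c(1, runif(1, 0.7, 1), runif(1, 0.7, 1)))
  semi_zone <- pmin(d_zone / 2 * runif(3, 0.92, 1), extent / 2 - 1)
  # keep the zone inside the grid
  ctr <- pmin(pmax(ctr, semi_zone + 0.5), extent - semi_zone - 0.5)

  # the structured part lives in the zone bounding box (+4 mm); the
  # correlated texture fields are only generated there
  lo <- pmax(1L, as.integer(floor((ctr - semi_zone - 4) / sp)) + 1L)
  hi <- pmin(dims, as.integer(ceiling((ctr + semi_zone + 4) / sp)) + 1L)
  bdims <- hi - lo + 1L
  baxes <- lapply(1:3, function(k) (seq.int(lo[k], hi[k]) - 1) * sp[k])
  rdist <- function(centre, semi) {
    ex <- ((baxes[[1]] - centre[1]) / semi[1])^2
    ey <- ((baxes[[2]] - centre[2]) / semi[2])^2
    ez <- ((baxes[[3]] - centre[3]) / semi[3])^2
    sqrt(outer(outer(ex, ey, "+"), ez, "+"))
  }
  r_nod <- rdist(ctr, semi_nod)
  r_zone <- rdist(ctr, semi_zone)
  bx <- lo[1]:hi[1]; by <- lo[2]:hi[2]; bz <- lo[3]:hi[3]

  background <- function() -800 + 45 * texture_field(dims, 1.0, sp)

  # pre-ablation: solid nodule, class-independent texture
  w_nod <- soft_inside(r_nod)
  nodule_hu <- 20 + 60 * texture_field(bdims, 1.2, sp)
  pre <- background()
  pre[bx, by, bz] <- pre[bx, by, bz] * (1 - w_nod) + nodule_hu * w_nod

  # post-ablation: necrotic core shading into a GGO rim; class-dependent
  # correlation length and remnant only when a signal preset is active
  corr <- if (identical(label, "nonCR")) preset$corr_noncr else preset$corr_cr
  w_zone <- soft_inside(r_zone)
  rimw <- pmin(pmax((r_zone - 0.70) / 0.25, 0), 1)
  zone_hu <- (-250 - 200 * rimw) + 60 * texture_field(bdims, corr, sp)
  if (identical(label, "nonCR") && preset$remnant_contrast > 0) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    rc <- ctr + u * 0.4 * semi_zone
    rr <- preset$remnant_frac * d_nod / 2
    r_rem <- rdist(rc, rep(rr, 3))
    zone_hu <- zone_hu + preset$remnant_contrast * soft_inside(r_rem, 0.15)
  }
  post <- background()
  post[bx, by, bz] <- post[bx, by, bz] * (1 - w_zone) + zone_hu * w_zone

  pre_mask <- array(0, dims)
  pre_mask[bx, by, bz] <- as.numeric(r_nod <= 1)
  post_mask <- array(0, dims)
  post_mask[bx, by, bz] <- as.numeric(r_zone <= 1)
  list(
    pre_volume = volume3d(pre, sp),
    pre_mask = volume3d(pre_mask, sp),
    post_volume = volume3d(post, sp),
    post_mask = volume3d(post_mask, sp)
  )
}

#' Generate a full synthetic cohort
#'
#' Clinical covariates, outcome labels, and (optionally) phantom image pairs
#' for `n_lesions` lesions, all reproducible from `config$seed`.
#'
#' @param config a [generator_config()].
#' @param images generate phantom volumes (set `FALSE` for clinical-only
#'   simulations, which is much faster).
#' @return an `rfa_cohort`: list with `clinical` (data.frame incl. `lesion_id`,
#'   `patient_id`, `label`), `cases` (list of `lesion_case`, `NULL` without
#'   images), `config`, and `manifest`.
#' @export
generate_cohort <- function(config, images = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_lesions
  clinical <- withr::with_seed(derive_seed(config$seed, "clinical"),
                               sample_clinical(config, n))
  label <- withr::with_seed(derive_seed(config$seed, "outcome"),
                            sample_outcome(clinical, config))
  clinical <- cbind(lesion_id = sprintf("L%04d", seq_len(n)),
                    patient_id = sprintf("P%04d", seq_len(n)),
                    clinical, label = label)
  cases <- NULL
  if (images) {
    cases <- lapply(seq_len(n), function(i) {
      imgs <- withr::with_seed(derive_seed(config$seed, "phantom", i),
                               generate_phantom_pair(clinical[i, ], label[i], config))
      structure(c(list(lesion_id = clinical$lesion_id[i],
                       patient_id = clinical$patient_id[i],
                       clinical = clinical[i, ], label = label[i]),
                  imgs),
                class = "lesion_case")
    })
  }
  manifest <- cbind(clinical,
                    seed = config$seed,
                    config_hash = config_hash(unclass(config)))
  structure(list(clinical = clinical, cases = cases, config = config,
                 manifest = manifest),
            class = "rfa_cohort")
}

#' @export
print.rfa_cohort <- function(x, ...) {
  cat(sprintf("<rfa_cohort> %d lesions (%d non-CR), images: %s, seed %d\n",
              nrow(x$clinical), sum(x$clinical$label == "nonCR"),
              if (is.null(x$cases)) "no" else "yes", x$config$seed))
  invisible(x)
}
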