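# Fully synthetic stand-in cohort: phantom subtraction-MRI volumes containing
# one ellipsoidal lesion each, filled with a class-dependent stationary
# Gaussian-random-field texture (plus an optional rim-enhancement ridge), and
# per-subject covariates drawn at the published prevalences.  Nothing here
# attempts physical MRI realism; the generator plants just enough structure
# (mean contrast, correlation length, rim) for the pipeline to have a
# recoverable signal, and can be collapsed to an exact null.

#' Synthetic cohort configuration
#'
#' Defaults state the emulated cohort: 16 carriers vs 25 controls; TNBC
#' prevalence 0.80 vs 0.14; bilateral cancer 0.441 vs 0.172; age at onset
#' 36.8 +/- 7 vs 38 +/- 11 years; voxels 3.7 x 0.75 x 0.75 mm.  Per-class
#' texture parameters are vectors \code{c(carrier, control)}.
#'
#' @param n_carriers,n_controls subject counts (defaults 16 / 25)
#' @param shape volume shape (slice, row, col) in voxels
#' @param spacing voxel size (slice, row, col) in mm
#' @param semi_axes_inplane_mm,semi_axes_slice_mm lesion ellipsoid semi-axis
#'   ranges in mm
#' @param contrast mean lesion contrast per class (arbitrary units above a
#'   zero-mean noise background)
#' @param corr_length_mm in-plane Gaussian-random-field correlation length
#'   per class, mm
#' @param texture_sd random-field SD per class
#' @param rim_amplitude,rim_width_mm rim-enhancement ridge per class
#' @param noise_sd background (and intra-lesion additive) noise SD
#' @param tnbc_prev,bbc_prev,mbc_prev Bernoulli prevalences per class
#' @param age_mean,age_sd age distribution per class (years, truncated to
#'   18--90)
#' @param fdr_bc_rate,fdr_oc_rate,sdr_bc_rate,sdr_oc_rate,tdr_bc_rate,tdr_oc_rate
#'   Poisson rates per class for affected-relative counts
#' @param bilateral_two_volumes if TRUE (default), subjects with BBC = 1 get
#'   two volumes, exercising multi-image aggregation
#' @param patch_margin in-plane margin (voxels) kept between the lesion and
#'   the volume edge so that default 65x65 patches never cross the boundary
#' @param rng_seed master seed
#' @return object of class \code{synthetic_cohort_config}
#' @export
synthetic_cohort_config <- function(
    n_carriers = 16L, n_controls = 25L,
    shape = c(12L, 128L, 128L), spacing = c(3.7, 0.75, 0.75),
    semi_axes_inplane_mm = c(6, 12), semi_axes_slice_mm = c(4, 8),
    contrast = c(1.0, 0.6), corr_length_mm = c(2.25, 0.75),
    texture_sd = c(0.2, 0.2), rim_amplitude = c(0.5, 0.1),
    rim_width_mm = c(1.5, 1.5), noise_sd = 0.05,
    tnbc_prev = c(0.80, 0.14), bbc_prev = c(0.441, 0.172),
    mbc_prev = c(0.05, 0.01),
    age_mean = c(36.8, 38), age_sd = c(7, 11),
    fdr_bc_rate = c(1.0, 0.5), fdr_oc_rate = c(0.3, 0.1),
    sdr_bc_rate = c(0.8, 0.5), sdr_oc_rate = c(0.2, 0.1),
    tdr_bc_rate = c(0.5, 0.4), tdr_oc_rate = c(0.1, 0.05),
    bilateral_two_volumes = TRUE, patch_margin = 33L, rng_seed = 1L) {
  cfg <- list(n_carriers = as.integer(n_carriers),
              n_controls = as.integer(n_controls),
              shape = as.integer(shape), spacing = as.numeric(spacing),
              semi_axes_inplane_mm = semi_axes_inplane_mm,
              semi_axes_slice_mm = semi_axes_slice_mm,
              contrast = contrast, corr_length_mm = corr_length_mm,
              texture_sd = texture_sd, rim_amplitude = rim_amplitude,
              rim_width_mm = rim_width_mm, noise_sd = noise_sd,
              tnbc_prev = tnbc_prev, bbc_prev = bbc_prev, mbc_prev = mbc_prev,
              age_mean = age_mean, age_sd = age_sd,
              fdr_bc_rate = fdr_bc_rate, fdr_oc_rate = fdr_oc_rate,
              sdr_bc_rate = sdr_bc_rate, sdr_oc_rate = sdr_oc_rate,
              tdr_bc_rate = tdr_bc_rate, tdr_oc_rate = tdr_oc_rate,
              bilateral_two_volumes = isTRUE(bilateral_two_volumes),
              patch_margin = as.integer(patch_margin),
              rng_seed = as.integer(rng_seed))
  if (cfg$n_carriers < 1L || cfg$n_controls < 1L) stop("subject counts must be >= 1")
  if (length(cfg$shape) != 3L || any(cfg$shape < 1L)) stop("invalid `shape`")
  if (any(cfg$spacing <= 0)) stop("spacing components must be > 0")
  for (f in c("tnbc_prev", "bbc_prev", "mbc_prev"))
    if (any(cfg[[f]] < 0 | cfg[[f]] > 1)) stop("`", f, "` must lie in [0, 1]")
  if (any(cfg$corr_length_mm <= 0)) stop("correlation lengths must be > 0")
  structure(cfg, class = "synthetic_cohort_config")
}

#' Null-cohort configuration: zero planted effect
#'
#' Both classes share the control texture and covariate parameters (the
#' permutation-equivalent null used for calibration checks).
#'
#' @param ... overrides forwarded to \code{\link{synthetic_cohort_config}}
#' @return a \code{synthetic_cohort_config}
#' @export
null_cohort_config <- function(...) {
  synthetic_cohort_config(
    contrast = c(0.6, 0.6), corr_length_mm = c(0.75, 0.75),
    texture_sd = c(0.2, 0.2), rim_amplitude = c(0.1, 0.1),
    tnbc_prev = c(0.14, 0.14), bbc_prev = c(0.172, 0.172),
    mbc_prev = c(0.01, 0.01), age_mean = c(38, 38), age_sd = c(11, 11),
    fdr_bc_rate = c(0.5, 0.5), fdr_oc_rate = c(0.1, 0.1),
    sdr_bc_rate = c(0.5, 0.5), sdr_oc_rate = c(0.1, 0.1),
    tdr_bc_rate = c(0.4, 0.4), tdr_oc_rate = c(0.05, 0.05), ...)
}

# per-class parameter lookup: class 1 = carrier -> first element
.cls <- function(cfg, field, class) cfg[[field]][[2L - as.integer(class)]]

# separable in-plane Gaussian smoothing of each slice; sigma in voxels
.smooth_slices <- function(arr, sigma_r, sigma_c) {
  kern <- function(sig, n) {
    if (sig <= 1e-8) return(NULL)
    r <- max(1L, ceiling(3 * sig))
    K <- outer(seq_len(n), seq_len(n),
               function(i, j) exp(-((i - j)^2) / (2 * sig^2)))
    K[abs(row(K) - col(K)) > r] <- 0
    K
  }
  Kr <- kern(sigma_r, dim(arr)[2]); Kc <- kern(sigma_c, dim(arr)[3])
  out <- arr
  for (s in seq_len(dim(arr)[1])) {
    sl <- arr[s, , ]
    if (!is.null(Kr)) sl <- Kr %*% sl
    if (!is.null(Kc)) sl <- sl %*% Kc
    out[s, , ] <- sl
  }
  out
}

#' Generate one phantom lesion volume and its exact mask
#'
#' Background is zero-mean Gaussian noise.  The lesion is an axis-aligned
#' ellipsoid at a seeded random interior position, filled with
#' \code{contrast + texture_sd * GRF + rim ridge + noise}, where the GRF is
#' in-plane-smoothed white noise rescaled to unit SD and the rim ridge is a
#' Gaussian ridge at the ellipsoid surface.  The mask equals the exact
#' discretized ellipsoid support.
#'
#' @param class 1 = carrier, 0 = control (selects the per-class texture)
#' @param cfg a \code{\link{synthetic_cohort_config}}
#' @param rng_seed integer seed
#' @return list with \code{volume} (\code{volume_image}), \code{mask}
#'   (\code{lesion_mask}) and \code{params} (the realized lesion geometry)
#' @export
generate_lesion_volume <- function(class, cfg, rng_seed) {
  stopifnot(inherits(cfg, "synthetic_cohort_config"))
  d <- cfg$shape; sp <- cfg$spacing
  with_rng_seed(rng_seed, {
    a_sl <- runif(1, cfg$semi_axes_slice_mm[1], cfg$semi_axes_slice_mm[2])
    a_r <- runif(1, cfg$semi_axes_inplane_mm[1], cfg$semi_axes_inplane_mm[2])
    a_c <- runif(1, cfg$semi_axes_inplane_mm[1], cfg$semi_axes_inplane_mm[2])
    a_vox <- c(a_sl, a_r, a_c) / sp
    m <- cfg$patch_margin
    lo <- c(1 + a_vox[1], m + a_vox[2] + 1, m + a_vox[3] + 1)
    hi <- c(d[1] - a_vox[1], d[2] - m - a_vox[2], d[3] - m - a_vox[3])
    if (any(hi < lo))
      stop("geometry error: lesion (semi-axes ",
           paste(signif(c(a_sl, a_r, a_c), 3), collapse = "/"),
           " mm) does not fit the ", paste(d, collapse = "x"),
           " volume with patch margin ", m)
    ctr <- runif(3, lo, hi)
    vol <- array(rnorm(prod(d), 0, cfg$noise_sd), dim = d)
    # ellipsoid membership by the analytic inequality, via outer sums
    u2 <- ((seq_len(d[1]) - ctr[1]) / a_vox[1])^2
    v2 <- ((seq_len(d[2]) - ctr[2]) / a_vox[2])^2
    w2 <- ((seq_len(d[3]) - ctr[3]) / a_vox[3])^2
    rho2 <- outer(outer(u2, v2, `+`), w2, `+`)
    inside <- rho2 <= 1
    if (!any(inside))
      stop("geometry error: lesion support is empty at this voxel grid")
    sig_r <- .cls(cfg, "corr_length_mm", class) / sp[2]
    sig_c <- .cls(cfg, "corr_length_mm", class) / sp[3]
    field <- .smooth_slices(array(rnorm(prod(d)), dim = d), sig_r, sig_c)
    fsd <- sd(field)
    if (fsd > 0) field <- field / fsd
    rim_w <- .cls(cfg, "rim_width_mm", class) / mean(sp[2:3])
    r_eff <- mean(a_vox[2:3])
    ridge <- .cls(cfg, "rim_amplitude", class) *
      exp(-((sqrt(rho2) - 1) * r_eff / max(rim_w, 1e-8))^2)
    lesion_vals <- .cls(cfg, "contrast", class) +
      .cls(cfg, "texture_sd", class) * field[inside] + ridge[inside]
    vol[inside] <- vol[inside] + lesion_vals
    list(volume = volume_image(vol, sp),
         mask = lesion_mask(array(as.integer(inside), dim = d), sp),
         params = list(class = as.integer(class), center = ctr,
                       semi_axes_mm = c(a_sl, a_r, a_c)))
  })
}

#' Draw one subject's covariates
#'
#' TNBC, BBC, MBC ~ Bernoulli at the class prevalence; Age ~ Normal at the
#' class mean/SD truncated to [18, 90] (redrawn until inside); relative
#' counts ~ Poisson at the class rates.
#'
#' @param class 1 = carrier, 0 = control
#' @param cfg a \code{\link{synthetic_cohort_config}}
#' @param rng_seed integer seed
#' @return one-row data.frame with Age, BBC, FDR.BC, FDR.OC, SDR.BC, SDR.OC,
#'   TDR.BC, TDR.OC, MBC, TNBC, label
#' @export
generate_covariates <- function(class, cfg, rng_seed) {
  stopifnot(inherits(cfg, "synthetic_cohort_config"))
  with_rng_seed(rng_seed, {
    age <- rnorm(1, .cls(cfg, "age_mean", class), .cls(cfg, "age_sd", class))
    tries <- 0L
    while ((age < 18 || age > 90) && tries < 1000L) {
      age <- rnorm(1, .cls(cfg, "age_mean", class), .cls(cfg, "age_sd", class))
      tries <- tries + 1L
    }
    data.frame(
      Age = age,
      BBC = rbinom(1, 1, .cls(cfg, "bbc_prev", class)),
      FDR.BC = rpois(1, .cls(cfg, "fdr_bc_rate", class)),
      FDR.OC = rpois(1, .cls(cfg, "fdr_oc_rate", class)),
      SDR.BC = rpois(1, .cls(cfg, "sdr_bc_rate", class)),
      SDR.OC = rpois(1, .cls(cfg, "sdr_oc_rate", class)),
      TDR.BC = rpois(1, .cls(cfg, "tdr_bc_rate", class)),
      TDR.OC = rpois(1, .cls(cfg, "tdr_oc_rate", class)),
      MBC = rbinom(1, 1, .cls(cfg, "mbc_prev", class)),
      TNBC = rbinom(1, 1, .cls(cfg, "tnbc_prev", class)),
      label = as.integer(class))
  })
}

#' Generate a full synthetic cohort
#'
#' Draws covariates and one phantom volume per subject (two when BBC = 1 and
#' \code{bilateral_two_volumes} is set).  With \code{dir = NULL} everything
#' stays in memory in the shape \code{\link{build_cohort_patches}} consumes;
#' with a directory, MetaImage volumes/masks, a tab-delimited covariate table
#' (\code{covariates.tsv}) and a ground-truth manifest
#' (\code{manifest.json}) are written and file paths attached.
#'
#' @param cfg a \code{\link{synthetic_cohort_config}}
#' @param dir optional output directory (created if needed)
#' @return object of class \code{synthetic_cohort}: \code{subjects} (list of
#'   id/label/covariates/images), \code{covariates} (data.frame), \code{cfg},
#'   and \code{dir} when written
#' @export
generate_cohort <- function(cfg = synthetic_cohort_config(), dir = NULL) {
  stopifnot(inherits(cfg, "synthetic_cohort_config"))
  n_total <- cfg$n_carriers + cfg$n_controls
  classes <- c(rep(1L, cfg$n_carriers), rep(0L, cfg$n_controls))
  ids <- sprintf("S%03d", seq_len(n_total))
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subjects <- vector("list", n_total)
  cov_rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    cov <- generate_covariates(classes[i], cfg,
                               derive_seed(cfg$rng_seed, "cov", i))
    n_img <- if (cov$BBC == 1L && cfg$bilateral_two_volumes) 2L else 1L
    images <- vector("list", n_img)
    for (j in seq_len(n_img)) {
      gen <- generate_lesion_volume(classes[i], cfg,
                                    derive_seed(cfg$rng_seed, "img", i * 100L + j))
      image_id <- paste0(ids[i], "_img", j)
      img <- list(volume = gen$volume, mask = gen$mask, image_id = image_id,
                  params = gen$params)
      if (!is.null(dir)) {
        vp <- file.path(dir, paste0(image_id, ".mhd"))
        mp <- file.path(dir, paste0(image_id, "_mask.mhd"))
        write_volume(gen$volume, vp)
        write_mask(gen$mask, mp)
        img$volume_path <- vp; img$mask_path <- mp
      }
      images[[j]] <- img
    }
    subjects[[i]] <- list(id = ids[i], label = classes[i], covariates = cov,
                          images = images)
    cov_rows[[i]] <- cbind(data.frame(subject_id = ids[i]), cov)
  }
  covariates <- do.call(rbind, cov_rows)
  out <- structure(list(subjects = subjects, covariates = covariates,
                        cfg = cfg, dir = dir),
                   class = "synthetic_cohort")
  if (!is.null(dir)) {
    write.table(covariates, file.path(dir, "covariates.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    manifest <- list(
      cfg = unclass(cfg),
      subjects = lapply(subjects, function(s) list(
        id = s$id, label = s$label,
        images = lapply(s$images, function(im) list(
          image_id = im$image_id, volume = basename(im$volume_path),
          mask = basename(im$mask_path),
          center = im$params$center, semi_axes_mm = im$params$semi_axes_mm)))))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", sum(x$covariates$label == 1L), " carriers / ",
      sum(x$covariates$label == 0L), " controls",
      if (!is.null(x$dir)) paste0(" (written to ", x$dir, ")"), "\n", sep = "")
  invisible(x)
}

#' Load a cohort previously written by \code{generate_cohort}
#'
#' Reads the manifest, covariate table and every MetaImage volume/mask pair
#' back through the imaging IO layer (masks are alignment-checked against
#' their volumes).
#'
#' @param dir cohort directory
#' @return a \code{synthetic_cohort}-shaped list usable by
#'   \code{\link{build_cohort_patches}}
#' @export
load_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json under ", dir)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  covariates <- read.delim(file.path(dir, "covariates.tsv"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  subjects <- lapply(man$subjects, function(s) {
    images <- lapply(s$images, function(im) {
      vol <- read_volume(file.path(dir, im$volume))
      msk <- read_mask(file.path(dir, im$mask), vol)
      list(volume = vol, mask = msk, image_id = im$image_id)
    })
    list(id = s$id, label = as.integer(s$label),
         covariates = covariates[covariates$subject_id == s$id, , drop = FALSE],
         images = images)
  })
  structure(list(subjects = subjects, covariates = covariates, cfg = man$cfg,
                 dir = dir),
            class = "synthetic_cohort")
}
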