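# Uniform seed-point sampling inside lesion masks and extraction of min-max
# normalized in-plane intensity patches.  Defaults follow the study protocol:
# 65x65 patches (4225 features), ~1000 samples per image, cohort-level 1:1
# positive:negative patch ratio.

#' Sampling plan for cohort patch extraction
#'
#' @param n_per_image target seed count per image (default 1000)
#' @param class_ratio integer length-2 \code{c(pos, neg)} target ratio
#'   (default 1:1)
#' @param rng_seed integer seed controlling all sampling
#' @param patch_size odd in-plane patch side length (default 65)
#' @param normalization_scope \code{"patch"} (default) or \code{"volume"}:
#'   whether min-max normalization uses the patch window or the whole volume
#' @return an object of class \code{sampling_plan}
#' @export
sampling_plan <- function(n_per_image = 1000L, class_ratio = c(1L, 1L),
                          rng_seed = 1L, patch_size = 65L,
                          normalization_scope = c("patch", "volume")) {
  normalization_scope <- match.arg(normalization_scope)
  n_per_image <- as.integer(n_per_image)
  class_ratio <- as.integer(class_ratio)
  if (n_per_image < 1L) stop("`n_per_image` must be >= 1")
  if (length(class_ratio) != 2L || any(class_ratio < 1L))
    stop("`class_ratio` must be two integers >= 1")
  if (patch_size %% 2L == 0L || patch_size < 1L)
    stop("`patch_size` must be a positive odd integer")
  structure(list(n_per_image = n_per_image, class_ratio = class_ratio,
                 rng_seed = as.integer(rng_seed),
                 patch_size = as.integer(patch_size),
                 normalization_scope = normalization_scope),
            class = "sampling_plan")
}

#' Sample seed points uniformly from mask foreground
#'
#' Seeds are drawn with replacement, uniformly over the foreground voxels,
#' deterministically for a fixed \code{rng_seed}.
#'
#' @param mask a \code{\link{lesion_mask}}
#' @param n number of seeds
#' @param rng_seed integer seed
#' @param subject_id,label carried through into the seed table
#' @return data.frame with columns slice, row, col (1-based voxel indices),
#'   subject_id, label
#' @export
sample_seed_points <- function(mask, n, rng_seed, subject_id = NA_character_,
                               label = NA_integer_) {
  if (!inherits(mask, "lesion_mask")) stop("`mask` must be a lesion_mask")
  if (mask_is_empty(mask))
    stop("sampling error: mask for subject '", subject_id,
         "' has no foreground voxels")
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1")
  fg <- which(mask$voxels != 0L, arr.ind = TRUE)
  idx <- with_rng_seed(rng_seed, sample.int(nrow(fg), n, replace = TRUE))
  data.frame(slice = fg[idx, 1], row = fg[idx, 2], col = fg[idx, 3],
             subject_id = subject_id, label = as.integer(label),
             stringsAsFactors = FALSE)
}

#' Min-max normalize a patch to [0, 1]
#'
#' \code{(x - min) / (max - min)}; a constant input maps to all zeros (the
#' division-by-zero guard that keeps the [0,1] contract NaN-free).
#'
#' @param raw numeric matrix or array of finite intensities
#' @return matrix of the same shape with values in [0, 1]
#' @export
normalize_patch <- function(raw) {
  if (!all(is.finite(raw))) stop("patch intensities must be finite")
  lo <- min(raw); hi <- max(raw)
  if (hi == lo) return(array(0, dim = dim(raw) %||% length(raw)))
  (raw - lo) / (hi - lo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract one normalized in-plane patch around a seed
#'
#' Returns the \code{size x size} window centered at the seed on the seed's
#' slice.  Seeds whose window would cross the volume boundary are rejected by
#' returning \code{NULL} (the caller resamples); this keeps the seed
#' distribution uniform over the interior support rather than inventing
#' padding behavior.
#'
#' @param volume a \code{\link{volume_image}}
#' @param seed one-row data.frame (or list) with \code{slice}, \code{row},
#'   \code{col} 1-based indices
#' @param size odd patch side length (default 65)
#' @param normalize min-max normalize the window (default TRUE)
#' @return an object of class \code{mri_patch} with fields \code{values}
#'   (size x size matrix), \code{seed}; or \code{NULL} if the window crosses
#'   the boundary
#' @export
extract_patch <- function(volume, seed, size = 65L, normalize = TRUE) {
  if (!inherits(volume, "volume_image")) stop("`volume` must be a volume_image")
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L)
    stop("parameter error: `size` must be a positive odd integer, got ", size)
  d <- dim(volume$voxels)
  s <- as.integer(seed$slice); r <- as.integer(seed$row); c0 <- as.integer(seed$col)
  if (s < 1L || s > d[1] || r < 1L || r > d[2] || c0 < 1L || c0 > d[3])
    stop("seed (", s, ",", r, ",", c0, ") lies outside the volume")
  h <- (size - 1L) %/% 2L
  if (r - h < 1L || r + h > d[2] || c0 - h < 1L || c0 + h > d[3])
    return(NULL)  # boundary rejection signal
  win <- volume$voxels[s, (r - h):(r + h), (c0 - h):(c0 + h), drop = TRUE]
  win <- matrix(win, nrow = size, ncol = size)
  if (normalize) win <- normalize_patch(win)
  structure(list(values = win, seed = seed), class = "mri_patch")
}

# Split `total` into `n_parts` integers as evenly as possible (deterministic).
.split_quota <- function(total, n_parts) {
  base <- total %/% n_parts
  extra <- total %% n_parts
  rep(base, n_parts) + c(rep(1L, extra), rep(0L, n_parts - extra))
}

# Sample `n` accepted patches from one image, resampling boundary rejections
# up to 100 * n draws.
.sample_image_patches <- function(volume, mask, n, rng_seed, subject_id, label,
                                  plan) {
  size <- plan$patch_size
  vol_for_patch <- volume
  if (plan$normalization_scope == "volume") {
    vol_for_patch <- volume
    vol_for_patch$voxels <- normalize_patch(volume$voxels)
  }
  accepted_X <- matrix(NA_real_, nrow = n, ncol = size * size)
  info <- vector("list", n)
  got <- 0L; drawn <- 0L; batch_i <- 0L
  while (got < n) {
    if (drawn >= 100L * n)
      stop("patch sampling for subject '", subject_id, "' exceeded ",
           100L * n, " draws: lesion too close to the volume boundary for ",
           size, "x", size, " patches")
    need <- n - got
    seeds <- sample_seed_points(mask, need, derive_seed(rng_seed, "seeds", batch_i),
                                subject_id, label)
    drawn <- drawn + need; batch_i <- batch_i + 1L
    for (i in seq_len(nrow(seeds))) {
      p <- extract_patch(vol_for_patch, seeds[i, ], size = size,
                         normalize = (plan$normalization_scope == "patch"))
      if (is.null(p)) next
      got <- got + 1L
      accepted_X[got, ] <- as.vector(p$values)
      info[[got]] <- seeds[i, ]
    }
  }
  list(X = accepted_X, info = do.call(rbind, info))
}

#' Build a balanced cohort patch set
#'
#' Samples patches from every image of every subject, enforcing the
#' cohort-level positive:negative patch ratio (default 1:1) by down-scaling
#' the per-image quota of the majority class.  With ratio a:b the retained
#' totals are \code{a*t} and \code{b*t} where
#' \code{t = floor(min(U_pos/a, U_neg/b))} and \code{U_c} is the unscaled
#' per-class total (\code{n_per_image * images in class c}); totals therefore
#' match the ratio exactly (difference at most 1 only for non-integer splits).
#'
#' @param subjects list; each element a list with \code{id}, \code{label}
#'   (1 = carrier, 0 = control) and \code{images}: a list of
#'   \code{list(volume =, mask =, image_id =)}
#' @param plan a \code{\link{sampling_plan}}
#' @return object of class \code{patch_set}: \code{X} (patches x size^2
#'   matrix), \code{info} (sidecar data.frame: subject_id, image_id, slice,
#'   row, col, label), \code{patch_size}
#' @export
build_cohort_patches <- function(subjects, plan = sampling_plan()) {
  labels <- vapply(subjects, function(s) as.integer(s$label), integer(1))
  if (length(unique(labels)) < 2L)
    stop("balance error: cohort must contain both classes (got only class ",
         unique(labels), ")")
  img_tab <- do.call(rbind, lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    data.frame(subj = i, label = as.integer(s$label),
               img = seq_along(s$images))
  }))
  n_img <- table(factor(img_tab$label, levels = c(1L, 0L)))
  U_pos <- plan$n_per_image * n_img[["1"]]
  U_neg <- plan$n_per_image * n_img[["0"]]
  a <- plan$class_ratio[1]; b <- plan$class_ratio[2]
  t_scale <- floor(min(U_pos / a, U_neg / b))
  totals <- c(`1` = a * t_scale, `0` = b * t_scale)
  quotas <- list(
    `1` = .split_quota(totals[["1"]], n_img[["1"]]),
    `0` = .split_quota(totals[["0"]], n_img[["0"]])
  )
  parts <- list(); counter <- c(`1` = 0L, `0` = 0L)
  img_counter <- 0L
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    lab <- as.character(as.integer(s$label))
    for (j in seq_along(s$images)) {
      img_counter <- img_counter + 1L
      counter[[lab]] <- counter[[lab]] + 1L
      quota <- quotas[[lab]][counter[[lab]]]
      if (quota < 1L) next
      im <- s$images[[j]]
      res <- .sample_image_patches(
        im$volume, im$mask, quota,
        derive_seed(plan$rng_seed, "image", img_counter),
        s$id, s$label, plan)
      res$info$image_id <- im$image_id %||% paste0(s$id, "_img", j)
      parts[[length(parts) + 1L]] <- res
    }
  }
  X <- do.call(rbind, lapply(parts, `[[`, "X"))
  info <- do.call(rbind, lapply(parts, `[[`, "info"))
  rownames(info) <- NULL
  structure(list(X = X, info = info, patch_size = plan$patch_size),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat("<patch_set> ", nrow(x$X), " patches of ", x$patch_size, "x",
      x$patch_size, " (", ncol(x$X), " features); ",
      sum(x$info$label == 1L), " positive / ", sum(x$info$label == 0L),
      " negative\n", sep = "")
  invisible(x)
}

#' Write a patch set as plain text (flat matrix + sidecar table)
#' @param ps a \code{patch_set}
#' @param prefix output path prefix; writes \code{<prefix>_matrix.tsv} and
#'   \code{<prefix>_info.tsv}
#' @return invisibly, the two paths
#' @export
write_patch_set <- function(ps, prefix) {
  mpath <- paste0(prefix, "_matrix.tsv")
  ipath <- paste0(prefix, "_info.tsv")
  write.table(ps$X, mpath, sep = "\t", row.names = FALSE, col.names = FALSE)
  write.table(ps$info, ipath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(matrix = mpath, info = ipath))
}
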