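#' Specification of one synthetic nodule phantom
#'
#' Describes a single two-class nodule phantom: an ellipsoidal (spherical in
#' mm) mask of the requested diameter whose in-mask intensity is a base
#' level plus a spatially correlated Gaussian texture field, plus — for the
#' heterogeneous (malignant-like) class — a coarse blob component of 3-6
#' smooth intensity blobs at about a third of the nodule diameter, the
#' spot/edge micro-structure that Laws kernels detect. Benign-like phantoms
#' use `heterogeneity_amp = 0`.
#'
#' @param label `"benign"` or `"malignant"`.
#' @param diameter_mm nodule diameter in mm (> 0).
#' @param spacing_mm voxel pitch (dx, dy, dz) in mm.
#' @param base_intensity mean in-mask intensity (HU-like; default 40, soft
#'   tissue).
#' @param noise_sd standard deviation of the correlated texture field.
#' @param correlation_length_mm Gaussian smoothing scale of the texture
#'   field in mm.
#' @param heterogeneity_amp amplitude of the coarse blob component (>= 0;
#'   0 disables it).
#' @param seed integer RNG seed; identical spec + seed give a bit-identical
#'   phantom.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(label = c("benign", "malignant"),
                         diameter_mm = 20, spacing_mm = c(1, 1, 1),
                         base_intensity = 40, noise_sd = 10,
                         correlation_length_mm = 2,
                         heterogeneity_amp = if (label == "malignant") 30 else 0,
                         seed = 1L) {
  label <- match.arg(label)
  force(heterogeneity_amp)
  stopifnot(diameter_mm > 0, noise_sd >= 0, heterogeneity_amp >= 0,
            correlation_length_mm > 0, all(spacing_mm > 0))
  structure(list(label = label, diameter_mm = diameter_mm,
                 spacing_mm = as.numeric(spacing_mm),
                 base_intensity = base_intensity, noise_sd = noise_sd,
                 correlation_length_mm = correlation_length_mm,
                 heterogeneity_amp = heterogeneity_amp,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one nodule phantom
#'
#' Renders the phantom described by a [phantom_spec()]: a spherical mask of
#' the requested physical diameter plus margin, background air at -800 HU,
#' and in-mask intensity = base + correlated texture + blob heterogeneity.
#' The texture field is white Gaussian noise convolved with a Gaussian
#' kernel of the correlation length (kernel normalised to unit L2 norm so
#' the field keeps standard deviation `noise_sd`); the heterogeneity
#' component adds 3-6 signed Gaussian blobs of scale diameter/6 centred
#' inside the nodule. Fully deterministic given the spec seed, and the
#' caller's RNG state is left untouched.
#'
#' @param spec a [phantom_spec()].
#' @param margin_voxels background margin around the nodule box.
#' @return List with elements `volume` (an [image_volume()]) and `mask`
#'   (logical array of the same shape).
#' @examples
#' ph <- generate_phantom(phantom_spec("malignant", diameter_mm = 12))
#' sum(ph$mask)
#' @export
generate_phantom <- function(spec, margin_voxels = 3L) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing_mm
  r_mm <- spec$diameter_mm / 2
  if (any(spec$diameter_mm < sp))
    stop("diameter ", spec$diameter_mm, " mm is smaller than one voxel")
  nvox <- ceiling(spec$diameter_mm / sp) + 2L * margin_voxels
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  cx <- (nvox + 1) / 2
  ax <- lapply(1:3, function(a) (seq_len(nvox[a]) - cx[a]) * sp[a])
  dx2 <- array(rep(ax[[1]]^2, times = nvox[2] * nvox[3]), nvox)
  dy2 <- array(rep(rep(ax[[2]]^2, each = nvox[1]), times = nvox[3]), nvox)
  dz2 <- array(rep(ax[[3]]^2, each = nvox[1] * nvox[2]), nvox)
  r2 <- dx2 + dy2 + dz2
  mask <- r2 <= r_mm^2
  # correlated texture field, unit-variance before scaling by noise_sd
  field <- array(rnorm(prod(nvox)), nvox)
  if (spec$noise_sd > 0) {
    ks <- lapply(1:3, function(a) {
      k <- gaussian_kernel_1d(spec$correlation_length_mm / sp[a])
      k / sqrt(sum(k^2))          # unit L2: preserves white-noise variance
    })
    field <- separable_conv3(field, ks[[1]], ks[[2]], ks[[3]])
  }
  vox <- array(-800, nvox) + 20 * array(rnorm(prod(nvox)), nvox) * !mask
  vox[mask] <- spec$base_intensity + spec$noise_sd * field[mask]
  if (spec$heterogeneity_amp > 0) {
    n_blob <- sample(3:6, 1)
    sig <- spec$diameter_mm / 6
    ctr_idx <- which(r2 <= (0.6 * r_mm)^2)
    centers <- sample(ctr_idx, n_blob, replace = TRUE)
    ci <- arrayInd(centers, nvox)
    blob <- array(0, nvox)
    for (b in seq_len(n_blob)) {
      d2 <- sweep_dist2(ax, ci[b, ], nvox)
      blob <- blob + sample(c(-1, 1), 1) * exp(-d2 / (2 * sig^2))
    }
    vox[mask] <- vox[mask] + spec$heterogeneity_amp * blob[mask]
  }
  list(volume = image_volume(vox, spacing = sp), mask = mask)
}

# squared physical distance from voxel centre `ci` on the coordinate axes
sweep_dist2 <- function(ax, ci, nvox) {
  dx <- (ax[[1]] - ax[[1]][ci[1]])^2
  dy <- (ax[[2]] - ax[[2]][ci[2]])^2
  dz <- (ax[[3]] - ax[[3]][ci[3]])^2
  array(rep(dx, times = nvox[2] * nvox[3]), nvox) +
    array(rep(rep(dy, each = nvox[1]), times = nvox[3]), nvox) +
    array(rep(dz, each = nvox[1] * nvox[2]), nvox)
}

#' Generate a two-class phantom cohort on disk
#'
#' Writes `n_benign + n_malignant` NIfTI image/mask pairs with per-case
#' seeds `master_seed + case index`, and returns (and writes) the cohort
#' manifest. The default class templates differ only in the heterogeneity
#' amplitude, the designed class contrast.
#'
#' @param n_benign,n_malignant per-class case counts (>= 1). The reference
#'   cohort shape is 33 benign / 42 malignant.
#' @param out_dir output directory (created if needed).
#' @param benign_template,malignant_template [phantom_spec()] templates;
#'   per-case seeds override the template seed.
#' @param master_seed integer master seed.
#' @return A tibble manifest with columns `case_id`, `image_path`,
#'   `mask_path`, `label`; also written to `out_dir/manifest.csv`.
#' @export
generate_cohort <- function(n_benign = 33L, n_malignant = 42L,
                            out_dir = tempfile("cohort"),
                            benign_template = phantom_spec("benign"),
                            malignant_template = phantom_spec("malignant"),
                            master_seed = 20260101L) {
  stopifnot(n_benign >= 1L, n_malignant >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create ", out_dir)
  labels <- c(rep("benign", n_benign), rep("malignant", n_malignant))
  rows <- lapply(seq_along(labels), function(i) {
    tmpl <- if (labels[i] == "benign") benign_template else malignant_template
    spec <- tmpl
    spec$seed <- as.integer(master_seed + i)
    ph <- generate_phantom(spec)
    cid <- sprintf("case_%03d_%s", i, substr(labels[i], 1, 1))
    ipath <- file.path(out_dir, paste0(cid, "_img.nii.gz"))
    mpath <- file.path(out_dir, paste0(cid, "_mask.nii.gz"))
    write_volume(ph$volume, ipath)
    write_volume(image_volume(array(as.numeric(ph$mask), dim(ph$mask)),
                              spacing = ph$volume$spacing), mpath)
    tibble::tibble(case_id = cid, image_path = ipath, mask_path = mpath,
                   label = labels[i])
  })
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Tiny fixed micro-volumes for oracle tests
#'
#' A documented set of hand-specified arrays (all at most 4^3) used as the
#' substrate for brute-force matrix-feature oracles:
#' \describe{
#'   \item{constant4}{4x4x4 array of 5s, full mask.}
#'   \item{checker221}{single-slice 2x2 checkerboard of codes \{0, 1\}.}
#'   \item{run331}{3x3x1 patch whose middle row is one run of length 3.}
#'   \item{masked333}{3^3 ramp with an off-centre 2-voxel hole in the mask.}
#' }
#'
#' @return Named list; each element has `voxels` and `mask` arrays.
#' @export
fixture_microvolumes <- function() {
  list(
    constant4 = list(voxels = array(5, c(4, 4, 4)),
                     mask = array(TRUE, c(4, 4, 4))),
    checker221 = list(voxels = array(c(0, 1, 1, 0), c(2, 2, 1)),
                      mask = array(TRUE, c(2, 2, 1))),
    run331 = list(voxels = array(c(0, 2, 0,
                                   1, 1, 1,
                                   0, 2, 0), c(3, 3, 1)),
                  mask = array(TRUE, c(3, 3, 1))),
    masked333 = {
      m <- array(TRUE, c(3, 3, 3)); m[2, 1, 1] <- FALSE; m[3, 3, 2] <- FALSE
      list(voxels = array(seq(0, 26), c(3, 3, 3)), mask = m)
    })
}

#' Simulate a planted-signal feature table
#'
#' Builds a cases-by-features tibble mimicking the screened stage of the
#' pipeline: `n_signal` informative features whose class means differ by
#' `effect` standard deviations, among `n_noise` pure-noise features, for
#' `n_per_class` cases per class. The informative columns are given the
#' four signature feature names (then `signal_k`), so selection tests can
#' check recovery by name.
#'
#' @param n_per_class cases per class (benign and malignant).
#' @param n_signal number of planted informative features.
#' @param n_noise number of null features.
#' @param effect class mean separation in SD units.
#' @param seed RNG seed.
#' @return A tibble with `case_id`, `label` and feature columns; attribute
#'   `"planted"` holds the informative feature names.
#' @export
simulate_feature_table <- function(n_per_class = 20L, n_signal = 4L,
                                   n_noise = 72L, effect = 3, seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  n <- 2L * n_per_class
  labels <- rep(c("benign", "malignant"), each = n_per_class)
  sig_names <- c("Laws_LSL_min", "Laws_SLL_energy", "Laws_SSL_skewness",
                 "Laws_EEL_uniformity")
  if (n_signal > 4L) sig_names <- c(sig_names,
                                    paste0("signal_", seq_len(n_signal - 4L)))
  sig_names <- sig_names[seq_len(n_signal)]
  X <- matrix(rnorm(n * (n_signal + n_noise)), n)
  shift <- matrix(0, n, n_signal + n_noise)
  shift[labels == "malignant", seq_len(n_signal)] <- effect
  X <- X + shift
  colnames(X) <- c(sig_names, paste0("noise_", seq_len(n_noise)))
  X <- X[, sample(ncol(X)), drop = FALSE]  # no positional hint for selection
  out <- dplyr::bind_cols(
    tibble::tibble(case_id = sprintf("case_%03d", seq_len(n)), label = labels),
    tibble::as_tibble(X))
  attr(out, "planted") <- sig_names
  out
}
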