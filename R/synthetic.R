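# Synthetic stained-epidermis generator.
#
# Emulates immunohistochemically stained skin sections: an undulating
# epidermis band over dermis, nuclei inside the band, and a red chromogen
# marking UV-damaged regions. Damage is assigned by thresholding a
# Gaussian-smoothed white-noise field at the quantile that hits the target
# damaged-area fraction; the smoothing length is the single heterogeneity
# knob (fine speckle at 0, large contiguous damage patches at 1). Every
# sample carries exact ground truth: the 3-class mask, the nuclei list with
# per-nucleus damage flags, and both scores. No claim of histological
# realism is made beyond what segmentation and regression models need to
# learn the task.

#' Configuration for the synthetic-histology generator
#'
#' @param height_px,width_px Image size in pixels. The default 256 x 256 is
#'   the desk-scale size; `preset = "slide"` selects the full-slide
#'   1040 x 1384 geometry.
#' @param resolution_um_per_px Physical resolution (default 0.645 um/px,
#'   the acquisition resolution of the cohort this generator emulates).
#' @param band_thickness_um Range the epidermis thickness is drawn from.
#' @param undulation_amplitude_um,undulation_period_um Geometry of the
#'   sinusoidal rete-ridge-like undulation of the band.
#' @param nuclei_density_per_um2 Expected nuclei per square micron of
#'   epidermis.
#' @param target_damage_fraction Desired damaged fraction of the epidermis
#'   area, in `[0, 1]`.
#' @param heterogeneity Spatial heterogeneity of the damage in `[0, 1]`:
#'   0 gives fine-grained speckle, 1 gives large coherent patches.
#' @param contrast Dynamic-range factor in `(0, 1]`; values below 1
#'   compress all colors toward the background tone (low-contrast variant).
#' @param noise_sigma Pixel noise standard deviation (0-255 scale).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param preset `"desk"` (256 x 256) or `"slide"` (1040 x 1384).
#' @return A list of class `epiderm_generator_config`.
#' @export
generator_config <- function(height_px = 256, width_px = 256,
                             resolution_um_per_px = 0.645,
                             band_thickness_um = c(40, 80),
                             undulation_amplitude_um = 15,
                             undulation_period_um = 120,
                             nuclei_density_per_um2 = 0.005,
                             target_damage_fraction = 0.3,
                             heterogeneity = 0.5,
                             contrast = 1,
                             noise_sigma = 8,
                             seed = 1L,
                             preset = c("desk", "slide")) {
  preset <- match.arg(preset)
  if (preset == "slide" && missing(height_px)) { height_px <- 1040; width_px <- 1384 }
  stopifnot(height_px >= 32, width_px >= 32, resolution_um_per_px > 0,
            length(band_thickness_um) == 2, all(band_thickness_um > 0),
            undulation_amplitude_um >= 0, undulation_period_um > 0,
            nuclei_density_per_um2 > 0, contrast > 0, contrast <= 1,
            noise_sigma >= 0)
  if (target_damage_fraction < 0 || target_damage_fraction > 1)
    ep_stop("target_damage_fraction must lie in [0, 1]", "epiderm_config_error")
  if (heterogeneity < 0 || heterogeneity > 1)
    ep_stop("heterogeneity must lie in [0, 1]", "epiderm_config_error")
  if (min(band_thickness_um) / resolution_um_per_px < 2)
    ep_stop("epidermis band thinner than 2 px at the declared resolution",
            "epiderm_config_error")
  structure(as.list(environment())[setdiff(names(formals()), "preset")],
            class = "epiderm_generator_config")
}

# stain colors (RGB, 0-255)
SYNTH_COLORS <- list(
  above = c(246, 243, 246),     # mounting medium above the tissue surface
  dermis = c(232, 175, 192),    # eosin-stained dermis
  epidermis = c(214, 182, 222), # keratinocyte cytoplasm
  chromogen = c(196, 92, 80),   # diffuse red chromogen in damaged regions
  nucleus = c(84, 62, 150),     # hematoxylin-stained healthy nucleus
  nucleus_dmg = c(150, 38, 46)  # chromogen-dense damaged nucleus
)

#' Generate one synthetic stained-epidermis sample
#'
#' Deterministic for a fixed seed. The epidermis is a smooth undulating
#' band spanning the full image width; nuclei are placed only inside the
#' band; damaged (class 2) pixels always lie inside the band; and the
#' returned `true_scores` are exact: `s_nuclei` equals the damaged fraction
#' of the nuclei list and `s_area` equals [s_area_from_mask()] of the mask.
#'
#' @param config An [generator_config()].
#' @return A list of class `epiderm_sample` with `image` (H x W x 3,
#'   0-255), `mask` (integer H x W, classes 0/1/2), `nuclei` (data.frame
#'   `x_px`, `y_px`, `damaged`), `true_scores` ([score_pair()]),
#'   `heterogeneity_value` (the realized [heterogeneity_index()]) and
#'   `config`.
#' @export
generate_sample <- function(config = generator_config()) {
  stopifnot(inherits(config, "epiderm_generator_config"))
  with_seed(config$seed, {
    H <- config$height_px; W <- config$width_px
    res <- config$resolution_um_per_px
    px <- function(um) um / res

    # --- band geometry ---
    t_px <- px(stats::runif(1, config$band_thickness_um[1], config$band_thickness_um[2]))
    amp <- px(config$undulation_amplitude_um)
    per <- px(config$undulation_period_um)
    phase <- stats::runif(1, 0, 2 * pi)
    y0 <- amp + 4 + 0.08 * H
    xs <- seq_len(W)
    surface <- y0 + amp * sin(2 * pi * xs / per + phase)
    rows <- matrix(seq_len(H), H, W)
    surf <- matrix(surface, H, W, byrow = TRUE)
    band <- rows >= surf & rows < surf + t_px
    above <- rows < surf

    # --- damage field: thresholded smoothed white noise ---
    sigma <- 2 + config$heterogeneity * (min(H, W) / 5 - 2)
    field <- gauss_blur(matrix(stats::rnorm(H * W), H, W), sigma)
    fb <- field[band]
    thr <- if (config$target_damage_fraction <= 0) Inf
           else if (config$target_damage_fraction >= 1) -Inf
           else stats::quantile(fb, 1 - config$target_damage_fraction, names = FALSE)
    damaged_px <- band & field > thr

    mask <- matrix(0L, H, W)
    mask[band] <- 1L
    mask[damaged_px] <- 2L

    # --- nuclei ---
    band_area_um2 <- sum(band) * res^2
    n_nuc <- max(1L, stats::rpois(1, config$nuclei_density_per_um2 * band_area_um2))
    band_idx <- which(band)
    centers <- sample(band_idx, n_nuc, replace = n_nuc > length(band_idx))
    cy <- ((centers - 1) %% H) + 1
    cx <- ((centers - 1) %/% H) + 1
    damaged_nuc <- field[centers] > thr
    nuclei <- data.frame(x_px = cx, y_px = cy, damaged = damaged_nuc)

    # --- rendering ---
    col <- SYNTH_COLORS
    img <- array(0, c(H, W, 3))
    for (ch in 1:3) {
      plane <- matrix(col$dermis[ch], H, W)
      plane[above] <- col$above[ch]
      plane[band] <- col$epidermis[ch]
      img[, , ch] <- plane
    }
    # diffuse chromogen over damaged regions
    alpha <- 0.45
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[damaged_px] <- (1 - alpha) * plane[damaged_px] + alpha * col$chromogen[ch]
      img[, , ch] <- plane
    }
    # nuclei as filled ellipses, 4-8 um diameter
    for (i in seq_len(n_nuc)) {
      a <- px(stats::runif(1, 2, 4)); b <- px(stats::runif(1, 2, 4))
      nc <- if (damaged_nuc[i]) col$nucleus_dmg else col$nucleus
      yr <- max(1, floor(cy[i] - a)):min(H, ceiling(cy[i] + a))
      xr <- max(1, floor(cx[i] - b)):min(W, ceiling(cx[i] + b))
      dy <- (yr - cy[i]) / a
      dx <- (xr - cx[i]) / b
      inside <- outer(dy^2, dx^2, `+`) <= 1
      for (ch in 1:3) {
        sub <- img[yr, xr, ch]
        sub[inside] <- nc[ch]
        img[yr, xr, ch] <- sub
      }
    }
    if (config$noise_sigma > 0)
      img <- img + array(stats::rnorm(H * W * 3, sd = config$noise_sigma), c(H, W, 3))
    if (config$contrast < 1) {
      mid <- mean(unlist(col[c("above", "dermis", "epidermis")]))
      img <- mid + config$contrast * (img - mid)
    }
    img <- round(clip(img, 0, 255))

    area <- s_area_from_mask(mask)
    structure(list(
      image = img, mask = mask, nuclei = nuclei,
      true_scores = score_pair(s_nuclei = mean(damaged_nuc), s_area = area$s_area),
      heterogeneity_value = heterogeneity_index(mask),
      config = config), class = "epiderm_sample")
  })
}

#' Spatial heterogeneity of damage in a label mask
#'
#' The mask is cut into `tile_px` x `tile_px` tiles; for every tile that
#' contains epidermis the damaged fraction (class 2 over classes 1+2) is
#' computed, and the index is the population standard deviation of those
#' fractions rescaled by its maximum attainable value 0.5. Spatially
#' uniform damage scores near 0; damage concentrated in one half of the
#' tissue scores near 1.
#'
#' @param mask Integer matrix with classes 0/1/2.
#' @param tile_px Tile edge in pixels (minimum 8).
#' @return A scalar in `[0, 1]`.
#' @export
heterogeneity_index <- function(mask, tile_px = 32) {
  stopifnot(tile_px >= 8)
  if (!any(mask == 1L | mask == 2L))
    ep_stop("mask contains no epidermis", "epiderm_undefined_score")
  H <- nrow(mask); W <- ncol(mask)
  fr <- c()
  for (y0 in seq(1, H, tile_px)) {
    for (x0 in seq(1, W, tile_px)) {
      tile <- mask[y0:min(H, y0 + tile_px - 1), x0:min(W, x0 + tile_px - 1)]
      epi <- sum(tile >= 1L)
      if (epi > 0) fr <- c(fr, sum(tile == 2L) / epi)
    }
  }
  min(1, pop_sd(fr) / 0.5)
}

#' Annotator-noise model configuration
#'
#' Models interobserver variability in the S_nuclei score: an annotator
#' returns the true score plus zero-mean Gaussian noise whose standard
#' deviation grows linearly with the sample's spatial heterogeneity —
#' heterogeneous damage is where experts disagree most. The default
#' coupling is calibrated (see [calibrate_annotator()]) so that two
#' independent annotators disagree by an MAE of about 0.2 on fully
#' heterogeneous samples, the regime reported for pathologists scoring
#' heterogeneous sections.
#'
#' @param base_noise_sd Noise floor on homogeneous samples.
#' @param heterogeneity_coupling Added noise sd per unit heterogeneity.
#' @param seed Optional integer seed for reproducible draws.
#' @return A list of class `epiderm_annotator_config`.
#' @export
annotator_config <- function(base_noise_sd = 0.02,
                             heterogeneity_coupling = 0.19,
                             seed = NULL) {
  stopifnot(is.finite(base_noise_sd), base_noise_sd >= 0,
            is.finite(heterogeneity_coupling), heterogeneity_coupling >= 0)
  structure(list(base_noise_sd = base_noise_sd,
                 heterogeneity_coupling = heterogeneity_coupling,
                 seed = seed),
            class = "epiderm_annotator_config")
}

#' Simulate a noisy annotator scoring S_nuclei
#'
#' Returns `true_s_nuclei` plus Gaussian noise with
#' `sd = base_noise_sd + heterogeneity_coupling * heterogeneity_value`,
#' truncated to `[0, 1]`. Vectorized over samples; deterministic for a
#' fixed `config$seed`.
#'
#' @param true_s_nuclei True score(s) in `[0, 1]`.
#' @param heterogeneity_value Heterogeneity value(s) in `[0, 1]`.
#' @param config An [annotator_config()].
#' @return Simulated score(s) in `[0, 1]`.
#' @export
simulate_annotator <- function(true_s_nuclei, heterogeneity_value,
                               config = annotator_config()) {
  stopifnot(all(true_s_nuclei >= 0 & true_s_nuclei <= 1),
            all(heterogeneity_value >= 0 & heterogeneity_value <= 1))
  n <- max(length(true_s_nuclei), length(heterogeneity_value))
  s <- rep_len(true_s_nuclei, n)
  h <- rep_len(heterogeneity_value, n)
  sd <- config$base_noise_sd + config$heterogeneity_coupling * h
  with_seed(config$seed, clip(s + stats::rnorm(n, sd = sd), 0, 1))
}

#' Calibrate the annotator-noise coupling to a target disagreement
#'
#' Sweeps the heterogeneity coupling until the empirical mean absolute
#' difference between two independent simulated annotators, over `n`
#' Monte-Carlo samples with uniformly drawn true scores at the given
#' heterogeneity, matches `target_mae`. Common random numbers make the
#' objective smooth, so a root find suffices.
#'
#' @param target_mae Target annotator-vs-annotator MAE (default 0.2).
#' @param heterogeneity Heterogeneity level of the calibration samples.
#' @param base_noise_sd Noise floor held fixed during calibration.
#' @param n Number of Monte-Carlo samples.
#' @param seed RNG seed for the calibration draws.
#' @return The calibrated `heterogeneity_coupling`.
#' @export
calibrate_annotator <- function(target_mae = 0.2, heterogeneity = 1,
                                base_noise_sd = 0.02, n = 2000, seed = 99L) {
  draws <- with_seed(seed, list(s = stats::runif(n),
                                e1 = stats::rnorm(n), e2 = stats::rnorm(n)))
  mae_at <- function(coupling) {
    sd <- base_noise_sd + coupling * heterogeneity
    a1 <- clip(draws$s + sd * draws$e1, 0, 1)
    a2 <- clip(draws$s + sd * draws$e2, 0, 1)
    mean(abs(a1 - a2))
  }
  stats::uniroot(function(cc) mae_at(cc) - target_mae,
                 lower = 0, upper = 2, tol = 1e-5)$root
}

#' Composition of the emulated epidermis cohort
#'
#' Marginal strata shares used as the default by [generate_dataset()]:
#' tissue sources 60.6% abdominal human skin / 33.5% in-vitro human skin
#' model / 6.0% porcine ear skin, stainings 51.6% CPD / 39.4% 6-4PP /
#' 4.5% MAA / 4.5% MAC, and pixel-wise segmentation annotation for 25.1%
#' of samples.
#'
#' @return A list with `tissue`, `staining` and `has_segmentation` shares.
#' @export
strata_epidermis_cohort <- function() {
  list(tissue = c(human_skin = 487, human_skin_model = 269, porcine_skin = 48) / 804,
       staining = c(CPD = 415, "64PP" = 317, MAA = 36, MAC = 36) / 804,
       has_segmentation = 202 / 804)
}

# largest-remainder allocation of n into round(n * p) integer counts
allocate_counts <- function(n, p) {
  p <- p / sum(p)
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes `images/`, `masks/` (for the annotated share only) and
#' `manifest.csv` in the exact layout [load_manifest()] reads. Tissue,
#' staining and mask availability are allocated by largest remainder, so
#' stratum counts match the requested shares to within one sample. The
#' per-sample damage fraction is drawn from a mixture covering `[0, 1]`
#' (mostly-low, uniform, mostly-high components); heterogeneity is drawn
#' uniformly. The manifest's `s_nuclei` column carries the exact
#' ground-truth nuclei score; noisy annotator columns can be added with
#' `annotate = TRUE`.
#'
#' @param n Number of samples.
#' @param out_dir Output directory (created if needed).
#' @param strata Marginal strata shares, see [strata_epidermis_cohort()].
#' @param config_template An [generator_config()] providing geometry and
#'   rendering parameters; per-sample seed and damage settings are filled
#'   in by the generator.
#' @param seed Master seed for the whole dataset.
#' @param annotate If `TRUE`, add `s_nuclei_annot` / `s_nuclei_annot2`
#'   columns from two independent simulated annotators.
#' @param annotator An [annotator_config()] used when `annotate = TRUE`.
#' @return The written `epiderm_manifest` (invisibly reloadable from
#'   `file.path(out_dir, "manifest.csv")`).
#' @export
generate_dataset <- function(n, out_dir, strata = strata_epidermis_cohort(),
                             config_template = generator_config(), seed = 42L,
                             annotate = FALSE, annotator = annotator_config()) {
  stopifnot(n >= 1)
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) ep_stop("cannot create output directory", "epiderm_io_error")

  tissue <- rep(names(strata$tissue), allocate_counts(n, strata$tissue))
  staining <- rep(names(strata$staining), allocate_counts(n, strata$staining))
  n_seg <- allocate_counts(n, c(strata$has_segmentation, 1 - strata$has_segmentation))[1]

  with_seed(seed, {
    staining <- sample(staining)           # decorrelate the two margins
    has_seg <- sample(rep(c(TRUE, FALSE), c(n_seg, n - n_seg)))
    comp <- sample.int(3, n, replace = TRUE, prob = c(0.35, 0.40, 0.25))
    dmg <- ifelse(comp == 1, stats::rbeta(n, 1.5, 6),
           ifelse(comp == 2, stats::runif(n), stats::rbeta(n, 6, 1.5)))
    het <- stats::runif(n)
    sample_seeds <- sample.int(.Machine$integer.max, n)
  })

  ids <- sprintf("S%04d", seq_len(n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config_template
    cfg$seed <- sample_seeds[i]
    cfg$target_damage_fraction <- dmg[i]
    cfg$heterogeneity <- het[i]
    smp <- generate_sample(cfg)
    img_rel <- file.path("images", paste0(ids[i], ".png"))
    png::writePNG(smp$image / 255, file.path(out_dir, img_rel))
    mask_rel <- NA_character_
    s_area <- NA_real_
    if (has_seg[i]) {
      mask_rel <- file.path("masks", paste0(ids[i], "_mask.png"))
      write_mask(smp$mask, file.path(out_dir, mask_rel))
      s_area <- smp$true_scores$s_area
    }
    rows[[i]] <- data.frame(
      sample_id = ids[i], image_path = img_rel, tissue = tissue[i],
      staining = staining[i], s_nuclei = smp$true_scores$s_nuclei,
      mask_path = mask_rel, s_area = s_area,
      heterogeneity = smp$heterogeneity_value,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  if (annotate) {
    cfg1 <- annotator; cfg1$seed <- seed + 101L
    cfg2 <- annotator; cfg2$seed <- seed + 202L
    df$s_nuclei_annot <- simulate_annotator(df$s_nuclei, df$heterogeneity, cfg1)
    df$s_nuclei_annot2 <- simulate_annotator(df$s_nuclei, df$heterogeneity, cfg2)
  }
  man <- new_manifest(df, config_template$resolution_um_per_px,
                      config_template$height_px, config_template$width_px,
                      base_dir = out_dir)
  write_manifest(man, file.path(out_dir, "manifest.csv"))
  load_manifest(file.path(out_dir, "manifest.csv"))
}
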