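#' Phantom generator configuration
#'
#' Parameters of the synthetic shoulder-MRI-like phantom: a single
#' connected, elongated crescent target (emulating the coronal course of
#' the supraspinatus) on a darker background, surrounded by distractor
#' structures whose intensity sits within `contrast` grey levels of the
#' target's, plus additive Gaussian noise. Subjects contribute small stacks
#' of correlated slices, as in a clinical acquisition where a few informative
#' slices are kept per sequence.
#'
#' @param image_size Pixels per side; must be >= 32 and divisible by 32
#'   (the encoder downsamples by a total stride of 32). 512 matches the
#'   clinical export; 128 is a convenient test size.
#' @param target_area_frac Closed interval of allowed mask-area fraction.
#' @param contrast Mean intensity gap between target and distractors
#'   (8-bit units); 255 pushes distractors to the background level.
#' @param noise_sigma Additive Gaussian noise standard deviation (8-bit units).
#' @param n_distractors Number of non-target structures; the first one is
#'   placed abutting the target boundary to exercise the blurred-boundary
#'   failure mode.
#' @param slices_per_subject Integer range (low, high) of slices per subject.
#' @param seed Integer seed for [generate_dataset()].
#' @return A `museg_phantom_config` list.
#' @export
phantom_config <- function(image_size = 512L, target_area_frac = c(0.02, 0.10),
                           contrast = 25, noise_sigma = 8, n_distractors = 3L,
                           slices_per_subject = c(3L, 5L), seed = 1L) {
  if (image_size < 32 || image_size %% 32 != 0) {
    stop("image_size must be >= 32 and divisible by 32: the encoder ",
         "downsamples by a total stride of 32")
  }
  if (length(target_area_frac) != 2 || target_area_frac[1] <= 0 ||
      target_area_frac[1] > target_area_frac[2] || target_area_frac[2] >= 1) {
    stop("target_area_frac must satisfy 0 < low <= high < 1")
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (n_distractors < 0) stop("n_distractors must be >= 0")
  if (length(slices_per_subject) != 2 || slices_per_subject[1] < 1 ||
      slices_per_subject[1] > slices_per_subject[2]) {
    stop("slices_per_subject must be an increasing integer range >= 1")
  }
  structure(list(image_size = as.integer(image_size),
                 target_area_frac = as.numeric(target_area_frac),
                 contrast = as.numeric(contrast),
                 noise_sigma = as.numeric(noise_sigma),
                 n_distractors = as.integer(n_distractors),
                 slices_per_subject = as.integer(slices_per_subject),
                 seed = as.integer(seed)),
            class = "museg_phantom_config")
}

#' 4-connected component labelling
#'
#' @param mask Binary matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  cpp_label4(matrix(as.integer(mask != 0), nrow = nrow(mask)))
}

# Rasterize a crescent: ellipse E1 minus an offset, slightly widened ellipse
# E2, both rotated by theta about (cx, cy).
crescent_mask <- function(S, cx, cy, a, b, off, theta) {
  X <- matrix(rep(seq_len(S), each = S), nrow = S)   # column coordinate
  Y <- matrix(rep(seq_len(S), times = S), nrow = S)  # row coordinate
  u <- cos(theta) * (X - cx) + sin(theta) * (Y - cy)
  v <- -sin(theta) * (X - cx) + cos(theta) * (Y - cy)
  e1 <- (u / a)^2 + (v / b)^2 <= 1
  e2 <- (u / (1.1 * a))^2 + ((v + off) / b)^2 <= 1
  (e1 & !e2) * 1L
}

ellipse_mask <- function(S, cx, cy, a, b, theta) {
  X <- matrix(rep(seq_len(S), each = S), nrow = S)
  Y <- matrix(rep(seq_len(S), times = S), nrow = S)
  u <- cos(theta) * (X - cx) + sin(theta) * (Y - cy)
  v <- -sin(theta) * (X - cx) + cos(theta) * (Y - cy)
  ((u / a)^2 + (v / b)^2 <= 1) * 1L
}

mask_valid <- function(mask, cfg) {
  frac <- sum(mask) / length(mask)
  if (frac < cfg$target_area_frac[1] || frac > cfg$target_area_frac[2]) return(FALSE)
  max(label_components(mask)) == 1L
}

# Draw base crescent parameters until the rasterized mask satisfies the
# single-component and area-fraction invariants.
draw_base_shape <- function(cfg) {
  S <- cfg$image_size
  lo <- cfg$target_area_frac[1]; hi <- cfg$target_area_frac[2]
  for (try in 1:200) {
    f_t <- stats::runif(1, lo + 0.15 * (hi - lo), hi - 0.15 * (hi - lo))
    a <- stats::runif(1, 0.26, 0.36) * S
    b <- min(max(f_t * S^2 / (0.45 * pi * a), 2), 0.45 * a)
    off <- stats::runif(1, 0.6, 1.0) * b
    theta <- stats::runif(1, -25, 25) * pi / 180
    cx <- stats::runif(1, 0.42, 0.58) * S
    cy <- stats::runif(1, 0.42, 0.58) * S
    pars <- list(cx = cx, cy = cy, a = a, b = b, off = off, theta = theta)
    mask <- do.call(crescent_mask, c(list(S = S), pars))
    if (mask_valid(mask, cfg)) return(list(pars = pars, mask = mask))
  }
  stop("phantom generator could not satisfy the mask invariants for ",
       "target_area_frac [", lo, ", ", hi, "] at size ", S)
}

jitter_shape <- function(pars, S) {
  sc <- stats::runif(1, 0.95, 1.05)
  list(cx = pars$cx + stats::runif(1, -0.02, 0.02) * S,
       cy = pars$cy + stats::runif(1, -0.02, 0.02) * S,
       a = pars$a * sc, b = pars$b * sc,
       off = pars$off * stats::runif(1, 0.95, 1.05),
       theta = pars$theta + stats::runif(1, -5, 5) * pi / 180)
}

# Boundary pixels of a binary mask (foreground with a 4-neighbor outside).
boundary_pixels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  inner <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  which(mask == 1L & !inner, arr.ind = TRUE)
}

render_slice <- function(cfg, pars, mask, mu_t, mu_bg) {
  S <- cfg$image_size
  mu_d <- min(max(mu_t - cfg$contrast, 0), 255)
  gray <- matrix(mu_bg, S, S)
  if (cfg$n_distractors > 0) {
    for (k in seq_len(cfg$n_distractors)) {
      ra <- stats::runif(1, 0.06, 0.12) * S
      rb <- stats::runif(1, 0.04, 0.09) * S
      th <- stats::runif(1, 0, pi)
      if (k == 1) {
        bp <- boundary_pixels(mask)
        p <- bp[sample.int(nrow(bp), 1), ]
        dirv <- c(p[2] - pars$cx, p[1] - pars$cy)
        nv <- sqrt(sum(dirv^2)); if (nv < 1e-9) dirv <- c(1, 0) else dirv <- dirv / nv
        cx <- p[2] + dirv[1] * (rb + 1)
        cy <- p[1] + dirv[2] * (rb + 1)
        th <- atan2(dirv[2], dirv[1]) + pi / 2
      } else {
        cx <- stats::runif(1, 0.1, 0.9) * S
        cy <- stats::runif(1, 0.1, 0.9) * S
      }
      dm <- ellipse_mask(S, cx, cy, ra, rb, th)
      gray[dm == 1L & mask == 0L] <- mu_d
    }
  }
  gray[mask == 1L] <- mu_t
  img <- array(0L, c(S, S, 3L))
  choff <- sample(-2:2, 3, replace = TRUE)
  for (ch in 1:3) {
    plane <- gray + choff[ch]
    if (cfg$noise_sigma > 0) plane <- plane + stats::rnorm(S * S, 0, cfg$noise_sigma)
    img[, , ch] <- matrix(as.integer(pmin(pmax(round(plane), 0), 255)), S, S)
  }
  img
}

#' Generate the slices of one synthetic subject
#'
#' Draws a base crescent shape and intensity profile for the subject, then
#' renders 3-5 slices (per `slices_per_subject`) as shift/scale/intensity
#' perturbations of that base, so slices of one subject are correlated -
#' the property that makes subject-level splitting matter.
#'
#' @param config A `museg_phantom_config`.
#' @param subject_id Subject identifier string.
#' @param seed Integer seed; `NULL` continues from the current RNG state.
#' @return List of samples, each with `image` (8-bit HxWx3 integer array),
#'   `mask` (binary HxW matrix, one 4-connected component with area
#'   fraction inside the configured interval), `subject_id`, `slice_index`.
#' @export
generate_subject <- function(config, subject_id, seed = NULL) {
  stopifnot(inherits(config, "museg_phantom_config"))
  if (!is.null(seed)) set.seed(seed)
  base <- draw_base_shape(config)
  mu_t <- stats::runif(1, 200, 240)
  mu_bg <- stats::runif(1, 20, 50)
  slice_choices <- config$slices_per_subject[1]:config$slices_per_subject[2]
  n_slices <- slice_choices[sample.int(length(slice_choices), 1)]
  out <- vector("list", n_slices)
  for (s in seq_len(n_slices)) {
    mask <- NULL
    for (try in 1:50) {
      pars <- jitter_shape(base$pars, config$image_size)
      cand <- do.call(crescent_mask, c(list(S = config$image_size), pars))
      if (mask_valid(cand, config)) { mask <- cand; break }
    }
    if (is.null(mask)) { pars <- base$pars; mask <- base$mask }
    mu_ts <- min(max(mu_t + stats::runif(1, -5, 5), 0), 255)
    img <- render_slice(config, pars, mask, mu_ts, mu_bg)
    out[[s]] <- list(image = img, mask = mask, subject_id = subject_id,
                     slice_index = s)
  }
  out
}

#' Generate a multi-subject phantom dataset
#'
#' @param config A `museg_phantom_config`.
#' @param n_subjects Number of subjects (>= 1). Each subject gets a
#'   deterministic seed derived from `config$seed`.
#' @return A `museg_dataset`: `samples` (flat list) and `manifest`
#'   (data frame with subject_id, slice_index, image_path, mask_path;
#'   paths are filled by [write_dataset()]).
#' @export
generate_dataset <- function(config, n_subjects) {
  stopifnot(inherits(config, "museg_phantom_config"))
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    stop("n_subjects must be >= 1")
  }
  n_subjects <- as.integer(n_subjects)
  samples <- list()
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("subj%03d", i)
    seed_i <- (config$seed + i * 7919L) %% 2147483647L
    samples <- c(samples, generate_subject(config, sid, seed = seed_i))
  }
  manifest <- data.frame(
    subject_id = vapply(samples, `[[`, character(1), "subject_id"),
    slice_index = vapply(samples, `[[`, integer(1), "slice_index"),
    image_path = NA_character_, mask_path = NA_character_,
    stringsAsFactors = FALSE
  )
  structure(list(samples = samples, manifest = manifest, config = config),
            class = "museg_dataset")
}

#' Write a phantom dataset to disk
#'
#' Images as 8-bit RGB PNG, masks as 8-bit grayscale PNG with values
#' \{0, 255\}, and a CSV manifest.
#'
#' @param dataset A `museg_dataset`.
#' @param out_dir Output directory (created if missing).
#' @return The manifest data frame with paths filled in (also written to
#'   `manifest.csv`).
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "museg_dataset"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    stem <- sprintf("%s_slice%02d", s$subject_id, s$slice_index)
    ip <- file.path(out_dir, paste0(stem, ".png"))
    mp <- file.path(out_dir, paste0(stem, "_mask.png"))
    write_image(s$image, ip)
    write_mask(s$mask, mp)
    man$image_path[i] <- ip
    man$mask_path[i] <- mp
  }
  write_manifest(man, file.path(out_dir, "manifest.csv"))
  man
}
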