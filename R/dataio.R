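#' Read an image / mask PNG
#'
#' `read_image` returns an 8-bit HxWx3 integer array, replicating
#' single-channel files across three channels and dropping an alpha
#' channel. `read_mask` binarizes at grey level 128 (pixel >= 128 -> 1),
#' tolerating anti-aliased hand annotations.
#'
#' @param path Path to a PNG file.
#' @return `read_image`: HxWx3 integer array in \[0, 255\];
#'   `read_mask`: binary HxW integer matrix.
#' @export
read_image <- function(path) {
  x <- read_png_checked(path)
  x8 <- round(x * 255)
  if (length(dim(x8)) == 2) {
    out <- array(as.integer(x8), c(dim(x8), 3L))
  } else {
    if (dim(x8)[3] >= 3) x8 <- x8[, , 1:3, drop = FALSE]
    else x8 <- array(rep(x8[, , 1], 3), c(dim(x8)[1:2], 3L))
    out <- array(as.integer(x8), dim(x8))
  }
  out
}

#' @rdname read_image
#' @export
read_mask <- function(path) {
  x <- read_png_checked(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  matrix(as.integer(round(x * 255) >= 128), nrow = nrow(x))
}

read_png_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tryCatch(png::readPNG(path), error = function(e) {
    stop("format error: ", path, " is not a decodable 8-bit PNG (",
         conditionMessage(e), ")")
  })
}

#' Write an image / mask PNG
#'
#' Images are written as 8-bit RGB; masks as 8-bit grayscale with values
#' \{0, 255\}.
#'
#' @param image 8-bit HxWx3 array.
#' @param mask Binary HxW matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname write_image
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask %in% c(0, 1)))
  png::writePNG(matrix(as.numeric(mask), nrow = nrow(mask)), path)
  invisible(path)
}

## --- manifests --------------------------------------------------------------

manifest_cols <- c("subject_id", "slice_index", "image_path", "mask_path")

#' Read / write a dataset manifest
#'
#' A manifest is a CSV with columns subject_id, slice_index, image_path,
#' mask_path; (subject_id, slice_index) pairs must be unique and the
#' referenced files must exist at load time.
#'
#' @param path CSV path.
#' @param check_paths Verify that referenced image/mask files exist.
#' @param manifest Manifest data frame.
#' @return `read_manifest`: the manifest data frame.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(manifest_cols %in% names(man))) {
    stop("manifest must have columns ", paste(manifest_cols, collapse = ", "))
  }
  if (anyDuplicated(man[, c("subject_id", "slice_index")])) {
    stop("manifest has duplicated (subject_id, slice_index) pairs")
  }
  if (check_paths) {
    missing <- c(man$image_path, man$mask_path)
    missing <- missing[!is.na(missing) & !file.exists(missing)]
    if (length(missing)) {
      stop("manifest references missing files, e.g. ", missing[1])
    }
  }
  man
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  if (!all(manifest_cols %in% names(manifest))) {
    stop("manifest must have columns ", paste(manifest_cols, collapse = ", "))
  }
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Load the samples a manifest points at
#'
#' @param manifest Manifest data frame with valid paths.
#' @return List of samples (image, mask, subject_id, slice_index).
#' @export
load_samples <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) {
    list(image = read_image(manifest$image_path[i]),
         mask = read_mask(manifest$mask_path[i]),
         subject_id = manifest$subject_id[i],
         slice_index = manifest$slice_index[i])
  })
}

## --- subject-level split ----------------------------------------------------

#' Split specification
#'
#' @param train,val,test Nonnegative fractions summing to 1.
#' @param seed Integer seed for the subject shuffle.
#' @return A `museg_split_spec`.
#' @export
split_spec <- function(train = 0.70, val = 0.15, test = 0.15, seed = 1L) {
  f <- c(train, val, test)
  if (any(f < 0) || any(f > 1)) stop("split fractions must lie in [0, 1]")
  if (abs(sum(f) - 1) > 1e-9) stop("split fractions must sum to 1")
  structure(list(fractions = f, seed = as.integer(seed)),
            class = "museg_split_spec")
}

# Largest-remainder apportionment of n items to fractions; ties broken by
# split order (train, val, test).
largest_remainder <- function(n, fractions) {
  exact <- fractions * n
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(-(exact - base), seq_along(fractions))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Subject-level train/validation/test split
#'
#' Subjects (not slices) are shuffled with the spec seed and partitioned by
#' the fractions with largest-remainder rounding; all slices of a subject
#' travel together, so no subject appears in two splits - the evaluation
#' hygiene rule that prevents intra-subject leakage.
#'
#' @param manifest Manifest data frame (>= 3 subjects).
#' @param spec A `museg_split_spec`.
#' @return List of three manifests: `train`, `val`, `test`.
#' @export
split_by_subject <- function(manifest, spec = split_spec()) {
  stopifnot(inherits(spec, "museg_split_spec"))
  subjects <- unique(manifest$subject_id)
  if (length(subjects) < 3) {
    stop("need at least 3 subjects to split, got ", length(subjects))
  }
  set.seed(spec$seed)
  shuffled <- sample(subjects)
  counts <- largest_remainder(length(subjects), spec$fractions)
  if (any(counts == 0)) {
    stop("a split would be empty under fractions (",
         paste(spec$fractions, collapse = ", "), ") with ", length(subjects),
         " subjects; use more subjects")
  }
  cut <- cumsum(counts)
  groups <- list(train = shuffled[seq_len(cut[1])],
                 val = shuffled[(cut[1] + 1):cut[2]],
                 test = shuffled[(cut[2] + 1):cut[3]])
  lapply(groups, function(g) manifest[manifest$subject_id %in% g, , drop = FALSE])
}

## --- augmentation -----------------------------------------------------------

rot90_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

rotate_mat <- function(m, deg) {
  deg <- deg %% 360
  if (deg %% 90 == 0) {
    k <- deg %/% 90
    if (k > 0) for (i in seq_len(k)) m <- rot90_cw(m)
    return(m)
  }
  # nearest-neighbor inverse mapping about the center (non-right angles)
  H <- nrow(m); W <- ncol(m)
  th <- -deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  X <- matrix(rep(seq_len(W), each = H), nrow = H)
  Y <- matrix(rep(seq_len(H), times = W), nrow = H)
  sx <- round(cos(th) * (X - cx) - sin(th) * (Y - cy) + cx)
  sy <- round(sin(th) * (X - cx) + cos(th) * (Y - cy) + cy)
  ok <- sx >= 1 & sx <= W & sy >= 1 & sy <= H
  out <- matrix(0, H, W)
  out[ok] <- m[cbind(sy[ok], sx[ok])]
  out
}

apply_geom <- function(x, f) {
  if (is.matrix(x)) return(f(x))
  planes <- lapply(seq_len(dim(x)[3]), function(c) f(x[, , c]))
  out <- array(0, c(dim(planes[[1]]), length(planes)))
  for (c in seq_along(planes)) out[, , c] <- planes[[c]]
  if (is.integer(x)) out <- array(as.integer(out), dim(out))
  out
}

#' Geometric transforms applied identically to image and mask
#'
#' @param sample A sample with `$image` and `$mask`.
#' @param deg Rotation angle in degrees (multiples of 90 are exact; other
#'   angles use nearest-neighbor resampling).
#' @return The transformed sample.
#' @export
rotate_sample <- function(sample, deg = 90) {
  sample$image <- apply_geom(sample$image, function(m) rotate_mat(m, deg))
  sample$mask <- apply_geom(sample$mask, function(m) rotate_mat(m, deg))
  if (is.matrix(sample$mask)) sample$mask <- matrix(as.integer(sample$mask != 0),
                                                    nrow = nrow(sample$mask))
  sample
}

#' @rdname rotate_sample
#' @param axis `"horizontal"` (mirror left-right) or `"vertical"`
#'   (mirror top-bottom).
#' @export
flip_sample <- function(sample, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  f <- if (axis == "horizontal") {
    function(m) m[, ncol(m):1, drop = FALSE]
  } else {
    function(m) m[nrow(m):1, , drop = FALSE]
  }
  sample$image <- apply_geom(sample$image, f)
  sample$mask <- apply_geom(sample$mask, f)
  sample
}

#' Threefold augmentation
#'
#' Expands the corpus exactly 3x: each input contributes itself, a rotated
#' copy, and a flipped copy, with the identical geometric transform applied
#' to image and mask. The flip axis alternates with the sample index so
#' both horizontal and vertical flips occur in the corpus; each output
#' carries an `$augment` tag recording its transform.
#'
#' @param samples List of samples with paired `$image` and `$mask`.
#' @param rotation_deg Rotation angle (default 90, which is mask-exact).
#' @return List of `3 * length(samples)` samples.
#' @export
augment_threefold <- function(samples, rotation_deg = 90) {
  out <- vector("list", 3L * length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    if (is.null(s$image) || is.null(s$mask) ||
        !identical(dim(s$image)[1:2], dim(s$mask)[1:2])) {
      stop("pairing error: sample ", i, " lacks a matched image/mask pair")
    }
    s$augment <- "original"
    r <- rotate_sample(s, rotation_deg)
    r$augment <- paste0("rot", rotation_deg)
    axis <- if (i %% 2 == 1) "horizontal" else "vertical"
    fl <- flip_sample(s, axis)
    fl$augment <- paste0(substr(axis, 1, 1), "flip")
    out[[3 * i - 2]] <- s
    out[[3 * i - 1]] <- r
    out[[3 * i]] <- fl
  }
  out
}

#' Convert an 8-bit image to network input
#'
#' @param image 8-bit HxWx3 array with H, W divisible by 32.
#' @return Channels-first (3, H, W) double array scaled to \[0, 1\].
#' @export
to_model_input <- function(image) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) stop("expected an 8-bit HxWx3 image array")
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0) {
    stop("input-size error: image dims (", d[1], " x ", d[2],
         ") must be divisible by 32")
  }
  aperm(image, c(3, 1, 2)) / 255
}
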