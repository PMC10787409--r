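# Independent oracles used across tests. These deliberately avoid the
# package's own compiled kernels.

# Connected-component labelling by iterative label propagation (4-neighbor
# minimum until fixpoint) - independent of the package's flood fill.
label4_oracle <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(seq_len(H * W), H, W)
  lab[mask == 0] <- 0L
  repeat {
    new <- lab
    up <- rbind(Inf, lab[-H, , drop = FALSE])
    dn <- rbind(lab[-1, , drop = FALSE], Inf)
    lf <- cbind(Inf, lab[, -W, drop = FALSE])
    rt <- cbind(lab[, -1, drop = FALSE], Inf)
    for (nb in list(up, dn, lf, rt)) {
      cand <- nb > 0 & nb < new & new > 0
      new[cand] <- nb[cand]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  length(unique(lab[lab > 0]))
}

# Brute-force per-pixel confusion tally.
confusion_oracle <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j]; t <- truth[i, j]
    if (p == 1 && t == 1) tp <- tp + 1
    else if (p == 1 && t == 0) fp <- fp + 1
    else if (p == 0 && t == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Direct convolution, quadruple loop.
conv_oracle <- function(x, w, b, s, p, d) {
  dx <- dim(x); dw <- dim(w)
  H <- dx[1]; W <- dx[2]; C <- dx[3]; N <- dx[4]
  KH <- dw[1]; KW <- dw[2]; Cout <- dw[4]
  Ho <- (H + 2 * p - (d * (KH - 1) + 1)) %/% s + 1
  Wo <- (W + 2 * p - (d * (KW - 1) + 1)) %/% s + 1
  y <- array(0, c(Ho, Wo, Cout, N))
  for (n in 1:N) for (co in 1:Cout) for (wo in 1:Wo) for (ho in 1:Ho) {
    acc <- if (length(b)) b[co] else 0
    for (ci in 1:C) for (kw in 1:KW) for (kh in 1:KH) {
      hi <- (ho - 1) * s - p + (kh - 1) * d + 1
      wi <- (wo - 1) * s - p + (kw - 1) * d + 1
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
        acc <- acc + x[hi, wi, ci, n] * w[kh, kw, ci, co]
      }
    }
    y[ho, wo, co, n] <- acc
  }
  y
}

# Small phantom configuration used by many tests.
tiny_phantom_config <- function(...) {
  phantom_config(image_size = 64L, noise_sigma = 2, contrast = 60,
                 n_distractors = 2L, slices_per_subject = c(2L, 2L), seed = 5L, ...)
}

# Easy, high-contrast samples a small model can fit quickly.
easy_samples <- function(n_subjects, size = 64L, slices = 2L, seed = 7L,
                         contrast = 255, noise = 0) {
  cfg <- phantom_config(image_size = size, contrast = contrast,
                        noise_sigma = noise, n_distractors = 0L,
                        slices_per_subject = c(slices, slices), seed = seed)
  generate_dataset(cfg, n_subjects)$samples
}

# Channel-mean midpoint thresholding - the classical segmenter the
# noiseless phantom limit is calibrated against.
threshold_segmenter <- function(image, cutoff = NULL) {
  g <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  if (is.null(cutoff)) cutoff <- (min(g) + max(g)) / 2
  (g >= cutoff) * 1L
}
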