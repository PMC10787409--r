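#' Model configuration
#'
#' Describes one variant of the segmentation network: a LinkNet-style
#' residual encoder-decoder with optional squeeze-excitation channel
#' attention on the skip connections and an optional DenseASPP bridge
#' between encoder and decoder.
#'
#' @param encoder_depth Residual encoder depth, 18 or 34 (block counts
#'   (2,2,2,2) and (3,4,6,3) respectively).
#' @param use_attention Apply channel attention to each skip feature
#'   immediately before fusion with the decoder.
#' @param use_denseaspp Insert the densely connected atrous pyramid bridge
#'   at the bottleneck.
#' @param attention_reduction Squeeze-excitation bottleneck reduction r;
#'   must divide every skip channel count (64, 128, 256).
#' @param dilation_rates Strictly increasing dilation rates of the DenseASPP
#'   branches.
#' @param in_channels,out_channels Input image channels and output map
#'   channels (single logistic map).
#' @param aspp_reduce,aspp_growth Channel budget of each DenseASPP branch:
#'   the 1x1 reduction width and the 3x3 atrous output width.
#' @return A `museg_config` list.
#' @export
model_config <- function(encoder_depth = 34L, use_attention = TRUE,
                         use_denseaspp = TRUE, attention_reduction = 16L,
                         dilation_rates = c(3L, 6L, 12L, 18L, 24L),
                         in_channels = 3L, out_channels = 1L,
                         aspp_reduce = 128L, aspp_growth = 64L) {
  if (!encoder_depth %in% c(18L, 34L)) {
    stop("encoder_depth must be 18 or 34, got ", encoder_depth)
  }
  if (length(dilation_rates) < 1 || any(dilation_rates <= 0) ||
      any(diff(dilation_rates) <= 0)) {
    stop("dilation_rates must be strictly increasing positive integers")
  }
  if (attention_reduction < 1) stop("attention_reduction must be positive")
  if (use_attention && any(c(64L, 128L, 256L) %% attention_reduction != 0)) {
    stop("attention_reduction r = ", attention_reduction,
         " must divide the skip channel counts 64, 128, 256")
  }
  structure(list(
    encoder_depth = as.integer(encoder_depth),
    use_attention = isTRUE(use_attention),
    use_denseaspp = isTRUE(use_denseaspp),
    attention_reduction = as.integer(attention_reduction),
    dilation_rates = as.integer(dilation_rates),
    in_channels = as.integer(in_channels),
    out_channels = as.integer(out_channels),
    aspp_reduce = as.integer(aspp_reduce),
    aspp_growth = as.integer(aspp_growth)
  ), class = "museg_config")
}

#' Ablation variant factory
#'
#' Maps the five ablation variant names onto model configurations:
#' `baseline` is the depth-18 encoder-decoder with neither addition,
#' `scheme1` deepens the encoder to depth 34, `scheme2` adds channel
#' attention on the skip connections, `scheme3` instead adds the DenseASPP
#' bridge, and `full` combines both additions on the depth-34 encoder.
#'
#' @param name One of `"baseline"`, `"scheme1"`, `"scheme2"`, `"scheme3"`,
#'   `"full"`.
#' @param ... Passed on to [model_config()] (e.g. custom dilation rates).
#' @return A `museg_config`.
#' @export
build_variant <- function(name, ...) {
  variants <- list(
    baseline = list(encoder_depth = 18L, use_attention = FALSE, use_denseaspp = FALSE),
    scheme1 = list(encoder_depth = 34L, use_attention = FALSE, use_denseaspp = FALSE),
    scheme2 = list(encoder_depth = 34L, use_attention = TRUE, use_denseaspp = FALSE),
    scheme3 = list(encoder_depth = 34L, use_attention = FALSE, use_denseaspp = TRUE),
    full = list(encoder_depth = 34L, use_attention = TRUE, use_denseaspp = TRUE)
  )
  if (!is.character(name) || length(name) != 1 || !name %in% names(variants)) {
    stop("unknown variant '", paste(name, collapse = ","), "'; valid names are: ",
         paste(names(variants), collapse = ", "))
  }
  do.call(model_config, c(variants[[name]], list(...)))
}

#' @export
variant_names <- function() c("baseline", "scheme1", "scheme2", "scheme3", "full")

## --- DenseASPP bridge -------------------------------------------------------

# Each branch consumes the concatenation of the block input with all previous
# branch outputs (dense connectivity), reduces channels 1x1, then applies a
# 3x3 atrous conv with padding = dilation; a final 1x1 projection restores
# the input channel count and is added residually to the input.
new_denseaspp <- function(C, rates, reduce, growth) {
  if (any(diff(rates) <= 0)) stop("DenseASPP dilation rates must be ascending")
  e <- new_layer_env("denseaspp")
  k <- length(rates)
  ch <- list()
  for (i in seq_len(k)) {
    cin_i <- C + (i - 1L) * growth
    ch[[paste0("branch", i, ".reduce")]] <- new_conv(cin_i, reduce, 1, bias = FALSE)
    ch[[paste0("branch", i, ".reduce_bn")]] <- new_bn(reduce)
    ch[[paste0("branch", i, ".reduce_relu")]] <- new_relu()
    ch[[paste0("branch", i, ".atrous")]] <-
      new_conv(reduce, growth, 3, 1, rates[i], rates[i], bias = FALSE)
    ch[[paste0("branch", i, ".atrous_bn")]] <- new_bn(growth)
    ch[[paste0("branch", i, ".atrous_relu")]] <- new_relu()
  }
  ch$proj <- new_conv(C + k * growth, C, 1, bias = FALSE)
  ch$proj_bn <- new_bn(C)
  e$children <- ch
  e$C <- C; e$k <- k; e$growth <- growth
  e$fwd <- function(x, training) {
    acc <- x
    for (i in seq_len(e$k)) {
      b <- function(part) ch[[paste0("branch", i, ".", part)]]
      r <- b("reduce_relu")$fwd(b("reduce_bn")$fwd(b("reduce")$fwd(acc, training), training), training)
      o <- b("atrous_relu")$fwd(b("atrous_bn")$fwd(b("atrous")$fwd(r, training), training), training)
      acc <- channel_cat(acc, o)
    }
    p <- ch$proj_bn$fwd(ch$proj$fwd(acc, training), training)
    pre <- p + x
    if (training) e$mask <- pre > 0
    pre[pre < 0] <- 0
    pre
  }
  e$bwd <- function(dy) {
    C <- e$C; g <- e$growth
    dpre <- dy * e$mask
    dx <- dpre
    dcat <- ch$proj$bwd(ch$proj_bn$bwd(dpre))
    dx <- dx + channel_slice(dcat, 1L, C)
    douts <- vector("list", e$k)
    for (i in seq_len(e$k)) {
      douts[[i]] <- channel_slice(dcat, C + (i - 1L) * g + 1L, C + i * g)
    }
    for (i in rev(seq_len(e$k))) {
      b <- function(part) ch[[paste0("branch", i, ".", part)]]
      dr <- b("atrous")$bwd(b("atrous_bn")$bwd(b("atrous_relu")$bwd(douts[[i]])))
      dbi <- b("reduce")$bwd(b("reduce_bn")$bwd(b("reduce_relu")$bwd(dr)))
      dx <- dx + channel_slice(dbi, 1L, C)
      if (i > 1) {
        for (j in seq_len(i - 1L)) {
          douts[[j]] <- douts[[j]] +
            channel_slice(dbi, C + (j - 1L) * g + 1L, C + j * g)
        }
      }
    }
    dx
  }
  e
}

channel_cat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

channel_slice <- function(x, from, to) {
  x[, , from:to, , drop = FALSE]
}

## --- model assembly ---------------------------------------------------------

#' Build a segmentation model
#'
#' Assembles the encoder (stride-2 stem plus four residual stages), the
#' optional channel-attention modules on the three skip connections, the
#' optional DenseASPP bridge, the four-block transposed-convolution decoder
#' with additive skip fusion, and the segmentation head ending in a logistic
#' unit. All weights are He-initialized from the current RNG (or `seed`).
#'
#' @param config A `museg_config`, e.g. from [build_variant()].
#' @param seed Optional integer seed for weight initialization.
#' @return A `museg_model` environment.
#' @export
seg_model <- function(config = model_config(), seed = NULL) {
  stopifnot(inherits(config, "museg_config"))
  if (!is.null(seed)) set.seed(seed)
  blocks <- if (config$encoder_depth == 18L) c(2L, 2L, 2L, 2L) else c(3L, 4L, 6L, 3L)
  chans <- c(64L, 128L, 256L, 512L)

  stem_conv <- new_conv(config$in_channels, 64L, 7, 2, 3, bias = FALSE)
  stem_conv$input_layer <- TRUE
  stem <- new_seq(list(conv = stem_conv, bn = new_bn(64L), relu = new_relu(),
                       pool = new_maxpool(3L, 2L, 1L)))

  make_stage <- function(cin, cout, n, stride) {
    bl <- list()
    bl[["b1"]] <- new_basic_block(cin, cout, stride)
    if (n > 1) for (i in 2:n) bl[[paste0("b", i)]] <- new_basic_block(cout, cout, 1L)
    new_seq(bl)
  }
  stages <- list(
    stage1 = make_stage(64L, chans[1], blocks[1], 1L),
    stage2 = make_stage(chans[1], chans[2], blocks[2], 2L),
    stage3 = make_stage(chans[2], chans[3], blocks[3], 2L),
    stage4 = make_stage(chans[3], chans[4], blocks[4], 2L)
  )

  attn <- NULL
  if (config$use_attention) {
    r <- config$attention_reduction
    attn <- list(skip1 = new_se(chans[1], r), skip2 = new_se(chans[2], r),
                 skip3 = new_se(chans[3], r))
  }

  bridge <- if (config$use_denseaspp) {
    new_denseaspp(chans[4], config$dilation_rates, config$aspp_reduce, config$aspp_growth)
  } else {
    new_identity()
  }

  make_dec <- function(cin, cout) {
    mid <- cin %/% 4L
    new_seq(list(
      reduce = new_conv(cin, mid, 1, bias = FALSE), reduce_bn = new_bn(mid),
      reduce_relu = new_relu(),
      up = new_convt(mid, mid, 3, 2, 1, 1, bias = FALSE), up_bn = new_bn(mid),
      up_relu = new_relu(),
      expand = new_conv(mid, cout, 1, bias = FALSE), expand_bn = new_bn(cout),
      expand_relu = new_relu()
    ))
  }
  decs <- list(block1 = make_dec(512L, 256L), block2 = make_dec(256L, 128L),
               block3 = make_dec(128L, 64L), block4 = make_dec(64L, 64L))

  head <- new_seq(list(
    up = new_convt(64L, 32L, 3, 2, 1, 1, bias = FALSE), up_bn = new_bn(32L),
    up_relu = new_relu(),
    conv = new_conv(32L, 32L, 3, 1, 1, bias = FALSE), conv_bn = new_bn(32L),
    conv_relu = new_relu(),
    out = new_conv(32L, config$out_channels, 1, bias = TRUE)
  ))

  children <- list(encoder = new_container(c(list(stem = stem), stages)))
  if (config$use_attention) children$attention <- new_container(attn)
  if (config$use_denseaspp) children$bridge <- bridge
  children$decoder <- new_container(decs)
  children$head <- head

  m <- new_layer_env("model")
  m$children <- children
  m$config <- config
  m$stem <- stem; m$stages <- stages; m$attn <- attn
  m$bridge <- bridge; m$decs <- decs; m$head <- head
  class(m) <- c("museg_model", "environment")
  m
}

check_input_dims <- function(d) {
  if (length(d) != 4) stop("expected a (H, W, C, N) array, got ", length(d), " dims")
  if (d[1] < 32 || d[2] < 32 || d[1] %% 32 != 0 || d[2] %% 32 != 0) {
    stop("input spatial dims (", d[1], " x ", d[2], ") must be divisible by 32 ",
         "(the encoder downsamples by a total stride of 32)")
  }
}

#' Run the encoder
#'
#' @param model A `museg_model`.
#' @param x Input batch, (H, W, C, N) array with H, W divisible by 32.
#' @param training Cache intermediates for backprop and use batch statistics
#'   in the normalization layers.
#' @return List with `skips` (features at 1/4, 1/8, 1/16 resolution with 64,
#'   128, 256 channels) and `bottleneck` (512 channels at 1/32 resolution).
#' @export
encode <- function(model, x, training = FALSE) {
  check_input_dims(dim(x))
  h <- model$stem$fwd(x, training)
  f1 <- model$stages$stage1$fwd(h, training)
  f2 <- model$stages$stage2$fwd(f1, training)
  f3 <- model$stages$stage3$fwd(f2, training)
  f4 <- model$stages$stage4$fwd(f3, training)
  list(skips = list(f1, f2, f3), bottleneck = f4)
}

#' Run the decoder
#'
#' Four decoder blocks (1x1 reduce, stride-2 transposed conv, 1x1 expand);
#' after blocks 1-3 the matching encoder skip - gated by channel attention
#' when the model has it - is fused by elementwise addition. The head
#' upsamples to full resolution and applies a logistic unit.
#'
#' @param model A `museg_model`.
#' @param f4p Bottleneck feature map (possibly transformed by the bridge).
#' @param skips List of the three encoder skip features.
#' @param training Caching / batch-statistics flag.
#' @return Probability map, (H, W, 1, N) with values in (0, 1).
#' @export
decode <- function(model, f4p, skips, training = FALSE) {
  gate <- function(i, f) {
    if (is.null(model$attn)) f else model$attn[[paste0("skip", i)]]$fwd(f, training)
  }
  u1 <- model$decs$block1$fwd(f4p, training)
  s3 <- gate(3, skips[[3]])
  if (!identical(dim(u1), dim(s3))) {
    stop("decoder stage 1: skip shape ", paste(dim(s3), collapse = "x"),
         " does not match upsampled shape ", paste(dim(u1), collapse = "x"))
  }
  u1 <- u1 + s3
  u2 <- model$decs$block2$fwd(u1, training) + gate(2, skips[[2]])
  u3 <- model$decs$block3$fwd(u2, training) + gate(1, skips[[1]])
  u4 <- model$decs$block4$fwd(u3, training)
  z <- model$head$fwd(u4, training)
  p <- 1 / (1 + exp(-z))
  # keep the map strictly inside (0, 1): the logistic saturates in floating
  # point for large logits
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  dim(p) <- dim(z)
  if (training) model$prob <- p
  p
}

#' Full forward pass
#'
#' @inheritParams encode
#' @return Probability map, (H, W, 1, N).
#' @export
model_forward <- function(model, x, training = FALSE) {
  enc <- encode(model, x, training)
  f4p <- model$bridge$fwd(enc$bottleneck, training)
  decode(model, f4p, enc$skips, training)
}

# Backward pass from the gradient wrt the logits; accumulates parameter
# gradients across the whole tree and returns nothing useful.
model_backward <- function(model, dz) {
  du4 <- model$head$bwd(dz)
  du3 <- model$decs$block4$bwd(du4)
  gate_bwd <- function(i, d) {
    if (is.null(model$attn)) d else model$attn[[paste0("skip", i)]]$bwd(d)
  }
  df1_skip <- gate_bwd(1, du3)
  du2 <- model$decs$block3$bwd(du3)
  df2_skip <- gate_bwd(2, du2)
  du1 <- model$decs$block2$bwd(du2)
  df3_skip <- gate_bwd(3, du1)
  db <- model$decs$block1$bwd(du1)
  df4 <- model$bridge$bwd(db)
  df3 <- model$stages$stage4$bwd(df4) + df3_skip
  df2 <- model$stages$stage3$bwd(df3) + df2_skip
  df1 <- model$stages$stage2$bwd(df2) + df1_skip
  dh <- model$stages$stage1$bwd(df1)
  model$stem$bwd(dh)
  invisible(NULL)
}

#' Apply squeeze-excitation channel attention to a feature map
#'
#' Functional form: global average pooling to a per-channel descriptor,
#' affine reduction to C/r, ReLU, affine expansion back to C, logistic
#' squashing, and channel-wise rescaling of the input. Weights are drawn
#' from the current RNG unless an existing attention layer is supplied.
#'
#' @param f Feature map, (H, W, C, N) array.
#' @param r Channel reduction; must divide C.
#' @param layer Optional existing attention layer to apply.
#' @return Gated feature map of the same shape.
#' @export
channel_attention <- function(f, r = 16L, layer = NULL) {
  d <- dim(f)
  if (length(d) != 4) stop("expected a (H, W, C, N) feature map")
  if (is.null(layer)) layer <- new_se(d[3], r)
  layer$fwd(f, FALSE)
}

#' Apply a DenseASPP bridge to a bottleneck feature map
#'
#' Functional form of the densely connected atrous pyramid: branch i
#' consumes the concatenation of the input with the outputs of branches
#' 1..i-1, and a final 1x1 projection plus residual addition restores the
#' input channel count and spatial dims. Weights are drawn from the current
#' RNG unless an existing bridge is supplied.
#'
#' @param f4 Bottleneck feature map, (H, W, C, N).
#' @param rates Ascending dilation rates.
#' @param reduce,growth Per-branch channel budget.
#' @param layer Optional existing bridge layer to apply.
#' @return Feature map of the same shape as `f4`.
#' @export
dense_aspp <- function(f4, rates = c(3L, 6L, 12L, 18L, 24L),
                       reduce = 128L, growth = 64L, layer = NULL) {
  d <- dim(f4)
  if (length(d) != 4) stop("expected a (H, W, C, N) feature map")
  if (is.null(layer)) layer <- new_denseaspp(d[3], as.integer(rates), reduce, growth)
  layer$fwd(f4, FALSE)
}

#' Count trainable parameters
#'
#' @param x A `museg_config` or `museg_model`.
#' @return Integer count of trainable scalars.
#' @export
count_params <- function(x) {
  if (inherits(x, "museg_config")) x <- seg_model(x, seed = 1L)
  stopifnot(inherits(x, "museg_model"))
  sum(vapply(collect_params(x), length, integer(1)))
}

#' @export
print.museg_model <- function(x, ...) {
  cfg <- x$config
  cat("<museg_model> depth-", cfg$encoder_depth,
      " encoder | attention: ", cfg$use_attention,
      " | DenseASPP: ", cfg$use_denseaspp,
      " | params: ", format(count_params(x), big.mark = ","), "\n", sep = "")
  invisible(x)
}
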