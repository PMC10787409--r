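#' @useDynLib museg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Minimal layer system: each primitive layer is an environment exposing
#   $fwd(x, training)  forward pass; caches what backward needs when training
#   $bwd(dy)           backward pass; accumulates parameter gradients, returns dx
#   $ptensors          names of trainable tensors (grads live in g<name>)
#   $buffers           names of non-trainable state (e.g. batch-norm running stats)
# Composite layers expose $children (a named list) instead; collection walks
# the tree and flattens names with ".". Activations are (H, W, C, N) arrays.

new_layer_env <- function(type, ptensors = character(), buffers = character()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$ptensors <- ptensors
  e$buffers <- buffers
  e
}

zero_like <- function(x) {
  if (is.matrix(x)) return(matrix(0, nrow(x), ncol(x)))
  if (is.array(x)) return(array(0, dim(x)))
  numeric(length(x))
}

init_grads <- function(e) {
  for (p in e$ptensors) assign(paste0("g", p), zero_like(get(p, envir = e)), envir = e)
  invisible(e)
}

he_init <- function(n, fan_in) stats::rnorm(n, sd = sqrt(2 / fan_in))

## --- convolution ------------------------------------------------------------

new_conv <- function(cin, cout, k, stride = 1L, pad = 0L, dil = 1L, bias = TRUE) {
  e <- new_layer_env("conv", if (bias) c("w", "b") else "w")
  e$w <- array(he_init(k * k * cin * cout, k * k * cin), dim = c(k, k, cin, cout))
  e$b <- if (bias) numeric(cout) else numeric(0)
  e$has_bias <- bias
  e$stride <- as.integer(stride); e$pad <- as.integer(pad); e$dil <- as.integer(dil)
  e$input_layer <- FALSE  # set TRUE on the stem conv to skip dx
  init_grads(e)
  e$fwd <- function(x, training) {
    if (!training) return(cpp_conv2d_fw(x, e$w, e$b, e$stride, e$pad, e$dil))
    r <- cpp_conv2d_fw_cached(x, e$w, e$b, e$stride, e$pad, e$dil)
    e$cols <- r$cols
    e$xdim <- dim(x)
    r$y
  }
  e$bwd <- function(dy) {
    g <- cpp_conv2d_bw_cached(e$cols, e$xdim, e$w, dy, e$stride, e$pad, e$dil,
                              !e$input_layer, e$has_bias)
    e$cols <- NULL
    e$gw <- e$gw + g$dw
    if (e$has_bias) e$gb <- e$gb + g$db
    g$dx
  }
  e
}

new_convt <- function(cin, cout, k, stride = 2L, pad = 1L, opad = 1L, bias = TRUE) {
  e <- new_layer_env("convt", if (bias) c("w", "b") else "w")
  e$w <- array(he_init(k * k * cin * cout, k * k * cin), dim = c(k, k, cout, cin))
  e$b <- if (bias) numeric(cout) else numeric(0)
  e$has_bias <- bias
  e$stride <- as.integer(stride); e$pad <- as.integer(pad); e$opad <- as.integer(opad)
  init_grads(e)
  e$fwd <- function(x, training) {
    if (training) e$x <- x
    cpp_convt2d_fw(x, e$w, e$b, e$stride, e$pad, e$opad)
  }
  e$bwd <- function(dy) {
    g <- cpp_convt2d_bw(e$x, e$w, dy, e$stride, e$pad, e$opad, TRUE, e$has_bias)
    e$gw <- e$gw + g$dw
    if (e$has_bias) e$gb <- e$gb + g$db
    g$dx
  }
  e
}

## --- batch normalization ----------------------------------------------------

new_bn <- function(C, momentum = 0.1, eps = 1e-5) {
  e <- new_layer_env("bn", c("gamma", "beta"), c("rmean", "rvar"))
  e$gamma <- rep(1, C); e$beta <- numeric(C)
  e$rmean <- numeric(C); e$rvar <- rep(1, C)
  e$momentum <- momentum; e$eps <- eps
  init_grads(e)
  e$fwd <- function(x, training) {
    r <- cpp_bn_fw(x, e$gamma, e$beta, e$rmean, e$rvar, e$momentum, e$eps, training)
    if (training) {
      e$x <- x; e$mean <- r$mean; e$invstd <- r$invstd
      e$rmean <- r$rmean; e$rvar <- r$rvar
    }
    r$y
  }
  e$bwd <- function(dy) {
    g <- cpp_bn_bw(e$x, e$gamma, e$mean, e$invstd, dy)
    e$ggamma <- e$ggamma + g$dgamma
    e$gbeta <- e$gbeta + g$dbeta
    g$dx
  }
  e
}

## --- pointwise and pooling --------------------------------------------------

new_relu <- function() {
  e <- new_layer_env("relu")
  e$fwd <- function(x, training) {
    if (training) e$mask <- x > 0
    y <- x
    y[y < 0] <- 0
    y
  }
  e$bwd <- function(dy) dy * e$mask
  e
}

new_maxpool <- function(k = 3L, stride = 2L, pad = 1L) {
  e <- new_layer_env("maxpool")
  e$k <- as.integer(k); e$stride <- as.integer(stride); e$pad <- as.integer(pad)
  e$fwd <- function(x, training) {
    r <- cpp_maxpool_fw(x, e$k, e$stride, e$pad)
    if (training) { e$idx <- r$idx; e$xdim <- dim(x) }
    r$y
  }
  e$bwd <- function(dy) cpp_maxpool_bw(e$idx, dy, e$xdim)
  e
}

new_identity <- function() {
  e <- new_layer_env("identity")
  e$fwd <- function(x, training) x
  e$bwd <- function(dy) dy
  e
}

## --- squeeze-excitation channel attention -----------------------------------

# Global average pool -> C/r bottleneck -> ReLU -> expand -> logistic gate,
# applied multiplicatively per channel.
new_se <- function(C, r) {
  if (C %% r != 0) {
    stop("channel attention: channel count ", C, " is not divisible by reduction r = ", r)
  }
  cr <- C %/% r
  e <- new_layer_env("se", c("w1", "b1", "w2", "b2"))
  e$w1 <- matrix(he_init(cr * C, C), cr, C); e$b1 <- numeric(cr)
  e$w2 <- matrix(he_init(C * cr, cr), C, cr); e$b2 <- numeric(C)
  init_grads(e)
  e$fwd <- function(x, training) {
    d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
    xm <- x; dim(xm) <- c(HW, C * N)
    z <- matrix(.colMeans(xm, HW, C * N), C, N)
    a1 <- pmax(e$w1 %*% z + e$b1, 0)
    g <- 1 / (1 + exp(-(e$w2 %*% a1 + e$b2)))
    y <- xm * rep(as.vector(g), each = HW)
    dim(y) <- d
    if (training) { e$x <- x; e$z <- z; e$a1 <- a1; e$g <- g }
    y
  }
  e$bwd <- function(dy) {
    d <- dim(dy); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
    dym <- dy; dim(dym) <- c(HW, C * N)
    xm <- e$x; dim(xm) <- c(HW, C * N)
    dg <- matrix(.colSums(dym * xm, HW, C * N), C, N)
    dx <- dym * rep(as.vector(e$g), each = HW)
    ds2 <- dg * e$g * (1 - e$g)
    e$gw2 <- e$gw2 + ds2 %*% t(e$a1)
    e$gb2 <- e$gb2 + rowSums(ds2)
    da1 <- crossprod(e$w2, ds2)
    ds1 <- da1 * (e$a1 > 0)
    e$gw1 <- e$gw1 + ds1 %*% t(e$z)
    e$gb1 <- e$gb1 + rowSums(ds1)
    dz <- crossprod(e$w1, ds1)
    dx <- dx + rep(as.vector(dz), each = HW) / HW
    dim(dx) <- d
    dx
  }
  e
}

## --- containers -------------------------------------------------------------

new_seq <- function(children) {
  e <- new_layer_env("seq")
  e$children <- children
  e$fwd <- function(x, training) {
    for (l in e$children) x <- l$fwd(x, training)
    x
  }
  e$bwd <- function(dy) {
    for (l in rev(e$children)) dy <- l$bwd(dy)
    dy
  }
  e
}

new_container <- function(children) {
  e <- new_layer_env("container")
  e$children <- children
  e
}

# ResNet basic block: two 3x3 convs with BN, identity or projected shortcut.
new_basic_block <- function(cin, cout, stride = 1L) {
  e <- new_layer_env("block")
  ch <- list(
    conv1 = new_conv(cin, cout, 3, stride, 1, bias = FALSE),
    bn1 = new_bn(cout),
    relu1 = new_relu(),
    conv2 = new_conv(cout, cout, 3, 1, 1, bias = FALSE),
    bn2 = new_bn(cout)
  )
  e$proj <- (stride != 1L || cin != cout)
  if (e$proj) {
    ch$sconv <- new_conv(cin, cout, 1, stride, 0, bias = FALSE)
    ch$sbn <- new_bn(cout)
  }
  e$children <- ch
  e$fwd <- function(x, training) {
    h <- ch$relu1$fwd(ch$bn1$fwd(ch$conv1$fwd(x, training), training), training)
    h <- ch$bn2$fwd(ch$conv2$fwd(h, training), training)
    s <- if (e$proj) ch$sbn$fwd(ch$sconv$fwd(x, training), training) else x
    pre <- h + s
    if (training) e$mask <- pre > 0
    pre[pre < 0] <- 0
    pre
  }
  e$bwd <- function(dy) {
    dpre <- dy * e$mask
    dh <- ch$conv1$bwd(ch$bn1$bwd(ch$relu1$bwd(ch$conv2$bwd(ch$bn2$bwd(dpre)))))
    ds <- if (e$proj) ch$sconv$bwd(ch$sbn$bwd(dpre)) else dpre
    dh + ds
  }
  e
}

## --- tree walking -----------------------------------------------------------

# Flat named list of primitive layers (depth-first, names joined with ".").
collect_layers <- function(node, prefix = "") {
  if (!is.null(node$children)) {
    out <- list()
    nm <- names(node$children)
    for (i in seq_along(node$children)) {
      p <- if (prefix == "") nm[i] else paste(prefix, nm[i], sep = ".")
      out <- c(out, collect_layers(node$children[[i]], p))
    }
    return(out)
  }
  stats::setNames(list(node), prefix)
}

# Named list of trainable tensors across the whole tree.
collect_params <- function(node) {
  layers <- collect_layers(node)
  out <- list()
  for (nm in names(layers)) {
    l <- layers[[nm]]
    for (p in l$ptensors) out[[paste(nm, p, sep = ".")]] <- get(p, envir = l)
  }
  out
}

# Trainable tensors plus buffers (for checkpointing).
collect_state <- function(node) {
  layers <- collect_layers(node)
  out <- list()
  for (nm in names(layers)) {
    l <- layers[[nm]]
    for (p in c(l$ptensors, l$buffers)) out[[paste(nm, p, sep = ".")]] <- get(p, envir = l)
  }
  out
}

set_state <- function(node, state) {
  layers <- collect_layers(node)
  for (nm in names(layers)) {
    l <- layers[[nm]]
    for (p in c(l$ptensors, l$buffers)) {
      key <- paste(nm, p, sep = ".")
      if (!key %in% names(state)) stop("checkpoint error: missing tensor ", key)
      assign(p, state[[key]], envir = l)
    }
  }
  invisible(node)
}

zero_grads <- function(node) {
  layers <- collect_layers(node)
  for (l in layers) for (p in l$ptensors) {
    assign(paste0("g", p), zero_like(get(p, envir = l)), envir = l)
  }
  invisible(node)
}
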