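# Minimal convolutional-network framework backing the conditional
# adversarial model: layer construction, forward/backward passes and an
# Adam optimiser. Feature maps are H x W x C arrays; convolution kernels
# run in compiled code (src/kernels.cpp). Batch size is 1 throughout
# (the pix2pix regime), so batch normalisation reduces to per-channel
# normalisation over the spatial dimensions; the same statistics are
# used in training and inference.

layer_conv <- function(cin, cout, k = 4, stride = 2, pad = 1) {
  list(kind = "conv",
       w = array(rnorm(k * k * cin * cout, 0, 0.02), c(k, k, cin, cout)),
       b = numeric(cout), stride = stride, pad = pad, trainable = TRUE)
}

layer_tconv <- function(cin, cout, k = 4, stride = 2, pad = 1) {
  list(kind = "transposed_conv",
       w = array(rnorm(k * k * cin * cout, 0, 0.02), c(k, k, cin, cout)),
       b = numeric(cout), stride = stride, pad = pad, trainable = TRUE)
}

layer_batchnorm <- function(c) {
  list(kind = "batchnorm", gamma = rep(1, c), beta = numeric(c),
       eps = 1e-5, trainable = TRUE)
}

layer_lrelu <- function(slope = 0.2) list(kind = "leaky_relu", slope = slope)

layer_dropout <- function(rate = 0.5) list(kind = "dropout", rate = rate)

layer_concat <- function(source) list(kind = "depth_concat", source = source)

layer_input <- function() list(kind = "image_input")

is_param_layer <- function(ly)
  ly$kind %in% c("conv", "transposed_conv", "batchnorm")

new_net <- function(layers, kind, spec = NULL) {
  structure(list(layers = layers, kind = kind, spec = spec, opt = NULL),
            class = "cbct_net")
}

#' @export
print.cbct_net <- function(x, ...) {
  np <- sum(vapply(x$layers, function(ly) {
    if (!is_param_layer(ly)) return(0L)
    if (ly$kind == "batchnorm") length(ly$gamma) * 2L
    else length(ly$w) + length(ly$b)
  }, integer(1)))
  cat(sprintf("<cbct_net:%s> %d layers, %d trainable parameters\n",
              x$kind, length(x$layers), np))
  invisible(x)
}

bn_stats <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  mu <- colMeans(m)
  v <- colMeans(m^2) - mu^2
  list(m = m, mu = mu, v = pmax(v, 0))
}

net_forward <- function(net, x, training = FALSE) {
  L <- length(net$layers)
  acts <- vector("list", L)
  extras <- vector("list", L)
  cur <- x
  for (i in seq_len(L)) {
    ly <- net$layers[[i]]
    if (ly$kind == "image_input") {
      # pass through
    } else if (ly$kind == "conv") {
      cur <- cpp_conv_fwd(cur, ly$w, ly$b, ly$stride, ly$pad)
    } else if (ly$kind == "transposed_conv") {
      cur <- cpp_tconv_fwd(cur, ly$w, ly$b, ly$stride, ly$pad)
    } else if (ly$kind == "batchnorm") {
      st <- bn_stats(cur)
      invstd <- 1 / sqrt(st$v + ly$eps)
      xhat <- sweep(sweep(st$m, 2, st$mu), 2, invstd, `*`)
      out <- sweep(sweep(xhat, 2, ly$gamma, `*`), 2, ly$beta, `+`)
      extras[[i]] <- list(xhat = xhat, invstd = invstd)
      cur <- array(out, dim(cur))
    } else if (ly$kind == "leaky_relu") {
      pos <- cur > 0
      extras[[i]] <- pos
      cur <- cur * ifelse(pos, 1, ly$slope)
    } else if (ly$kind == "dropout") {
      if (training) {
        mask <- runif(length(cur)) >= ly$rate
        extras[[i]] <- mask
        cur <- cur * mask / (1 - ly$rate)
      }
    } else if (ly$kind == "depth_concat") {
      src <- acts[[ly$source]]
      d1 <- dim(cur); d2 <- dim(src)
      extras[[i]] <- c(d1[3], d2[3])
      cur <- array(c(cur, src), c(d1[1], d1[2], d1[3] + d2[3]))
    } else stop("unknown layer kind: ", ly$kind)
    acts[[i]] <- cur
  }
  list(out = cur, acts = acts, extras = extras)
}

net_backward <- function(net, fw, dout) {
  L <- length(net$layers)
  gbuf <- vector("list", L)
  grads <- vector("list", L)
  gbuf[[L]] <- dout
  add_grad <- function(buf, g) if (is.null(buf)) g else buf + g
  for (i in L:2) {
    gi <- gbuf[[i]]
    if (is.null(gi)) next
    ly <- net$layers[[i]]
    xin <- fw$acts[[i - 1]]
    if (ly$kind == "conv") {
      bw <- cpp_conv_bwd(xin, ly$w, gi, ly$stride, ly$pad)
      grads[[i]] <- list(w = bw$dw, b = bw$db)
      gbuf[[i - 1]] <- add_grad(gbuf[[i - 1]], bw$dx)
    } else if (ly$kind == "transposed_conv") {
      bw <- cpp_tconv_bwd(xin, ly$w, gi, ly$stride, ly$pad)
      grads[[i]] <- list(w = bw$dw, b = bw$db)
      gbuf[[i - 1]] <- add_grad(gbuf[[i - 1]], bw$dx)
    } else if (ly$kind == "batchnorm") {
      ex <- fw$extras[[i]]
      d <- dim(xin)
      n <- d[1] * d[2]
      gm <- matrix(gi, n, d[3])
      dgamma <- colSums(gm * ex$xhat)
      dbeta <- colSums(gm)
      dxhat <- sweep(gm, 2, ly$gamma, `*`)
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * ex$xhat)
      dx <- sweep(
        dxhat - matrix(s1 / n, n, d[3], byrow = TRUE) -
          ex$xhat * matrix(s2 / n, n, d[3], byrow = TRUE),
        2, ex$invstd, `*`)
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
      gbuf[[i - 1]] <- add_grad(gbuf[[i - 1]], array(dx, d))
    } else if (ly$kind == "leaky_relu") {
      pos <- fw$extras[[i]]
      gbuf[[i - 1]] <- add_grad(gbuf[[i - 1]],
                                gi * ifelse(pos, 1, ly$slope))
    } else if (ly$kind == "dropout") {
      mask <- fw$extras[[i]]
      g <- if (is.null(mask)) gi else gi * mask / (1 - ly$rate)
      gbuf[[i - 1]] <- add_grad(gbuf[[i - 1]], g)
    } else if (ly$kind == "depth_concat") {
      split <- fw$extras[[i]]
      d <- dim(gi)
      g_main <- array(gi[, , seq_len(split[1]), drop = FALSE],
                      c(d[1], d[2], split[1]))
      g_src <- array(gi[, , split[1] + seq_len(split[2]), drop = FALSE],
                     c(d[1], d[2], split[2]))
      gbuf[[i - 1]] <- add_grad(gbuf[[i - 1]], g_main)
      gbuf[[ly$source]] <- add_grad(gbuf[[ly$source]], g_src)
    }
    gbuf[i] <- list(NULL)  # free without shifting indices
  }
  list(grads = grads, dx = gbuf[[1]])
}

adam_init <- function(net) {
  net$opt <- list(t = 0L, state = lapply(net$layers, function(ly) {
    if (!is_param_layer(ly)) return(NULL)
    if (ly$kind == "batchnorm")
      list(m1 = numeric(length(ly$gamma)), v1 = numeric(length(ly$gamma)),
           m2 = numeric(length(ly$beta)), v2 = numeric(length(ly$beta)))
    else
      list(m1 = array(0, dim(ly$w)), v1 = array(0, dim(ly$w)),
           m2 = numeric(length(ly$b)), v2 = numeric(length(ly$b)))
  }))
  net
}

adam_update <- function(net, grads, lr, beta1, beta2, eps = 1e-8) {
  if (is.null(net$opt)) net <- adam_init(net)
  net$opt$t <- net$opt$t + 1L
  t <- net$opt$t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  step <- function(p, g, st) {
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    p <- p - lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    list(p = p, m = st$m, v = st$v)
  }
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (!is_param_layer(ly) || !isTRUE(ly$trainable) || is.null(grads[[i]]))
      next
    st <- net$opt$state[[i]]
    if (ly$kind == "batchnorm") {
      u1 <- step(ly$gamma, grads[[i]]$gamma, list(m = st$m1, v = st$v1))
      u2 <- step(ly$beta, grads[[i]]$beta, list(m = st$m2, v = st$v2))
      ly$gamma <- u1$p; ly$beta <- u2$p
    } else {
      u1 <- step(ly$w, grads[[i]]$w, list(m = st$m1, v = st$v1))
      u2 <- step(ly$b, grads[[i]]$b, list(m = st$m2, v = st$v2))
      ly$w <- u1$p; ly$b <- u2$p
    }
    net$opt$state[[i]] <- list(m1 = u1$m, v1 = u1$v, m2 = u2$m, v2 = u2$v)
    net$layers[[i]] <- ly
  }
  net
}

combine_grads <- function(g1, g2, w1 = 0.5, w2 = 0.5) {
  lapply(seq_along(g1), function(i) {
    if (is.null(g1[[i]])) return(NULL)
    Map(function(a, b) w1 * a + w2 * b, g1[[i]], g2[[i]])
  })
}

param_layer_indices <- function(net)
  which(vapply(net$layers, is_param_layer, logical(1)))

#' Per-layer parameter checksums
#'
#' Returns an MD5 checksum of the serialised parameters of every
#' parameterised layer (convolutions, transposed convolutions, batch
#' normalisations) in topological order. Used to verify which layers a
#' transfer-learning run actually modified.
#'
#' @param model a `pix2pix` model or a raw network.
#' @return named character vector of checksums.
#' @export
layer_checksums <- function(model) {
  net <- if (inherits(model, "pix2pix")) model$generator else model
  idx <- param_layer_indices(net)
  out <- vapply(idx, function(i) {
    ly <- net$layers[[i]]
    p <- if (ly$kind == "batchnorm") list(ly$gamma, ly$beta)
         else list(ly$w, ly$b)
    fingerprint(p)
  }, character(1))
  names(out) <- sprintf("L%02d_%s", idx,
                        vapply(net$layers[idx], `[[`, "", "kind"))
  out
}

set_trainable_last <- function(net, n) {
  idx <- param_layer_indices(net)
  if (n < 1 || n > length(idx))
    stop("number of trainable parameterised layers must lie in [1, ",
         length(idx), "]")
  keep <- utils::tail(idx, n)
  for (i in idx) net$layers[[i]]$trainable <- i %in% keep
  net
}

trainable_param_layers <- function(net) {
  idx <- param_layer_indices(net)
  idx[vapply(net$layers[idx], function(ly) isTRUE(ly$trainable), logical(1))]
}
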