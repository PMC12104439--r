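# Minimal dense decoder networks with hand-written backpropagation and an
# Adam optimizer. Decoders take a 4-vector conformation input (constant
# [1,1,1,1] in single-model mode, latent coordinates padded to length 4 in
# series mode) and output transform / offset parameters. The final layer is
# initialized at zero so every decoder starts as the identity deformation.

#' Create a dense decoder network
#'
#' Four hidden layers with tanh activations and a zero-initialized linear
#' output layer.
#'
#' @param n_in input dimension (4: the conformation vector)
#' @param n_out output dimension
#' @param width hidden width
#' @param seed seed for the weight initialization
#' @return object of class `decoder`
#' @export
decoder_new <- function(n_in = 4, n_out, width = 64, seed = 1) {
  set.seed(seed)
  dims <- c(n_in, rep(width, 4), n_out)
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1)) {
    sd0 <- sqrt(1 / dims[l])
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1], 0, sd0),
                     dims[l], dims[l + 1])
    b[[l]] <- numeric(dims[l + 1])
  }
  nl <- length(W)
  W[[nl]][] <- 0                 # identity start: outputs exactly zero
  b[[nl]][] <- 0
  structure(list(W = W, b = b, n_in = n_in, n_out = n_out, width = width),
            class = "decoder")
}

#' Decoder forward pass
#' @param net a `decoder`
#' @param x input matrix (m x n_in) or vector
#' @param keep_cache keep activations for [decoder_backward()]
#' @return output matrix m x n_out (with cache attribute if requested)
#' @export
decoder_forward <- function(net, x, keep_cache = FALSE) {
  x <- rbind(x)
  h <- x
  cache <- list(h)
  nl <- length(net$W)
  for (l in seq_len(nl)) {
    z <- sweep(h %*% net$W[[l]], 2, net$b[[l]], "+")
    h <- if (l < nl) tanh(z) else z
    if (keep_cache) cache[[l + 1]] <- h
  }
  if (keep_cache) attr(h, "cache") <- cache
  h
}

#' Decoder backward pass
#' @param net a `decoder`
#' @param out forward output with cache (from `decoder_forward(..., keep_cache = TRUE)`)
#' @param dout gradient of the loss w.r.t. the output (m x n_out)
#' @return list of gradients `W`, `b` matching the network shapes
#' @export
decoder_backward <- function(net, out, dout) {
  cache <- attr(out, "cache")
  nl <- length(net$W)
  gW <- vector("list", nl); gb <- vector("list", nl)
  delta <- rbind(dout)
  for (l in rev(seq_len(nl))) {
    h_in <- cache[[l]]
    gW[[l]] <- crossprod(h_in, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- delta %*% t(net$W[[l]])
      delta <- delta * (1 - cache[[l]]^2)   # through tanh
    }
  }
  list(W = gW, b = gb)
}

#' Create an Adam optimizer state for a list of parameter arrays
#' @param params named list of numeric arrays
#' @param lr learning rate
#' @return optimizer state
#' @export
adam_new <- function(params, lr = 1e-3) {
  z <- lapply(params, function(p) p * 0)
  list(m = z, v = z, t = 0, lr = lr, b1 = 0.9, b2 = 0.999, eps = 1e-8)
}

#' One Adam update
#' @param opt optimizer state from [adam_new()]
#' @param params list of parameter arrays
#' @param grads list of gradient arrays (same shapes)
#' @return list with updated `params` and `opt`
#' @export
adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1
  c1 <- 1 - opt$b1^opt$t; c2 <- 1 - opt$b2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$b1 * opt$m[[nm]] + (1 - opt$b1) * g
    opt$v[[nm]] <- opt$b2 * opt$v[[nm]] + (1 - opt$b2) * g^2
    params[[nm]] <- params[[nm]] -
      opt$lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + opt$eps)
  }
  list(params = params, opt = opt)
}

# flatten decoder params to a named list for Adam
decoder_params <- function(net) {
  p <- list()
  for (l in seq_along(net$W)) {
    p[[paste0("W", l)]] <- net$W[[l]]
    p[[paste0("b", l)]] <- net$b[[l]]
  }
  p
}

decoder_set_params <- function(net, p) {
  for (l in seq_along(net$W)) {
    net$W[[l]] <- p[[paste0("W", l)]]
    net$b[[l]] <- p[[paste0("b", l)]]
  }
  net
}

decoder_grads_as_params <- function(g) {
  p <- list()
  for (l in seq_along(g$W)) {
    p[[paste0("W", l)]] <- g$W[[l]]
    p[[paste0("b", l)]] <- g$b[[l]]
  }
  p
}
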