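#' Autoencoder architecture and training settings
#'
#' Symmetric three-layer encoder/decoder used to compress the long, sparse
#' similarity pair vectors. The reference operating point is an input of
#' 913 (336 diseases + 577 miRNAs), a 512-unit hidden layer and a 256-unit
#' code; [scaled_autoencoder_spec()] keeps those proportions for other input
#' widths. The two intermediate layers use ReLU; the code (bottleneck) and
#' reconstruction layers are linear - a linear bottleneck recovers low-rank
#' structure that a rectified one truncates. The loss is mean squared error
#' minimised by full-batch Adam on inputs min-max scaled to \[0, 1\] per
#' coordinate.
#'
#' @param input_dim width of the input vectors.
#' @param hidden_dim units in the intermediate layer.
#' @param code_dim width of the learned code (the encoder output).
#' @param epochs full-batch Adam iterations.
#' @param learning_rate Adam step size.
#' @param seed integer seed for weight initialisation.
#' @return An object of class `"autoencoder_spec"`.
#' @export
autoencoder_spec <- function(input_dim = 913, hidden_dim = 512, code_dim = 256,
                             epochs = 200, learning_rate = 0.01, seed = 1L) {
  stopifnot(input_dim >= 1, hidden_dim >= 1, code_dim >= 1, epochs >= 1,
            learning_rate > 0)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dim = as.integer(hidden_dim),
                 code_dim = as.integer(code_dim),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "autoencoder_spec")
}

#' @rdname autoencoder_spec
#' @param base spec whose proportions and training settings to keep.
#' @export
scaled_autoencoder_spec <- function(input_dim, base = autoencoder_spec()) {
  if (input_dim == base$input_dim) return(base)
  r_h <- base$hidden_dim / base$input_dim
  r_c <- base$code_dim / base$input_dim
  autoencoder_spec(input_dim,
                   hidden_dim = max(4L, round(input_dim * r_h)),
                   code_dim = max(2L, round(input_dim * r_c)),
                   epochs = base$epochs, learning_rate = base$learning_rate,
                   seed = base$seed)
}

relu <- function(x) (x > 0) * x

ae_init <- function(spec) {
  set.seed(spec$seed)
  dims <- c(spec$input_dim, spec$hidden_dim, spec$code_dim,
            spec$hidden_dim, spec$input_dim)
  W <- vector("list", 4L); b <- vector("list", 4L)
  for (l in 1:4) {
    lim <- sqrt(6 / (dims[l] + dims[l + 1L]))  # Glorot uniform
    W[[l]] <- matrix(runif(dims[l] * dims[l + 1L], -lim, lim), dims[l], dims[l + 1L])
    b[[l]] <- rep(0, dims[l + 1L])
  }
  list(W = W, b = b)
}

ae_forward <- function(par, X) {
  H1 <- relu(sweep(X %*% par$W[[1L]], 2L, par$b[[1L]], `+`))
  C  <- sweep(H1 %*% par$W[[2L]], 2L, par$b[[2L]], `+`)  # linear bottleneck
  H3 <- relu(sweep(C %*% par$W[[3L]], 2L, par$b[[3L]], `+`))
  Xh <- sweep(H3 %*% par$W[[4L]], 2L, par$b[[4L]], `+`)
  list(H1 = H1, C = C, H3 = H3, Xh = Xh)
}

#' Fit the similarity-feature autoencoder
#'
#' Trains the encoder/decoder by full-batch Adam on the mean squared
#' reconstruction error of the min-max-scaled inputs. The per-coordinate
#' scaling learned from the training matrix is stored and re-applied to any
#' matrix passed to [encode()]/`predict()`, so held-out vectors are scaled
#' with training statistics only.
#'
#' @param X numeric matrix (rows = pair vectors) of width `spec$input_dim`.
#' @param spec an [autoencoder_spec()].
#' @return An object of class `"stim_autoencoder"` with elements `par`
#'   (weights), `scale` (per-column min/range), `spec` and `history`
#'   (per-epoch training MSE; `history[1]` is the untrained model's error).
#' @export
fit_autoencoder <- function(X, spec = autoencoder_spec()) {
  stopifnot(inherits(spec, "autoencoder_spec"))
  X <- as.matrix(X)
  if (!nrow(X)) stop2("cannot fit an autoencoder on an empty matrix")
  if (ncol(X) != spec$input_dim)
    stop2("input width ", ncol(X), " does not match spec input_dim ", spec$input_dim)

  cmin <- apply(X, 2L, min)
  crange <- apply(X, 2L, max) - cmin
  crange[crange == 0] <- 1  # constant coordinates scale to 0
  Xs <- sweep(sweep(X, 2L, cmin), 2L, crange, `/`)

  par <- ae_init(spec)
  m1 <- lapply(c(par$W, par$b), function(p) p * 0)
  m2 <- m1
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(Xs)
  history <- numeric(spec$epochs + 1L)
  history[1L] <- mean((ae_forward(par, Xs)$Xh - Xs)^2)

  for (ep in seq_len(spec$epochs)) {
    f <- ae_forward(par, Xs)
    err <- f$Xh - Xs                               # n x input
    d4 <- 2 * err / length(err)
    gW4 <- crossprod(f$H3, d4); gb4 <- colSums(d4)
    d3 <- (d4 %*% t(par$W[[4L]])) * (f$H3 > 0)
    gW3 <- crossprod(f$C, d3); gb3 <- colSums(d3)
    d2 <- d3 %*% t(par$W[[3L]])                # linear code layer
    gW2 <- crossprod(f$H1, d2); gb2 <- colSums(d2)
    d1 <- (d2 %*% t(par$W[[2L]])) * (f$H1 > 0)
    gW1 <- crossprod(Xs, d1); gb1 <- colSums(d1)

    grads <- list(gW1, gW2, gW3, gW4, gb1, gb2, gb3, gb4)
    pars <- c(par$W, par$b)
    for (p in seq_along(pars)) {
      m1[[p]] <- beta1 * m1[[p]] + (1 - beta1) * grads[[p]]
      m2[[p]] <- beta2 * m2[[p]] + (1 - beta2) * grads[[p]]^2
      mh <- m1[[p]] / (1 - beta1^ep)
      vh <- m2[[p]] / (1 - beta2^ep)
      pars[[p]] <- pars[[p]] - spec$learning_rate * mh / (sqrt(vh) + eps)
    }
    par$W <- pars[1:4]; par$b <- pars[5:8]
    history[ep + 1L] <- mean((ae_forward(par, Xs)$Xh - Xs)^2)
  }

  structure(list(par = par, scale = list(min = cmin, range = crange),
                 spec = spec, history = history),
            class = "stim_autoencoder")
}

#' @export
print.stim_autoencoder <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Autoencoder %d-%d-%d-%d-%d: training MSE %.4g -> %.4g (%d epochs)\n",
              s$input_dim, s$hidden_dim, s$code_dim, s$hidden_dim, s$input_dim,
              x$history[1L], x$history[length(x$history)], s$epochs))
  invisible(x)
}

ae_scale <- function(object, X) {
  X <- as.matrix(X)
  if (ncol(X) != object$spec$input_dim)
    stop2("input width ", ncol(X), " does not match encoder input_dim ",
          object$spec$input_dim)
  sweep(sweep(X, 2L, object$scale$min), 2L, object$scale$range, `/`)
}

#' Encode vectors with a trained autoencoder
#'
#' Applies the training-set min-max scaling and the encoder half of the
#' network. Deterministic: a pure function of the fitted weights.
#'
#' @param object a fitted [fit_autoencoder()] model.
#' @param X matrix of vectors (width = `spec$input_dim`); rownames preserved.
#' @return matrix of codes, width `spec$code_dim`.
#' @export
encode <- function(object, X) {
  stopifnot(inherits(object, "stim_autoencoder"))
  Xs <- ae_scale(object, X)
  H1 <- relu(sweep(Xs %*% object$par$W[[1L]], 2L, object$par$b[[1L]], `+`))
  C <- sweep(H1 %*% object$par$W[[2L]], 2L, object$par$b[[2L]], `+`)
  rownames(C) <- rownames(X)
  C
}

#' @export
#' @rdname encode
#' @param type `"code"` for the encoder output, `"reconstruction"` for the
#'   full autoencoder output on the \[0, 1\] scale.
#' @param ... unused.
predict.stim_autoencoder <- function(object, X, type = c("code", "reconstruction"),
                                     ...) {
  type <- match.arg(type)
  if (type == "code") return(encode(object, X))
  out <- ae_forward(object$par, ae_scale(object, X))$Xh
  rownames(out) <- rownames(X)
  out
}
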