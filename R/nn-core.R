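# Layer primitives for the two-stream network. Activations are (H, W, C, N)
# arrays; fully connected activations are (features, N) matrices. Each
# forward returns what its backward needs; backwards return gradients with
# the same shapes as their inputs/parameters.

convF <- function(x, W, stride = 1L, pad = 1L) {
  conv2d_forward_cpp(x, W, numeric(dim(W)[4]), as.integer(stride),
                     as.integer(pad))
}

convB <- function(x, W, gradOut, stride = 1L, pad = 1L) {
  conv2d_backward_cpp(x, W, gradOut, as.integer(stride), as.integer(pad))
}

# Batch normalisation over (H, W, N) per channel.
# In training mode uses batch statistics and updates the running ones;
# in eval mode uses the running statistics.
bnF <- function(x, gamma, beta, rm, rv, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  C <- d[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)  # (H*W*N) x C
  if (training) {
    mu <- colMeans(xm)
    varb <- colMeans(xm^2) - mu^2
    rm <- (1 - momentum) * rm + momentum * mu
    rv <- (1 - momentum) * rv + momentum * varb
  } else {
    mu <- rm; varb <- rv
  }
  istd <- 1 / sqrt(varb + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, istd, "*")
  ym <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  y <- aperm(array(ym, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
  list(y = y, cache = list(xhat = xhat, istd = istd, gamma = gamma, d = d,
                           training = training),
       rm = rm, rv = rv)
}

bnB <- function(gradOut, cache) {
  d <- cache$d
  gm <- matrix(aperm(gradOut, c(1, 2, 4, 3)), ncol = d[3])
  dgamma <- colSums(gm * cache$xhat)
  dbeta <- colSums(gm)
  if (cache$training) {
    m <- nrow(gm)
    t1 <- sweep(gm, 2, dbeta / m)
    t2 <- sweep(cache$xhat, 2, dgamma / m, "*")
    dxm <- sweep(t1 - t2, 2, cache$gamma * cache$istd, "*")
  } else {
    dxm <- sweep(gm, 2, cache$gamma * cache$istd, "*")
  }
  dx <- aperm(array(dxm, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

reluF <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

reluB <- function(gradOut, x) {
  gradOut * (x > 0)
}

gapF <- function(x) {
  d <- dim(x)
  apply(x, c(3, 4), mean)  # (C, N)
}

gapB <- function(gradOut, xdim) {
  HW <- xdim[1] * xdim[2]
  g <- gradOut / HW  # (C, N)
  aperm(array(rep(t(g), each = HW), dim = c(xdim[1], xdim[2], xdim[4], xdim[3])),
        c(1, 2, 4, 3))
}

linearF <- function(x, W, b) {
  # x: (in, N); W: (out, in); b: (out)
  sweep(W %*% x, 1, b, "+")
}

linearB <- function(x, W, gradOut) {
  list(dx = t(W) %*% gradOut, dW = gradOut %*% t(x), db = rowSums(gradOut))
}

# Softmax cross-entropy over columns; labels are 1-based integers.
softmaxCE <- function(logits, labels) {
  K <- nrow(logits); N <- ncol(logits)
  m <- apply(logits, 2, max)
  z <- sweep(logits, 2, m)
  ez <- exp(z)
  p <- sweep(ez, 2, colSums(ez), "/")
  picked <- p[cbind(labels, seq_len(N))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dlogits <- p
  dlogits[cbind(labels, seq_len(N))] <-
    dlogits[cbind(labels, seq_len(N))] - 1
  dlogits <- dlogits / N
  list(loss = loss, dlogits = dlogits, probs = p)
}

# He-style initialisers (draws consumed from R's RNG stream).
initConv <- function(kh, kw, cin, cout) {
  fan <- kh * kw * cin
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / fan)),
        dim = c(kh, kw, cin, cout))
}

initLinear <- function(din, dout) {
  list(W = matrix(stats::rnorm(dout * din, sd = sqrt(2 / din)), dout, din),
       b = numeric(dout))
}

# ---- Optimisers ------------------------------------------------------------

optimInit <- function(params, optimizer = "adam") {
  list(step = 0L, optimizer = optimizer,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

# One update over a named grad list; names missing from `grads` or listed in
# `frozen` are left untouched.
optimStep <- function(params, grads, state, lr, frozen = character(0),
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$step <- state$step + 1L
  t <- state$step
  for (nm in names(grads)) {
    if (nm %in% frozen) next
    g <- grads[[nm]]
    if (is.null(g)) next
    switch(state$optimizer,
      adam = {
        state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
        state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
        mhat <- state$m[[nm]] / (1 - beta1^t)
        vhat <- state$v[[nm]] / (1 - beta2^t)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      },
      nadam = {
        state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
        state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
        mhat <- state$m[[nm]] / (1 - beta1^t)
        vhat <- state$v[[nm]] / (1 - beta2^t)
        mbar <- beta1 * mhat + (1 - beta1) * g / (1 - beta1^t)
        params[[nm]] <- params[[nm]] - lr * mbar / (sqrt(vhat) + eps)
      },
      sgd = {
        state$m[[nm]] <- 0.9 * state$m[[nm]] + g
        params[[nm]] <- params[[nm]] - lr * state$m[[nm]]
      },
      rmsprop = {
        state$v[[nm]] <- 0.99 * state$v[[nm]] + 0.01 * g^2
        params[[nm]] <- params[[nm]] - lr * g / (sqrt(state$v[[nm]]) + eps)
      },
      stop("unknown optimizer: ", state$optimizer))
  }
  list(params = params, state = state)
}
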