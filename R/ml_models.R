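# Native implementations of the non-tree learners used by the ensemble:
# Gaussian process classifier (RBF kernel, Laplace approximation),
# single-hidden-layer ReLU perceptron, k-nearest-neighbour vote,
# Gaussian naive Bayes, and quadratic discriminant analysis.

# --- k-nearest neighbours ----------------------------------------------

knn_fit <- function(x, y, k = 5L) {
  structure(list(x = as.matrix(x), y = y, k = as.integer(k)),
            class = "phenoENM_knn")
}

knn_predict <- function(model, x) {
  x <- as.matrix(x)
  tr <- model$x
  k <- min(model$k, nrow(tr))
  # squared Euclidean distances, all queries at once
  d2 <- outer(rowSums(x^2), rep(1, nrow(tr))) +
    outer(rep(1, nrow(x)), rowSums(tr^2)) - 2 * x %*% t(tr)
  apply(d2, 1L, function(row) {
    nb <- order(row)[seq_len(k)]
    mean(model$y[nb])
  })
}

# --- Gaussian naive Bayes ----------------------------------------------
# Per-class, per-feature Gaussian densities with ML variance (denominator
# n_k) plus a small smoothing term for numerical safety.

nbc_fit <- function(x, y) {
  x <- as.matrix(x)
  classes <- sort(unique(y))
  stats <- lapply(classes, function(k) {
    xk <- x[y == k, , drop = FALSE]
    mu <- colMeans(xk)
    v <- colMeans(sweep(xk, 2, mu)^2)
    list(mu = mu, var = v, prior = nrow(xk) / nrow(x))
  })
  names(stats) <- classes
  eps <- 1e-9 * max(vapply(stats, function(s) max(s$var), 0), 1e-12)
  for (k in seq_along(stats)) stats[[k]]$var <- stats[[k]]$var + eps
  structure(list(stats = stats, classes = classes),
            class = "phenoENM_nbc")
}

nbc_predict <- function(model, x) {
  x <- as.matrix(x)
  loglik <- vapply(model$stats, function(s) {
    rowSums(-0.5 * log(2 * pi * rep(s$var, each = nrow(x))) -
              0.5 * sweep(x, 2, s$mu)^2 /
                rep(s$var, each = nrow(x))) + log(s$prior)
  }, numeric(nrow(x)))
  if (is.null(dim(loglik))) loglik <- matrix(loglik, nrow = 1)
  mx <- apply(loglik, 1L, max)
  post <- exp(loglik - mx)
  post <- post / rowSums(post)
  post[, which(model$classes == 1)]
}

# --- quadratic discriminant analysis -----------------------------------
# Per-class mean and full covariance; posterior by Bayes' rule.

qda_fit <- function(x, y) {
  x <- as.matrix(x)
  classes <- sort(unique(y))
  stats <- lapply(classes, function(k) {
    xk <- x[y == k, , drop = FALSE]
    if (nrow(xk) <= ncol(xk))
      stop("QDA requires more samples than features per class")
    S <- stats::cov(xk)
    ridge <- 1e-8 * mean(diag(S))
    S <- S + diag(ridge, ncol(S))
    list(mu = colMeans(xk), Sinv = solve(S),
         logdet = determinant(S, logarithm = TRUE)$modulus[1],
         prior = nrow(xk) / nrow(x))
  })
  names(stats) <- classes
  structure(list(stats = stats, classes = classes),
            class = "phenoENM_qda")
}

qda_predict <- function(model, x) {
  x <- as.matrix(x)
  disc <- vapply(model$stats, function(s) {
    xc <- sweep(x, 2, s$mu)
    -0.5 * s$logdet - 0.5 * rowSums((xc %*% s$Sinv) * xc) + log(s$prior)
  }, numeric(nrow(x)))
  if (is.null(dim(disc))) disc <- matrix(disc, nrow = 1)
  mx <- apply(disc, 1L, max)
  post <- exp(disc - mx)
  post <- post / rowSums(post)
  post[, which(model$classes == 1)]
}

# --- Gaussian process classifier ---------------------------------------
# Logistic-link GP with RBF kernel K(x, x') = a^2 exp(-|x-x'|^2 / (2 l^2)).
# The latent posterior is approximated by Laplace's method (IRLS Newton
# mode finding); the kernel scale and length are chosen by maximizing the
# approximate log marginal likelihood from a (1, 1) start. Predictive
# probabilities use the MacKay logistic-moderation approximation.

.rbf_kernel <- function(x1, x2, a2, l2) {
  d2 <- outer(rowSums(x1^2), rep(1, nrow(x2))) +
    outer(rep(1, nrow(x1)), rowSums(x2^2)) - 2 * x1 %*% t(x2)
  d2[d2 < 0] <- 0
  a2 * exp(-0.5 * d2 / l2)
}

# Laplace mode finding; returns the approximate log marginal likelihood
# and the quantities needed for prediction.
.gpc_laplace <- function(K, y, max_newton = 50L) {
  n <- length(y)
  f <- rep(0, n)
  obj_old <- -Inf
  for (it in seq_len(max_newton)) {
    pi_ <- plogis(f)
    W <- pi_ * (1 - pi_)
    sW <- sqrt(W)
    B <- diag(n) + (sW %o% sW) * K
    L <- chol(B)
    b <- W * f + (y - pi_)
    a <- b - sW * backsolve(L, forwardsolve(t(L), sW * (K %*% b)))
    f <- as.vector(K %*% a)
    obj <- -0.5 * sum(a * f) + sum(plogis((2 * y - 1) * f, log.p = TRUE))
    if (abs(obj - obj_old) < 1e-8) break
    obj_old <- obj
  }
  logZ <- obj - sum(log(diag(L)))
  list(f = f, logZ = logZ, L = L, sW = sqrt(plogis(f) * (1 - plogis(f))),
       grad = y - plogis(f))
}

gpc_fit <- function(x, y, optimize = TRUE, maxit = 40L) {
  x <- as.matrix(x)
  nll <- function(theta) {
    K <- .rbf_kernel(x, x, exp(2 * theta[1]), exp(2 * theta[2]))
    -(.gpc_laplace(K, y)$logZ)
  }
  theta <- c(0, 0)                      # a = l = 1
  if (optimize) {
    opt <- stats::optim(theta, nll, method = "Nelder-Mead",
                        control = list(maxit = maxit))
    theta <- opt$par
  }
  a2 <- exp(2 * theta[1]); l2 <- exp(2 * theta[2])
  K <- .rbf_kernel(x, x, a2, l2)
  lap <- .gpc_laplace(K, y)
  structure(list(x = x, a2 = a2, l2 = l2, lap = lap),
            class = "phenoENM_gpc")
}

gpc_predict <- function(model, x) {
  x <- as.matrix(x)
  ks <- .rbf_kernel(model$x, x, model$a2, model$l2)   # n_train x n_test
  fbar <- as.vector(t(ks) %*% model$lap$grad)
  v <- forwardsolve(t(model$lap$L), model$lap$sW * ks)
  var_f <- pmax(model$a2 - colSums(v^2), 0)
  plogis(fbar / sqrt(1 + pi * var_f / 8))
}

# --- single-hidden-layer ReLU perceptron --------------------------------
# 2 -> n_hidden -> 1 with logistic output, mean cross-entropy loss plus an
# L2 penalty alpha/(2n) * (|W1|^2 + |W2|^2), trained full-batch with Adam
# (deterministic given the seed). He-scaled Gaussian initialization.

ann_fit <- function(x, y, n_hidden = 100L, alpha = 1, max_iter = 400L,
                    lr = 0.05, tol = 1e-6, seed = 1L) {
  x <- as.matrix(x); n <- nrow(x); p <- ncol(x)
  withr::with_seed(as.integer(seed), {
    W1 <- matrix(rnorm(p * n_hidden, 0, sqrt(2 / p)), p, n_hidden)
    b1 <- rep(0, n_hidden)
    W2 <- matrix(rnorm(n_hidden, 0, sqrt(2 / n_hidden)), n_hidden, 1)
    b2 <- 0
  })
  mW1 <- vW1 <- W1 * 0; mb1 <- vb1 <- b1 * 0
  mW2 <- vW2 <- W2 * 0; mb2 <- vb2 <- 0
  beta1 <- 0.9; beta2 <- 0.999; epsn <- 1e-8
  loss_old <- Inf
  for (t in seq_len(max_iter)) {
    Z1 <- sweep(x %*% W1, 2, b1, `+`)
    H <- pmax(Z1, 0)
    z2 <- as.vector(H %*% W2) + b2
    p1 <- plogis(z2)
    loss <- -mean(y * log(pmax(p1, 1e-12)) +
                    (1 - y) * log(pmax(1 - p1, 1e-12))) +
      alpha / (2 * n) * (sum(W1^2) + sum(W2^2))
    if (abs(loss_old - loss) < tol) break
    loss_old <- loss
    d2 <- (p1 - y) / n                       # d loss / d z2
    gW2 <- t(H) %*% d2 + alpha / n * W2
    gb2 <- sum(d2)
    dH <- (d2 %o% as.vector(W2)) * (Z1 > 0)
    gW1 <- t(x) %*% dH + alpha / n * W1
    gb1 <- colSums(dH)
    upd <- function(m, v, g) {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^t); vh <- v / (1 - beta2^t)
      list(m = m, v = v, step = lr * mh / (sqrt(vh) + epsn))
    }
    u <- upd(mW1, vW1, gW1); mW1 <- u$m; vW1 <- u$v; W1 <- W1 - u$step
    u <- upd(mb1, vb1, gb1); mb1 <- u$m; vb1 <- u$v; b1 <- b1 - u$step
    u <- upd(mW2, vW2, gW2); mW2 <- u$m; vW2 <- u$v; W2 <- W2 - u$step
    u <- upd(mb2, vb2, gb2); mb2 <- u$m; vb2 <- u$v; b2 <- b2 - u$step
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2),
            class = "phenoENM_ann")
}

ann_predict <- function(model, x) {
  x <- as.matrix(x)
  H <- pmax(sweep(x %*% model$W1, 2, model$b1, `+`), 0)
  plogis(as.vector(H %*% model$W2) + model$b2)
}
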