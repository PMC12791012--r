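# Two-stream CDR3 convolutional network, implemented with vectorised
# matrix operations (BLAS-backed) and an Adam optimiser. Each stream runs
# 1-D "valid" convolutions over a one-hot CDR3 matrix; per-stream global
# pooling (masked max + masked mean over real positions, so padding never
# influences a score) feeds a shared multilayer perceptron with a
# two-logit softmax output.

#' Hyperparameters of the CDR3 convolutional network
#'
#' @param kernel_size Convolution window width (residues).
#' @param n_filters Filters per convolutional layer.
#' @param n_conv_layers 1 or 2 convolutional layers per stream.
#' @param mlp_hidden Hidden units of the classifier head.
#' @param optimizer `"adaptive"` (Adam) or `"sgd"`.
#' @param learning_rate Step size.
#' @param epochs Training epochs (desk scale; bounded at 200).
#' @param batch_size Minibatch size.
#' @param seed Integer seed governing initialisation and batch order.
#' @param residual Add a skip connection around the second convolution.
#' @param input_pool Concatenate a parameter-free composition shortcut to
#'   each stream's pooled convolutional features: the masked mean of the
#'   raw one-hot input (residue-composition fractions) plus six standard
#'   physicochemical CDR3 descriptors derived from it (net charge,
#'   positive/negative/hydrophobic/aromatic fractions, fixed-scale length).
#'   This hands the classifier head the composition statistics that govern
#'   chain-pairing biophysics directly, while the convolutions capture
#'   local motifs.
#' @return A validated `cnn_hyperparams` list.
#' @export
cnn_hyperparams <- function(kernel_size = 3, n_filters = 4,
                            n_conv_layers = 2, mlp_hidden = 256,
                            optimizer = c("adaptive", "sgd"),
                            learning_rate = 3e-3, epochs = 30,
                            batch_size = 64, seed = 1, residual = FALSE,
                            input_pool = TRUE) {
  optimizer <- match.arg(optimizer)
  stopifnot(kernel_size >= 2, n_filters >= 1, n_conv_layers %in% 1:2,
            mlp_hidden >= 1, learning_rate > 0, epochs >= 1, epochs <= 200,
            batch_size >= 1)
  structure(list(kernel_size = as.integer(kernel_size),
                 n_filters = as.integer(n_filters),
                 n_conv_layers = as.integer(n_conv_layers),
                 mlp_hidden = as.integer(mlp_hidden), optimizer = optimizer,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), residual = isTRUE(residual),
                 input_pool = isTRUE(input_pool)),
            class = "cnn_hyperparams")
}

relu <- function(x) (x > 0) * x

softmax2 <- function(logits) {
  m <- pmax(logits[, 1], logits[, 2])
  e1 <- exp(logits[, 1] - m); e2 <- exp(logits[, 2] - m)
  e2 / (e1 + e2)  # probability of the cognate class (logit index 2)
}

# unfold a sample-major position matrix (n*L rows) into convolution
# windows: returns (n*Lw) x (k*ncol) matrix, Lw = L - k + 1
unfold_windows <- function(x, n, len, k) {
  lw <- len - k + 1L
  base <- rep((seq_len(n) - 1L) * len, each = lw) + seq_len(lw)
  cols <- lapply(0:(k - 1L), function(o) x[base + o, , drop = FALSE])
  do.call(cbind, cols)
}

# flatten a (n x L x A) one-hot array to sample-major (n*L) x A matrix
flatten_stream <- function(arr) {
  d <- dim(arr)
  m <- matrix(aperm(arr, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  m
}

# physicochemical summary descriptors of a composition-fraction matrix
# (columns in aa_alphabet() order): net charge, positive, negative,
# hydrophobic and aromatic fractions, and length on a fixed scale (so
# scores are invariant to the padded width)
physchem_descriptors <- function(comp, lens) {
  aa <- aa_alphabet()
  col <- function(letters) rowSums(comp[, match(letters, aa), drop = FALSE])
  pos <- col(c("K", "R"))
  neg <- col(c("D", "E"))
  cbind(net = pos - neg, pos = pos, neg = neg,
        hyd = col(c("A", "V", "I", "L", "M", "F", "W", "C")),
        arom = col(c("F", "W", "Y")),
        len = lens / 30)
}

init_cnn_params <- function(hyper, n_in = 21L) {
  k <- hyper$kernel_size; f <- hyper$n_filters
  gauss <- function(nr, nc, fan_in) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  }
  stream <- function() {
    p <- list(K1 = gauss(k * n_in, f, k * n_in), b1 = rep(0, f))
    if (hyper$n_conv_layers == 2) {
      p$K2 <- gauss(k * f, f, k * f)
      p$b2 <- rep(0, f)
    }
    p
  }
  # masked max + masked mean per stream (+ composition shortcut)
  d_pool <- 2L * f + if (hyper$input_pool) n_in + 6L else 0L
  list(H = stream(), L = stream(),
       Wm1 = gauss(2L * d_pool, hyper$mlp_hidden, 2L * d_pool),
       bm1 = rep(0, hyper$mlp_hidden),
       Wm2 = gauss(hyper$mlp_hidden, 2L, hyper$mlp_hidden),
       bm2 = rep(0, 2))
}

# forward pass of one stream; returns pooled features and caches for
# backprop. x: (n*L) x A sample-major one-hot; lens: true CDR3 lengths.
stream_forward <- function(x, n, len, lens, params, hyper) {
  k <- hyper$kernel_size; f <- hyper$n_filters
  w1in <- unfold_windows(x, n, len, k)
  lw <- len - k + 1L
  z1 <- sweep(w1in %*% params$K1, 2, params$b1, "+")
  a1 <- relu(z1)
  if (hyper$n_conv_layers == 2) {
    w2in <- unfold_windows(a1, n, lw, k)
    lw2 <- lw - k + 1L
    z2 <- sweep(w2in %*% params$K2, 2, params$b2, "+")
    if (hyper$residual) {
      centre <- rep((seq_len(n) - 1L) * lw, each = lw2) + seq_len(lw2) +
        ((k - 1L) %/% 2L)
      z2 <- z2 + a1[centre, , drop = FALSE]
    }
    top <- relu(z2)
    valid <- pmax(lens - 2L * (k - 1L), 1L)
    lt <- lw2
  } else {
    top <- a1
    valid <- pmax(lens - (k - 1L), 1L)
    lt <- lw
  }
  # masked pooling over the first `valid[i]` window positions
  pos <- rep(seq_len(lt), n)
  grp <- rep(seq_len(n), each = lt)
  mask <- pos <= valid[grp]
  pmaxm <- matrix(-Inf, n, f)
  amax <- matrix(1L, n, f)
  for (q in seq_len(lt)) {
    rows_q <- (seq_len(n) - 1L) * lt + q
    cur <- top[rows_q, , drop = FALSE]
    cur[q > valid, ] <- -Inf
    upd <- cur > pmaxm
    amax[upd] <- q
    pmaxm[upd] <- cur[upd]
  }
  pmaxm[!is.finite(pmaxm)] <- 0
  sums <- rowsum(top * mask, grp)
  pmeanm <- sums / valid
  pooled <- cbind(pmaxm, pmeanm)
  if (hyper$input_pool) {
    posx <- rep(seq_len(len), n)
    grpx <- rep(seq_len(n), each = len)
    maskx <- posx <= lens[grpx]
    comp <- rowsum(x * maskx, grpx) / lens
    pooled <- cbind(pooled, comp, physchem_descriptors(comp, lens))
  }
  list(pooled = pooled, w1in = w1in, a1 = a1,
       w2in = if (hyper$n_conv_layers == 2) w2in else NULL,
       top = top, mask = mask, valid = valid, amax = amax,
       lw = lw, lt = lt)
}

# backprop through one stream given gradient of its pooled features;
# returns parameter gradients
stream_backward <- function(dpooled, fw, n, params, hyper) {
  k <- hyper$kernel_size; f <- hyper$n_filters
  dmax <- dpooled[, seq_len(f), drop = FALSE]
  dmean <- dpooled[, f + seq_len(f), drop = FALSE]
  lt <- fw$lt
  dtop <- matrix(0, n * lt, f)
  # mean branch: spread over valid positions
  dmean_row <- dmean / fw$valid
  dtop <- dtop + dmean_row[rep(seq_len(n), each = lt), , drop = FALSE] *
    fw$mask
  # max branch: scatter to argmax positions
  idx <- cbind(as.vector((seq_len(n) - 1L) * lt + fw$amax),
               rep(seq_len(f), each = n))
  dtop[idx] <- dtop[idx] + as.vector(dmax)
  dtop <- dtop * (fw$top > 0)
  grads <- list()
  if (hyper$n_conv_layers == 2) {
    grads$K2 <- crossprod(fw$w2in, dtop)
    grads$b2 <- colSums(dtop)
    dw2in <- dtop %*% t(params$K2)
    lw <- fw$lw
    lw2 <- lt
    base <- rep((seq_len(n) - 1L) * lw, each = lw2) + seq_len(lw2)
    da1 <- matrix(0, n * lw, f)
    for (o in 0:(k - 1L)) {
      da1[base + o, ] <- da1[base + o, ] +
        dw2in[, o * f + seq_len(f), drop = FALSE]
    }
    if (hyper$residual) {
      centre <- base + ((k - 1L) %/% 2L)
      da1[centre, ] <- da1[centre, ] + dtop
    }
    dz1 <- da1 * (fw$a1 > 0)
  } else {
    dz1 <- dtop  # relu grad already applied (top == a1)
  }
  grads$K1 <- crossprod(fw$w1in, dz1)
  grads$b1 <- colSums(dz1)
  grads
}

cnn_forward_batch <- function(xh, xl, n, dims, lens_h, lens_l, params,
                              hyper) {
  fh <- stream_forward(xh, n, dims["heavy"], lens_h, params$H, hyper)
  fl <- stream_forward(xl, n, dims["light"], lens_l, params$L, hyper)
  z <- cbind(fh$pooled, fl$pooled)
  h1 <- relu(sweep(z %*% params$Wm1, 2, params$bm1, "+"))
  logits <- sweep(h1 %*% params$Wm2, 2, params$bm2, "+")
  list(fh = fh, fl = fl, z = z, h1 = h1, logits = logits)
}

# flatten/unflatten parameter lists for the optimiser
param_names <- function(params) {
  unlist(lapply(names(params), function(nm) {
    if (is.list(params[[nm]])) paste0(nm, ".", names(params[[nm]])) else nm
  }))
}
get_param <- function(params, name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (length(parts) == 2) params[[parts[1]]][[parts[2]]] else params[[name]]
}
set_param <- function(params, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (length(parts) == 2) params[[parts[1]]][[parts[2]]] <- value
  else params[[name]] <- value
  params
}

#' Train the two-stream CDR3 convolutional classifier
#'
#' Trains the pairing classifier on one-hot CDR3 encodings by minimising
#' cross-entropy with minibatch gradient descent. The pairing score of a
#' pair is the softmax probability of the cognate class (logit index 2).
#' All randomness (initialisation, batch order) derives from the seed in
#' `hyper`; identical data and hyperparameters give identical weights.
#'
#' @param encoded An [encode_cdr3_onehot()] result.
#' @param labels Integer labels (1 = cognate, 0 = shuffled), aligned with
#'   the encoded pairs.
#' @param hyper A [cnn_hyperparams()] configuration.
#' @param scope Light-chain scope recorded on the scorer: `"all"`,
#'   `"kappa_only"` or `"lambda_only"`.
#' @param verbose Emit a message with the mean training loss per epoch.
#' @return A `pair_scorer` of scheme `cdr3_cnn`.
#' @export
train_cdr3_cnn <- function(encoded, labels, hyper = cnn_hyperparams(),
                           scope = "all", verbose = FALSE) {
  stopifnot(identical(attr(encoded, "scheme"), "cdr3_onehot"))
  n <- dim(encoded$heavy)[1]
  if (length(labels) != n) {
    stop("labels length (", length(labels), ") does not match encoded ",
         "pairs (", n, ")", call. = FALSE)
  }
  if (length(unique(labels)) < 2) {
    stop("labels are single-class; nothing to learn", call. = FALSE)
  }
  dims <- c(heavy = dim(encoded$heavy)[2], light = dim(encoded$light)[2])
  xh <- flatten_stream(encoded$heavy)
  xl <- flatten_stream(encoded$light)
  y <- as.integer(labels)
  history <- numeric(hyper$epochs)
  with_local_seed(hyper$seed, {
    params <- init_cnn_params(hyper)
    pnames <- param_names(params)
    mstate <- vstate <- setNames(vector("list", length(pnames)), pnames)
    step <- 0L
    for (epoch in seq_len(hyper$epochs)) {
      # step decay: settle into a minimum late in training
      lr <- hyper$learning_rate *
        0.3^findInterval(epoch, hyper$epochs * c(0.6, 0.85) + 1)
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / hyper$batch_size))
      losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        b <- batches[[bi]]
        nb <- length(b)
        rh <- rep((b - 1L) * dims["heavy"], each = dims["heavy"]) +
          seq_len(dims["heavy"])
        rl <- rep((b - 1L) * dims["light"], each = dims["light"]) +
          seq_len(dims["light"])
        fw <- cnn_forward_batch(xh[rh, , drop = FALSE],
                                xl[rl, , drop = FALSE], nb, dims,
                                encoded$len_heavy[b], encoded$len_light[b],
                                params, hyper)
        p <- softmax2(fw$logits)
        eps <- 1e-12
        losses[bi] <- -mean(ifelse(y[b] == 1, log(p + eps),
                                   log(1 - p + eps)))
        dlogits <- cbind((1 - p) - (1 - y[b]), p - y[b]) / nb
        grads <- list(
          Wm2 = crossprod(fw$h1, dlogits), bm2 = colSums(dlogits))
        dh1 <- (dlogits %*% t(params$Wm2)) * (fw$h1 > 0)
        grads$Wm1 <- crossprod(fw$z, dh1)
        grads$bm1 <- colSums(dh1)
        dz <- dh1 %*% t(params$Wm1)
        dp <- ncol(fw$fh$pooled)
        grads$H <- stream_backward(dz[, seq_len(dp), drop = FALSE],
                                   fw$fh, nb, params$H, hyper)
        grads$L <- stream_backward(dz[, dp + seq_len(dp), drop = FALSE],
                                   fw$fl, nb, params$L, hyper)
        step <- step + 1L
        for (nm in pnames) {
          g <- get_param(grads, nm)
          if (hyper$optimizer == "sgd") {
            params <- set_param(params, nm,
                                get_param(params, nm) - lr * g)
          } else {
            m <- mstate[[nm]]; v <- vstate[[nm]]
            if (is.null(m)) { m <- g * 0; v <- g * 0 }
            m <- 0.9 * m + 0.1 * g
            v <- 0.999 * v + 0.001 * g^2
            mstate[[nm]] <- m; vstate[[nm]] <- v
            mhat <- m / (1 - 0.9^step)
            vhat <- v / (1 - 0.999^step)
            params <- set_param(params, nm,
                                get_param(params, nm) -
                                  lr * mhat / (sqrt(vhat) + 1e-8))
          }
        }
      }
      history[epoch] <- mean(losses)
      if (verbose) {
        message(sprintf("epoch %d/%d: loss %.4f", epoch, hyper$epochs,
                        history[epoch]))
      }
    }
    new_pair_scorer(
      scheme = "cdr3_cnn", scope = scope,
      fit = list(params = params, hyper = hyper,
                 max_len = attr(encoded, "max_len")),
      meta = list(n_train = n, loss_history = history))
  })
}

# deterministic forward scoring of encoded pairs
cnn_scores <- function(scorer, encoded, chunk = 2048L) {
  params <- scorer$fit$params
  hyper <- scorer$fit$hyper
  n <- dim(encoded$heavy)[1]
  dims <- c(heavy = dim(encoded$heavy)[2], light = dim(encoded$light)[2])
  xh <- flatten_stream(encoded$heavy)
  xl <- flatten_stream(encoded$light)
  out <- numeric(n)
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    b <- s:min(s + chunk - 1L, n)
    rh <- rep((b - 1L) * dims["heavy"], each = dims["heavy"]) +
      seq_len(dims["heavy"])
    rl <- rep((b - 1L) * dims["light"], each = dims["light"]) +
      seq_len(dims["light"])
    fw <- cnn_forward_batch(xh[rh, , drop = FALSE], xl[rl, , drop = FALSE],
                            length(b), dims, encoded$len_heavy[b],
                            encoded$len_light[b], params, hyper)
    out[b] <- softmax2(fw$logits)
  }
  out
}
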