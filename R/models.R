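# Pairing scorer contract, baseline trainers and kappa/lambda routing.

new_pair_scorer <- function(scheme, scope, fit, meta = list()) {
  stopifnot(scheme %in% c("gene_linear", "gene_boosted", "cdr3_cnn",
                          "external"),
            scope %in% c("all", "kappa_only", "lambda_only"))
  structure(list(scheme = scheme, scope = scope, fit = fit, meta = meta),
            class = c(paste0(scheme, "_scorer"), "pair_scorer"))
}

#' @export
print.pair_scorer <- function(x, ...) {
  cat("<pair_scorer>", x$scheme, "| scope:", x$scope,
      "| trained on", x$meta$n_train %||% NA, "pairs\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_scope <- function(scorer, pairs, override_scope = FALSE) {
  if (scorer$scope == "all" || override_scope) return(invisible(TRUE))
  want <- if (scorer$scope == "kappa_only") "IGK" else "IGL"
  off <- sum(pairs$light_locus != want)
  if (off > 0) {
    warning(sprintf(
      "scorer has scope %s but %d pair(s) carry a different light locus",
      scorer$scope, off), call. = FALSE)
  }
  invisible(TRUE)
}

#' Score heavy-light pairs with a fitted scorer
#'
#' Returns one pairing score in `[0, 1]` per pair (order preserving,
#' deterministic); a score of at least 0.5 corresponds to a predicted
#' cognate pair under the default decision rule. A warning is emitted when
#' pairs violate the scorer's light-chain scope unless `override_scope` is
#' set (used deliberately for cross-type generalisation checks).
#'
#' @param scorer A fitted `pair_scorer`.
#' @param pairs A pair table.
#' @param override_scope Silence the scope check.
#' @param ... Passed to methods.
#' @return Numeric vector of pairing scores.
#' @export
score_pairs <- function(scorer, pairs, override_scope = FALSE, ...) {
  if (!inherits(scorer, "pair_scorer")) {
    stop("not a pair_scorer", call. = FALSE)
  }
  if (is.null(scorer$fit)) stop("scorer is not fitted", call. = FALSE)
  UseMethod("score_pairs")
}

#' @export
score_pairs.gene_linear_scorer <- function(scorer, pairs,
                                           override_scope = FALSE, ...) {
  check_scope(scorer, pairs, override_scope)
  x <- encode_gene_usage(pairs, scorer$fit$vocab)
  as.numeric(predict(scorer$fit$model, newx = x, s = "lambda.min",
                     type = "response"))
}

#' @export
score_pairs.gene_boosted_scorer <- function(scorer, pairs,
                                            override_scope = FALSE, ...) {
  check_scope(scorer, pairs, override_scope)
  x <- encode_gene_usage(pairs, scorer$fit$vocab)
  predict(scorer$fit$model, xgboost::xgb.DMatrix(unname(x)))
}

#' @export
score_pairs.cdr3_cnn_scorer <- function(scorer, pairs,
                                        override_scope = FALSE, ...) {
  check_scope(scorer, pairs, override_scope)
  ml <- scorer$fit$max_len
  enc <- encode_cdr3_onehot(pairs, unname(ml["heavy"]),
                            unname(ml["light"]), truncate = TRUE)
  cnn_scores(scorer, enc)
}

#' @export
score_pairs.external_scorer <- function(scorer, pairs,
                                        override_scope = FALSE, ...) {
  check_scope(scorer, pairs, override_scope)
  s <- scorer$fit$backend(pairs$heavy_sequence_vdj_aa,
                          pairs$light_sequence_vdj_aa)
  s <- as.numeric(s)
  if (length(s) != nrow(pairs) || anyNA(s) || any(s < 0 | s > 1)) {
    stop("external backend violated the scoring contract ",
         "(one score in [0, 1] per pair)", call. = FALSE)
  }
  s
}

#' Train the regularised gene-usage logistic baseline
#'
#' Ridge-penalised logistic regression on one-hot V/J gene usage, with the
#' regularisation strength chosen by internal cross-validation. Mirrors a
#' `LogisticRegressionCV`-style baseline.
#'
#' @param features An [encode_gene_usage()] matrix.
#' @param labels Integer labels (1 = cognate, 0 = shuffled).
#' @param k_folds Internal cross-validation folds.
#' @param seed Integer seed (fixes the internal fold assignment).
#' @param scope Light-chain scope recorded on the scorer.
#' @return A `pair_scorer` of scheme `gene_linear`.
#' @export
train_gene_linear <- function(features, labels, k_folds = 10, seed = 1,
                              scope = "all") {
  stopifnot(identical(attr(features, "scheme"), "gene_usage"))
  if (length(unique(labels)) < 2) {
    stop("labels are single-class; nothing to learn", call. = FALSE)
  }
  with_local_seed(seed, {
    foldid <- sample(rep_len(seq_len(k_folds), length(labels)))
    model <- glmnet::cv.glmnet(features, as.integer(labels),
                               family = "binomial", alpha = 0,
                               foldid = foldid, standardize = FALSE)
    new_pair_scorer("gene_linear", scope,
                    fit = list(model = model,
                               vocab = attr(features, "vocab")),
                    meta = list(n_train = length(labels)))
  })
}

#' Train the gene-usage boosted-tree baseline
#'
#' Gradient-boosted decision trees with histogram-based splitting on
#' one-hot V/J gene usage.
#'
#' @param features An [encode_gene_usage()] matrix.
#' @param labels Integer labels (1 = cognate, 0 = shuffled).
#' @param params Named list overriding the xgboost defaults
#'   (`max_depth = 4`, `eta = 0.2`, `nrounds = 100`).
#' @param seed Integer seed.
#' @param scope Light-chain scope recorded on the scorer.
#' @return A `pair_scorer` of scheme `gene_boosted`.
#' @export
train_gene_boosted <- function(features, labels, params = list(), seed = 1,
                               scope = "all") {
  stopifnot(identical(attr(features, "scheme"), "gene_usage"))
  if (length(unique(labels)) < 2) {
    stop("labels are single-class; nothing to learn", call. = FALSE)
  }
  nrounds <- params$nrounds %||% 100
  xgb_params <- list(objective = "binary:logistic", tree_method = "hist",
                     max_depth = params$max_depth %||% 4,
                     eta = params$eta %||% 0.2,
                     nthread = 1, seed = seed)
  dtrain <- xgboost::xgb.DMatrix(unname(features),
                                 label = as.integer(labels))
  model <- xgboost::xgb.train(params = xgb_params, data = dtrain,
                              nrounds = nrounds, verbose = 0)
  new_pair_scorer("gene_boosted", scope,
                  fit = list(model = model, vocab = attr(features, "vocab")),
                  meta = list(n_train = length(labels)))
}

#' Wrap an external scoring backend as a pair scorer
#'
#' Plug-in point for pretrained sequence classifiers (e.g. fine-tuned
#' protein language models) whose training is outside this package. The
#' backend must honour the contract
#' `(heavy variable-domain aa, light variable-domain aa) -> score in [0,1]`,
#' vectorised over pairs; violations raise an error at scoring time.
#'
#' @param backend A function of two character vectors returning numeric
#'   scores, or the path of an executable which reads a two-column TSV
#'   (heavy, light) on stdin and prints one score per line.
#' @param scope Light-chain scope of the backend.
#' @return A `pair_scorer` of scheme `external`.
#' @export
load_external_scorer <- function(backend, scope = "all") {
  if (is.character(backend)) {
    cmd <- backend
    if (Sys.which(cmd) == "" && !file.exists(cmd)) {
      stop("external scoring backend '", cmd, "' is not available; ",
           "install it or pass an R function backend", call. = FALSE)
    }
    backend_fun <- function(heavy, light) {
      tmp <- tempfile()
      on.exit(unlink(tmp))
      writeLines(paste(heavy, light, sep = "\t"), tmp)
      as.numeric(system2(cmd, stdin = tmp, stdout = TRUE))
    }
  } else if (is.function(backend)) {
    backend_fun <- backend
  } else {
    stop("backend must be a function or an executable path", call. = FALSE)
  }
  new_pair_scorer("external", scope, fit = list(backend = backend_fun),
                  meta = list(n_train = NA_integer_))
}

#' Train a scorer of a given scheme directly from pairs
#'
#' Convenience wrapper that encodes `pairs` as required by `scheme` and
#' dispatches to the matching training routine.
#'
#' @param pairs A labeled pair table.
#' @param scheme `"gene_linear"`, `"gene_boosted"` or `"cdr3_cnn"`.
#' @param seed Integer seed.
#' @param scope Light-chain scope recorded on the scorer.
#' @param hyper [cnn_hyperparams()] for the CNN scheme (its seed is
#'   overridden by `seed`).
#' @param ... Passed on to the underlying trainer.
#' @return A fitted `pair_scorer`.
#' @export
train_pair_scorer <- function(pairs, scheme = c("cdr3_cnn", "gene_linear",
                                                "gene_boosted"),
                              seed = 1, scope = "all",
                              hyper = cnn_hyperparams(), ...) {
  scheme <- match.arg(scheme)
  labels <- pair_labels(pairs)
  if (scheme == "cdr3_cnn") {
    ml_h <- max(22L, max(nchar(pairs$heavy_cdr3_aa)))
    ml_l <- max(14L, max(nchar(pairs$light_cdr3_aa)))
    enc <- encode_cdr3_onehot(pairs, ml_h, ml_l)
    hyper$seed <- as.integer(seed)
    train_cdr3_cnn(enc, labels, hyper, scope = scope, ...)
  } else {
    feats <- encode_gene_usage(pairs, build_vocabulary(pairs))
    if (scheme == "gene_linear") {
      train_gene_linear(feats, labels, seed = seed, scope = scope, ...)
    } else {
      train_gene_boosted(feats, labels, seed = seed, scope = scope, ...)
    }
  }
}

#' Train light-chain-type specific scorers
#'
#' Splits a curated dataset by light-chain locus and trains one scorer per
#' locus (the kappa model never sees a lambda light chain and vice versa).
#' The dataset is expected to have been curated per locus, i.e. pseudo
#' negatives generated within each light-chain type.
#'
#' @param dataset A `pair_dataset` containing both loci.
#' @param trainer Function `(pairs, seed) -> pair_scorer` (see
#'   [scorer_trainer()]).
#' @param seed Integer seed (each locus trains with a derived seed).
#' @param balance Down-sample the larger locus so both training sets have
#'   the size of the smaller one.
#' @param min_per_locus Minimum trainable pair count per locus.
#' @return A `routed_scorer` with `kappa` and `lambda` slots.
#' @export
train_type_specific <- function(dataset, trainer, seed = 1,
                                balance = FALSE, min_per_locus = 50) {
  pairs <- if (inherits(dataset, "pair_dataset")) dataset$pairs else dataset
  kappa <- pairs[pairs$light_locus == "IGK", ]
  lambda <- pairs[pairs$light_locus == "IGL", ]
  for (side in list(c("kappa", nrow(kappa)), c("lambda", nrow(lambda)))) {
    if (as.integer(side[2]) < min_per_locus) {
      stop("locus ", side[1], " has only ", side[2],
           " pairs (< ", min_per_locus, "); cannot train a ",
           side[1], "-specific scorer", call. = FALSE)
    }
  }
  if (balance) {
    n_min <- min(nrow(kappa), nrow(lambda))
    with_local_seed(seed, {
      kappa <- kappa[sort(sample(nrow(kappa), n_min)), ]
      lambda <- lambda[sort(sample(nrow(lambda), n_min)), ]
    })
  }
  k_scorer <- trainer(kappa, seed = seed)
  l_scorer <- trainer(lambda, seed = seed + 1L)
  k_scorer$scope <- "kappa_only"
  l_scorer$scope <- "lambda_only"
  routed_scorer(k_scorer, l_scorer)
}

#' Bundle kappa- and lambda-specific scorers for routed scoring
#'
#' @param kappa_scorer,lambda_scorer Fitted `pair_scorer`s with matching
#'   scopes (`kappa_only` / `lambda_only`).
#' @return A `routed_scorer`.
#' @export
routed_scorer <- function(kappa_scorer, lambda_scorer) {
  stopifnot(inherits(kappa_scorer, "pair_scorer"),
            inherits(lambda_scorer, "pair_scorer"),
            kappa_scorer$scope == "kappa_only",
            lambda_scorer$scope == "lambda_only")
  structure(list(kappa = kappa_scorer, lambda = lambda_scorer),
            class = "routed_scorer")
}

#' Route pairs to the matching light-chain-type scorer and score them
#'
#' H-kappa pairs are scored by the kappa scorer and H-lambda pairs by the
#' lambda scorer; the output order matches the input order. `force_scope`
#' deliberately sends all pairs through one scorer (cross-type
#' generalisation checks).
#'
#' @param routed A [routed_scorer()].
#' @param pairs A pair table with light loci in `{IGK, IGL}`.
#' @param force_scope `NULL` (route normally), `"kappa"` or `"lambda"`.
#' @return Numeric vector of pairing scores; the scorer used for each pair
#'   is attached as the `routed_to` attribute.
#' @export
route_and_score <- function(routed, pairs, force_scope = NULL) {
  stopifnot(inherits(routed, "routed_scorer"))
  bad <- !pairs$light_locus %in% c("IGK", "IGL")
  if (any(bad)) {
    stop("unknown light locus: ",
         paste(unique(pairs$light_locus[bad]), collapse = ", "),
         call. = FALSE)
  }
  scores <- numeric(nrow(pairs))
  if (!is.null(force_scope)) {
    scorer <- if (force_scope == "kappa") routed$kappa else routed$lambda
    scores <- score_pairs(scorer, pairs, override_scope = TRUE)
    attr(scores, "routed_to") <- rep(force_scope, nrow(pairs))
    return(scores)
  }
  is_k <- pairs$light_locus == "IGK"
  if (any(is_k)) scores[is_k] <- score_pairs(routed$kappa, pairs[is_k, ])
  if (any(!is_k)) scores[!is_k] <- score_pairs(routed$lambda, pairs[!is_k, ])
  attr(scores, "routed_to") <- ifelse(is_k, "kappa", "lambda")
  scores
}

#' Factory for trainer closures used in cross-validation and routing
#'
#' @param scheme Scorer scheme passed to [train_pair_scorer()].
#' @param ... Fixed arguments (e.g. `hyper`) for [train_pair_scorer()].
#' @return A function `(pairs, seed) -> pair_scorer`.
#' @export
scorer_trainer <- function(scheme = "cdr3_cnn", ...) {
  fixed <- list(...)
  function(pairs, seed = 1) {
    do.call(train_pair_scorer,
            c(list(pairs = pairs, scheme = scheme, seed = seed), fixed))
  }
}

#' Save / load a fitted scorer
#'
#' Model archives contain the fitted parameters, feature metadata
#' (vocabulary or padded lengths) and training seeds, so reloaded scorers
#' reproduce scores exactly.
#'
#' @param scorer A `pair_scorer` or `routed_scorer`.
#' @param path Archive file path.
#' @return `write_scorer`: `path` invisibly; `read_scorer`: the scorer.
#' @export
write_scorer <- function(scorer, path) {
  stopifnot(inherits(scorer, "pair_scorer") ||
              inherits(scorer, "routed_scorer"))
  if (inherits(scorer, "gene_boosted_scorer")) {
    scorer$fit$model_raw <- xgboost::xgb.save.raw(scorer$fit$model)
    scorer$fit$model <- NULL
  }
  if (inherits(scorer, "routed_scorer")) {
    for (slot in c("kappa", "lambda")) {
      if (inherits(scorer[[slot]], "gene_boosted_scorer")) {
        scorer[[slot]]$fit$model_raw <-
          xgboost::xgb.save.raw(scorer[[slot]]$fit$model)
        scorer[[slot]]$fit$model <- NULL
      }
    }
  }
  saveRDS(scorer, path)
  invisible(path)
}

#' @rdname write_scorer
#' @export
read_scorer <- function(path) {
  scorer <- readRDS(path)
  restore <- function(s) {
    if (inherits(s, "gene_boosted_scorer") && !is.null(s$fit$model_raw)) {
      s$fit$model <- xgboost::xgb.load.raw(s$fit$model_raw)
      s$fit$model_raw <- NULL
    }
    s
  }
  if (inherits(scorer, "routed_scorer")) {
    scorer$kappa <- restore(scorer$kappa)
    scorer$lambda <- restore(scorer$lambda)
  } else {
    scorer <- restore(scorer)
  }
  scorer
}
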