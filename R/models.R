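# Single-label and multi-label feed-forward context classifiers.
#
# Architecture: input(1024) -> [linear(hidden) + ReLU + dropout] x nLayers
# -> linear(nLabels) + final activation. The single-label model uses softmax
# with categorical cross-entropy weighted per example by yield/100; the
# multi-label model uses binary cross-entropy, unweighted, with a softmax
# final activation by default (sigmoid available via the config, and needed
# when the predicted label-set cardinality matters, since softmax caps the
# number of implied positives). Optimized with Adam. Everything is plain
# matrix arithmetic, deterministic under fixed seeds on a single device.

.SEARCH_SPACE <- list(
  single = list(batchSize = c(32L, 64L), epochs = c(10L, 15L),
                hiddenSize = c(128L, 256L, 512L, 1024L, 2048L),
                nHiddenLayers = 1:3, lrRange = c(1e-5, 5e-3),
                dropoutRange = c(0, 0.9)),
  multi = list(batchSize = c(32L, 64L), epochs = c(10L, 15L, 20L),
               hiddenSize = c(128L, 256L, 512L),
               nHiddenLayers = 1:3, lrRange = c(1e-5, 5e-3),
               dropoutRange = c(0, 0.9)))

#' Model configuration with the optimized published defaults
#'
#' Single-label: one hidden layer of 1024 units, dropout 0.60, learning
#' rate 6.1e-4, 10 epochs, batch 64, softmax output. Multi-label: one
#' hidden layer of 512 units, dropout 0.64, learning rate 9.2e-4, 20
#' epochs, batch 64, softmax output.
#'
#' @param mode "single" or "multi".
#' @param ... overrides for individual fields (e.g.
#'   \code{finalActivation = "sigmoid"}, \code{seed = 7}).
#' @return named list: mode, hiddenSize, nHiddenLayers, dropoutRate,
#'   learningRate, batchSize, epochs, finalActivation, seed.
#' @export
defaultModelConfig <- function(mode = c("single", "multi"), ...) {
  mode <- match.arg(mode)
  cfg <- if (mode == "single") {
    list(mode = "single", hiddenSize = 1024L, nHiddenLayers = 1L,
         dropoutRate = 0.60, learningRate = 6.1e-4, batchSize = 64L,
         epochs = 10L, finalActivation = "softmax", seed = 42L)
  } else {
    list(mode = "multi", hiddenSize = 512L, nHiddenLayers = 1L,
         dropoutRate = 0.64, learningRate = 9.2e-4, batchSize = 64L,
         epochs = 20L, finalActivation = "softmax", seed = 42L)
  }
  override <- list(...)
  stopifnot(all(names(override) %in% names(cfg)))
  cfg[names(override)] <- override
  .validateModelConfig(cfg)
  cfg
}

.validateModelConfig <- function(cfg) {
  stopifnot(cfg$mode %in% c("single", "multi"),
            cfg$hiddenSize >= 1, cfg$nHiddenLayers >= 1,
            cfg$dropoutRate >= 0, cfg$dropoutRate <= 0.9,
            cfg$learningRate > 0, cfg$batchSize >= 1, cfg$epochs >= 1,
            cfg$finalActivation %in% c("softmax", "sigmoid"))
  invisible(cfg)
}

#' ModelBundle: a trained network with everything needed to apply it
#'
#' @slot config the model configuration list.
#' @slot weights list of weight matrices and bias vectors per layer.
#' @slot labelSpace the ordered \linkS4class{LabelSpace} the output layer
#'   maps to.
#' @slot fpConfig fingerprint configuration the model was trained under;
#'   prediction refuses inputs featurized differently.
#' @slot history per-epoch training/validation losses and headline metric.
#' @export
setClass("ModelBundle",
         representation(config = "list", weights = "list",
                        labelSpace = "LabelSpace", fpConfig = "list",
                        history = "data.frame"))

setValidity("ModelBundle", function(object) {
  if (!length(object@weights)) return("empty weights")
  Wout <- object@weights[[length(object@weights)]]$W
  if (nLabels(object@labelSpace) > 0 &&
      ncol(Wout) != nLabels(object@labelSpace))
    return("output dimension must equal the label-space size")
  TRUE
})

setMethod("show", "ModelBundle", function(object) {
  cfg <- object@config
  cat(sprintf("ModelBundle (%s-label): 1024 -> %s -> %d labels\n",
              cfg$mode,
              paste(rep(cfg$hiddenSize, cfg$nHiddenLayers), collapse = " -> "),
              ncol(object@weights[[length(object@weights)]]$W)))
  if (nrow(object@history)) {
    last <- object@history[nrow(object@history), ]
    cat(sprintf("  trained %d epochs; final val loss %.4f, %s %.4f\n",
                nrow(object@history), last$val_loss,
                names(object@history)[4], last[[4]]))
  }
})

# ---- network internals -----------------------------------------------------

.initParams <- function(sizes) {
  # He initialization for the ReLU layers, Glorot-ish for the output
  lapply(seq_len(length(sizes) - 1L), function(l) {
    fan_in <- sizes[l]
    sd <- sqrt(2 / fan_in)
    list(W = matrix(stats::rnorm(fan_in * sizes[l + 1L], sd = sd),
                    fan_in, sizes[l + 1L]),
         b = numeric(sizes[l + 1L]))
  })
}

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

.forward <- function(params, X, dropout, training) {
  L <- length(params) - 1L
  As <- vector("list", L + 1L)  # post-dropout activations feeding layer l+1
  Zs <- vector("list", L)
  Ds <- vector("list", L)
  A <- X
  for (l in seq_len(L)) {
    Z <- sweep(A %*% params[[l]]$W, 2, params[[l]]$b, "+")
    H <- pmax(Z, 0)
    if (training && dropout > 0) {
      D <- matrix((stats::runif(length(H)) >= dropout) / (1 - dropout),
                  nrow(H), ncol(H))
      H <- H * D
      Ds[[l]] <- D
    }
    As[[l]] <- A
    Zs[[l]] <- Z
    A <- H
  }
  As[[L + 1L]] <- A
  Zout <- sweep(A %*% params[[L + 1L]]$W, 2, params[[L + 1L]]$b, "+")
  list(As = As, Zs = Zs, Ds = Ds, Zout = Zout)
}

.activate <- function(Zout, finalActivation) {
  if (finalActivation == "softmax") .softmax(Zout)
  else 1 / (1 + exp(-Zout))
}

.clip <- function(p) pmin(pmax(p, 1e-7), 1 - 1e-7)

# loss value for a batch (T = 0/1 target matrix, w = per-example weights)
.lossValue <- function(P, T, w, mode) {
  if (mode == "single") {
    sum(w * -log(.clip(rowSums(P * T)))) / nrow(P)
  } else {
    P <- .clip(P)
    -mean(T * log(P) + (1 - T) * log(1 - P))
  }
}

# gradient of the loss w.r.t. the output pre-activation Zout
.lossGradZ <- function(P, T, w, mode, finalActivation) {
  B <- nrow(P)
  if (mode == "single") {
    # weighted categorical cross-entropy with softmax
    (P - T) * (w / B)
  } else if (finalActivation == "sigmoid") {
    (P - T) / (B * ncol(P))
  } else {
    # binary cross-entropy through the softmax Jacobian
    Pc <- .clip(P)
    dP <- (Pc - T) / (Pc * (1 - Pc)) / (B * ncol(P))
    P * (dP - rowSums(P * dP))
  }
}

.adamStep <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(params)) {
    for (nm in c("W", "b")) {
      g <- grads[[l]][[nm]]
      state[[l]][[nm]]$m <- beta1 * state[[l]][[nm]]$m + (1 - beta1) * g
      state[[l]][[nm]]$v <- beta2 * state[[l]][[nm]]$v + (1 - beta2) * g^2
      mhat <- state[[l]][[nm]]$m / (1 - beta1^t)
      vhat <- state[[l]][[nm]]$v / (1 - beta2^t)
      params[[l]][[nm]] <- params[[l]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

.backward <- function(params, fwd, dZout) {
  L <- length(params) - 1L
  grads <- vector("list", L + 1L)
  grads[[L + 1L]] <- list(W = crossprod(fwd$As[[L + 1L]], dZout),
                          b = colSums(dZout))
  dA <- dZout %*% t(params[[L + 1L]]$W)
  for (l in rev(seq_len(L))) {
    if (!is.null(fwd$Ds[[l]])) dA <- dA * fwd$Ds[[l]]
    dZ <- dA * (fwd$Zs[[l]] > 0)
    grads[[l]] <- list(W = crossprod(fwd$As[[l]], dZ), b = colSums(dZ))
    if (l > 1L) dA <- dZ %*% t(params[[l]]$W)
  }
  grads
}

# run RNG-dependent code under a fixed seed without disturbing the caller's
# RNG stream
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# stratified 80/20 split; singleton labels stay in training
.splitIndex <- function(labels, splitSeed, frac = 0.8) {
  .withSeed(splitSeed, {
    if (is.matrix(labels)) {
      n <- nrow(labels)
      val <- sample(n, max(1, round((1 - frac) * n)))
    } else {
      n <- length(labels)
      val <- unlist(lapply(split(seq_len(n), labels), function(idx) {
        k <- floor((1 - frac) * length(idx) + stats::runif(1))
        if (length(idx) < 2 || k == 0) integer(0) else sample(idx, k)
      }), use.names = FALSE)
      if (!length(val)) val <- sample(n, max(1, round((1 - frac) * n)))
    }
    sort(val)
  })
}

#' Train a context-prediction network
#'
#' Trains the feed-forward classifier on difference fingerprints with an
#' 80/20 train/validation split (stratified by label in single mode).
#' Single mode uses softmax + categorical cross-entropy with per-example
#' yield weights; multi mode uses binary cross-entropy, unweighted. The
#' history records per-epoch training and validation loss plus the mode's
#' headline metric (top-1 accuracy or LRAP) on the validation split. With
#' fixed \code{cfg$seed} and \code{splitSeed} the run is reproducible.
#'
#' @param labels integer label vector (single mode, 1-based indices into
#'   the label space) or binary matrix (multi mode, one row per example).
#' @param features numeric matrix of difference fingerprints, rows aligned
#'   with \code{labels}.
#' @param cfg model configuration from \code{\link{defaultModelConfig}}.
#' @param labelSpace the \linkS4class{LabelSpace} the labels refer to.
#' @param weights per-example loss weights (single mode: yield/100);
#'   defaults to 1.
#' @param splitSeed seed for the train/validation split, kept separate
#'   from the weight-init seed so splits can be held fixed across
#'   architecture comparisons.
#' @return a \linkS4class{ModelBundle}.
#' @export
trainModel <- function(labels, features, cfg, labelSpace,
                       weights = NULL, splitSeed = 1L) {
  .validateModelConfig(cfg)
  K <- nLabels(labelSpace)
  n <- nrow(features)
  if (is.matrix(labels)) {
    stopifnot(cfg$mode == "multi", nrow(labels) == n, ncol(labels) == K)
    T_all <- labels
    strat <- labels
  } else {
    stopifnot(cfg$mode == "single", length(labels) == n,
              all(labels >= 1 & labels <= K))
    T_all <- oneHot(labels, K)
    strat <- labels
  }
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  if (n < 10 * K)
    warning("fewer than 10 examples per label (n = ", n, ", labels = ", K,
            "); results may be unstable")

  val <- .splitIndex(strat, splitSeed)
  tr <- setdiff(seq_len(n), val)
  Xtr <- features[tr, , drop = FALSE]; Ttr <- T_all[tr, , drop = FALSE]
  wtr <- weights[tr]
  Xva <- features[val, , drop = FALSE]; Tva <- T_all[val, , drop = FALSE]
  wva <- weights[val]

  bundle <- .withSeed(cfg$seed, {
    sizes <- c(ncol(features), rep(cfg$hiddenSize, cfg$nHiddenLayers), K)
    params <- .initParams(sizes)
    state <- lapply(params, function(p)
      list(W = list(m = p$W * 0, v = p$W * 0),
           b = list(m = p$b * 0, v = p$b * 0)))
    step <- 0L
    hist <- vector("list", cfg$epochs)
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample(nrow(Xtr))
      for (start in seq(1, length(perm), by = cfg$batchSize)) {
        idx <- perm[start:min(start + cfg$batchSize - 1L, length(perm))]
        fwd <- .forward(params, Xtr[idx, , drop = FALSE],
                        cfg$dropoutRate, training = TRUE)
        P <- .activate(fwd$Zout, cfg$finalActivation)
        dZ <- .lossGradZ(P, Ttr[idx, , drop = FALSE], wtr[idx],
                         cfg$mode, cfg$finalActivation)
        grads <- .backward(params, fwd, dZ)
        step <- step + 1L
        upd <- .adamStep(params, grads, state, cfg$learningRate, step)
        params <- upd$params
        state <- upd$state
      }
      Ptr <- .activate(.forward(params, Xtr, 0, FALSE)$Zout,
                       cfg$finalActivation)
      Pva <- .activate(.forward(params, Xva, 0, FALSE)$Zout,
                       cfg$finalActivation)
      train_loss <- .lossValue(Ptr, Ttr, wtr, cfg$mode)
      val_loss <- .lossValue(Pva, Tva, wva, cfg$mode)
      if (!is.finite(train_loss) || !is.finite(val_loss))
        stop("non-finite loss at epoch ", epoch,
             "; try a lower learning rate", call. = FALSE)
      hist[[epoch]] <- if (cfg$mode == "single") {
        data.frame(epoch = epoch, train_loss = train_loss,
                   val_loss = val_loss,
                   val_top1 = topkAccuracy(Pva, Tva, 1L),
                   val_top3 = topkAccuracy(Pva, Tva, min(3L, K)))
      } else {
        data.frame(epoch = epoch, train_loss = train_loss,
                   val_loss = val_loss, val_lrap = lrap(Pva, Tva))
      }
    }
    hist <- do.call(rbind, hist)
    methods::new("ModelBundle", config = cfg, weights = params,
                 labelSpace = labelSpace, fpConfig = list(),
                 history = hist)
  })
  fpc <- attr(features, "fpConfig")
  if (!is.null(fpc)) bundle@fpConfig <- fpc
  bundle
}

#' Predict context scores
#'
#' One row of scores per input reaction, in [0, 1]; softmax rows sum to 1.
#' If the bundle carries a fingerprint configuration, inputs featurized
#' under a different configuration are refused.
#'
#' @param bundle a \linkS4class{ModelBundle}.
#' @param features numeric matrix of difference fingerprints.
#' @return numeric score matrix, rows aligned with \code{features},
#'   columns with the bundle's label space.
#' @export
predictScores <- function(bundle, features) {
  stopifnot(methods::is(bundle, "ModelBundle"))
  if (ncol(features) != nrow(bundle@weights[[1]]$W))
    stop("feature dimension (", ncol(features), ") does not match the ",
         "model input (", nrow(bundle@weights[[1]]$W), ")", call. = FALSE)
  if (length(bundle@fpConfig)) {
    fpc <- attr(features, "fpConfig")
    if (!is.null(fpc) && !identical(unclass(fpc), unclass(bundle@fpConfig)))
      stop("features were computed under a different fingerprint ",
           "configuration than the model was trained with", call. = FALSE)
  }
  .activate(.forward(bundle@weights, features, 0, FALSE)$Zout,
            bundle@config$finalActivation)
}

#' Random-search hyper-parameter tuning with cross-validation
#'
#' Samples configurations from the published search space (batch size 32 or
#' 64; epochs 10/15 single, 10/15/20 multi; hidden size 128-2048 single,
#' 128-512 multi; 1-3 hidden layers; learning rate log-uniform in
#' [1e-5, 5e-3]; dropout uniform in [0, 0.9]) and scores each by k-fold
#' cross-validated top-1 accuracy (single) or LRAP (multi).
#'
#' @inheritParams trainModel
#' @param mode "single" or "multi".
#' @param nTrials number of sampled configurations (>= 1).
#' @param cvFolds number of cross-validation folds (default 5).
#' @param seed seed for the trial sampler and fold assignment.
#' @return the best configuration, with the trial log (one row per trial)
#'   attached as attribute \code{"trials"}.
#' @export
tuneModel <- function(labels, features, mode = c("single", "multi"),
                      nTrials = 10L, cvFolds = 5L, seed = 1L,
                      labelSpace = NULL, weights = NULL) {
  mode <- match.arg(mode)
  if (nTrials < 1) stop("nTrials must be >= 1", call. = FALSE)
  sp <- .SEARCH_SPACE[[mode]]
  n <- nrow(features)
  if (is.null(labelSpace)) {
    K <- if (is.matrix(labels)) ncol(labels) else max(labels)
    labelSpace <- methods::new("LabelSpace",
                               contexts = paste0("ctx", seq_len(K)),
                               counts = rep(1L, K))
  }
  configs <- .withSeed(seed, lapply(seq_len(nTrials), function(i) {
    defaultModelConfig(mode,
      batchSize = sample(sp$batchSize, 1),
      epochs = sample(sp$epochs, 1),
      hiddenSize = sample(sp$hiddenSize, 1),
      nHiddenLayers = sample(sp$nHiddenLayers, 1),
      learningRate = exp(stats::runif(1, log(sp$lrRange[1]),
                                      log(sp$lrRange[2]))),
      dropoutRate = stats::runif(1, sp$dropoutRange[1], sp$dropoutRange[2]),
      seed = sample.int(1e6, 1))
  }))
  folds <- .withSeed(seed + 1L, sample(rep_len(seq_len(cvFolds), n)))
  scores <- vapply(seq_len(nTrials), function(i) {
    cfg <- configs[[i]]
    mean(vapply(seq_len(cvFolds), function(f) {
      tr <- which(folds != f); te <- which(folds == f)
      b <- trainModel(if (is.matrix(labels)) labels[tr, , drop = FALSE]
                      else labels[tr],
                      features[tr, , drop = FALSE], cfg, labelSpace,
                      weights = weights[tr], splitSeed = seed)
      P <- predictScores(b, features[te, , drop = FALSE])
      Tte <- if (is.matrix(labels)) labels[te, , drop = FALSE]
             else oneHot(labels[te], nLabels(labelSpace))
      if (mode == "single") topkAccuracy(P, Tte, 1L) else lrap(P, Tte)
    }, numeric(1)))
  }, numeric(1))
  best <- configs[[which.max(scores)]]
  trials <- do.call(rbind, lapply(seq_len(nTrials), function(i)
    data.frame(trial = i, score = scores[i],
               as.data.frame(configs[[i]][c("hiddenSize", "nHiddenLayers",
                                            "dropoutRate", "learningRate",
                                            "batchSize", "epochs")]))))
  attr(best, "trials") <- trials
  best
}

#' Save / load a ModelBundle
#'
#' The on-disk bundle is a directory holding \code{config.json},
#' \code{labelspace.json}, \code{fp_config.json}, \code{history.csv} and
#' the network parameters in \code{weights.rds}. A reloaded bundle
#' reproduces predictions bit-identically.
#'
#' @param bundle a \linkS4class{ModelBundle}.
#' @param dir directory to write (created if absent).
#' @return \code{loadModelBundle}: the restored \code{ModelBundle}.
#' @export
saveModelBundle <- function(bundle, dir) {
  stopifnot(methods::is(bundle, "ModelBundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(bundle@config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLabelSpace(bundle@labelSpace, file.path(dir, "labelspace.json"))
  jsonlite::write_json(bundle@fpConfig, file.path(dir, "fp_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(bundle@history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  saveRDS(bundle@weights, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname saveModelBundle
#' @export
loadModelBundle <- function(dir) {
  needed <- c("config.json", "labelspace.json", "fp_config.json",
              "history.csv", "weights.rds")
  missing <- needed[!file.exists(file.path(dir, needed))]
  if (length(missing))
    stop("bundle at ", dir, " is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  cfg <- jsonlite::fromJSON(file.path(dir, "config.json"))
  cfg$hiddenSize <- as.integer(cfg$hiddenSize)
  cfg$nHiddenLayers <- as.integer(cfg$nHiddenLayers)
  cfg$batchSize <- as.integer(cfg$batchSize)
  cfg$epochs <- as.integer(cfg$epochs)
  cfg$seed <- as.integer(cfg$seed)
  weights <- tryCatch(readRDS(file.path(dir, "weights.rds")),
                      error = function(e)
                        stop("corrupt weights file in ", dir, ": ",
                             conditionMessage(e), call. = FALSE))
  if (!is.list(weights) || !all(vapply(weights, function(p)
        is.matrix(p$W) && is.numeric(p$b), TRUE)))
    stop("corrupt weights file in ", dir, call. = FALSE)
  fpc <- jsonlite::fromJSON(file.path(dir, "fp_config.json"))
  if (length(fpc)) {
    fpc$circularBits <- as.integer(fpc$circularBits)
    fpc$pathBits <- as.integer(fpc$pathBits)
  }
  methods::new("ModelBundle", config = cfg, weights = weights,
               labelSpace = readLabelSpace(file.path(dir, "labelspace.json")),
               fpConfig = as.list(fpc),
               history = utils::read.csv(file.path(dir, "history.csv")))
}
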