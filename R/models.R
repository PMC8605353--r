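#' Confusion matrix at a score threshold
#'
#' @param scores classifier scores in \code{[0, 1]}.
#' @param labels 0/1 truth.
#' @param threshold decision threshold (default 0.5).
#' @return list with TP, TN, FP, FN (class \code{confusion_matrix}).
#' @export
confusion_matrix <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  structure(list(TP = sum(pred == 1 & labels == 1),
                 TN = sum(pred == 0 & labels == 0),
                 FP = sum(pred == 1 & labels == 0),
                 FN = sum(pred == 0 & labels == 1)),
            class = "confusion_matrix")
}

#' Trapezoidal AUC over the score sweep
#'
#' Sweeps the decision threshold over all observed scores and integrates the
#' ROC curve by the trapezoidal rule.
#'
#' @param scores classifier scores.
#' @param labels 0/1 truth.
#' @return area under the ROC curve.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1); fp <- cumsum(labels[ord] == 0)
  # collapse threshold ties to unique operating points
  last <- c(diff(scores[ord]) != 0, TRUE)
  tpr <- c(0, tp[last] / np); fpr <- c(0, fp[last] / nn)
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' Performance metrics from a confusion matrix
#'
#' Accuracy, sensitivity (recall), specificity, precision, F1, and MCC,
#' computed exactly from the four confusion-matrix counts. MCC is 0 when its
#' denominator vanishes; a single-class test set leaves sensitivity or
#' specificity NA.
#'
#' @param cm a [confusion_matrix()], or scores (with \code{labels}).
#' @param labels,threshold used when \code{cm} is a score vector.
#' @param auc optional AUC to attach (computed automatically from scores).
#' @return named numeric vector: Acc, Sn, Sp, Precision, F1, MCC (and AUC
#'   when scores were supplied).
#' @export
classification_metrics <- function(cm, labels = NULL, threshold = 0.5,
                                   auc = NULL) {
  if (!inherits(cm, "confusion_matrix")) {
    scores <- cm
    auc <- auc %||% roc_auc(scores, labels)
    cm <- confusion_matrix(scores, labels, threshold)
  }
  TP <- cm$TP; TN <- cm$TN; FP <- cm$FP; FN <- cm$FN
  acc <- (TN + TP) / (TN + TP + FN + FP)
  sn <- if (TP + FN == 0) NA_real_ else TP / (TP + FN)
  sp <- if (TN + FP == 0) NA_real_ else TN / (TN + FP)
  prec <- if (TP + FP == 0) NA_real_ else TP / (TP + FP)
  f1 <- if (is.na(prec) || is.na(sn) || prec + sn == 0) NA_real_
        else 2 * prec * sn / (prec + sn)
  den <- sqrt(as.numeric(TP + FP)) * sqrt(as.numeric(TP + FN)) *
         sqrt(as.numeric(TN + FP)) * sqrt(as.numeric(TN + FN))
  mcc <- if (den == 0) 0 else
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / den
  out <- c(Acc = acc, Sn = sn, Sp = sp, Precision = prec, F1 = f1, MCC = mcc)
  if (!is.null(auc)) out <- c(out, AUC = auc)
  out
}

#' Train a gradient-boosted-tree classifier
#'
#' xgboost with the established configuration: learning rate 0.2, maximum
#' depth 4, logistic objective, log-loss evaluation, base score at the label
#' mean. Single-threaded and seed-deterministic by default.
#'
#' @param x numeric feature matrix.
#' @param y 0/1 labels.
#' @param nrounds boosting rounds (default 1000).
#' @param eta learning rate (default 0.2).
#' @param max_depth tree depth (default 4).
#' @param nthread threads (default 1, for deterministic runs).
#' @param seed RNG seed.
#' @return object of class \code{rbp_gbt}.
#' @export
train_gbt <- function(x, y, nrounds = 1000, eta = 0.2, max_depth = 4,
                      nthread = 1, seed = 1) {
  if (anyNA(x)) stop("NaN/NA features: impute before training")
  y <- as.numeric(y)
  with_seed(seed, {
    dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = nthread)
    booster <- xgboost::xgb.train(
      params = list(eta = eta, max_depth = max_depth,
                    objective = "binary:logistic",
                    base_score = mean(y), eval_metric = "logloss",
                    nthread = nthread, seed = seed),
      data = dtrain, nrounds = nrounds, verbose = 0)
  })
  structure(list(booster = booster, feature_names = colnames(x),
                 kind = "gbt"), class = "rbp_gbt")
}

#' @export
predict.rbp_gbt <- function(object, newdata, ...) {
  if (!is.null(object$feature_names) && !is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$feature_names))
    stop("feature schema mismatch")
  predict(object$booster, xgboost::xgb.DMatrix(newdata, nthread = 1))
}

## ---- compact two-hidden-layer feed-forward net ----------------------------

act_fun <- function(name) {
  switch(name,
         relu = list(f = function(z) pmax(z, 0),
                     df = function(z, a) (z > 0) * 1),
         elu = list(f = function(z) ifelse(z > 0, z, expm1(z)),
                    df = function(z, a) ifelse(z > 0, 1, a + 1)),
         stop("unknown activation: ", name))
}

#' Train a two-hidden-layer feed-forward network
#'
#' A compact dense net: two hidden layers (ReLU then ELU), sigmoid output,
#' binary cross-entropy loss, Adam optimizer with L2 weight decay,
#' mini-batches, and early stopping on a held-out fraction of the training
#' data. Deterministic under the seed (single-threaded matrix code).
#'
#' @param x numeric feature matrix (standardized internally).
#' @param y 0/1 labels.
#' @param hidden hidden-layer widths (default \code{c(1024, 1024)}; the
#'   reference configuration varies 700-1300 per layer).
#' @param activations activation names for the two hidden layers.
#' @param lr Adam learning rate (default 0.005; tuning range 0.001-0.01).
#' @param l2 L2 weight decay (default 1e-4).
#' @param batch mini-batch size (default 128; range 50-200).
#' @param epochs maximum epochs (default 100; up to 1000 via config).
#' @param patience early-stopping patience in epochs (default 10).
#' @param validation_fraction fraction held out for early stopping.
#' @param seed RNG seed.
#' @return object of class \code{rbp_dnn}.
#' @export
train_dnn <- function(x, y, hidden = c(1024, 1024),
                      activations = c("relu", "elu"), lr = 0.005, l2 = 1e-4,
                      batch = 128, epochs = 100, patience = 10,
                      validation_fraction = 0.1, seed = 1) {
  if (anyNA(x)) stop("NaN/NA features: impute before training")
  y <- as.numeric(y)
  mu <- colMeans(x); sdv <- apply(x, 2, stats::sd); sdv[sdv == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  n <- nrow(xs)
  a1 <- act_fun(activations[1]); a2 <- act_fun(activations[2])

  with_seed(seed, {
    nval <- max(1, round(validation_fraction * n))
    vidx <- sample(n, nval)
    xv <- xs[vidx, , drop = FALSE]; yv <- y[vidx]
    xt <- xs[-vidx, , drop = FALSE]; yt <- y[-vidx]
    nt <- nrow(xt)

    init <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
    W <- list(init(ncol(xs), hidden[1]), init(hidden[1], hidden[2]),
              init(hidden[2], 1))
    b <- list(rep(0, hidden[1]), rep(0, hidden[2]), 0)
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(bb) bb * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; epsad <- 1e-8; t_step <- 0

    fwd <- function(xb) {
      z1 <- sweep(xb %*% W[[1]], 2, b[[1]], "+"); h1 <- a1$f(z1)
      z2 <- sweep(h1 %*% W[[2]], 2, b[[2]], "+"); h2 <- a2$f(z2)
      z3 <- h2 %*% W[[3]] + b[[3]]
      p <- 1 / (1 + exp(-z3))
      list(z1 = z1, h1 = h1, z2 = z2, h2 = h2, p = p)
    }
    val_loss <- function() {
      p <- pmin(pmax(fwd(xv)$p, 1e-12), 1 - 1e-12)
      -mean(yv * log(p) + (1 - yv) * log(1 - p))
    }

    best <- list(W = W, b = b, loss = Inf)
    stall <- 0
    for (ep in seq_len(epochs)) {
      ord <- sample(nt)
      for (s in seq(1, nt, by = batch)) {
        idx <- ord[s:min(s + batch - 1, nt)]
        xb <- xt[idx, , drop = FALSE]; yb <- yt[idx]
        f <- fwd(xb)
        m <- length(idx)
        d3 <- (f$p - yb) / m                        # dL/dz3
        gW3 <- t(f$h2) %*% d3 + l2 * W[[3]]
        gb3 <- sum(d3)
        d2 <- (d3 %*% t(W[[3]])) * a2$df(f$z2, f$h2)
        gW2 <- t(f$h1) %*% d2 + l2 * W[[2]]
        gb2 <- colSums(d2)
        d1 <- (d2 %*% t(W[[2]])) * a1$df(f$z1, f$h1)
        gW1 <- t(xb) %*% d1 + l2 * W[[1]]
        gb1 <- colSums(d1)
        grads_W <- list(gW1, gW2, gW3); grads_b <- list(gb1, gb2, gb3)
        t_step <- t_step + 1
        for (l in 1:3) {
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * grads_W[[l]]
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * grads_W[[l]]^2
          mhat <- mW[[l]] / (1 - beta1^t_step)
          vhat <- vW[[l]] / (1 - beta2^t_step)
          W[[l]] <- W[[l]] - lr * mhat / (sqrt(vhat) + epsad)
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * grads_b[[l]]
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * grads_b[[l]]^2
          mbh <- mb[[l]] / (1 - beta1^t_step)
          vbh <- vb[[l]] / (1 - beta2^t_step)
          b[[l]] <- b[[l]] - lr * mbh / (sqrt(vbh) + epsad)
        }
      }
      vl <- val_loss()
      if (vl < best$loss - 1e-6) {
        best <- list(W = W, b = b, loss = vl); stall <- 0
      } else if ((stall <- stall + 1) >= patience) break
    }
  })

  structure(list(W = best$W, b = best$b, mu = mu, sd = sdv,
                 activations = activations, feature_names = colnames(x),
                 val_loss = best$loss, kind = "dnn"),
            class = "rbp_dnn")
}

#' @export
predict.rbp_dnn <- function(object, newdata, ...) {
  if (!is.null(object$feature_names) && !is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$feature_names))
    stop("feature schema mismatch")
  xs <- sweep(sweep(newdata, 2, object$mu), 2, object$sd, "/")
  a1 <- act_fun(object$activations[1]); a2 <- act_fun(object$activations[2])
  h1 <- a1$f(sweep(xs %*% object$W[[1]], 2, object$b[[1]], "+"))
  h2 <- a2$f(sweep(h1 %*% object$W[[2]], 2, object$b[[2]], "+"))
  as.vector(1 / (1 + exp(-(h2 %*% object$W[[3]] + object$b[[3]]))))
}

#' Train a classifier of the requested kind
#'
#' @param x feature matrix; @param y labels.
#' @param kind \code{"gbt"} or \code{"dnn"}.
#' @param seed RNG seed.
#' @param ... passed to [train_gbt()] or [train_dnn()].
#' @return fitted classifier.
#' @export
train_classifier <- function(x, y, kind = c("gbt", "dnn"), seed = 1, ...) {
  kind <- match.arg(kind)
  if (kind == "gbt") train_gbt(x, y, seed = seed, ...)
  else train_dnn(x, y, seed = seed, ...)
}

#' Evaluate a classifier on held-out data
#'
#' @param model fitted classifier.
#' @param x test features; @param y test labels.
#' @param threshold decision threshold (default 0.5).
#' @return list with \code{scores}, \code{confusion}, \code{metrics}.
#' @export
evaluate_model <- function(model, x, y, threshold = 0.5) {
  scores <- predict(model, x)
  cm <- confusion_matrix(scores, y, threshold)
  list(scores = scores, confusion = cm,
       metrics = classification_metrics(scores, y, threshold))
}

#' Repeated random 70:30 holdout evaluation
#'
#' The consistency check behind the reported cross-validation: each round
#' reshuffles with a seed derived from the master seed, retrains from
#' scratch on the training fraction, and evaluates on the held-out rest.
#'
#' @param x features; @param y labels.
#' @param kind classifier kind.
#' @param rounds number of repeats (default 10).
#' @param train_fraction training fraction per round (default 0.7).
#' @param seed master seed.
#' @param ... passed to the trainer.
#' @return list with \code{per_round} (metric matrix), \code{mean},
#'   \code{sd}.
#' @export
repeated_holdout <- function(x, y, kind = "gbt", rounds = 10,
                             train_fraction = 0.7, seed = 1, ...) {
  y <- as.integer(y)
  res <- lapply(seq_len(rounds), function(r) {
    rseed <- (seed * 1000L + r) %% .Machine$integer.max
    idx <- with_seed(rseed, {
      pos <- which(y == 1); neg <- which(y == 0)
      c(sample(pos, round(train_fraction * length(pos))),
        sample(neg, round(train_fraction * length(neg))))
    })
    mod <- train_classifier(x[idx, , drop = FALSE], y[idx], kind = kind,
                            seed = rseed, ...)
    evaluate_model(mod, x[-idx, , drop = FALSE], y[-idx])$metrics
  })
  per_round <- do.call(rbind, res)
  list(per_round = per_round, mean = colMeans(per_round),
       sd = apply(per_round, 2, stats::sd))
}

#' Choose the dinucleotide window size by validation accuracy
#'
#' Trains a light gradient-boosted model per candidate size on dinucleotide
#' features alone and returns the size with the best validation accuracy
#' (ties broken toward the smaller window).
#'
#' @param seqs instance sequences.
#' @param labels 0/1 labels.
#' @param candidate_sizes window sizes to try.
#' @param train_fraction fraction used for training (default 0.7).
#' @param nrounds light-model boosting rounds (default 60).
#' @param seed RNG seed.
#' @return the selected window size (integer).
#' @export
select_dinucleotide_window <- function(seqs, labels, candidate_sizes,
                                       train_fraction = 0.7, nrounds = 60,
                                       seed = 1) {
  stopifnot(length(candidate_sizes) >= 1)
  if (length(candidate_sizes) == 1) return(candidate_sizes)
  labels <- as.integer(labels)
  idx <- with_seed(seed, {
    pos <- which(labels == 1); neg <- which(labels == 0)
    c(sample(pos, round(train_fraction * length(pos))),
      sample(neg, round(train_fraction * length(neg))))
  })
  acc <- vapply(candidate_sizes, function(w) {
    feats <- impute_col_means(dinucleotide_densities(seqs, w))$mat
    mod <- train_gbt(feats[idx, , drop = FALSE], labels[idx],
                     nrounds = nrounds, seed = seed)
    unname(evaluate_model(mod, feats[-idx, , drop = FALSE],
                          labels[-idx])$metrics["Acc"])
  }, 0)
  candidate_sizes[order(-acc, candidate_sizes)][1]
}
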