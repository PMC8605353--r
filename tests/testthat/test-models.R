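test_that("confusion-matrix metrics follow the printed equations", {
  m <- classification_metrics(structure(list(TP = 50, TN = 50, FP = 0, FN = 0),
                                        class = "confusion_matrix"))
  expect_equal(unname(m[c("Acc", "F1", "MCC")]), c(1, 1, 1))
  cm <- structure(list(TP = 40, TN = 35, FP = 15, FN = 10),
                  class = "confusion_matrix")
  m2 <- classification_metrics(cm)
  expect_equal(unname(m2["Acc"]), 0.75)
  expect_equal(unname(m2["MCC"]), 1250 / sqrt(55 * 50 * 50 * 45),
               tolerance = 1e-12)
  # degenerate denominators
  z <- classification_metrics(structure(list(TP = 0, TN = 10, FP = 0, FN = 0),
                                        class = "confusion_matrix"))
  expect_equal(unname(z["MCC"]), 0)
  expect_true(is.na(z["Sn"]))
})

test_that("metrics match an independent evaluation on 1000 random matrices", {
  set.seed(81)
  for (i in 1:1000) {
    counts <- as.list(sample(0:60, 4, replace = TRUE))
    names(counts) <- c("TP", "TN", "FP", "FN")
    if (sum(unlist(counts)) == 0) next
    got <- classification_metrics(structure(counts, class = "confusion_matrix"))
    want <- naive_metrics(counts$TP, counts$TN, counts$FP, counts$FN)
    expect_equal(got[names(want)], want, tolerance = 1e-10)
  }
})

test_that("trapezoidal AUC agrees with pROC and is 0.5 for random scores", {
  skip_if_not_installed("pROC")
  set.seed(82)
  for (i in 1:200) {
    n <- sample(10:80, 1)
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)                       # force score ties
    want <- as.numeric(suppressMessages(pROC::auc(y, s,
      direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(s, y), want, tolerance = 1e-10)
  }
  y <- rep(0:1, 5000)
  s <- runif(10^4)
  expect_equal(roc_auc(s, y), 0.5, tolerance = 0.02)
})

test_that("gradient boosting learns separable data and is seed-deterministic", {
  set.seed(83)
  n <- 300
  x <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- as.integer(x[, 1] + x[, 2] > 0)
  mod <- train_gbt(x, y, nrounds = 80, seed = 2)
  expect_gte(mean((predict(mod, x) >= 0.5) == (y == 1)), 0.99)
  mod2 <- train_gbt(x, y, nrounds = 80, seed = 2)
  expect_identical(predict(mod, x), predict(mod2, x))
  expect_error(predict(mod, x[, rev(colnames(x))]), "schema")
  xna <- x; xna[1, 1] <- NA
  expect_error(train_gbt(xna, y), "impute")
})

test_that("label-shuffled training yields chance-level held-out accuracy", {
  set.seed(84)
  n <- 1000
  x <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- sample(rep(0:1, n / 2))
  tr <- sample(n, 700)
  mod <- train_gbt(x[tr, ], y[tr], nrounds = 60, seed = 1)
  acc <- mean((predict(mod, x[-tr, ]) >= 0.5) == (y[-tr] == 1))
  expect_lt(abs(acc - 0.5), 0.06)
})

test_that("the feed-forward net learns separable data deterministically", {
  set.seed(85)
  n <- 240
  x <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, paste0("f", 1:12)))
  y <- as.integer(x[, 3] - x[, 4] > 0)
  mod <- train_dnn(x, y, hidden = c(32, 32), epochs = 60, batch = 64, seed = 4)
  expect_gte(mean((predict(mod, x) >= 0.5) == (y == 1)), 0.95)
  mod2 <- train_dnn(x, y, hidden = c(32, 32), epochs = 60, batch = 64, seed = 4)
  expect_identical(predict(mod, x), predict(mod2, x))
})

test_that("repeated holdout reruns identically and tracks separability", {
  set.seed(86)
  n <- 400
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- as.integer(x[, 1] > 0)
  r1 <- repeated_holdout(x, y, rounds = 4, seed = 11, nrounds = 40)
  r2 <- repeated_holdout(x, y, rounds = 4, seed = 11, nrounds = 40)
  expect_identical(r1$per_round, r2$per_round)
  expect_gte(unname(r1$mean["Acc"]), 0.95)
  expect_lte(unname(r1$sd["Acc"]), 0.03)
  ynoise <- sample(y)
  rn <- repeated_holdout(x, ynoise, rounds = 4, seed = 11, nrounds = 40)
  expect_lt(abs(unname(rn$mean["Acc"]) - 0.5), 0.08)
})

test_that("window selection prefers informative windows and breaks ties small", {
  set.seed(87)
  expect_equal(select_dinucleotide_window(NULL, NULL, 43), 43)
  # signal concentrated within +/-20 of the anchor: a compact window wins
  mk <- function(lab) vapply(1:160, function(i) {
    s <- rand_rna(156)
    if (lab == 1) {
      core <- paste(rep("CG", 10), collapse = "")
      s <- paste0(substr(s, 1, 60), core, substr(s, 81, 156))
    }
    s
  }, "")
  seqs <- c(mk(1), mk(0))
  labels <- rep(c(1, 0), each = 160)
  w <- select_dinucleotide_window(seqs, labels, c(17, 131), seed = 5,
                                  nrounds = 30)
  expect_equal(w, 17)
})

test_that("model evaluation separates scores, confusion and metrics", {
  set.seed(88)
  x <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.integer(x[, 1] > 0)
  mod <- train_gbt(x[1:70, ], y[1:70], nrounds = 40, seed = 1)
  ev <- evaluate_model(mod, x[71:100, ], y[71:100])
  expect_equal(length(ev$scores), 30)
  expect_s3_class(ev$confusion, "confusion_matrix")
  with(ev$confusion, expect_equal(TP + TN + FP + FN, 30))
  expect_true(all(c("Acc", "Sn", "Sp", "Precision", "F1", "MCC", "AUC")
                  %in% names(ev$metrics)))
})
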