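test_that("up-sampling balances classes deterministically, train only", {
  set.seed(2)
  X <- matrix(rnorm(100 * 3), 100, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(c("normal", "agitation"), c(90, 10))
  up <- upsample(X, y, seed = 7)
  expect_equal(as.integer(table(up$labels)), c(90L, 90L))
  up2 <- upsample(X, y, seed = 7)
  expect_identical(up$index, up2$index)
  # resampled rows all come from the minority class
  expect_true(all(y[up$index[-(1:100)]] == "agitation"))
  # already balanced input is unchanged
  yb <- rep(c("normal", "agitation"), 50)
  expect_equal(upsample(X, yb, 1)$index, 1:100)
  expect_error(upsample(X, rep("normal", 100), 1), "both classes")
})

test_that("classifiers fit separable data and are seed-deterministic", {
  set.seed(5)
  n <- 120
  X <- data.frame(f1 = c(rnorm(n / 2, 0), rnorm(n / 2, 6)),
                  f2 = rnorm(n))
  y <- rep(c("normal", "agitation"), each = n / 2)
  for (algo in c("extra_trees", "random_forest", "gradient_boosting")) {
    fit <- train_classifier(X, y, algo, seed = 3)
    sc <- predict(fit, X)
    expect_equal(mean((sc >= 0.5) == (y == "agitation")), 1,
                 info = algo)
    fit2 <- train_classifier(X, y, algo, seed = 3)
    expect_identical(predict(fit2, X), sc, info = algo)
  }
  fit_m <- train_classifier(X, y, "mlp", seed = 3)
  expect_gt(auc_score(as.integer(y == "agitation"), predict(fit_m, X)),
            0.99)
  expect_error(train_classifier(X, rep("normal", n), "extra_trees"),
               "both classes")
  expect_error(train_classifier(X, y, "extra_trees",
                                manifest = c("f1", "nope")),
               "contract error")
})

test_that("metrics identities hold on every confusion matrix", {
  set.seed(11)
  for (i in 1:20) {
    y <- sample(c("agitation", "normal"), 50, replace = TRUE)
    sc <- runif(50)
    r <- metrics_report(y, sc)
    expect_equal(r$accuracy, (r$tp + r$tn) / (r$tp + r$tn + r$fp + r$fn))
    if (r$tp + r$fn > 0) expect_equal(r$recall, r$tp / (r$tp + r$fn))
    if (r$tp + r$fp > 0) expect_equal(r$precision, r$tp / (r$tp + r$fp))
    expect_true(r$auc >= 0 && r$auc <= 1)
  }
})

test_that("AUC matches brute-force pair counting", {
  set.seed(13)
  y <- rbinom(40, 1, 0.4)
  sc <- rnorm(40)
  pos <- sc[y == 1]; neg <- sc[y == 0]
  brute <- mean(outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b)))
  expect_equal(auc_score(y, sc), brute)
})

test_that("protocols split deterministically with no train/test leakage", {
  tab <- small_table()
  tab$wid <- seq_len(nrow(tab))
  bin <- tab[tab$label != "preagitation", ]
  sp1 <- agiwatch:::stratified_split(bin$label, 0.7, 42)
  sp2 <- agiwatch:::stratified_split(bin$label, 0.7, 42)
  expect_identical(sp1, sp2)
  expect_length(intersect(sp1$train, sp1$test), 0L)
  expect_setequal(c(sp1$train, sp1$test), seq_len(nrow(bin)))
  # canary: up-sampling the training partition never adds a test window id
  up <- upsample(bin[sp1$train, physio_feature_manifest()],
                 bin$label[sp1$train], 1)
  train_ids <- bin$wid[sp1$train][up$index]
  expect_length(intersect(train_ids, bin$wid[sp1$test]), 0L)
  expect_error(agiwatch:::stratified_split(bin$label, 1.0, 1),
               "protocol error")
})

test_that("personalized and general protocols produce sound reports", {
  tabs <- list(pA = small_table(2), pB = small_table(3))
  pers <- run_personalized_protocol(tabs, algos = "extra_trees", seed = 1)
  expect_equal(nrow(pers), 2L)
  expect_true(all(pers$accuracy >= 0 & pers$accuracy <= 1))
  pers2 <- run_personalized_protocol(tabs, algos = "extra_trees", seed = 1)
  expect_equal(pers$accuracy, pers2$accuracy)
  gen <- run_general_protocol(tabs, algos = "extra_trees", seed = 1)
  expect_equal(gen$participant_id, "all")
  expect_error(run_general_protocol(tabs["pA"], algos = "extra_trees"),
               "at least 2")
  one_class <- tabs
  one_class$pA$label <- "normal"
  expect_warning(
    run_personalized_protocol(one_class["pA"] , algos = "extra_trees",
                              seed = 1) |> try(silent = TRUE),
    "single class")
})

test_that("model comparison matches a closed-form paired t oracle", {
  mk <- function(algo, acc, auc)
    data.frame(participant_id = paste0("p", seq_along(acc)), algo = algo,
               accuracy = acc, auc = auc)
  set.seed(17)
  acc_a <- runif(6, 0.8, 1); acc_b <- runif(6, 0.8, 1)
  auc_a <- runif(6, 0.9, 1); auc_b <- runif(6, 0.9, 1)
  rep <- rbind(mk("extra_trees", acc_a, auc_a), mk("mlp", acc_b, auc_b))
  cm <- compare_models(rep)
  d <- acc_b - acc_a
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  p_oracle <- 2 * pt(-abs(tstat), length(d) - 1)
  expect_equal(cm$p_vs_reference[cm$algo == "mlp"], p_oracle,
               tolerance = 1e-9)
  m <- mean(acc_b); s <- sd(acc_b)
  half <- qt(0.975, 5) * s / sqrt(6)
  expect_equal(cm$mean_accuracy[cm$algo == "mlp"], m)
  expect_equal(cm$ci_lo_accuracy[cm$algo == "mlp"], m - half)
  expect_true(all(cm$ci_lo_accuracy <= cm$mean_accuracy &
                    cm$mean_accuracy <= cm$ci_hi_accuracy))
})

test_that("degenerate comparisons: ties and exact differences", {
  mk <- function(algo, acc)
    data.frame(participant_id = paste0("p", 1:3), algo = algo,
               accuracy = acc, auc = acc)
  cm <- compare_models(rbind(mk("extra_trees", rep(0.9, 3)),
                             mk("mlp", rep(0.9, 3))))
  expect_equal(cm$p_vs_reference[cm$algo == "mlp"], 1.0)
  expect_equal(cm$sd_accuracy, c(0, 0))
  cm2 <- compare_models(rbind(mk("extra_trees", rep(0.9, 3)),
                              mk("mlp", rep(0.8, 3))))
  expect_equal(cm2$mean_accuracy[cm2$algo == "extra_trees"] -
                 cm2$mean_accuracy[cm2$algo == "mlp"], 0.1)
  expect_true(cm2$exact_difference[cm2$algo == "mlp"])
  # unequal participant sets are a contract error
  bad <- rbind(mk("extra_trees", rep(0.9, 3)),
               mk("mlp", rep(0.9, 3))[1:2, ])
  expect_error(compare_models(bad), "contract error")
})
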