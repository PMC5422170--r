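# A small, cleanly separated 3-class feature table used across classifier
# tests; built directly (not via the silhouette pipeline) to keep these
# tests fast.
toy_population <- function(n_per_class = 40, seed = 123, sd = 0.4) {
  set.seed(seed)
  centers <- list(c(30, 12, 8, 6, 4, 2, 30),
                  c(40, 16, 10, 8, 5, 3, 45),
                  c(50, 20, 12, 10, 6, 4, 60))
  rows <- lapply(seq_along(centers), function(k) {
    m <- matrix(rnorm(n_per_class * 7, mean = rep(centers[[k]], each = n_per_class),
                      sd = sd), n_per_class, 7)
    df <- tibble::as_tibble(as.data.frame(m))
    names(df) <- seed_feature_names
    df$label <- paste0("V", k)
    df
  })
  dplyr::bind_rows(rows)
}

test_that("the hidden-layer sizing rule adds input, output and offset", {
  expect_identical(hidden_nodes(7, 3, 0), 10L)
  expect_identical(hidden_nodes(7, 3, -2), 8L)
  expect_identical(hidden_nodes(7, 3, 2), 12L)
  expect_error(hidden_nodes(7, 3, 1), "k must be")
  expect_error(hidden_nodes(1, 1, -2), "at least 1")
})

test_that("BPNN training is deterministic and converges on separable data", {
  pop <- toy_population()
  f1 <- train_bpnn(pop, seed = 7, max_epochs = 5000)
  f2 <- train_bpnn(pop, seed = 7, max_epochs = 5000)
  expect_identical(f1$W1, f2$W1)
  expect_identical(f1$W2, f2$W2)
  expect_identical(f1$log, f2$log)
  expect_true(f1$converged)
  expect_lt(glance(f1)$final_mse, 0.01)
  expect_equal(f1$n_h, 10L)
  # training-set predictions recover the labels
  pred <- predict(f1, pop)
  expect_gte(mean(pred$.label == pop$label), 0.99)
})

test_that("irreducibly conflicting labels cannot reach tolerance and are flagged", {
  df <- toy_population(2)[c(1, 1), ]
  df$label <- c("a", "b")
  expect_warning(fit <- train_bpnn(df, max_epochs = 60), "did not reach tolerance")
  expect_false(fit$converged)
})

test_that("epoch MSE trends downward on separable data", {
  pop <- toy_population()
  fit <- train_bpnn(pop, seed = 1, max_epochs = 5000)
  mse <- fit$log$mse
  k <- length(mse)
  if (k > 20) {
    head_win <- mean(mse[1:10])
    tail_win <- mean(mse[(k - 9):k])
    expect_lt(tail_win, head_win)
  }
  expect_lt(mse[k], mse[1])
})

test_that("BPNN prediction applies stored ranges and breaks ties by label order", {
  pop <- toy_population()
  fit <- train_bpnn(pop, seed = 2)
  x <- pop[5, ]
  expect_identical(predict(fit, x), predict(fit, x))
  # degenerate model with all-zero weights gives identical activations
  degen <- fit
  degen$W1[] <- 0; degen$b1[] <- 0; degen$W2[] <- 0; degen$b2[] <- 0
  p <- predict(degen, pop[1:3, ])
  expect_true(all(p$.label == fit$labels[1]))
  expect_error(predict(fit, pop[, 1:3]), "missing feature columns")
})

test_that("tanh hidden activation is available and trains", {
  pop <- toy_population()
  fit <- train_bpnn(pop, seed = 3, activation = "tanh", max_epochs = 5000)
  expect_true(fit$converged)
})

test_that("Gaussian Bayes places the two-cloud boundary at the midpoint", {
  set.seed(42)
  n <- 400
  base <- matrix(rnorm(n * 7), n, 7)
  df <- tibble::as_tibble(as.data.frame(base))
  names(df) <- seed_feature_names
  df$len_AB <- df$len_AB + rep(c(0, 10), each = n / 2)
  df$label <- rep(c("a", "b"), each = n / 2)
  fit <- train_bayes(df)
  expect_equal(fit$priors, c(0.5, 0.5))
  mid <- df[1, ]
  mid$len_AB <- 5   # equidistant in the separated coordinate
  probe <- df[1, ]; probe$len_AB <- 1
  expect_equal(as.character(predict(fit, probe)$.label), "a")
  probe$len_AB <- 9
  expect_equal(as.character(predict(fit, probe)$.label), "b")
})

test_that("Bayes training validates class sizes and predicts class means correctly", {
  pop <- toy_population()
  fit <- train_bayes(pop)
  means <- dplyr::summarise(dplyr::group_by(pop, label),
                            dplyr::across(dplyr::all_of(seed_feature_names), mean))
  pred <- predict(fit, means)
  expect_equal(as.character(pred$.label), means$label)

  solo <- pop[c(1, 2, 41), ]
  expect_error(train_bayes(solo), "two samples per class")
})

test_that("Bayes predictions agree with a direct density-evaluation oracle", {
  pop <- toy_population(sd = 2)   # overlapping clouds make the check non-trivial
  fit <- train_bayes(pop)
  means <- lapply(fit$params, `[[`, "mean")
  covs <- lapply(fit$params, `[[`, "cov")
  set.seed(99)
  probes <- toy_population(10, seed = 77, sd = 4)
  pred <- predict(fit, probes)
  for (i in seq_len(nrow(probes))) {
    x <- as.numeric(probes[i, seed_feature_names][1, ])
    expect_equal(as.character(pred$.label[i]),
                 oracle_bayes_label(x, means, covs, fit$priors, fit$classes))
  }
})

test_that("Bayes classifier agrees with MASS::qda on balanced data", {
  skip_if_not_installed("MASS")
  pop <- toy_population(sd = 3)
  fit <- train_bayes(pop)
  q <- MASS::qda(as.matrix(pop[seed_feature_names]), grouping = pop$label)
  probes <- toy_population(15, seed = 31, sd = 5)
  ours <- as.character(predict(fit, probes)$.label)
  theirs <- as.character(predict(q, as.matrix(probes[seed_feature_names]))$class)
  expect_gte(mean(ours == theirs), 0.95)
})

test_that("tidy and glance summarise classifier fits", {
  pop <- toy_population()
  fit <- train_bpnn(pop, seed = 5)
  td <- tidy(fit)
  expect_equal(nrow(td), 10 * 7 + 10 + 3 * 10 + 3)
  gl <- glance(fit)
  expect_equal(gl$n_h, 10L)
  bf <- train_bayes(pop)
  tb <- tidy(bf)
  expect_equal(nrow(tb), 3 * 7)
  expect_equal(glance(bf)$n_classes, 3L)
})
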