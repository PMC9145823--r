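test_that("stratified splits partition the data with near-equal fold sizes", {
  ds <- generate_mode_dataset(66, c(1, 1, 1), 0, seed = 7)
  sp <- stratified_splits(ds$labels, 5, seed = 7)
  sizes <- sort(vapply(sp, function(s) length(s$test_idx), integer(1)),
                decreasing = TRUE)
  expect_equal(sizes, c(14L, 13L, 13L, 13L, 13L))
  all_test <- sort(unlist(lapply(sp, `[[`, "test_idx")))
  expect_equal(all_test, 1:66)                       # cover, no repeats
  for (s in sp) {
    expect_length(intersect(s$train_idx, s$test_idx), 0L)
    expect_equal(sort(c(s$train_idx, s$test_idx)), 1:66)
  }
})

test_that("balanced folds keep exact per-class counts when divisible", {
  ds <- generate_mode_dataset(30, c(1, 1, 1), 0, seed = 2)
  sp <- stratified_splits(ds$labels, 5, seed = 2)
  per_fold <- sapply(sp, function(s) as.integer(table(ds$labels[s$test_idx])))
  expect_true(all(per_fold == 2L))
})

test_that("per-fold class proportions deviate by at most one record", {
  ds <- generate_mode_dataset(50, c(3, 1, 1), 0, seed = 4)
  sp <- stratified_splits(ds$labels, 5, seed = 4)
  tab <- table(ds$labels)
  for (s in sp) {
    got <- table(ds$labels[s$test_idx])
    expect_true(all(abs(got - tab / 5) <= 1))
  }
})

test_that("a class smaller than the fold count raises a stratification error", {
  labels <- factor(c(rep("zigzag", 10), rep("mixed", 10), rep("bumped", 3)))
  expect_error(stratified_splits(labels, 5, seed = 1), "stratification error")
})

test_that("complement naive Bayes matches the reference implementation", {
  # weights and predictions verified against an external complement-NB
  # reference (alpha = 1, no weight normalization) on this fixture
  x <- matrix(c(1, 2, 0,
                0, 1, 3,
                2, 0, 1,
                1, 1, 1,
                0, 2, 2,
                3, 0, 0), ncol = 3, byrow = TRUE)
  y <- factor(c("zigzag", "mixed", "zigzag", "bumped", "mixed", "bumped"),
              levels = c("bumped", "mixed", "zigzag"))
  fit <- dldflow:::cnb_fit(x, y, alpha = 1)
  ref <- -matrix(c(1.446918982936325, 1.041453874828161, 0.887303195000903,
                   0.628608659422374, 1.321755839982319, 1.609437912434100,
                   1.223775431622116, 1.223775431622116, 0.887303195000903),
                 ncol = 3, byrow = TRUE)
  expect_equal(unname(fit$weights), ref, tolerance = 1e-12)
  xt <- matrix(c(2, 1, 0,
                 0, 1, 4,
                 1, 1, 2), ncol = 3, byrow = TRUE)
  expect_equal(as.character(dldflow:::cnb_predict(fit, xt)),
               c("bumped", "mixed", "mixed"))
  expect_error(dldflow:::cnb_fit(matrix(c(-1, 1), 1, 2), factor("a")),
               "non-negative")
})

test_that("all three families reach perfect accuracy on separable data", {
  ds <- generate_mode_dataset(66, c(1, 1, 1), noise_sd = 0, seed = 7)
  for (fam in c("CNB", "KNN", "SVM_RBF")) {
    m <- train_mode_model(ds, fam, seed = 7)
    expect_equal(unname(m$split_accuracies), rep(1, 5), label = fam)
    expect_equal(m$best_split_accuracy, 1)
    expect_equal(m$best_split_accuracy, max(m$split_accuracies))
  }
})

test_that("KNN keeps the smallest neighbor count among perfect sweeps", {
  ds <- generate_mode_dataset(66, c(1, 1, 1), noise_sd = 0, seed = 7)
  m <- train_mode_model(ds, "KNN", seed = 7)
  expect_equal(m$chosen_k, 2L)
  expect_true(all(m$split_chosen_k >= 2 & m$split_chosen_k <= 55))
})

test_that("KNN neighbor selection equals an independent sweep", {
  ds <- generate_mode_dataset(36, c(1, 1, 1), noise_sd = 0.4, seed = 9)
  m <- train_mode_model(ds, "KNN", seed = 9, k_range = 2:15)
  sp <- stratified_splits(ds$labels, 5, seed = 9)
  for (f in seq_along(sp)) {
    tr <- sp[[f]]$train_idx; te <- sp[[f]]$test_idx
    mu <- colMeans(ds$features[tr, ]); sg <- apply(ds$features[tr, ], 2, sd)
    sg[sg == 0] <- 1
    xtr <- scale(ds$features[tr, ], mu, sg)
    xte <- scale(ds$features[te, ], mu, sg)
    accs <- vapply(2:15, function(k) {
      set.seed(9 + k)
      mean(class::knn(xtr, xte, ds$labels[tr], k = k) == ds$labels[te])
    }, numeric(1))
    expect_equal(m$split_accuracies[f], max(accs))
    expect_equal(m$split_chosen_k[f], (2:15)[which(accs == max(accs))[1]])
  }
})

test_that("training is reproducible under a fixed seed", {
  ds <- generate_mode_dataset(45, c(1, 1, 1), noise_sd = 0.3, seed = 5)
  for (fam in c("CNB", "KNN", "SVM_RBF")) {
    m1 <- train_mode_model(ds, fam, seed = 11)
    m2 <- train_mode_model(ds, fam, seed = 11)
    expect_identical(m1$split_accuracies, m2$split_accuracies)
    expect_identical(m1$chosen_k, m2$chosen_k)
    expect_identical(as.character(predict(m1, ds$features)),
                     as.character(predict(m2, ds$features)))
  }
})

test_that("evaluation reports a perfect model as all ones", {
  ds <- generate_mode_dataset(66, c(1, 1, 1), noise_sd = 0, seed = 7)
  m <- train_mode_model(ds, "CNB", seed = 7)
  sp <- stratified_splits(ds$labels, 5, seed = 7)
  te <- sp[[m$best_split]]$test_idx
  ev <- evaluate_mode_model(m, ds$features[te, , drop = FALSE], ds$labels[te])
  expect_true(all(ev$confusion[upper.tri(ev$confusion)] == 0))
  expect_true(all(ev$confusion[lower.tri(ev$confusion)] == 0))
  expect_equal(ev$report$precision, rep(1, 3))
  expect_equal(ev$report$recall, rep(1, 3))
  expect_equal(ev$report$f1, rep(1, 3))
  expect_equal(ev$accuracy, 1)
  # counting identity: confusion row sums equal per-true-class support
  expect_equal(as.integer(rowSums(ev$confusion)),
               as.integer(table(factor(ds$labels[te], levels = m$classes))))
})

test_that("a fully wrong prediction set scores zero", {
  ds <- generate_mode_dataset(30, c(1, 1, 1), noise_sd = 0, seed = 3)
  m <- train_mode_model(ds, "CNB", seed = 3)
  two <- ds$features[c(1, 11), , drop = FALSE]  # one zigzag, one mixed
  wrong <- c("bumped", "bumped")
  ev <- evaluate_mode_model(m, two, wrong)
  expect_equal(sum(diag(ev$confusion)), 0)
  expect_equal(ev$accuracy, 0)
})

test_that("mode prediction follows the size/distribution rule", {
  ds <- generate_mode_dataset(66, c(1, 1, 1), noise_sd = 0, seed = 7)
  m <- train_mode_model(ds, "CNB", seed = 7)
  expect_equal(predict_mode(m, 2.0, 20, c(0, 0, 0, 0, 0, 0, 0, 0, 2, 3, 4, 5)),
               "bumped")
  expect_equal(predict_mode(m, 2.0, 10, c(5, 4, 3, 2, 0, 0, 0, 0, 0, 0, 0, 0)),
               "zigzag")
  expect_error(predict_mode(m, 2.0, 10, c(1, 2, 3)), "dimension error")
})

test_that("KNN memorizes a training record at covering k", {
  ds <- generate_mode_dataset(66, c(1, 1, 1), noise_sd = 0, seed = 7)
  m <- train_mode_model(ds, "KNN", seed = 7)
  sp <- stratified_splits(ds$labels, 5, seed = 7)
  tr <- sp[[m$best_split]]$train_idx
  i <- tr[1]
  expect_equal(as.character(predict(m, ds$features[i, , drop = FALSE])),
               as.character(ds$labels[i]))
})

test_that("models persist with sidecars and survive a round trip", {
  ds <- generate_mode_dataset(30, c(1, 1, 1), noise_sd = 0, seed = 3)
  m <- train_mode_model(ds, "CNB", seed = 3)
  path <- file.path(withr::local_tempdir(), "model_cnb.rds")
  save_mode_model(m, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_mode_model(path)
  expect_identical(as.character(predict(back, ds$features)),
                   as.character(predict(m, ds$features)))
  # sidecar/model family mismatch is an integrity error
  meta <- jsonlite::read_json(paste0(path, ".json"))
  meta$family <- "KNN"
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(load_mode_model(path), "integrity error")
})

test_that("dataset assembly turns summaries into 14-feature records", {
  geom <- channel_geometry(seq(0, 120, by = 10))
  mk <- function(rows) {
    led <- new_detection_ledger(1)
    led$detections <- data.frame(frame_index = rep(2L, length(rows)),
                                 row = rows, col = seq_along(rows))
    summarize_run(led, geom)
  }
  s1 <- mk(rep(115, 25))  # all 25 particles in outlet 12
  ds <- assemble_dataset(list(
    list(summary = s1, flow_rate = 1.5, particle_size = 20, mode = "bumped"),
    list(summary = s1, flow_rate = 1.5, particle_size = 20, mode = "bumped")))
  expect_equal(dim(ds$features), c(2L, 14L))
  expect_equal(unname(ds$features[1, "outlet_12"]), 1)
  expect_true(all(ds$features[1, sprintf("outlet_%02d", 1:11)] == 0))
  # two identical summaries stay two identical rows
  expect_equal(ds$features[1, ], ds$features[2, ])
  expect_error(
    assemble_dataset(list(list(summary = s1, flow_rate = 1, particle_size = 10,
                               mode = NA))),
    "labeling error")
  empty <- mk(numeric(0))
  expect_warning(
    ds2 <- assemble_dataset(list(
      list(summary = s1, flow_rate = 1, particle_size = 10, mode = "zigzag"),
      list(summary = empty, flow_rate = 1, particle_size = 10, mode = "zigzag"))),
    "zero assigned")
  expect_equal(nrow(ds2$features), 1L)
})
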