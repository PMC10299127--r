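random_stack <- function(n = 12, seed = 1, strategy = "enhanced") {
  set.seed(seed)
  m <- matrix(rnorm(n * n), n); m <- (m + t(m)) / 2; diag(m) <- 0
  build_stack(connectivity_matrix(m, "tangent"), strategy)
}

test_that("prepare_input maps the stack to [0,255] then normalizes", {
  st <- random_stack()
  x <- prepare_input(st, backbone_spec("TinyConv"))      # tf mode: [-1, 1]
  raw <- (x + 1) * 127.5                                 # undo normalization
  expect_equal(min(raw), 0, tolerance = 1e-12)
  expect_equal(max(raw), 255, tolerance = 1e-12)
  # monotone: relative order of any two entries preserved
  v0 <- as.numeric(st$channels); v1 <- as.numeric(raw)
  expect_equal(order(v0), order(v1))
  # scale invariance of the shared min-max map
  st10 <- st; st10$channels <- st$channels * 10
  expect_equal(prepare_input(st10, backbone_spec("TinyConv")), x,
               tolerance = 1e-12)
  # caffe mode subtracts channel means of the 0-255 image
  xc <- prepare_input(st, backbone_spec("VGG16"))
  expect_equal(xc[, , 1], raw[, , 1] - 103.939, tolerance = 1e-10)
  flat <- st; flat$channels <- array(5, dim(st$channels))
  expect_error(prepare_input(flat), "constant stack")
})

test_that("extract_features runs TinyConv and refuses absent pretrained weights", {
  st <- random_stack(16)
  x <- prepare_input(st)
  f <- extract_features(x, backbone_spec("TinyConv"))
  expect_equal(dim(f), as.integer(feature_map_shape("TinyConv", 16)))
  expect_error(extract_features(x, backbone_spec("VGG16")),
               "not available offline")
  bb <- instantiate_tinyconv(32)
  expect_error(extract_features(x, bb), "side 32")
})

test_that("TinyConv gradients match finite differences", {
  set.seed(8)
  bb <- instantiate_tinyconv(8, 3, seed = 4)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  v <- rnorm(prod(bb$feature_shape))
  loss <- function(params) {
    b2 <- bb; b2$params <- params
    sum(as.numeric(connstack:::tinyconv_forward(b2, x)$features) * v)
  }
  fw <- connstack:::tinyconv_forward(bb, x, with_cache = TRUE)
  grads <- connstack:::tinyconv_backward(bb, fw$caches,
                                         array(v, dim(fw$features)))
  for (nm in c("W1", "b2", "W3")) {
    p <- bb$params
    i <- sample(length(p[[nm]]), 1)
    eps <- 1e-5
    p1 <- p; p1[[nm]][i] <- p1[[nm]][i] + eps
    p2 <- p; p2[[nm]][i] <- p2[[nm]][i] - eps
    num <- (loss(p1) - loss(p2)) / (2 * eps)
    expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
  }
})

test_that("head contract: parameters, dropout range, sigmoid output", {
  h <- build_head(c(3, 3, 32), dropout_rate = 0.5)
  expect_equal(h$n_params, 3L * 3L * 32L + 1L)
  expect_error(build_head(c(2, 2, 4), dropout_rate = 1), "\\[0, 1\\)")
  h0 <- build_head(c(4), dropout_rate = 0)
  expect_equal(h0$dropout, 0)                      # plain linear classifier
  p <- connstack:::head_predict(h, matrix(rnorm(288 * 5), 5))
  expect_true(all(p > 0 & p < 1))
})

test_that("phase-1 head reaches accuracy 1 on separable features (convex oracle)", {
  set.seed(21)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  f <- cbind(rnorm(n) + 3 * y, rnorm(n) - 2 * y)   # linearly separable shift
  # independent convex fit confirms separability of this feature set
  or <- suppressWarnings(stats::glm(y ~ f, family = stats::binomial()))
  expect_equal(mean((stats::fitted(or) > 0.5) == y), 1)
  h <- train_head(f, y, build_head(2, dropout_rate = 0), lr = 0.1,
                  epochs = 500, patience = 500, seed = 2)
  p <- connstack:::head_predict(h, f)
  expect_equal(mean((p > 0.5) == y), 1)
})

test_that("frozen backbone is bit-identical after phase-1 training", {
  co <- simulate_cohort(tiny_cohort_spec())
  stacks <- cohort_stacks(co$subjects, "correlation", "enhanced")
  idx_tr <- c(1:4, 7:10); idx_va <- c(5, 6, 11, 12)
  bb <- instantiate_tinyconv(12, seed = 3)
  before <- bb$params
  sched <- training_schedule(epochs_phase1 = 5, seed = 3)
  fit <- train_transfer(list(stacks = stacks[idx_tr], labels = co$labels[idx_tr]),
                        list(stacks = stacks[idx_va], labels = co$labels[idx_va]),
                        backbone = bb, schedule = sched)
  expect_identical(fit$backbone$params, before)
  expect_false(fit$fine_tuned)
  expect_true(all(c("train_loss", "val_loss") %in% names(fit$history$phase1)))
})

test_that("fine-tuning updates the backbone at a lower learning rate", {
  co <- simulate_cohort(tiny_cohort_spec())
  stacks <- cohort_stacks(co$subjects, "correlation", "enhanced")
  idx_tr <- c(1:4, 7:10); idx_va <- c(5, 6, 11, 12)
  sched <- training_schedule(epochs_phase1 = 5, epochs_fine_tune = 2,
                             fine_tune = TRUE, seed = 3)
  expect_lt(sched$lr_fine_tune, sched$lr_phase1)   # declared schedule contract
  expect_error(training_schedule(lr_phase1 = 1e-5, lr_fine_tune = 1e-3),
               "lower")
  bb <- instantiate_tinyconv(12, seed = 3)
  before <- bb$params
  fit <- train_transfer(list(stacks = stacks[idx_tr], labels = co$labels[idx_tr]),
                        list(stacks = stacks[idx_va], labels = co$labels[idx_va]),
                        backbone = bb, schedule = sched)
  expect_false(identical(fit$backbone$params, before))
  expect_true(!is.null(fit$history$phase2))
})

test_that("single-class training sets are rejected", {
  co <- simulate_cohort(tiny_cohort_spec())
  stacks <- cohort_stacks(co$subjects, "correlation", "enhanced")
  expect_error(train_transfer(list(stacks = stacks[1:4],
                                   labels = co$labels[1:4]),
                              list(stacks = stacks[7:8],
                                   labels = co$labels[7:8])),
               "single class")
})

test_that("accuracy implements (TP+TN)/(TP+TN+FP+FN)", {
  expect_equal(accuracy(confusion_counts(5, 0, 5, 0)), 1)
  expect_equal(accuracy(confusion_counts(3, 1, 4, 2)), 0.7)
  expect_equal(accuracy(confusion_counts(0, 2, 0, 3)), 0)
  expect_error(accuracy(confusion_counts(0, 0, 0, 0)), "undefined")
  expect_error(confusion_counts(-1, 0, 0, 0), "nonnegative")
})

test_that("cross_validate partitions subjects and honours stub classifiers", {
  co <- simulate_cohort(cohort_spec(n_per_group = 15, n_rois = 8,
                                    n_timepoints = 30, seed = 4))
  stacks <- cohort_stacks(co$subjects, "correlation", "plain")
  oracle_stub <- function(train, val) function(test) test$labels
  rep <- cross_validate(stacks, co$labels, k = 5, seed = 9,
                        classifier = oracle_stub)
  expect_s3_class(rep, "cv_report")
  expect_length(rep$per_fold, 5L)
  expect_equal(rep$mean_accuracy, 1)
  all_test <- sort(unlist(lapply(rep$per_fold, `[[`, "test_idx")))
  expect_equal(all_test, seq_along(stacks))      # disjoint and exhaustive
  accs <- vapply(rep$per_fold, `[[`, 0, "accuracy")
  expect_equal(rep$mean_accuracy, mean(accs))
  # confusion counts in each fold sum to the fold's test-set size
  for (pf in rep$per_fold) {
    cc <- pf$confusion
    expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, length(pf$test_idx))
  }
  expect_error(cross_validate(stacks[1:6], co$labels[1:6], k = 10,
                              classifier = oracle_stub),
               "fewer subjects")
  expect_error(cross_validate(stacks[1:21], co$labels[1:21], k = 10,
                              classifier = oracle_stub),
               "at least 10 subjects per class")
})

test_that("cross_validate is reproducible under a fixed seed", {
  co <- simulate_cohort(tiny_cohort_spec(n_per_group = 8))
  stacks <- cohort_stacks(co$subjects, "correlation", "enhanced")
  sched <- training_schedule(epochs_phase1 = 10, seed = 0)
  r1 <- cross_validate(stacks, co$labels, k = 4, seed = 5, schedule = sched)
  r2 <- cross_validate(stacks, co$labels, k = 4, seed = 5, schedule = sched)
  expect_identical(r1$fingerprint, r2$fingerprint)
  expect_identical(vapply(r1$per_fold, `[[`, 0, "accuracy"),
                   vapply(r2$per_fold, `[[`, 0, "accuracy"))
  r3 <- cross_validate(stacks, co$labels, k = 4, seed = 6, schedule = sched)
  expect_false(identical(lapply(r1$per_fold, `[[`, "test_idx"),
                         lapply(r3$per_fold, `[[`, "test_idx")))
})

test_that("cv reports serialize to JSON and CSV", {
  co <- simulate_cohort(cohort_spec(n_per_group = 5, n_rois = 8,
                                    n_timepoints = 30, seed = 4))
  stacks <- cohort_stacks(co$subjects, "correlation", "plain")
  rep <- cross_validate(stacks, co$labels, k = 5, seed = 1,
                        classifier = function(train, val) function(test) test$labels)
  dir <- withr::local_tempdir()
  jp <- file.path(dir, "rep.json"); cp <- file.path(dir, "rep.csv")
  write_cv_report(rep, jp, cp)
  back <- jsonlite::read_json(jp)
  expect_equal(back$mean_accuracy, 1)
  expect_equal(length(back$folds), 5L)
  expect_equal(nrow(utils::read.csv(cp)), 5L)
})
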