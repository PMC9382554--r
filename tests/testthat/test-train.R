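test_that("metrics agree with an independent implementation on random tables", {
  set.seed(19)
  labels <- c("None", "R1", "R2", "R3")
  for (i in 1:100) {
    n <- sample(20:60, 1)
    gold <- sample(labels, n, replace = TRUE)
    pred <- ifelse(stats::runif(n) < 0.5, gold, sample(labels, n, replace = TRUE))
    ev <- relation_metrics(pred, gold, labels, null_label = "None")
    ref <- prf_ref(pred, gold, labels, null_label = "None")
    expect_equal(ev$accuracy, ref$accuracy)
    expect_equal(ev$micro_f1, ref$micro_f1)
    # confusion-matrix row sums equal per-class gold counts
    expect_equal(as.numeric(rowSums(ev$confusion)),
                 as.numeric(table(factor(gold, levels = labels))))
  }
})

test_that("hand-computed binary counts give the textbook P/R/F1", {
  # TP = 2, FP = 1, FN = 1 on the positive class
  gold <- c("Yes", "Yes", "Yes", "No", "No", "No")
  pred <- c("Yes", "Yes", "No", "Yes", "No", "No")
  ev <- relation_metrics(pred, gold, c("No", "Yes"), null_label = "No")
  expect_equal(ev$micro_precision, 2 / 3)
  expect_equal(ev$micro_recall, 2 / 3)
  expect_equal(ev$micro_f1, 2 / 3)

  # perfect predictions
  evp <- relation_metrics(gold, gold, c("No", "Yes"), null_label = "No")
  expect_equal(evp$accuracy, 1)
  expect_equal(evp$micro_f1, 1)

  # all-null predictions score zero micro-F1 over positives
  evn <- relation_metrics(rep("No", 6), gold, c("No", "Yes"),
                          null_label = "No")
  expect_equal(evn$micro_f1, 0)

  expect_error(relation_metrics(character(0), character(0)), "empty")
})

test_that("a short training run is finite, logged, and seed-reproducible", {
  corpus <- tiny_corpus(n = 24, seed = 31, lengths = c(5, 10))
  cfg <- toy_config(epochs = 2, patience = 10)
  fit <- relgcn(corpus[1:20], dev = corpus[21:24], config = cfg,
                labels = binary_labels())
  expect_s3_class(fit, "relgcn")
  expect_true(all(is.finite(fit$log$train_loss)))
  expect_identical(nrow(fit$log), 2L)
  # learning rate decays multiplicatively per epoch
  expect_equal(fit$log$lr, cfg$lr * cfg$lr_decay^(0:1))

  fit2 <- relgcn(corpus[1:20], dev = corpus[21:24], config = cfg,
                 labels = binary_labels())
  expect_identical(fit$log, fit2$log)
  expect_identical(predict(fit, corpus), predict(fit2, corpus))

  # prediction surface
  probs <- predict(fit, corpus[1:5], type = "prob")
  expect_identical(dim(probs), c(5L, 2L))
  expect_equal(rowSums(probs), rep(1, 5), tolerance = 1e-9)
  expect_true(all(predict(fit, corpus[1:5]) %in% c("No", "Yes")))
})

test_that("training rejects label mismatches and reports divergence", {
  corpus <- tiny_corpus(n = 12, seed = 5)
  odd <- relation_instance(c("a", "b", "c", "d", "e"),
                           list(subject = c(0, 1), object = c(2, 3)),
                           "Maybe", id = "odd")
  expect_error(relgcn(corpus, dev = list(odd), config = toy_config(),
                      labels = binary_labels()),
               "absent from the label set")
})

test_that("cross-validation partitions the corpus and averages fold accuracy", {
  corpus <- tiny_corpus(n = 30, seed = 41, lengths = c(5, 9))
  cfg <- toy_config(epochs = 1)
  cv <- crossvalidate(corpus, folds = 3, config = cfg,
                      labels = binary_labels())
  expect_s3_class(cv, "relgcn_cv")
  expect_length(cv$fold_accuracy, 3)
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracy))
  # assignment is a partition: every instance in exactly one fold
  expect_identical(sort(unique(cv$assignment)), 1:3)
  expect_length(cv$assignment, 30)
  expect_identical(as.integer(table(cv$assignment)), rep(10L, 3))

  cv2 <- crossvalidate(corpus, folds = 3, config = cfg,
                       labels = binary_labels())
  expect_identical(cv$assignment, cv2$assignment)   # seeded split

  expect_error(crossvalidate(corpus[1:2], folds = 3, config = cfg),
               "more folds")
})

test_that("length-stratified evaluation partitions by token count", {
  corpus <- tiny_corpus(n = 20, seed = 51, lengths = c(5, 30))
  cfg <- toy_config(epochs = 1)
  fit <- relgcn(corpus[1:16], dev = corpus[17:20], config = cfg,
                labels = binary_labels())
  bins <- list(c(0, 12), c(12, 31))
  per_bin <- length_stratified_eval(fit, corpus, bins)
  expect_true(length(per_bin) >= 1)
  expect_identical(sum(vapply(per_bin, `[[`, numeric(1), "n")), 20)

  whole <- length_stratified_eval(fit, corpus, list(c(0, Inf)))
  expect_length(whole, 1)
  expect_equal(whole[[1]]$accuracy, evaluate(fit, corpus)$accuracy)

  expect_error(length_stratified_eval(fit, corpus, list(c(0, 6))),
               "do not cover")
})

test_that("config files round-trip through JSON and YAML", {
  cfg <- toy_config(heads = 2, use_pruning = FALSE, use_feature_capture = TRUE,
                    kernel_sigma = 2.5)
  fj <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, fj)
  expect_identical(read_config(fj), cfg)
  fy <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, fy)
  expect_identical(read_config(fy), cfg)
})

test_that("contradictory ablation flags are rejected at config time", {
  expect_error(relgcn_config(use_feature_capture = FALSE, use_pruning = TRUE),
               "contradictory")
  expect_error(relgcn_config(lr_decay = 0), "lr_decay")
  expect_error(relgcn_config(hidden_dim = 10, chunk_size = 4), "divide")
})

test_that("heat-map export writes matrices that read back bit-identically", {
  corpus <- tiny_corpus(n = 12, seed = 61, lengths = c(6, 9))
  cfg <- toy_config(epochs = 1)
  fit <- relgcn(corpus[1:10], dev = corpus[11:12], config = cfg,
                labels = binary_labels())
  out <- withr::local_tempdir()
  am <- export_heatmaps(fit, corpus[[1]], out, png = FALSE)
  n <- length(corpus[[1]]$tokens)
  for (nm in c("A", "B", "C")) {
    M <- am[[nm]]
    expect_identical(dim(M), c(n, n))
    expect_equal(rowSums(M), rep(1, n), tolerance = 1e-6)
    back <- read_matrix(file.path(out, paste0(nm, ".tsv")))
    expect_identical(back, unname(M))
  }
  expect_error(attention_matrices(fit, relation_instance(
    "x", list(subject = c(0, 1), object = c(0, 1)), "No")),
    "at least 2 tokens")
})
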