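test_that("stepwise recovers an exact 1-sparse signal among noise features", {
  set.seed(201)
  X <- matrix(rnorm(100 * 21), 100, 21,
              dimnames = list(NULL, c("x1", paste0("noise", 1:20))))
  y <- 2 + 3 * X[, "x1"]
  fit <- stepwise_fit(X, y)
  expect_identical(names(fit$coefficients), "x1")
  expect_equal(unname(fit$coefficients), 3, tolerance = 1e-10)
  expect_equal(fit$intercept, 2, tolerance = 1e-10)
})

test_that("pure-noise responses yield the empty model almost always", {
  set.seed(202)
  empty <- vapply(1:100, function(r) {
    X <- matrix(rnorm(60 * 20), 60, 20)
    fit <- stepwise_fit(X, rnorm(60), entry = 0.01)
    length(fit$coefficients) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.95)
})

test_that("bidirectional selection keeps a suppressor pair forward-only logic underrates", {
  # y depends on x1 + x2 where x2 alone is nearly uninformative but becomes
  # strongly significant once x1 is in -- verified against exhaustive
  # subset search
  set.seed(203)
  n <- 200
  x1 <- rnorm(n)
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(n)   # x2 correlated with x1
  y <- x1 - 0.9 * x2 + rnorm(n, sd = 0.05)      # marginal effect of x2 ~ 0
  X <- cbind(x1 = x1, x2 = x2, junk = rnorm(n))
  expect_lt(abs(stats::cor(x2, y)), 0.25)
  fit <- stepwise_fit(X, y)
  expect_setequal(names(fit$coefficients), c("x1", "x2"))
  # exhaustive search confirms {x1, x2} is the best two-feature subset
  rss <- function(cols) sum(stats::lm.fit(cbind(1, X[, cols, drop = FALSE]),
                                          y)$residuals^2)
  subsets <- utils::combn(colnames(X), 2, simplify = FALSE)
  best <- subsets[[which.min(vapply(subsets, rss, numeric(1)))]]
  expect_setequal(best, c("x1", "x2"))
})

test_that("selection is invariant to feature column order without ties", {
  set.seed(204)
  X <- matrix(rnorm(150 * 8), 150, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- 1 + 2 * X[, 3] - X[, 6] + rnorm(150, sd = 0.2)
  f1 <- stepwise_fit(X, y)
  perm <- c(5, 3, 8, 1, 6, 2, 7, 4)
  f2 <- stepwise_fit(X[, perm], y)
  expect_setequal(names(f1$coefficients), names(f2$coefficients))
  expect_equal(f1$coefficients[sort(names(f1$coefficients))],
               f2$coefficients[sort(names(f2$coefficients))],
               tolerance = 1e-10)
})

test_that("AIC mode selects the planted features too", {
  set.seed(205)
  X <- matrix(rnorm(200 * 10), 200, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- 2 * X[, 2] + rnorm(200, sd = 0.3)
  fit <- stepwise_fit(X, y, criterion = "AIC")
  expect_true("f2" %in% names(fit$coefficients))
})

helix_corpus <- function(n_chains, seed) {
  A <- pb_alphabet()
  corpus <- generate_corpus(synthetic_corpus_config(n_chains = n_chains),
                            seed = seed, A)
  corpus_fragments(corpus, A)
}

test_that("training, prediction and serialization are deterministic", {
  fr <- helix_corpus(12, seed = 301)
  P1 <- train_predictor(fr)
  P2 <- train_predictor(fr)
  expect_identical(lapply(P1$models, `[[`, "coefficients"),
                   lapply(P2$models, `[[`, "coefficients"))
  cls <- classify_q16(P1, fr$seq[1:200], fr$context[1:200])
  expect_true(all(cls$labels %in% LETTERS[1:16]))
  # JSON round trip preserves predictions
  tmp <- tempfile(fileext = ".json")
  write_predictor(P1, tmp)
  P3 <- read_predictor(tmp)
  cls3 <- classify_q16(P3, fr$seq[1:200], fr$context[1:200])
  expect_identical(cls$labels, cls3$labels)
  expect_equal(cls$similarities, cls3$similarities, tolerance = 1e-12)
  unlink(tmp)
})

test_that("a single-block corpus is rejected as degenerate", {
  fr <- helix_corpus(4, seed = 302)
  keep <- fr$label_rmsd == "M"
  frm <- list(seq = fr$seq[keep], context = fr$context[keep],
              D = matrix(rep(fr$D[which(keep)[1], ], sum(keep)),
                         sum(keep), 16, byrow = TRUE))
  expect_error(train_predictor(frm), "degenerate")
})

test_that("classification beats chance strongly on held-out synthetic chains", {
  A <- pb_alphabet()
  corpus <- generate_corpus(synthetic_corpus_config(n_chains = 40),
                            seed = 303, A)
  train_fr <- corpus_fragments(corpus[1:32], A)
  test_fr <- corpus_fragments(corpus[33:40], A)
  P <- train_predictor(train_fr)
  cls <- classify_q16(P, test_fr$seq, test_fr$context)
  acc <- evaluate_q16(cls$labels, test_fr$label_rmsd)$accuracy
  expect_gt(acc, 0.3)   # chance is 1/16
  # helix-coupled sequences land on M far above chance
  helixy <- test_fr$label_rmsd == "M"
  expect_gt(mean(cls$labels[helixy] == "M"), 0.5)
})

test_that("classify_q16 ties break to the alphabetically first label and are
           invariant to monotone transforms", {
  fr <- helix_corpus(4, seed = 304)
  P <- train_predictor(fr)
  # force equal scores: zero out every model
  Pz <- P
  for (i in seq_along(Pz$models)) {
    Pz$models[[i]]$coefficients <- numeric(0)
    Pz$models[[i]]$intercept <- 0.5
  }
  expect_identical(classify_q16(Pz, fr$seq[1], fr$context[1])$labels, "A")
  # monotone transform of similarities leaves the argmax unchanged
  sim <- predict_similarities(P, fr$seq[1:50], fr$context[1:50])
  lab1 <- colnames(sim)[max.col(sim, ties.method = "first")]
  lab2 <- colnames(sim)[max.col(exp(2 * sim), ties.method = "first")]
  expect_identical(lab1, lab2)
})

test_that("evaluation report totals are coherent", {
  ev <- evaluate_q16(c("M", "M", "D"), c("m", "m", "d"))
  expect_equal(ev$accuracy, 1)
  expect_equal(sum(diag(ev$confusion)), 3)
  truth <- c(rep("m", 3), rep("d", 7))
  ev2 <- evaluate_q16(rep("M", 10), truth)
  expect_equal(ev2$accuracy, 0.3)
  expect_equal(unname(ev2$per_label["d"]), 0)
  expect_equal(rowSums(ev2$confusion)[c("m", "d")], c(m = 3, d = 7))
  expect_error(evaluate_q16("z", "m"), "alphabet")
})
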