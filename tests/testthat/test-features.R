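test_that("sequence reduction follows the per-position maps", {
  ras <- default_reduced_alphabets()
  expect_identical(reduce_sequence("GAVLI", ras$six_class), "hhhhh")
  expect_identical(reduce_sequence("CMYWF", ras$six_class), "ssrrr")
  ident <- reduced_alphabet(stats::setNames(pbcoords:::AA20, pbcoords:::AA20),
                            "identity")
  expect_identical(reduce_sequence("AKQWD", ident), "AKQWD")
  # position-specific maps: identity at one position, wildcard elsewhere
  expect_identical(reduce_sequence("AAAAA", ras$pos3_identity), "xxAxx")
  expect_identical(reduce_sequence("KAAAA", ras$pos1_identity), "Kxxxx")
  # non-standard residue policy
  expect_identical(reduce_sequence("AAXAA", ras$six_class), "hhXhh")
  expect_true(is.na(reduce_sequence("AAXAA", ras$six_class,
                                    nonstandard = "na")))
})

test_that("class statistics match hand arithmetic and totals", {
  D <- matrix(0, 3, 16, dimnames = list(NULL, letters[1:16]))
  D[, 1] <- c(0.5, 0.7, 2)
  stats <- collect_class_stats(c("k1", "k1", "k2"), D)
  expect_equal(unname(stats$n_occ[c("k1", "k2")]), c(2L, 1L))
  expect_equal(stats$mu["k1", 1], 0.6, ignore_attr = TRUE)
  expect_equal(stats$sigma["k1", 1], sqrt(0.02), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(is.na(stats$sigma["k2", ])))   # singleton: sd undefined
  expect_equal(sum(stats$n_occ), 3L)             # counts total the corpus
  expect_error(collect_class_stats(character(0), D[0, ]), "empty")
})

test_that("rmsd-statistic features implement the t-contrast and fallbacks", {
  set.seed(101)
  D <- matrix(runif(200 * 16, 0.2, 3), 200, 16,
              dimnames = list(NULL, letters[1:16]))
  keys <- sample(c("aa", "bb", "cc"), 200, replace = TRUE)
  st <- collect_class_stats(keys, D)
  X <- rmsd_stat_features(c("aa", "zz"), st, lambda = 1, prefix = "ra")
  # seen class: reproduces its own statistics
  expect_equal(unname(X[1, "ra.mu.a"]), unname(st$mu["aa", "a"]))
  expect_equal(unname(X[1, "ra.n_occ"]), unname(st$n_occ["aa"]),
               ignore_attr = TRUE)
  expect_equal(unname(X[1, "ra.inv.a"]), 1 / (1 + st$mu["aa", "a"]),
               ignore_attr = TRUE)
  tt <- (st$mu["aa", "a"] - st$global$mu0["a"]) /
    (st$sigma["aa", "a"] / sqrt(st$n_occ["aa"]))
  expect_equal(unname(X[1, "ra.t.a"]), unname(tt))
  # unseen class: global statistics, zero contrast, flag set
  expect_equal(unname(X[2, paste0("ra.mu.", letters[1:16])]),
               unname(st$global$mu0))
  expect_equal(unname(X[2, "ra.t.m"]), 0)
  expect_equal(unname(X[2, "ra.n_occ"]), 0)
  expect_equal(unname(X[2, "ra.unseen"]), 1)
  # class mean equal to the global mean gives a zero contrast
  st0 <- st
  st0$mu["aa", ] <- st0$global$mu0
  X0 <- rmsd_stat_features("aa", st0, prefix = "ra")
  expect_equal(unname(X0[1, "ra.t.c"]), 0)
})

test_that("periodicity feature has its closed-form values and scaling", {
  expect_equal(periodicity_feature(rep(1, 5), T = 1), 25)
  expect_equal(periodicity_feature(rep(1, 5), T = 5), 0, tolerance = 1e-12)
  set.seed(7)
  H <- rnorm(9)
  expect_equal(periodicity_feature(3 * H, T = 3.6),
               9 * periodicity_feature(H, T = 3.6), tolerance = 1e-9)
  # shift-invariance holds exactly at T = n (roots of unity cancel)
  expect_equal(periodicity_feature(H + 10, T = 9),
               periodicity_feature(H, T = 9), tolerance = 1e-6)
  # an ideal amphipathic alternation peaks at the helical period
  ideal <- cos(2 * pi * (1:9) / 3.6)
  expect_gt(periodicity_feature(ideal, T = 3.6),
            periodicity_feature(ideal, T = 2))
  expect_error(periodicity_feature(1:3, T = 0), "positive")
})

test_that("feature generation is a pure function of its inputs", {
  set.seed(102)
  A <- pb_alphabet()
  corpus <- generate_corpus(synthetic_corpus_config(n_chains = 4), seed = 2, A)
  fr <- corpus_fragments(corpus, A)
  cfg <- feature_config()
  fs <- fit_feature_stats(fr$seq, fr$D, cfg)
  X1 <- generate_features(fr$seq[1:50], fr$context[1:50], fs)
  X2 <- generate_features(fr$seq[1:50], fr$context[1:50], fs)
  expect_identical(X1, X2)
  expect_true(all(is.finite(X1)))
  expect_gt(ncol(X1), 100)
})

test_that("classes coupled to a block have their mean distance minimum there", {
  # the generator couples signature residue A to helix block m: fragments
  # whose centre residue is A should sit closest to m on average
  A <- pb_alphabet()
  corpus <- generate_corpus(synthetic_corpus_config(n_chains = 30,
                                                    self_transition = 0.85),
                            seed = 12, A)
  fr <- corpus_fragments(corpus, A)
  ras <- default_reduced_alphabets()
  keys <- reduce_sequence(fr$seq, ras$pos3_identity)
  st <- collect_class_stats(keys, fr$D)
  expect_equal(unname(which.min(st$mu["xxAxx", ])), 13)  # block m
})
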