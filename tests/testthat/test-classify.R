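# synthetic island-score tables: n_islands features, class means separated
# by `shift` in units of the within-class SD
make_score_tables <- function(n_tumor, n_normal, n_islands = 10L, shift = 5,
                              sd = 0.05, seed = 1L) {
  set.seed(seed)
  islands <- sprintf("isl%02d", seq_len(n_islands))
  base <- runif(n_islands, 0.5, 1.5)
  tabs <- list(); labels <- character(0)
  for (s in seq_len(n_tumor + n_normal)) {
    tumor <- s <= n_tumor
    mu <- base + if (tumor) shift * sd else 0
    id <- sprintf("%s%02d", if (tumor) "t" else "n", s)
    tabs[[id]] <- data.frame(island_id = islands,
                             rate = rnorm(n_islands, mu, sd),
                             stringsAsFactors = FALSE)
    labels[id] <- if (tumor) "TUMOR" else "NORMAL"
  }
  list(tables = tabs, labels = labels)
}

test_that("matrix assembly: union, missingness filter, median imputation", {
  f <- make_score_tables(2, 2, n_islands = 3L, shift = 0, seed = 2L)
  mat <- build_matrix(f$tables, f$labels)
  expect_equal(dim(mat$values), c(4L, 3L))
  expect_equal(length(mat$dropped), 0L)

  # island missing in 3 of 4 samples is dropped at the default threshold
  f$tables[[1]] <- rbind(f$tables[[1]],
                         data.frame(island_id = "rare", rate = 2))
  mat <- build_matrix(f$tables, f$labels)
  expect_equal(mat$dropped, "rare")
  expect_false("rare" %in% colnames(mat$values))

  # NA cells take the column median
  f <- make_score_tables(5, 5, n_islands = 4L, shift = 0, seed = 3L)
  f$tables[[2]]$rate[3] <- NA
  mat <- build_matrix(f$tables, f$labels)
  expect_equal(mat$values[2, 3],
               median(mat$raw[-2, 3]))
  expect_true(is.na(mat$raw[2, 3]))
})

test_that("matrix assembly rejects degenerate inputs", {
  f <- make_score_tables(1, 0, n_islands = 2L)
  expect_error(build_matrix(f$tables, f$labels), "at least 2 samples")
})

test_that("well-separated clusters train to perfect resubstitution accuracy", {
  f <- make_score_tables(10, 10, shift = 5, seed = 4L)
  mat <- build_matrix(f$tables, f$labels)
  model <- train_classifier(mat, seed = 1L)
  pred <- predict(model, mat)
  expect_equal(pred$label, unname(ifelse(startsWith(pred$sample_id, "t"),
                                         "TUMOR", "NORMAL")))
})

test_that("two-point training puts the midpoint on the boundary", {
  tabs <- list(a = data.frame(island_id = c("i1", "i2"), rate = c(0, 0)),
               b = data.frame(island_id = c("i1", "i2"), rate = c(1, 1)))
  mat <- build_matrix(tabs, c(a = "NORMAL", b = "TUMOR"))
  model <- train_classifier(mat, seed = 1L)
  mid <- matrix(c(0.5, 0.5), nrow = 1, dimnames = list("mid", c("i1", "i2")))
  expect_lt(abs(predict(model, mid)$decision), 1e-6)
  expect_equal(predict(model, mat)$label, c("NORMAL", "TUMOR"))
})

test_that("an exact decision-value tie predicts NORMAL", {
  model <- structure(list(features = c("i1", "i2"),
                          center = c(i1 = 0, i2 = 0), scale = c(i1 = 1, i2 = 1),
                          medians = c(i1 = 0, i2 = 0),
                          w = c(1, -1), b = 0, cost = 1, seed = 1L),
                     class = "cleavage_classifier")
  x <- matrix(c(2, 2), nrow = 1, dimnames = list("s", c("i1", "i2")))
  pred <- predict(model, x)
  expect_identical(pred$decision, 0)
  expect_equal(pred$label, "NORMAL")
})

test_that("missing features at prediction impute the training median", {
  f <- make_score_tables(5, 5, n_islands = 4L, shift = 5, seed = 6L)
  mat <- build_matrix(f$tables, f$labels)
  model <- train_classifier(mat, seed = 1L)
  row <- mat$values[1, , drop = FALSE]
  row_missing <- row[, -2, drop = FALSE]
  row_imputed <- row
  row_imputed[, 2] <- model$medians[2]
  expect_equal(predict(model, row_missing)$label,
               predict(model, row_imputed)$label)
  expect_equal(predict(model, row_missing)$decision,
               predict(model, row_imputed)$decision)
})

test_that("prediction without feature overlap is an error; single class too", {
  f <- make_score_tables(3, 3, seed = 7L)
  mat <- build_matrix(f$tables, f$labels)
  model <- train_classifier(mat, seed = 1L)
  x <- matrix(1, nrow = 1, dimnames = list("s", "unrelated"))
  expect_error(predict(model, x), "no overlap")
  only_t <- build_matrix(f$tables[1:3], f$labels[1:3])
  expect_error(train_classifier(only_t), "both TUMOR and NORMAL")
})

test_that("rescaling an island by a positive constant leaves labels unchanged", {
  f <- make_score_tables(6, 6, shift = 3, seed = 8L)
  mat <- build_matrix(f$tables, f$labels)
  scaled <- mat
  scaled$values[, 1] <- scaled$values[, 1] * 37
  scaled$raw[, 1] <- scaled$raw[, 1] * 37
  m1 <- train_classifier(mat, seed = 2L)
  m2 <- train_classifier(scaled, seed = 2L)
  expect_equal(predict(m2, scaled)$label, predict(m1, mat)$label)
})

test_that("jack-knife bookkeeping, determinism and separable accuracy", {
  f <- make_score_tables(6, 6, shift = 5, seed = 9L)
  mat <- build_matrix(f$tables, f$labels)
  rep1 <- jackknife_evaluate(mat, rounds = 1L, holdout_per_class = 1L, seed = 3L)
  expect_equal(nrow(rep1$rounds), 2L)  # one tumor + one normal prediction

  rep2 <- jackknife_evaluate(mat, rounds = 10L, holdout_per_class = 2L, seed = 5L)
  rep3 <- jackknife_evaluate(mat, rounds = 10L, holdout_per_class = 2L, seed = 5L)
  expect_identical(rep2$aggregate, rep3$aggregate)
  expect_identical(rep2$rounds, rep3$rounds)

  expect_equal(unname(rep2$aggregate[c("tp_pct", "tn_pct")]), c(100, 100))
  expect_equal(unname(rep2$aggregate["tp_pct"] + rep2$aggregate["fn_pct"]), 100)
  expect_equal(unname(rep2$aggregate["tn_pct"] + rep2$aggregate["fp_pct"]), 100)

  expect_error(jackknife_evaluate(mat, rounds = 5L, holdout_per_class = 6L),
               "holdout_per_class")
})

test_that("labels independent of features give chance-level jack-knife accuracy", {
  f <- make_score_tables(10, 10, shift = 0, seed = 10L)  # no class signal
  mat <- build_matrix(f$tables, f$labels)
  rep <- jackknife_evaluate(mat, rounds = 50L, holdout_per_class = 2L, seed = 11L)
  # 95% binomial interval around 50% at n = 10 independent samples per class
  ci <- 100 * (0.5 + c(-1, 1) * 1.96 * sqrt(0.25 / 10))
  expect_gt(rep$aggregate["tp_pct"], ci[1])
  expect_lt(rep$aggregate["tp_pct"], ci[2])
  expect_gt(rep$aggregate["tn_pct"], ci[1])
  expect_lt(rep$aggregate["tn_pct"], ci[2])
})

test_that("island ranking orders by |class-mean difference| with stable ties", {
  tabs <- list(
    n1 = data.frame(island_id = c("A", "B", "C"), rate = c(1.0, 1.0, 2.0)),
    n2 = data.frame(island_id = c("A", "B", "C"), rate = c(1.0, 1.0, 2.0)),
    t1 = data.frame(island_id = c("A", "B", "C"), rate = c(2.0, 3.0, 2.0)),
    t2 = data.frame(island_id = c("A", "B", "C"), rate = c(2.0, 3.0, 2.0)))
  lab <- c(n1 = "NORMAL", n2 = "NORMAL", t1 = "TUMOR", t2 = "TUMOR")
  mat <- build_matrix(tabs, lab)
  rk <- rank_islands(mat)
  expect_equal(rk$island_id, c("B", "A", "C"))
  expect_equal(rk$difference, c(2, 1, 0))
  expect_equal(rk$normal_mean, c(1, 1, 2))

  # identical class means everywhere: all zero, id order
  flat_tabs <- list(n1 = tabs$n1, n2 = tabs$n2, t1 = tabs$n1, t2 = tabs$n2)
  flat <- build_matrix(flat_tabs, lab)
  rk0 <- rank_islands(flat)
  expect_equal(rk0$difference, c(0, 0, 0))
  expect_equal(rk0$island_id, c("A", "B", "C"))

  # sample permutation leaves the ranking unchanged
  perm <- mat
  ord <- c(3, 1, 4, 2)
  perm$raw <- mat$raw[ord, ]; perm$values <- mat$values[ord, ]
  perm$labels <- mat$labels[ord]
  expect_equal(rank_islands(perm), rk)

  expect_warning(rk_all <- rank_islands(mat, k = 10L), "exceeds island count")
  expect_equal(nrow(rk_all), 3L)
})

test_that("classifier and matrix round-trip through their file formats", {
  f <- make_score_tables(4, 4, shift = 4, seed = 12L)
  mat <- build_matrix(f$tables, f$labels)
  model <- train_classifier(mat, seed = 1L)
  mp <- tempfile(fileext = ".json")
  write_classifier(model, mp)
  model2 <- read_classifier(mp)
  expect_equal(predict(model2, mat), predict(model, mat))

  tp <- tempfile(fileext = ".tsv"); lp <- tempfile(fileext = ".tsv")
  write_matrix_tsv(mat, tp, lp)
  mat2 <- read_matrix_tsv(tp, lp)
  expect_equal(mat2$raw, mat$raw)
  expect_equal(mat2$labels, mat$labels)
  expect_equal(predict(model, mat2)$label, predict(model, mat)$label)
})
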