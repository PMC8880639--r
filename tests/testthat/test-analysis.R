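test_that("Kruskal-Wallis screening holds its nominal level and gatekeeps Dunn", {
  set.seed(3)
  fp <- 0L; tot <- 0L
  for (r in 1:20) {
    tab <- null_feature_table(20L, 10L)
    sig <- kruskal_dunn(tab)
    fp <- fp + sum(sig$significant)
    tot <- tot + nrow(sig)
    # Dunn p-values only appear where KW rejected
    ns <- !sig$significant
    expect_true(all(is.na(sig$p_CON_PD[ns])))
  }
  rate <- fp / tot
  expect_gte(rate, 0.5 * 0.05)
  expect_lte(rate, 2 * 0.05)
})

test_that("a shifted group is isolated by Dunn's pairwise tests", {
  set.seed(3)
  isolated <- 0L
  for (r in 1:20) {
    tab <- tibble::tibble(group = rep(c("CON", "PD", "PSP"), each = 20),
                          f = rnorm(60))
    tab$f[tab$group == "PSP"] <- tab$f[tab$group == "PSP"] + 3
    sig <- kruskal_dunn(tab)
    ok <- isTRUE(sig$significant[1]) &&
      sig$p_CON_PSP[1] < 0.05 && sig$p_PD_PSP[1] < 0.05 &&
      sig$p_CON_PD[1] >= 0.05
    isolated <- isolated + ok
  }
  expect_gte(isolated, 18L)
})

test_that("degenerate features are skipped and reported structure is tidy", {
  tab <- tibble::tibble(group = rep(c("A", "B", "C"), each = 5),
                        const = 1, ok = rnorm(15))
  sig <- kruskal_dunn(tab)
  expect_false("const" %in% sig$feature)
  expect_true("ok" %in% sig$feature)
  g <- glance(sig)
  expect_equal(g$n_features, nrow(sig))
  expect_s3_class(tidy(sig), "tbl_df")
})

test_that("the ECOC Gaussian SVM separates well-separated blobs", {
  set.seed(61)
  n <- 30
  x <- rbind(cbind(rnorm(n, 0), rnorm(n, 0)),
             cbind(rnorm(n, 6), rnorm(n, 6)),
             cbind(rnorm(n, 0), rnorm(n, 12)))
  y <- rep(c("CON", "PD", "PSP"), each = n)
  m <- train_ecoc_svm(x, y)
  expect_equal(mean(predict(m, x) == y), 1)
  # a duplicated training point lands in its own class
  expect_equal(predict(m, x[5, , drop = FALSE]), y[5])
  # missing class is rejected
  expect_error(train_ecoc_svm(x[1:60, ], y[1:60]),
               class = "lastkit_validation_error")
  expect_error(predict(m, x[, 1, drop = FALSE]),
               class = "lastkit_validation_error")
  # gamma conventions
  expect_equal(m$gamma, 1 / 2)
  expect_equal(train_ecoc_svm(x, y, gamma_mode = "paper")$gamma, 2)
  # deterministic repeated prediction
  expect_identical(predict(m, x), predict(m, x))
  expect_s3_class(tidy(m), "tbl_df")
  expect_equal(nrow(tidy(m)), 3L)
})

test_that("ECOC decoding follows Hamming distance over the one-vs-one codebook", {
  M <- lastkit:::ecoc_codebook(c("CON", "PD", "PSP"))
  expect_equal(dim(M), c(3L, 3L))
  expect_equal(sum(M == 0), 3L)
  expect_true(all(rowSums(M != 0) == 2))
  # votes matching PD's codeword exactly decode to PD:
  # dichotomizers are CON_vs_PD, CON_vs_PSP, PD_vs_PSP
  votes <- M["PD", ]
  dist <- apply(M, 1, function(cw) {
    nz <- cw != 0
    sum(votes[nz] != cw[nz])
  })
  expect_equal(names(which.min(dist)), "PD")
})

test_that("cross-validation is seeded, stratified and near chance on noise", {
  set.seed(62)
  tab <- null_feature_table(30L, 6L)
  cv1 <- cross_validate(tab, k = 5, seed = 9, select_features = FALSE)
  cv2 <- cross_validate(tab, k = 5, seed = 9, select_features = FALSE)
  expect_equal(cv1$accuracy, cv2$accuracy)
  expect_equal(cv1$predictions$fold, cv2$predictions$fold)
  # folds are stratified
  ft <- table(cv1$predictions$fold, tab$group)
  expect_true(all(ft == 6))
  # label-independent features stay near chance (wide Monte-Carlo margin)
  accs <- vapply(1:8, function(s) {
    cross_validate(tab, k = 5, seed = s, select_features = FALSE)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 100 / 3), 12)
  # perfectly separable data scores 100%
  sep <- tibble::tibble(group = rep(c("A", "B", "C"), each = 10),
                        f1 = rep(c(0, 10, 20), each = 10) + rnorm(30, 0, 0.1))
  expect_equal(cross_validate(sep, k = 5, seed = 1,
                              select_features = FALSE)$accuracy, 100)
  expect_error(cross_validate(sep, k = 11, seed = 1),
               class = "lastkit_validation_error")
  expect_s3_class(glance(cv1), "tbl_df")
})
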