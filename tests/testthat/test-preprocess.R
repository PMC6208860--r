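test_that("background filter enforces the fold rule in every sample", {
  vals <- rbind(G1 = c(3, 3), G2 = c(3, 3), G3 = c(3, 3))
  colnames(vals) <- c("s1", "s2")
  # linear signal is 8; backgrounds give ratios 2.0, (1.3, 2.0), 1.45
  bg <- rbind(G1 = c(4, 4), G2 = c(8 / 1.3, 4), G3 = c(8 / 1.45, 8 / 1.45))
  ds <- make_ds(vals, background = bg)
  kept <- rownames(filter_background(ds, 1.4)$values)
  expect_equal(kept, c("G1", "G3"))
  expect_equal(nrow(filter_background(ds, 0)$values), 3L)
  expect_error(filter_background(make_ds(vals)), "background")
})

test_that("background filter is monotone in the fold factor", {
  set.seed(42)
  vals <- rand_mat(50, 4)
  bg <- 2^vals / matrix(runif(200, 1.2, 3.5), 50, 4)
  ds <- make_ds(vals, background = bg)
  prev <- rownames(filter_background(ds, 2.0)$values)
  for (f in c(1.7, 1.4, 1.0)) {
    cur <- rownames(filter_background(ds, f)$values)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("quantile normalization matches the tied-rank definition and is idempotent", {
  m <- cbind(s1 = c(1, 3, 5), s2 = c(2, 4, 6))
  expect_equal(unname(quantile_normalize(m)),
               cbind(c(1.5, 3.5, 5.5), c(1.5, 3.5, 5.5)))
  # tied case, hand-computed: sorted-row means (1.5, 2.5, 4.5); the tie in
  # column 1 takes the mean of its tied quantile values
  mt <- cbind(s1 = c(1, 1, 3), s2 = c(2, 4, 6))
  expect_equal(unname(quantile_normalize(mt)),
               cbind(c(2, 2, 4.5), c(1.5, 2.5, 4.5)))
  # identical columns unchanged
  mi <- cbind(s1 = c(2, 1, 7), s2 = c(2, 1, 7))
  expect_equal(quantile_normalize(mi), mi)
  # idempotence and identical column distributions on random input
  r <- rand_mat(60, 5)
  q1 <- quantile_normalize(r)
  expect_equal(quantile_normalize(q1), q1)
  sorted <- apply(q1, 2L, sort)
  expect_equal(max(abs(sorted - sorted[, 1L])), 0)
  expect_warning(quantile_normalize(r[, 1, drop = FALSE]), "single column")
})

test_that("dataset merging intersects genes, prefixes samples, tracks batches", {
  v1 <- rand_mat(4, 3); rownames(v1) <- c("A", "B", "C", "D")
  v2 <- rand_mat(4, 4, seed = 2); rownames(v2) <- c("B", "C", "D", "E")
  m <- merge_datasets(list(x = make_ds(v1, batch = "x"),
                           y = make_ds(v2, batch = "y")))
  expect_setequal(rownames(m$values), c("B", "C", "D"))
  expect_equal(ncol(m$values), 7L)
  expect_equal(as.integer(table(m$meta$batch)[c("x", "y")]), c(3L, 4L))
  expect_true(all(grepl("^(x|y)\\.", colnames(m$values))))
  v3 <- rand_mat(3, 3, seed = 3); rownames(v3) <- c("X", "Y", "Z")
  expect_error(merge_datasets(list(make_ds(v1), make_ds(v3))), "intersection")
})

test_that("batch standardization equalizes batch means and guards constants", {
  v <- rand_mat(30, 10)
  v[, 6:10] <- v[, 6:10] + 5
  ds <- make_ds(v, batch = rep(c("b1", "b2"), each = 5))
  out <- batch_standardize(ds)$values
  m1 <- rowMeans(out[, 1:5]); m2 <- rowMeans(out[, 6:10])
  expect_equal(m1, m2, tolerance = 1e-10)
  # single batch: standardize-then-restore is the identity
  one <- make_ds(rand_mat(10, 6), batch = "b1")
  expect_equal(batch_standardize(one)$values, one$values)
  # constant gene: no divide-by-zero, values finite
  vc <- rand_mat(5, 6)
  vc[1, ] <- 3
  cds <- make_ds(vc, batch = rep(c("b1", "b2"), each = 3))
  outc <- batch_standardize(cds)$values
  expect_true(all(is.finite(outc)))
  expect_equal(unname(outc[1, ]), rep(3, 6))
  # batch of size 1 is an error naming the batch
  bad <- make_ds(rand_mat(5, 3), batch = c("b1", "b1", "solo"))
  expect_error(batch_standardize(bad), "solo")
})

test_that("robust covariate adjustment removes linear age effects and resists outliers", {
  set.seed(7)
  n <- 20
  age <- seq(60, 98, length.out = n)
  v <- rand_mat(5, n)
  ds0 <- make_ds(v, age = age)
  # gene exactly linear in age: residual variance ~ 0
  v1 <- v; v1[1, ] <- 2 + 0.1 * age
  adj <- adjust_covariates_robust(make_ds(v1, age = age), covariates = "age")
  expect_lt(sd(adj$values[1, ]), 1e-6)
  # gene independent of covariates stays put (within fit tolerance)
  expect_equal(adj$values[3, ], v1[3, ], tolerance = 0.5)
  expect_gt(cor(adj$values[3, ], v1[3, ]), 0.95)
  # gross outlier: recovered slope beats OLS (slope implied by y - adjusted)
  y <- 1 + 0.2 * age + rnorm(n, 0, 0.05)
  y[1] <- y[1] + 30
  v2 <- v; v2[2, ] <- y
  adj2 <- suppressWarnings(
    adjust_covariates_robust(make_ds(v2, age = age), covariates = "age"))
  implied <- function(fit_y) {
    removed <- y - fit_y
    cov(removed, age) / var(age)
  }
  slope_rob <- implied(adj2$values[2, ])
  ols <- lm(y ~ age)
  expect_lt(abs(slope_rob - 0.2), abs(coef(ols)[["age"]] - 0.2))
  # rank preservation when the covariate effect is zero: genes built
  # orthogonal to age with well-separated values keep their sample order
  ages0 <- seq(60, 90, length.out = 10)
  set.seed(9)
  v0 <- matrix(0, 3, 10, dimnames = list(c("g1", "g2", "g3"),
                                         sprintf("s%02d", 1:10)))
  for (g in 1:3) {
    y0 <- sample(seq(1, 20, by = 2))[1:10]
    v0[g, ] <- y0 - cov(y0, ages0) / var(ages0) * (ages0 - mean(ages0))
  }
  flat <- adjust_covariates_robust(make_ds(v0, age = ages0),
                                   covariates = "age")
  for (g in 1:3)
    expect_equal(rank(flat$values[g, ]), rank(v0[g, ]))
})

test_that("missing covariates drop samples and tiny designs error", {
  v <- rand_mat(4, 6)
  ds <- make_ds(v, age = c(70, NA, 75, 80, 85, 90))
  expect_message(out <- adjust_covariates_robust(ds, covariates = "age"),
                 "dropped")
  expect_equal(ncol(out$values), 5L)
  tiny <- make_ds(rand_mat(3, 2), age = c(70, 80), sex = c("M", "F"))
  expect_error(adjust_covariates_robust(tiny), "fewer samples")
})

test_that("age-correlation profile separates age blocks and flags degeneracy", {
  set.seed(11)
  n_genes <- 80
  young_proto <- rnorm(n_genes); old_proto <- rnorm(n_genes)
  mk <- function(proto, noise) proto + rnorm(n_genes, 0, noise)
  # old block is tight, young block is noisy: old samples correlate more
  v <- cbind(sapply(1:6, function(i) mk(young_proto, 1.5)),
             sapply(1:6, function(i) mk(old_proto, 0.2)))
  dimnames(v) <- list(sprintf("G%03d", 1:n_genes), sprintf("s%02d", 1:12))
  ds <- make_ds(v, group = rep("control", 12),
                age = c(seq(50, 60, length.out = 6), seq(70, 80, length.out = 6)))
  cp <- age_correlation_profile(ds, window = 3)
  expect_true(cp$t_available)
  expect_gt(cp$t_stat, 0)
  expect_lt(cp$p_value, 0.01)
  # oracle: classic pooled-variance t on the per-sample mean correlations
  cm <- cor(v[, order(ds$meta$age)])
  mean_cor <- (rowSums(cm) - 1) / 11
  old <- sort(ds$meta$age) >= 65
  a <- mean_cor[old]; b <- mean_cor[!old]
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
  expect_equal(cp$t_stat, t_hand, tolerance = 1e-12)
  # window = 1 leaves raw coefficients; moving average has full length
  cp1 <- age_correlation_profile(ds, window = 1)
  expect_equal(cp1$smoothed, cp1$mean_cor)
  expect_equal(length(cp$smoothed), 12L)
  # identical samples: all coefficients 1, t flagged unavailable
  same <- make_ds(matrix(rep(c(1, 2, 5), 8), 3, 8,
                         dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:8))),
                  group = rep("control", 8), age = seq(55, 90, 5))
  cps <- age_correlation_profile(same, window = 3)
  expect_equal(unname(cps$mean_cor), rep(1, 8))
  expect_false(cps$t_available)
})
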