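toy_logistic <- function(n = 40, p = 3, seed = 51) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", 1:p)))
  eta <- 0.3 + X %*% c(0.8, -0.5, rep(0, p - 2))
  y <- as.integer(runif(n) < plogis(eta))
  list(X = scale(X), y = y)
}

test_that("the lasso shrinks fully at large penalties", {
  d <- toy_logistic()
  cf <- fit_l1_logistic(d$X, d$y, lambda = 1e4)
  expect_true(all(cf[-1] == 0))
  expect_error(fit_l1_logistic(d$X, rep(1L, 40), 1), "both classes")
})

test_that("the unpenalized limit matches an independent MLE", {
  d <- toy_logistic()
  cf <- fit_l1_logistic(d$X, d$y, lambda = 0)
  mle <- glm.fit(cbind(1, d$X), d$y,
                 family = binomial())$coefficients
  expect_equal(unname(cf), unname(mle), tolerance = 1e-4)
})

test_that("duplicating the data with doubled lambda leaves the fit fixed", {
  d <- toy_logistic()
  lam <- 2.5
  a <- fit_l1_logistic(d$X, d$y, lam)
  b <- fit_l1_logistic(rbind(d$X, d$X), c(d$y, d$y), 2 * lam)
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("the number of selected features is monotone along the path", {
  d <- toy_logistic(n = 60, p = 10, seed = 53)
  grid <- c(0.1, 0.5, 1, 2, 5, 10, 25, 60)
  nz <- vapply(grid, function(l)
    sum(fit_l1_logistic(d$X, d$y, l)[-1] != 0), 1L)
  expect_true(all(diff(nz) <= 0))
})

test_that("ROC metrics match exhaustive pair counting", {
  sep <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.05)
  lab <- c(1, 1, 1, 0, 0, 0)
  m <- roc_metrics(sep, lab)
  expect_equal(unname(m["auc"]), 1)
  expect_equal(unname(roc_metrics(1 - sep, lab)["auc"]), 0)

  scores <- c(0.9, 0.6, 0.6, 0.4, 0.8, 0.3, 0.6, 0.2, 0.5, 0.1, 0.6, 0.05)
  labels <- rep(c(1, 0), 6)
  got <- roc_metrics(scores, labels, threshold = 0.5)
  expect_equal(unname(got["auc"]), oracle_auc(scores, labels))
  expect_equal(unname(got["sensitivity"]),
               mean(scores[labels == 1] >= 0.5))
  expect_equal(unname(got["specificity"]),
               mean(scores[labels == 0] < 0.5))
  # antisymmetry under score reversal
  expect_equal(unname(roc_metrics(-scores, labels)["auc"]),
               1 - unname(got["auc"]))
  expect_error(roc_metrics(scores, rep(1, 12)), "both classes")
})

test_that("the stable set applies the at-least rule with ordered output", {
  st <- data.frame(feature = c("a", "b", "c", "d"),
                   count = c(10, 5, 4, 0), fraction = c(1, 0.5, 0.4, 0))
  expect_equal(stable_set(st, 0.5), c("a", "b"))   # 0.5 boundary included
  expect_equal(stable_set(st, 0)[1], "a")          # fraction 1 first
  expect_setequal(stable_set(st, 0), c("a", "b", "c", "d"))
})

test_that("design assembly pools controls and drops incomplete samples", {
  m1 <- matrix(rnorm(3 * 6, 15), 3, 6,
               dimnames = list(paste0("x", 1:3), paste0("S", 1:6)))
  m2 <- matrix(rnorm(2 * 6, 15), 2, 6,
               dimnames = list(paste0("y", 1:2), paste0("S", 1:6)))
  m2["y1", "S6"] <- NA
  attr(m1, "standards") <- list(ovalbumin = character(), sis = character())
  attr(m2, "standards") <- attr(m1, "standards")
  meta <- data.frame(sample_id = paste0("S", 1:6),
                     group = c("case", "case", "benign", "benign",
                               "healthy", "healthy"),
                     cohort = "V", batch = "B1", stringsAsFactors = FALSE)
  d <- suppressMessages(build_design(list(AAL = m1, SNA = m2), meta,
                                     "combined"))
  expect_equal(ncol(d$X), 5L)    # concatenated feature blocks
  expect_equal(colnames(d$X), c(paste0("AAL-x", 1:3), paste0("SNA-y", 1:2)))
  expect_equal(nrow(d$X), 5L)    # S6 dropped for missingness
  expect_equal(attr(d, "n_dropped"), 1L)
  expect_equal(d$y, c(1L, 1L, 0L, 0L, 0L))  # benign and healthy pooled
  single <- build_design(list(AAL = m1, SNA = m2), meta, "AAL")
  expect_equal(ncol(single$X), 3L)
  expect_equal(nrow(single$X), 6L)
  expect_error(build_design(list(AAL = m1), meta, "STL"), "unknown lectin")
})

test_that("LOOCV yields one honest prediction per sample", {
  set.seed(61)
  n <- 24
  X <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  y <- rep(c(1L, 0L), each = n / 2)
  X[y == 1, 1] <- X[y == 1, 1] + 2
  cfg <- analysis_config(seed = 2L, n_boot = 100L)
  p <- loocv_panel(X, y, cfg)
  expect_equal(nrow(p$folds), n)
  expect_equal(p$folds$sample, seq_len(n))
  expect_equal(sum(p$stability$count), sum(p$selected))
  expect_true(all(p$stability$fraction >= 0 & p$stability$fraction <= 1))
  expect_true(all(p$metrics$lower <= p$metrics$value + 1e-12 &
                    p$metrics$value <= p$metrics$upper + 1e-12))

  # honesty: corrupting the left-out sample cannot change the features
  # selected in its own fold
  X2 <- X; X2[5, ] <- X2[5, ] + 50
  p2 <- loocv_panel(X2, y, cfg)
  expect_identical(p$selected[5, ], p2$selected[5, ])
  expect_error(loocv_panel(X[1:8, ], y[1:8], cfg), "at least 10")
})
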