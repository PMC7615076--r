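test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)          # m = 1 -> q = p
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_adjust(p), oracle_bh(p))
  expect_equal(bh_adjust(p), rep(0.04, 4))     # hand-evaluated step-up
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(19)
  for (i in 1:30) {
    p <- runif(sample(2:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("peptide differential testing adjusts within each family", {
  set.seed(23)
  m <- matrix(rnorm(50 * 12, 15), 50, 12,
              dimnames = list(paste0("pep", 1:50), paste0("S", 1:12)))
  attr(m, "protein_map") <- setNames(paste0("P", rep(1:10, each = 5)),
                                     rownames(m))
  attr(m, "lectin") <- "AAL"
  groups <- rep(c("case", "benign", "healthy"), each = 4)
  res <- peptide_differential(m, groups)
  expect_setequal(unique(res$comparison),
                  c("case-vs-benign", "case-vs-healthy"))
  for (cmp in unique(res$comparison)) {
    sub <- res[res$comparison == cmp, ]
    expect_equal(sub$q, oracle_bh(sub$p))
  }
  # identical groups -> p = q = 1
  m1 <- matrix(rep(c(1, 2, 3, 4), each = 2), 2, 4,
               dimnames = list(c("a", "b"), paste0("S", 1:4)))
  m1[] <- c(5, 6, 7, 8, 5, 6, 7, 8)
  attr(m1, "protein_map") <- c(a = "PA", b = "PB")
  r1 <- peptide_differential(m1, c("case", "case", "benign", "benign"),
                             "case-vs-benign")
  expect_equal(r1$p, c(1, 1))
  expect_equal(r1$q, c(1, 1))
  # a single peptide: q = p
  r2 <- peptide_differential(m1[1, , drop = FALSE],
                             c("case", "case", "benign", "benign"),
                             "case-vs-benign")
  expect_equal(r2$q, r2$p)
})

test_that("consistency percentages reproduce from their counts", {
  expect_equal(consistency_percentage(5, 23), 21.7)
  expect_equal(consistency_percentage(6, 20), 30)
  expect_equal(consistency_percentage(6, 19), 31.6)
  expect_error(consistency_percentage(1, 0), "positive")
})

fake_results <- function(lfc, q, proteins, features = NULL,
                         lectin = "AAL") {
  if (is.null(features)) features <- paste0("pep", seq_along(lfc))
  do.call(rbind, lapply(c("case-vs-benign", "case-vs-healthy"),
                        function(cmp)
    data.frame(feature = features, protein = proteins, lectin = lectin,
               comparison = cmp, log2fc = lfc, p = q, q = q,
               direction = ifelse(lfc > 0, "up",
                                  ifelse(lfc < 0, "down", "flat")),
               stringsAsFactors = FALSE)))
}

test_that("the consistency filter applies both protein-level modes", {
  # single significant peptide: consistent under both modes
  one <- fake_results(lfc = 1, q = 0.01, proteins = "P1")
  for (mode in c("direction", "strict")) {
    s <- consistency_filter(one, mode)
    expect_equal(s$n_consistent_proteins, 1L)
    expect_equal(s$up, "P1")
  }
  # peptides signed (+, +, -): not consistent even with significance
  mixed <- fake_results(lfc = c(1, 1.2, -0.8), q = c(0.01, 0.01, 0.01),
                        proteins = rep("P1", 3))
  expect_equal(consistency_filter(mixed)$n_consistent_proteins, 0L)
  expect_equal(consistency_filter(mixed)$n_any_significant_proteins, 1L)
  # direction mode admits a non-significant same-sign sibling; strict
  # does not
  sib <- fake_results(lfc = c(1, 0.9), q = c(0.01, 0.8),
                      proteins = rep("P1", 2))
  expect_equal(consistency_filter(sib, "direction")$n_consistent_proteins,
               1L)
  expect_equal(consistency_filter(sib, "strict")$n_consistent_proteins, 0L)
})

test_that("strict-mode consistent proteins are a subset of direction-mode", {
  set.seed(29)
  for (i in 1:20) {
    n <- 40L
    res <- fake_results(lfc = rnorm(n, 0, 1), q = runif(n),
                        proteins = paste0("P", sample(1:12, n, TRUE)))
    d <- consistency_filter(res, "direction")
    s <- consistency_filter(res, "strict")
    split_names <- function(x) unlist(strsplit(paste(x$up, x$down), "[ ,]"))
    expect_true(all(setdiff(split_names(s), "") %in%
                      c(split_names(d), "")))
    expect_lte(s$n_consistent_proteins, d$n_consistent_proteins)
    expect_lte(d$n_consistent_proteins, d$n_any_significant_proteins)
    if (d$n_any_significant_proteins > 0)
      expect_equal(d$pct_consistent,
                   round(100 * d$n_consistent_proteins /
                           d$n_any_significant_proteins, 1))
  }
})

test_that("validated proteins are cross-checked against discovery by join", {
  validated <- data.frame(lectin = c("AAL", "STL"),
                          protein = c("CO9", "A2MG"),
                          direction = c("up", "down"),
                          stringsAsFactors = FALSE)
  discovery <- data.frame(lectin = "AAL", feature = "CO9",
                          comparison = c("case-vs-benign",
                                         "case-vs-healthy"),
                          log2fc = c(0.7, -0.2), p = c(0.01, 0.6),
                          stringsAsFactors = FALSE)
  out <- crosscheck_in_discovery(validated, discovery)
  expect_equal(out$detected, c(TRUE, TRUE, FALSE))
  expect_equal(out$concordant[1:2], c(TRUE, FALSE))
  expect_true(is.na(out$log2fc[3]))

  # random instance against a brute-force join oracle
  set.seed(37)
  disc <- data.frame(lectin = sample(c("AAL", "SNA"), 30, TRUE),
                     feature = paste0("P", sample(1:10, 30, TRUE)),
                     comparison = "case-vs-benign",
                     log2fc = rnorm(30), p = runif(30),
                     stringsAsFactors = FALSE)
  disc <- disc[!duplicated(disc[c("lectin", "feature")]), ]
  val <- data.frame(lectin = sample(c("AAL", "SNA"), 8, TRUE),
                    protein = paste0("P", sample(1:12, 8)),
                    direction = sample(c("up", "down"), 8, TRUE),
                    stringsAsFactors = FALSE)
  out <- crosscheck_in_discovery(val, disc)
  for (i in seq_len(nrow(val))) {
    hit <- disc[disc$lectin == val$lectin[i] &
                  disc$feature == val$protein[i], ]
    row <- out[out$lectin == val$lectin[i] &
                 out$protein == val$protein[i], ]
    expect_equal(unique(row$detected), nrow(hit) > 0)
    if (nrow(hit)) expect_equal(row$log2fc, hit$log2fc)
  }
})
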