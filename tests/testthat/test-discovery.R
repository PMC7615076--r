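test_that("protein-group filtering applies all four evidence rules", {
  toy <- data.frame(
    id = paste0("R", 1:6),
    n_peptides = c(3L, 3L, 1L, 3L, 4L, 2L),
    score = c(50, 60, 70, 4.9, 80, 90),
    contaminant = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    reverse = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    S1 = 1:6, S2 = 2:7, stringsAsFactors = FALSE)
  attr(toy, "scale") <- "linear"; attr(toy, "samples") <- c("S1", "S2")
  out <- filter_protein_groups(toy)
  expect_equal(out$id, c("R5", "R6"))
  expect_equal(attr(out, "removed")$reason,
               c("contaminant", "reverse", "few_peptides", "low_score"))

  empty <- toy[0, ]
  attr(empty, "scale") <- "linear"; attr(empty, "samples") <- c("S1", "S2")
  expect_equal(nrow(filter_protein_groups(empty)), 0L)
})

test_that("peptide-to-protein summing matches a group-and-sum oracle", {
  toy <- make_peptide_toy()
  out <- sum_peptides_to_protein(toy)
  expect_equal(out$id, c("P1", "P2"))
  # peptides 100 and 200 observed -> 300; lone observed peptide carries
  expect_equal(out$S1[out$id == "P1"], 300)
  expect_equal(out$S2[out$id == "P1"], 150)
  # all peptides missing -> protein missing
  expect_true(is.na(out$S3[out$id == "P1"]))
  expect_true(is.na(out$S4[out$id == "P2"]))

  # random instance against an independent tapply oracle
  set.seed(11)
  n_pep <- 17L
  rt <- data.frame(id = paste0("pep", 1:n_pep),
                   protein = sample(paste0("P", 1:5), n_pep, TRUE),
                   n_peptides = 3L, score = 50,
                   contaminant = FALSE, reverse = FALSE,
                   stringsAsFactors = FALSE)
  vals <- matrix(rlnorm(n_pep * 6, 10, 1), n_pep, 6)
  vals[sample(length(vals), 20)] <- NA
  rt[paste0("S", 1:6)] <- vals
  attr(rt, "scale") <- "linear"; attr(rt, "samples") <- paste0("S", 1:6)
  out <- sum_peptides_to_protein(rt)
  for (s in paste0("S", 1:6)) {
    oracle <- tapply(rt[[s]], rt$protein, function(v)
      if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE))
    expect_equal(out[[s]], as.numeric(oracle[out$id]))
  }
  expect_error(sum_peptides_to_protein(within(rt, protein[2] <- NA)),
               "no protein")
})

test_that("pooled t statistics match the closed form and t.test", {
  m <- rbind(f1 = c(8, 9, 10, 5, 6, 7),
             f2 = c(4, 6, 8, 4, 6, 8))
  colnames(m) <- paste0("S", 1:6)
  groups <- c("case", "case", "case", "benign", "benign", "benign")
  res <- differential_test(m, groups, "case-vs-benign")
  # hand-derived: mean diff 3, pooled var 1, t = 3 * sqrt(3/2), df = 4
  t_hand <- 3 * sqrt(3 / 2)
  p_hand <- 2 * pt(-t_hand, df = 4)
  expect_equal(res$log2fc[1], 3)
  expect_equal(res$p[1], p_hand, tolerance = 1e-12)
  tt <- t.test(m[1, 1:3], m[1, 4:6], var.equal = TRUE)
  expect_equal(res$p[1], tt$p.value, tolerance = 1e-12)
  # identical group means with nonzero variance: flat, p = 1
  expect_equal(res$log2fc[2], 0)
  expect_equal(res$p[2], 1)
  expect_equal(res$direction, c("up", "flat"))

  # antisymmetry under label swap
  swapped <- c("benign", "benign", "benign", "case", "case", "case")
  res2 <- differential_test(m, swapped, "case-vs-benign")
  expect_equal(res2$log2fc, -res$log2fc)
  expect_equal(res2$p, res$p)

  expect_error(differential_test(m[, 1:4], groups[1:4], "case-vs-healthy"),
               "2 samples")
})

test_that("pooled and moderated variants agree on effect ranking", {
  set.seed(21)
  m <- matrix(rnorm(100 * 12), 100, 12,
              dimnames = list(paste0("f", 1:100), paste0("S", 1:12)))
  m[1:10, 1:6] <- m[1:10, 1:6] + 2
  groups <- rep(c("case", "healthy"), each = 6)
  a <- differential_test(m, groups, "case-vs-healthy", "student")
  b <- differential_test(m, groups, "case-vs-healthy", "moderated")
  expect_equal(a$log2fc, b$log2fc, tolerance = 1e-8)
  expect_gt(cor(rank(a$p), rank(b$p), method = "spearman"), 0.95)
  expect_gte(length(intersect(order(a$p)[1:10], order(b$p)[1:10])), 8L)
})

test_that("shortlisting applies strict and expanded thresholds", {
  res <- data.frame(feature = c("a", "b", "c"),
                    comparison = "case-vs-benign",
                    log2fc = c(1.2, 0.9, -1.4),
                    p = c(0.04, 0.04, 0.2),
                    stringsAsFactors = FALSE)
  strict <- shortlist_candidates(res, "strict")
  expect_equal(strict$feature, "a")
  expanded <- shortlist_candidates(res, "expanded")
  expect_setequal(expanded$feature, c("a", "b"))
  expect_equal(attr(strict, "provenance")$p, 0.05)
  expect_equal(nrow(shortlist_candidates(res[0, ], "strict")), 0L)
})

test_that("tightening shortlist thresholds never adds candidates", {
  set.seed(31)
  res <- data.frame(feature = paste0("f", 1:200),
                    comparison = "case-vs-benign",
                    log2fc = rnorm(200, 0, 1.2),
                    p = runif(200), stringsAsFactors = FALSE)
  loose <- analysis_config(p_discovery = 0.1, fc_discovery_log2 = 0.5)
  for (cfg in list(analysis_config(p_discovery = 0.05,
                                   fc_discovery_log2 = 0.5),
                   analysis_config(p_discovery = 0.1,
                                   fc_discovery_log2 = 1.0),
                   analysis_config(p_discovery = 0.02,
                                   fc_discovery_log2 = 1.5))) {
    tight_set <- shortlist_candidates(res, "strict", cfg)$feature
    loose_set <- shortlist_candidates(res, "strict", loose)$feature
    expect_true(all(tight_set %in% loose_set))
  }
})

test_that("cross-cohort concordance keeps matching-sign features only", {
  a <- data.frame(feature = c("x", "y", "z"), comparison = "case-vs-benign",
                  log2fc = c(0.8, 0.8, 0.4), p = 0.01)
  b <- data.frame(feature = c("x", "y", "z"), comparison = "case-vs-benign",
                  log2fc = c(0.6, -0.6, 0.9), p = 0.01)
  out <- cross_cohort_overlap(a, b, 0.5)
  expect_equal(out$feature, "x")

  set.seed(41)
  ra <- data.frame(feature = paste0("f", 1:100),
                   comparison = "case-vs-healthy",
                   log2fc = rnorm(100), p = runif(100))
  rb <- data.frame(feature = paste0("f", 1:100),
                   comparison = "case-vs-healthy",
                   log2fc = rnorm(100), p = runif(100))
  out <- cross_cohort_overlap(ra, rb, 0.5)
  oracle <- ra$feature[abs(ra$log2fc) > 0.5 & abs(rb$log2fc) > 0.5 &
                         sign(ra$log2fc) == sign(rb$log2fc)]
  expect_setequal(out$feature, oracle)
})

test_that("candidate summaries count distinct proteins per lectin", {
  cand <- example_candidate_table()
  s <- summarize_candidates(cand)
  expect_equal(unname(s$lectin_totals["AAL"]), 6L)
  expect_equal(unname(s$lectin_totals["CON-A"]), 4L)
  expect_equal(unname(s$lectin_totals["ECA"]), 11L)
  expect_equal(unname(s$lectin_totals["STL"]), 13L)
  expect_equal(unname(s$lectin_totals["WFA"]), 8L)

  # four disjoint singleton cells -> total 4, equality iff disjoint
  disjoint <- data.frame(lectin = "L", cohort = c("A", "B", "A", "B"),
                         comparison = rep(c("case-vs-benign",
                                            "case-vs-healthy"), each = 2),
                         protein = c("p1", "p2", "p3", "p4"))
  expect_equal(unname(summarize_candidates(disjoint)$lectin_totals), 4L)
  # totals never exceed the summed cell sizes
  s2 <- summarize_candidates(cand)
  cell_sums <- tapply(s2$cells$n, s2$cells$lectin, sum)
  expect_true(all(s2$lectin_totals <= cell_sums[names(s2$lectin_totals)]))
})

test_that("lectin ranking orders by count with lexicographic ties", {
  cand <- data.frame(
    lectin = rep(c("A", "B", "C"), c(6, 4, 11)),
    cohort = "X", comparison = "case-vs-benign",
    protein = paste0("p", c(1:6, 1:4, 1:11)))
  expect_equal(as.character(rank_lectins(cand, 2)), c("C", "A"))

  tie <- data.frame(lectin = rep(c("B", "A"), each = 5), cohort = "X",
                    comparison = "case-vs-benign",
                    protein = paste0("p", c(1:5, 1:5)))
  expect_message(r <- rank_lectins(tie, 1), "tie")
  expect_equal(as.character(r), "A")
  expect_warning(rank_lectins(cand, 5), "more lectins")
})
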