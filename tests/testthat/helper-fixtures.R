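# Shared fixtures and independent oracles. Oracles are deliberately
# naive re-derivations (enumeration, normal equations, step-up by hand)
# kept separate from the implementation paths they check.

# small linear-scale peptide table: 2 proteins x 2-1 peptides, 4 samples
make_peptide_toy <- function() {
  x <- data.frame(
    id = c("P1_a", "P1_b", "P2_a"),
    protein = c("P1", "P1", "P2"),
    n_peptides = c(2L, 2L, 1L),
    score = c(50, 50, 80),
    contaminant = FALSE, reverse = FALSE,
    S1 = c(100, 200, 400), S2 = c(150, NA, 500),
    S3 = c(NA, NA, 600), S4 = c(120, 180, NA),
    stringsAsFactors = FALSE)
  attr(x, "lectin") <- "AAL"; attr(x, "cohort") <- "TOY"
  attr(x, "scale") <- "linear"
  attr(x, "samples") <- c("S1", "S2", "S3", "S4")
  x
}

make_transition_toy <- function() {
  tt <- expand.grid(transition = c("t1", "t2"), sample = c("S1", "S2"),
                    stringsAsFactors = FALSE)
  tt$protein <- "P1"; tt$peptide <- "PEPA"
  tt$transition <- paste0("PEPA_", tt$transition)
  tt$area <- c(3, 5, 6, 10)
  tt[c("protein", "peptide", "transition", "sample", "area")]
}

# step-up BH by the definition: sort ascending, running min of p*m/j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# least squares with intercept via the Moore-Penrose pseudoinverse
oracle_lls <- function(neighbours, target, k) {
  obs <- which(!is.na(target)); mis <- which(is.na(target))
  r <- apply(neighbours[, obs, drop = FALSE], 1, function(v)
    suppressWarnings(stats::cor(v, target[obs])))
  r[is.na(r)] <- 0
  use <- order(abs(r), decreasing = TRUE)[seq_len(min(k, nrow(neighbours)))]
  N <- neighbours[use, , drop = FALSE]
  X <- cbind(1, t(N[, obs, drop = FALSE]))
  beta <- MASS::ginv(X) %*% target[obs]
  as.numeric(cbind(1, t(N[, mis, drop = FALSE])) %*% beta)
}

# AUC by exhaustive pair counting, half credit for ties
oracle_auc <- function(scores, labels) {
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(cs) * length(ct))
}

# overlap-aware candidate bookkeeping example: published-style discovery
# table rows whose cells overlap across cohorts and comparisons
example_candidate_table <- function() {
  cells <- list(
    AAL = list(bA = c("A1AG1", "A1AG2", "FA5", "HGFL"), bB = "MASP1",
               hA = "SEPP1", hB = "MASP1"),
    `CON-A` = list(bA = c("FIBB", "FCN3"), bB = character(),
                   hA = "HV551", hB = "APOM"),
    ECA = list(bA = c("LUM", "LG3BP"),
               bB = c("APOH", "CO7", "CO8G", "FBLN1", "PON1"),
               hA = c("CO9", "LG3BP", "CO8B", "CO8G", "LUM", "THBG"),
               hB = c("CO8G", "FBLN1", "PGRP2")),
    STL = list(bA = c("PON1", "FIBA", "FIBB"), bB = "LG3BP",
               hA = c("CD5L", "CHLE", "PON1", "FA10", "ACTG", "CBG"),
               hB = c("A1AT", "ITIH3", "HEP2", "IGLL5", "LG3BP")),
    WFA = list(bA = "GELS", bB = c("A1AT", "CO9", "ALDOA", "HV307"),
               hA = character(), hB = c("IGLL5", "CO7", "FA12")))
  key <- data.frame(cell = c("bA", "bB", "hA", "hB"),
                    cohort = c("A", "B", "A", "B"),
                    comparison = c("case-vs-benign", "case-vs-benign",
                                   "case-vs-healthy", "case-vs-healthy"),
                    stringsAsFactors = FALSE)
  do.call(rbind, lapply(names(cells), function(l)
    do.call(rbind, lapply(key$cell, function(cl) {
      p <- cells[[l]][[cl]]
      if (!length(p)) return(NULL)
      data.frame(lectin = l, cohort = key$cohort[key$cell == cl],
                 comparison = key$comparison[key$cell == cl],
                 protein = p, stringsAsFactors = FALSE)
    }))))
}

group_labels <- function(n_case, n_benign, n_healthy) {
  c(rep("case", n_case), rep("benign", n_benign),
    rep("healthy", n_healthy))
}
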