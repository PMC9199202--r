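est_ref_pair <- function(est_b, ref_b) {
  list(est = tibble::tibble(animal = sprintf("x%d", seq_along(est_b)),
                            method = "LR", stage = "raw",
                            b_B = est_b, b_C = 0.5 - est_b),
       ref = tibble::tibble(animal = sprintf("x%d", seq_along(ref_b)),
                            method = "TRUE", stage = "raw",
                            b_B = ref_b, b_C = 0.5 - ref_b))
}

test_that("evaluation metrics behave on constructed cases", {
  set.seed(4)
  r <- runif(30, 0.1, 0.4)
  p <- est_ref_pair(r, r)
  ev <- evaluate_estimates(p$est, p$ref)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$slope, 1)
  expect_equal(ev$max_error, 0)
  expect_equal(ev$rmse, 0)
  # constant offset: perfect correlation, errors equal the offset
  p2 <- est_ref_pair(r + 0.01, r)
  ev2 <- evaluate_estimates(p2$est, p2$ref)
  expect_equal(ev2$accuracy, 1)
  expect_equal(ev2$slope, 1)
  expect_equal(ev2$max_error, 0.01)
  expect_equal(ev2$rmse, 0.01)
  # doubling the spread halves the regression of reference on estimate
  p3 <- est_ref_pair(2 * (r - 0.25) + 0.25, r)
  expect_equal(evaluate_estimates(p3$est, p3$ref)$slope, 0.5)
})

test_that("slope, accuracy and the sd ratio are consistent", {
  set.seed(9)
  e <- runif(40)
  r <- 0.6 * e + rnorm(40, 0, 0.05)
  p <- est_ref_pair(e, r)
  ev <- evaluate_estimates(p$est, p$ref)
  expect_equal(ev$slope, ev$accuracy * stats::sd(r) / stats::sd(e),
               tolerance = 1e-12)
})

test_that("degenerate evaluations are rejected", {
  p <- est_ref_pair(rep(0.25, 5), runif(5))
  expect_error(evaluate_estimates(p$est, p$ref), "zero variance")
})

test_that("theoretical variance reproduces known values and limits", {
  # single-locus limit: the proportion is 0 or 0.5 with equal probability
  expect_equal(theoretical_variance(1e-9)$variance, 1 / 16, tolerance = 1e-6)
  # one chromosome of 1 Morgan (closed form, cross-checked by simulation in
  # the acceptance suite)
  expect_equal(theoretical_variance(1)$variance, 0.03547923, tolerance = 1e-6)
  # the simulated two-chromosome genome
  td <- theoretical_variance(c(3.20, 0.61))
  expect_equal(td$variance, 0.01273778, tolerance = 1e-6)
  expect_equal(td$sd, 0.1129, tolerance = 1e-3)
  expect_equal(td$mean, 0.25)
  expect_error(theoretical_variance(c(1, -1)), "> 0")
})

test_that("Weir-Cockerham F_ST matches hand-computed components", {
  g1 <- rbind(c(0, 1, 2), c(1, 1, 2), c(2, 0, 1), c(1, 0, 2))
  g2 <- rbind(c(0, 0, 1), c(0, 1, 1), c(1, 0, 0), c(0, 0, 1),
              c(1, 1, 0), c(0, 0, 1))
  geno <- rbind(g1, g2)
  storage.mode(geno) <- "integer"
  rownames(geno) <- sprintf("a%d", 1:10)
  panel <- genotype_panel(geno, rep(c("A", "B"), c(4, 6)), tiny_map(3))
  res <- fst_wc(panel, lines = c("A", "B"))
  # scalar textbook component arithmetic, locus by locus
  theta <- numeric(3)
  n1 <- 4; n2 <- 6; r <- 2
  for (m in 1:3) {
    p1 <- sum(g1[, m]) / (2 * n1); p2 <- sum(g2[, m]) / (2 * n2)
    h1 <- mean(g1[, m] == 1); h2 <- mean(g2[, m] == 1)
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    theta[m] <- a / (a + b + cc)
  }
  expect_equal(res$fst, mean(theta), tolerance = 1e-10)
  expect_equal(res$fst, 0.16047241, tolerance = 1e-7)  # frozen value
  expect_equal(res$n_loci, 3L)
})

test_that("F_ST edge cases: identical populations and fixed differences", {
  set.seed(12)
  m <- 2000
  p <- runif(m, 0.1, 0.9)
  geno <- t(vapply(seq_len(1000), function(i) rbinom(m, 2, p), integer(m)))
  rownames(geno) <- sprintf("a%d", 1:1000)
  panel <- genotype_panel(geno, rep(c("A", "B"), each = 500), tiny_map(m))
  expect_lt(abs(fst_wc(panel, lines = c("A", "B"))$fst), 0.01)
  # opposite fixation at every SNP
  g2 <- rbind(matrix(2L, 4, 3), matrix(0L, 4, 3))
  rownames(g2) <- sprintf("b%d", 1:8)
  p2 <- genotype_panel(g2, rep(c("A", "B"), each = 4), tiny_map(3))
  expect_equal(fst_wc(p2, lines = c("A", "B"))$fst, 1)
  # monomorphic everywhere is undefined
  g3 <- matrix(2L, 8, 3, dimnames = list(sprintf("c%d", 1:8), NULL))
  p3 <- genotype_panel(g3, rep(c("A", "B"), each = 4), tiny_map(3))
  expect_error(fst_wc(p3, lines = c("A", "B")), "monomorphic")
})

test_that("pairwise F_ST covers every line pair", {
  panel <- random_panel(n = 20, m = 50, seed = 31)
  pw <- fst_wc(panel, pairwise = TRUE)
  expect_equal(nrow(pw), 3L)
  expect_setequal(paste(pw$line1, pw$line2), c("A B", "A C", "B C"))
  ab <- fst_wc(panel, lines = c("A", "B"))$fst
  expect_equal(pw$fst[pw$line1 == "A" & pw$line2 == "B"], ab)
})

test_that("the method correlation table agrees with pairwise correlations", {
  set.seed(21)
  b1 <- runif(25, 0, 0.5)
  b2 <- b1 + rnorm(25, 0, 0.05)
  b3 <- runif(25, 0, 0.5)
  mk <- function(b, m) tibble::tibble(animal = sprintf("x%d", 1:25),
                                      method = m, stage = "raw",
                                      b_B = b, b_C = 0.5 - b)
  cm <- method_correlation_table(list(mk(b1, "LR"), mk(b2, "ADM"), mk(b3, "BOA")))
  expect_equal(diag(cm), c(LR = 1, ADM = 1, BOA = 1))
  expect_equal(cm, t(cm))
  expect_equal(cm["LR", "ADM"], stats::cor(b1, b2))
  expect_equal(cm["ADM", "BOA"], stats::cor(b2, b3))
  # duplicated method estimates correlate perfectly
  cm2 <- method_correlation_table(list(mk(b1, "LR"), mk(b1, "ADM")))
  expect_equal(cm2["LR", "ADM"], 1)
})
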