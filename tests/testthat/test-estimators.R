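make_freqs <- function(p_A, p_B, p_C) {
  damline:::new_line_freqs(sprintf("s%d", seq_along(p_A)), p_A, p_B, p_C,
                           "purebred-count")
}

test_that("BOA counting equals true proportions when assignment is complete", {
  sim <- simulate_scenario(quick_config(seed = 4))
  boa <- boa_proportions(sim$origins)
  expect_equal(boa$b_B, sim$truth$b_B)
  expect_equal(boa$b_C, sim$truth$b_C)
})

test_that("BOA handles unassigned alleles among assigned counts", {
  m <- 8
  pat <- matrix("A", 1, m, dimnames = list("x1", NULL))
  mat <- matrix(c(rep("B", 4), rep("C", 4)), 1, m, dimnames = list("x1", NULL))
  b <- boa_proportions(origin_matrix(pat, mat))
  expect_equal(c(b$b_B, b$b_C), c(0.25, 0.25))
  # random unassignment leaves the estimator unbiased
  sim <- simulate_scenario(quick_config(seed = 8))
  set.seed(99)
  o <- sim$origins
  drop <- matrix(runif(length(o$maternal)) < 0.1, nrow(o$maternal))
  o$maternal[drop] <- "U"
  drop_p <- matrix(runif(length(o$paternal)) < 0.1, nrow(o$paternal))
  o$paternal[drop_p] <- "U"
  b2 <- boa_proportions(o)
  expect_lt(abs(mean(b2$b_B - sim$truth$b_B)), 0.005)
  expect_gt(cor(b2$b_B, sim$truth$b_B), 0.99)
  # an animal with nothing assigned is an error
  o$maternal[1, ] <- "U"
  o$paternal[1, ] <- "U"
  expect_error(boa_proportions(o), "zero assigned")
})

test_that("LR solves the sire-adjusted system exactly on a square instance", {
  map <- tiny_map(2)
  # x_B = (2,0), x_C = (0,2), x_A = (1,1) as mean allele counts
  fr <- make_freqs(p_A = c(0.5, 0.5), p_B = c(1, 0), p_C = c(0, 1))
  g <- rbind(c(1L, 1L), c(2L, 0L))
  rownames(g) <- c("x1", "x2")
  pure <- matrix(c(1L, 2L, 0L), 3, 2, dimnames = list(c("a", "b", "c"), NULL))
  panel <- genotype_panel(rbind(pure, g), c("A", "B", "C", "ABC", "ABC"), map)
  est <- lr_estimate(panel, fr)
  expect_equal(est$b_B, c(0.25, 0.75))
  expect_equal(est$b_C, c(0.25, -0.25))
  expect_equal(est$resid_norm, c(0, 0))
})

test_that("LR equals the lm() normal-equations solution on random panels", {
  panel <- random_panel(n = 6, n_x = 8, m = 30, seed = 6)
  fr <- purebred_line_freqs(panel)
  est <- lr_estimate(panel, fr)
  X <- cbind(2 * fr$p_B, 2 * fr$p_C)
  for (i in c(1, 4, 8)) {
    id <- est$animal[i]
    gstar <- panel$geno[id, ] - fr$p_A  # g - 0.5 * 2p_A
    fit <- stats::lm(gstar ~ 0 + X)
    expect_lt(max(abs(c(est$b_B[i], est$b_C[i]) - unname(stats::coef(fit)))), 1e-10)
  }
})

test_that("LR rejects collinear dam-line regressors", {
  map <- tiny_map(2)
  fr <- make_freqs(p_A = c(0.5, 0.5), p_B = c(0.4, 0.2), p_C = c(0.4, 0.2))
  geno <- matrix(1L, 4, 2, dimnames = list(c("a", "b", "c", "x"), NULL))
  panel <- genotype_panel(geno, c("A", "B", "C", "ABC"), map)
  expect_error(lr_estimate(panel, fr), "collinear")
})

test_that("estimators are symmetric under relabeling of the dam lines", {
  panel <- random_panel(n = 6, n_x = 6, m = 40, seed = 13)
  swapped_line <- unname(c(A = "A", B = "C", C = "B", ABC = "ABC")[panel$line])
  panel_sw <- genotype_panel(panel$geno, swapped_line, panel$map)
  for (f in list(lr_estimate,
                 function(p, fr) admixture_supervised_em(p, fr, max_iter = 300))) {
    e1 <- f(panel, purebred_line_freqs(panel))
    e2 <- f(panel_sw, purebred_line_freqs(panel_sw))
    expect_equal(e1$b_B, e2$b_C, tolerance = 1e-9)
    expect_equal(e1$b_C, e2$b_B, tolerance = 1e-9)
  }
})

test_that("supervised EM respects degenerate likelihoods", {
  map <- tiny_map(4)
  # identical line frequencies: flat likelihood, q stays at its initialization
  fr_flat <- make_freqs(rep(0.4, 4), rep(0.4, 4), rep(0.4, 4))
  geno <- rbind(matrix(1L, 3, 4), matrix(1L, 1, 4))
  rownames(geno) <- c("a", "b", "c", "x")
  panel <- genotype_panel(geno, c("A", "B", "C", "ABC"), map)
  est <- admixture_supervised_em(panel, fr_flat)
  expect_equal(est$q_A, 0.5, tolerance = 1e-9)
  expect_equal(est$b_B, 0.25, tolerance = 1e-9)
  # line B fixed for the counted allele, others lack it, crossbred all 2 -> q_B -> 1
  fr_fix <- make_freqs(rep(0, 4), rep(1, 4), rep(0, 4))
  geno2 <- rbind(matrix(1L, 3, 4), matrix(2L, 1, 4))
  rownames(geno2) <- c("a", "b", "c", "x")
  panel2 <- genotype_panel(geno2, c("A", "B", "C", "ABC"), map)
  est2 <- admixture_supervised_em(panel2, fr_fix, max_iter = 5000)
  expect_gt(est2$b_B, 0.999)
})

test_that("EM log-likelihood is monotone and ends on the simplex", {
  panel <- random_panel(n = 8, n_x = 5, m = 60, seed = 17)
  est <- admixture_supervised_em(panel, purebred_line_freqs(panel))
  ll <- attr(est, "loglik")
  expect_true(all(diff(ll) > -1e-8))
  expect_equal(est$q_A + est$b_B + est$b_C, rep(1, 5), tolerance = 1e-9)
})

test_that("EM solution beats random points of the simplex", {
  sim <- simulate_scenario(quick_config(seed = 31))
  panel <- sim$panel
  fr <- purebred_line_freqs(panel)
  est <- admixture_supervised_em(panel, fr)
  P <- pmin(pmax(cbind(fr$p_A, fr$p_B, fr$p_C), 1e-6), 1 - 1e-6)
  set.seed(5)
  for (id in est$animal[1:3]) {
    g <- panel$geno[id, ]
    q_hat <- unlist(est[est$animal == id, c("q_A", "b_B", "b_C")], use.names = FALSE)
    ll_hat <- admixture_loglik(g, P, q_hat)
    # 200 random draws from the simplex (normalized exponentials)
    rand <- matrix(rexp(200 * 3), 200)
    rand <- rand / rowSums(rand)
    ll_rand <- apply(rand, 1, function(q) admixture_loglik(g, P, q))
    expect_gte(ll_hat, max(ll_rand) - 1e-6)
  }
})

test_that("cross-population relationship matches hand computation", {
  # 2 SNPs, p_i = p_j = (0.5, 0.5): centered g_i = (1, 0), g_j = (1, -1),
  # both scaling sums are 1 -> G_ij = 1, G_jj = 2
  r <- grm_cross(g_i = c(2, 1), g_j = c(2, 0), p_i = c(0.5, 0.5), p_j = c(0.5, 0.5))
  expect_equal(r$G_ij, 1)
  expect_equal(r$G_jj, 2)
  # genotypes equal to twice the frequencies are centered to zero
  p <- c(0.25, 0.5, 0.75)
  r0 <- grm_cross(2 * p, c(0, 1, 2), p, p)
  expect_equal(r0$G_ij, 0)
  # symmetry when the populations coincide
  g1 <- c(0, 1, 2)
  g2 <- c(2, 1, 0)
  expect_equal(grm_cross(g1, g2, p, p)$G_ij, grm_cross(g2, g1, p, p)$G_ij)
  expect_error(grm_cross(c(0, 2), c(0, 2), c(0, 1), c(0, 1)), "zero scaling")
})

test_that("grandparent estimators: centering, the inbreeding ratio, exclusions", {
  sim <- simulate_scenario(quick_config(seed = 23))
  fr <- regression_line_freqs(sim$panel)
  rel <- rel_gp_estimate(sim$panel, sim$pedigree, fr)
  gp <- rel$estimates[rel$estimates$method == "REL_GP", ]
  nof <- rel$estimates[rel$estimates$method == "REL_GP_noF", ]
  rg <- rel$relationships
  # REL_GP_noF = G_ij / G_jj entry-wise
  mgs <- rg[rg$role == "mgs", ]
  expect_equal(nof$b_B, gp$b_B / mgs$G_jj[match(gp$animal, mgs$animal)])
  # a crossbred whose genotypes equal twice the blend is centered to zero
  blend <- crossbred_blend_freqs(fr)
  r <- grm_cross(2 * blend, sim$panel$geno[sim$pedigree$mgs[1], ],
                 blend, fr$p_B)
  expect_equal(r$G_ij, 0)
  # masked grandparents are excluded and reported
  ped <- sim$pedigree
  ped$mgs[1:3] <- NA
  rel2 <- rel_gp_estimate(sim$panel, ped, fr)
  expect_setequal(rel2$excluded, ped$id[1:3])
  expect_false(any(ped$id[1:3] %in% rel2$estimates$animal))
})

test_that("relationship estimators swap with the dam lines", {
  sim <- simulate_scenario(quick_config(seed = 29))
  swapped_line <- unname(c(A = "A", B = "C", C = "B", ABC = "ABC")[sim$panel$line])
  panel_sw <- genotype_panel(sim$panel$geno, swapped_line, sim$panel$map)
  ped_sw <- sim$pedigree
  ped_sw$mgs <- sim$pedigree$mgd
  ped_sw$mgd <- sim$pedigree$mgs
  r1 <- rel_gp_estimate(sim$panel, sim$pedigree, regression_line_freqs(sim$panel))
  r2 <- rel_gp_estimate(panel_sw, ped_sw, regression_line_freqs(panel_sw))
  expect_equal(r1$estimates$b_B, r2$estimates$b_C, tolerance = 1e-9)
  expect_equal(r1$estimates$b_C, r2$estimates$b_B, tolerance = 1e-9)
})
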