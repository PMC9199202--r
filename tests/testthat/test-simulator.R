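test_that("meiosis degenerates correctly for tiny maps and identical parents", {
  # near-zero chromosome length: no recombination, gamete is a whole haplotype
  map0 <- marker_map(chrom = "1", snp = sprintf("s%d", 1:8),
                     cm = rep(1e-9, 8), a1 = "1", a2 = "2")
  h1 <- rep(0L, 8)
  h2 <- rep(1L, 8)
  set.seed(1)
  for (i in 1:20) {
    g <- meiosis(h1, h2, map0)
    expect_true(identical(g$gamete, h1) || identical(g$gamete, h2))
  }
  # identical parental haplotypes: gamete equals them regardless of crossovers
  map <- tiny_map(30, length_morgan = 3)
  h <- rbinom(30, 1, 0.5)
  g <- meiosis(h, h, map)
  expect_identical(g$gamete, h)
})

test_that("meiosis inherits origin labels segment-wise", {
  map <- tiny_map(50, length_morgan = 2)
  set.seed(3)
  h1 <- rbinom(50, 1, 0.5)
  h2 <- rbinom(50, 1, 0.5)
  g <- meiosis(h1, h2, map, origin1 = rep("B", 50), origin2 = rep("C", 50))
  expect_identical(g$origin, c("B", "C")[g$source])
  expect_identical(g$gamete, ifelse(g$source == 1L, h1, h2))
})

test_that("gamete origin fractions match the analytic variance", {
  map <- tiny_map(200, length_morgan = 1)
  set.seed(7)
  h <- rbinom(200, 1, 0.5)
  n_gam <- 4000
  frac_B <- vapply(seq_len(n_gam), function(i) {
    g <- meiosis(h, h, map, origin1 = rep("B", 200), origin2 = rep("C", 200))
    mean(g$origin == "B")
  }, numeric(1))
  expect_equal(mean(frac_B), 0.5, tolerance = 0.01)
  v_theory <- theoretical_variance(1)$gamete_variance
  se <- sqrt((mean((frac_B - mean(frac_B))^4) - stats::var(frac_B)^2) / n_gam)
  expect_lt(abs(stats::var(frac_B) - v_theory), 3 * se)
})

test_that("simulation is deterministic under a fixed seed", {
  s1 <- simulate_scenario(quick_config(seed = 77))
  s2 <- simulate_scenario(quick_config(seed = 77))
  expect_identical(s1$panel$geno, s2$panel$geno)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$pedigree, s2$pedigree)
  s3 <- simulate_scenario(quick_config(seed = 78))
  expect_false(identical(s1$panel$geno, s3$panel$geno))
})

test_that("crossbred structure: paternal gamete all A, dam lines sum to half", {
  sim <- simulate_scenario(quick_config(seed = 5))
  expect_true(all(sim$origins$paternal == "A"))
  expect_true(all(sim$origins$maternal %in% c("B", "C")))
  expect_equal(sim$truth$b_B + sim$truth$b_C, rep(0.5, nrow(sim$truth)))
  # grandparents are genotyped line-B / line-C purebreds
  expect_true(all(sim$pedigree$mgs %in% animal_ids(sim$panel)))
  expect_true(all(sim$panel$line[sim$pedigree$mgs] == "B"))
  expect_true(all(sim$panel$line[sim$pedigree$mgd] == "C"))
})

test_that("undiverged lines show near-zero F_ST", {
  cfg <- scenario_config(preset = NULL, t = 0, Ne = 50, burnin = 10,
                         chr_length_morgan = c(1.0), n_snp = 400,
                         n_per_line = 150, n_b_sires = 5, n_c_dams = 10,
                         n_f1_dams = 20, n_a_sires = 5, n_crossbred = 20,
                         seed = 3)
  sim <- simulate_scenario(cfg)
  pw <- fst_wc(sim$panel, pairwise = TRUE)
  expect_lt(max(abs(pw$fst)), 0.02)
})

test_that("true_proportions counts alleles exactly", {
  m <- 10
  ids <- c("x1", "x2", "x3")
  pat <- matrix("A", 3, m, dimnames = list(ids, NULL))
  mat <- rbind(rep("B", m),                       # all-B maternal gamete
               rep(c("B", "C"), m / 2),           # alternating
               c(rep("B", 3), rep("C", m - 3)))
  rownames(mat) <- ids
  tp <- true_proportions(origin_matrix(pat, mat))
  expect_equal(tp$b_B, c(0.5, 0.25, 3 / (2 * m)))
  expect_equal(tp$b_C, c(0, 0.25, 7 / (2 * m)))
  # random fixture vs per-allele brute-force count
  set.seed(11)
  mat_r <- matrix(sample(c("B", "C"), 3 * m, replace = TRUE), 3, m,
                  dimnames = list(ids, NULL))
  tp_r <- true_proportions(origin_matrix(pat, mat_r))
  for (i in 1:3) {
    expect_equal(tp_r$b_B[i],
                 sum(c(pat[i, ], mat_r[i, ]) == "B") / (2 * m))
  }
  # unassigned labels are refused
  mat_r[1, 1] <- "U"
  expect_error(true_proportions(origin_matrix(pat, mat_r)), "unassigned")
})

test_that("masking leaves some crossbreds without genotyped grandparents", {
  sim <- simulate_scenario(quick_config(seed = 19, mask_prob = 0.4))
  expect_true(anyNA(sim$pedigree$mgs) || anyNA(sim$pedigree$mgd))
})

test_that("true mean and variance of dam-line proportions follow theory", {
  # many crossbreds, small purebred pool: checks the origin-tracking pipeline
  cfg <- scenario_config(preset = NULL, t = 2, Ne = 30, burnin = 20,
                         chr_length_morgan = c(3.2, 0.61), n_snp = c(700, 140),
                         n_per_line = 80, n_b_sires = 20, n_c_dams = 40,
                         n_f1_dams = 80, n_a_sires = 20, n_crossbred = 400,
                         seed = 21)
  sim <- simulate_scenario(cfg)
  td <- theoretical_variance(c(3.2, 0.61))
  expect_equal(mean(sim$truth$b_B), 0.25, tolerance = 3 * td$sd / sqrt(400) / 0.25)
  expect_lt(abs(stats::var(sim$truth$b_B) - td$variance), 0.35 * td$variance)
})
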