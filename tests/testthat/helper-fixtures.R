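# Small deterministic fixtures built in code.

# A marker map with m SNPs on one chromosome, allele codes "1"/"2".
tiny_map <- function(m, chrom = "1", length_morgan = 1) {
  marker_map(chrom = chrom, snp = sprintf("s%d", seq_len(m)),
             cm = seq_len(m) * length_morgan * 100 / m,
             a1 = "1", a2 = "2")
}

# Random panel: n animals per line (A, B, C) plus n_x crossbreds, genotypes
# drawn from line-specific frequencies so lines are differentiated.
random_panel <- function(n = 10, n_x = 0, m = 20, seed = 1) {
  set.seed(seed)
  map <- tiny_map(m)
  p <- replicate(3, runif(m, 0.1, 0.9))
  geno_line <- function(k, n) {
    vapply(seq_len(m), function(j) rbinom(n, 2, p[j, k]), integer(n))
  }
  p_x <- 0.5 * p[, 1] + 0.25 * p[, 2] + 0.25 * p[, 3]
  gx <- if (n_x > 0) {
    vapply(seq_len(m), function(j) rbinom(n_x, 2, p_x[j]), integer(n_x))
  } else NULL
  geno <- rbind(geno_line(1, n), geno_line(2, n), geno_line(3, n), gx)
  rownames(geno) <- sprintf("an%02d", seq_len(nrow(geno)))
  line <- c(rep(c("A", "B", "C"), each = n), rep("ABC", n_x))
  genotype_panel(geno, line, map)
}

# A scaled-down scenario configuration for fast tests.
quick_config <- function(..., seed = 1) {
  scenario_config(preset = NULL, t = 3, Ne = 30, burnin = 20,
                  chr_length_morgan = c(1.0, 0.5), n_snp = c(220, 110),
                  n_per_line = 60, n_b_sires = 8, n_c_dams = 20,
                  n_f1_dams = 40, n_a_sires = 8, n_crossbred = 50,
                  seed = seed, ...)
}

# Continuous-genome Monte-Carlo oracle for the variance of the fraction of a
# gamete inherited from one parental haplotype (Haldane model), independent
# of the SNP-based meiosis implementation.
mc_gamete_fraction <- function(l, n, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    k <- rpois(1, l)
    cuts <- c(0, sort(runif(k, 0, l)), l)
    seg <- diff(cuts)
    phase <- (seq_along(seg) + sample(0:1, 1)) %% 2
    sum(seg[phase == 1]) / l
  }, numeric(1))
}
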