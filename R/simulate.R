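#' Configuration for a three-way-cross simulation scenario
#'
#' Builds the parameter set for [simulate_scenario()]. The three named presets
#' reproduce the study conditions of the simulated pig data: three purebred
#' lines diverged from a common base population for `t` generations of random
#' mating, two chromosomes of 3.20 and 0.61 Morgan (resembling SSC1 and
#' SSC18) at 60k-chip-like SNP density, ~1000 genotyped purebreds per line and
#' 428 A(BC) crossbreds. The per-line effective size is calibrated so that the
#' mean pairwise Weir-Cockerham F_ST between the lines, measured on the
#' MAF-filtered panel, reaches the fixation index each preset represents
#' (0.04, 0.12 and 0.22). The closed-form drift approximation
#' `E[F_ST] ~ 1 - (1 - 1/(2*Ne))^t` provides the starting point, but the MAF
#' filter preferentially retains less-drifted loci and biases measured F_ST
#' downward, so Ne was calibrated against the measured estimator:
#'
#' * `"close"`: t = 5, Ne = 55
#' * `"distant"`: t = 20, Ne = 72
#' * `"unrelated"`: t = 50, Ne = 81
#'
#' SNP counts per chromosome are the numbers of segregating founder sites
#' simulated; after drift and the joint MAF filter the retained panel is close
#' to the ~4800 + ~920 SNPs of the emulated data.
#'
#' @param preset One of `"close"`, `"distant"`, `"unrelated"`, or `NULL` to
#'   specify `t` and `Ne` directly.
#' @param t Divergence generations (overrides the preset when given).
#' @param Ne Effective size of each line during burn-in and divergence.
#' @param burnin Burn-in generations of random mating that build LD in the
#'   common base population before the lines split.
#' @param chr_length_morgan Chromosome map lengths in Morgan.
#' @param n_snp Founder SNPs per chromosome.
#' @param n_per_line Genotyped purebred animals per line.
#' @param n_b_sires,n_c_dams Line-B sires and line-C dams of the F1 generation.
#' @param n_f1_dams F1 (BC) dams produced.
#' @param n_a_sires Line-A sires of the crossbred generation.
#' @param n_crossbred A(BC) crossbred animals produced.
#' @param mask_prob Probability that a maternal grandparent's genotype is
#'   treated as unavailable (independently per grandparent); 0 by default.
#'   ~0.34 emulates the emulated data's availability (on average 188 of 428
#'   crossbreds with both maternal grandparents genotyped).
#' @param maf Joint MAF threshold applied to the simulated panel.
#' @param seed Integer random seed; identical seeds give identical output.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(preset = c("unrelated", "distant", "close"),
                            t = NULL, Ne = NULL, burnin = 100,
                            chr_length_morgan = c(3.20, 0.61),
                            n_snp = c(10800, 2060),
                            n_per_line = 1000,
                            n_b_sires = 25, n_c_dams = 100, n_f1_dams = 200,
                            n_a_sires = 25, n_crossbred = 428,
                            mask_prob = 0, maf = 0.1, seed = 1) {
  if (!is.null(preset)) {
    preset <- match.arg(preset)
    defaults <- switch(preset,
      close = list(t = 5, Ne = 55),
      distant = list(t = 20, Ne = 72),
      unrelated = list(t = 50, Ne = 81))
    if (is.null(t)) t <- defaults$t
    if (is.null(Ne)) Ne <- defaults$Ne
  }
  if (is.null(t) || is.null(Ne)) {
    rlang::abort("either a preset or both t and Ne must be given")
  }
  cfg <- list(preset = if (is.null(preset)) "custom" else preset,
              t = as.integer(t), Ne = as.integer(Ne),
              burnin = as.integer(burnin),
              chr_length_morgan = chr_length_morgan,
              n_snp = as.integer(rep_len(n_snp, length(chr_length_morgan))),
              n_per_line = as.integer(n_per_line),
              n_b_sires = as.integer(n_b_sires),
              n_c_dams = as.integer(n_c_dams),
              n_f1_dams = as.integer(n_f1_dams),
              n_a_sires = as.integer(n_a_sires),
              n_crossbred = as.integer(n_crossbred),
              mask_prob = mask_prob, maf = maf, seed = as.integer(seed))
  stopifnot(cfg$t >= 0, cfg$Ne >= 2, all(cfg$chr_length_morgan > 0),
            cfg$mask_prob >= 0, cfg$mask_prob <= 1)
  if (cfg$n_b_sires > cfg$n_per_line || cfg$n_c_dams > cfg$n_per_line ||
      cfg$n_a_sires > cfg$n_per_line) {
    rlang::abort("requested parents exceed the number of purebreds per line")
  }
  class(cfg) <- "scenario_config"
  cfg
}

# Crossover source vector for one gamete under the Haldane model:
# Poisson(length) crossovers, uniform positions, no interference, random
# starting haplotype. Returns 1/2 per SNP.
gamete_source <- function(pos_list, lengths) {
  n_chr <- length(pos_list)
  out <- vector("list", n_chr)
  for (ci in seq_len(n_chr)) {
    pos <- pos_list[[ci]]
    l <- lengths[ci]
    k <- stats::rpois(1L, l)
    start <- sample.int(2L, 1L)
    if (k == 0L) {
      out[[ci]] <- rep.int(start, length(pos))
    } else {
      breaks <- sort(stats::runif(k, 0, l))
      out[[ci]] <- 1L + (start - 1L + findInterval(pos, breaks)) %% 2L
    }
  }
  unlist(out, use.names = FALSE)
}

#' Simulate one meiosis
#'
#' Produces a single gamete from a parent's two haplotypes under the Haldane
#' recombination model: the crossover count per chromosome is Poisson with
#' mean equal to the chromosome length in Morgan, crossover positions are
#' uniform, there is no interference, and the starting haplotype is chosen
#' with probability 1/2. Origin labels are inherited segment-wise.
#'
#' @param h1,h2 Integer vectors (0/1 allele codes), the parent's two
#'   haplotypes, in marker-map SNP order.
#' @param map A [marker_map()] matching the haplotypes.
#' @param origin1,origin2 Optional per-SNP origin labels of the two parental
#'   haplotypes; when supplied the gamete's origin labels are returned.
#' @return A list with `gamete` (integer vector), `source` (1 where the allele
#'   came from `h1`, 2 from `h2`) and `origin` (or `NULL`).
#' @export
meiosis <- function(h1, h2, map, origin1 = NULL, origin2 = NULL) {
  stopifnot(inherits(map, "marker_map"), length(h1) == nrow(map),
            length(h2) == nrow(map))
  lengths <- chrom_lengths(map)
  pos_list <- split(map$cm / 100, factor(map$chrom, levels = unique(map$chrom)))
  src <- gamete_source(pos_list, lengths)
  gam <- h1
  gam[src == 2L] <- h2[src == 2L]
  orig <- NULL
  if (!is.null(origin1)) {
    orig <- origin1
    orig[src == 2L] <- origin2[src == 2L]
  }
  list(gamete = gam, source = src, origin = orig)
}

# One generation of random mating: n_off offspring from the diploid
# population in H (2N x M haplotype matrix, rows 2i-1/2i belong to animal i).
next_generation <- function(H, n_off, pos_list, lengths) {
  N <- nrow(H) %/% 2L
  out <- matrix(0L, 2L * n_off, ncol(H))
  for (i in seq_len(n_off)) {
    par <- sample.int(N, 2L)
    for (k in 1:2) {
      src <- gamete_source(pos_list, lengths)
      h <- H[2L * par[k] - 1L, ]
      sel <- src == 2L
      h[sel] <- H[2L * par[k], sel]
      out[2L * i - 2L + k, ] <- h
    }
  }
  out
}

#' Simulate a three-way crossbreeding scenario
#'
#' Runs the full forward simulation: founder haplotypes are drawn
#' independently per SNP with allele frequencies uniform on (0.05, 0.95), a
#' burn-in of random mating builds LD in the common base population, the
#' population then splits into lines A, B and C which mate randomly within
#' line for `t` generations, and the cross is made (line-B sires x line-C
#' dams give F1 dams; line-A sires x F1 dams give the A(BC) crossbreds) with
#' full per-allele line-of-origin tracking. The joint MAF filter is applied
#' to the combined panel and the true line proportions are computed on the
#' filtered panel — the same SNP set every estimator sees.
#'
#' @param config A [scenario_config()].
#' @return A list of class `sim_scenario` with elements `panel`
#'   ([genotype_panel()] of purebreds and crossbreds after MAF filtering),
#'   `pedigree` (crossbred pedigree tibble with `NA` for masked
#'   grandparents), `origins` ([origin_matrix()] of the crossbreds on the
#'   filtered panel), `truth` (tibble of true proportions, method `"TRUE"`)
#'   and `config`.
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  set.seed(cfg$seed)

  lengths <- cfg$chr_length_morgan
  n_chr <- length(lengths)
  pos_list <- lapply(seq_len(n_chr),
                     function(ci) sort(stats::runif(cfg$n_snp[ci], 0, lengths[ci])))
  M <- sum(cfg$n_snp)
  chrom <- rep(seq_len(n_chr), cfg$n_snp)
  map <- marker_map(
    chrom = chrom,
    snp = sprintf("snp%d_%d", chrom, unlist(lapply(cfg$n_snp, seq_len))),
    cm = unlist(pos_list) * 100,
    a1 = "1", a2 = "2",
    lengths_morgan = stats::setNames(lengths, as.character(seq_len(n_chr))))

  # founders + burn-in in the common base population
  p0 <- stats::runif(M, 0.05, 0.95)
  H <- vapply(p0, function(p) stats::rbinom(2L * cfg$Ne, 1L, p),
              integer(2L * cfg$Ne))
  for (g in seq_len(cfg$burnin)) H <- next_generation(H, cfg$Ne, pos_list, lengths)

  # split into three lines, t generations of random mating within line,
  # then one expansion generation of genotyped purebreds
  pure <- vector("list", 3L)
  names(pure) <- c("A", "B", "C")
  for (ln in names(pure)) {
    HL <- H
    for (g in seq_len(cfg$t)) HL <- next_generation(HL, cfg$Ne, pos_list, lengths)
    pure[[ln]] <- next_generation(HL, cfg$n_per_line, pos_list, lengths)
  }

  id_pure <- lapply(names(pure), function(ln) sprintf("%s%04d", ln, seq_len(cfg$n_per_line)))
  names(id_pure) <- names(pure)

  draw_gamete <- function(HP, idx) {
    src <- gamete_source(pos_list, lengths)
    h <- HP[2L * idx - 1L, ]
    sel <- src == 2L
    h[sel] <- HP[2L * idx, sel]
    list(h = h, src = src)
  }

  # the cross: B sires x C dams -> F1 dams
  b_sires <- sample.int(cfg$n_per_line, cfg$n_b_sires)
  c_dams <- sample.int(cfg$n_per_line, cfg$n_c_dams)
  f1_sire <- b_sires[sample.int(cfg$n_b_sires, cfg$n_f1_dams, replace = TRUE)]
  f1_dam <- c_dams[rep_len(seq_len(cfg$n_c_dams), cfg$n_f1_dams)]
  f1_pat <- matrix(0L, cfg$n_f1_dams, M)  # line-B gamete
  f1_mat <- matrix(0L, cfg$n_f1_dams, M)  # line-C gamete
  for (i in seq_len(cfg$n_f1_dams)) {
    f1_pat[i, ] <- draw_gamete(pure$B, f1_sire[i])$h
    f1_mat[i, ] <- draw_gamete(pure$C, f1_dam[i])$h
  }

  # A sires x F1 dams -> A(BC) crossbreds with origin tracking
  a_sires <- sample.int(cfg$n_per_line, cfg$n_a_sires)
  x_sire <- a_sires[sample.int(cfg$n_a_sires, cfg$n_crossbred, replace = TRUE)]
  x_f1 <- sample.int(cfg$n_f1_dams, cfg$n_crossbred, replace = TRUE)
  x_geno <- matrix(0L, cfg$n_crossbred, M)
  orig_mat <- matrix("", cfg$n_crossbred, M)
  for (i in seq_len(cfg$n_crossbred)) {
    pat <- draw_gamete(pure$A, x_sire[i])$h
    f <- x_f1[i]
    src <- gamete_source(pos_list, lengths)
    mat <- f1_pat[f, ]
    sel <- src == 2L
    mat[sel] <- f1_mat[f, sel]
    x_geno[i, ] <- pat + mat
    orig_mat[i, ] <- c("B", "C")[src]
  }
  x_ids <- sprintf("X%04d", seq_len(cfg$n_crossbred))
  rownames(x_geno) <- x_ids
  orig_pat <- matrix("A", cfg$n_crossbred, M, dimnames = list(x_ids, NULL))
  rownames(orig_mat) <- x_ids

  geno_of <- function(HP) HP[seq(1L, nrow(HP), 2L), ] + HP[seq(2L, nrow(HP), 2L), ]
  geno <- rbind(geno_of(pure$A), geno_of(pure$B), geno_of(pure$C), x_geno)
  rownames(geno) <- c(unlist(id_pure), x_ids)
  line <- c(rep(c("A", "B", "C"), each = cfg$n_per_line),
            rep("ABC", cfg$n_crossbred))
  panel <- genotype_panel(geno, line, map)

  # grandparent masking emulates incomplete genotype availability
  mgs <- id_pure$B[f1_sire[x_f1]]
  mgd <- id_pure$C[f1_dam[x_f1]]
  if (cfg$mask_prob > 0) {
    mgs[stats::runif(cfg$n_crossbred) < cfg$mask_prob] <- NA_character_
    mgd[stats::runif(cfg$n_crossbred) < cfg$mask_prob] <- NA_character_
  }
  pedigree <- tibble::tibble(
    id = x_ids,
    sire = id_pure$A[x_sire],
    dam = sprintf("F1%04d", x_f1),
    mgs = mgs,
    mgd = mgd)

  panel <- maf_filter(panel, cfg$maf)
  kept <- match(panel$map$snp, map$snp)
  origins <- origin_matrix(orig_pat[, kept, drop = FALSE],
                           orig_mat[, kept, drop = FALSE])
  truth <- true_proportions(origins)

  structure(list(panel = panel, pedigree = pedigree, origins = origins,
                 truth = truth, config = cfg),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("<sim_scenario> preset \"%s\" (t = %d, Ne = %d, seed = %d)\n",
              x$config$preset, x$config$t, x$config$Ne, x$config$seed))
  print(x$panel)
  n_gp <- sum(!is.na(x$pedigree$mgs) & !is.na(x$pedigree$mgd))
  cat(sprintf("  crossbreds with both maternal grandparents genotyped: %d of %d\n",
              n_gp, nrow(x$pedigree)))
  invisible(x)
}

#' Export a simulated scenario to plain-text files
#'
#' Writes the PED/MAP panel, the line table, the crossbred pedigree, the
#' origin matrix and the true proportions so the file-based pipeline
#' ([run_real_data()]) can reproduce the in-memory results.
#'
#' @param sim A [simulate_scenario()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix, default `"sim"`.
#' @return Invisibly, a named character vector of the written paths.
#' @export
export_scenario <- function(sim, dir, prefix = "sim") {
  stopifnot(inherits(sim, "sim_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pm <- write_pedmap(sim$panel, file.path(dir, prefix))
  paths <- c(pm,
    lines = write_line_table(sim$panel, file.path(dir, paste0(prefix, "_lines.tsv"))),
    pedigree = write_pedigree(sim$pedigree, file.path(dir, paste0(prefix, "_pedigree.tsv"))),
    origins = write_origins(sim$origins, file.path(dir, paste0(prefix, "_origins.tsv"))),
    truth = write_result_tsv(sim$truth, file.path(dir, paste0(prefix, "_truth.tsv"))))
  invisible(paths)
}
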