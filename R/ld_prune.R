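#' Pairwise r-squared between two SNPs
#'
#' Squared Pearson correlation of unphased allele counts (composite LD). A
#' zero-variance vector yields an r-squared of 0 by convention, so that
#' monomorphic SNPs are never treated as linked during pruning.
#'
#' @param g1,g2 Integer genotype vectors of equal length (>= 2).
#' @return Squared correlation in `[0, 1]`.
#' @export
pairwise_r2 <- function(g1, g2) {
  stopifnot(length(g1) == length(g2), length(g1) >= 2)
  if (stats::var(g1) == 0 || stats::var(g2) == 0) return(0)
  stats::cor(g1, g2)^2
}

#' Windowed pairwise-r-squared SNP pruning
#'
#' Greedy LD pruning in the style of PLINK's `--indep-pairwise`: per
#' chromosome, a window of `window` SNPs slides forward by `step` SNPs; within
#' each window, while any surviving pair has r-squared above `threshold`, the
#' pair with the largest r-squared is found and its lower-MAF member removed
#' (ties remove the later index). The returned SNP set contains no
#' within-window pair above the threshold. Exact index-level agreement with
#' any particular external tool is not a goal; the post-condition is the
#' contract.
#'
#' @param panel A [genotype_panel()]; r-squared and MAF are computed over all
#'   of its animals.
#' @param window Window size in SNPs (>= 2), default 50.
#' @param step Window shift in SNPs, default 10.
#' @param threshold r-squared above which one SNP of a pair is removed;
#'   default 0.5.
#' @return Integer vector of kept SNP column indices (relative to the panel).
#' @export
indep_pairwise <- function(panel, window = 50, step = 10, threshold = 0.5) {
  stopifnot(inherits(panel, "genotype_panel"), window >= 2,
            step >= 1, step <= window)
  geno <- panel$geno
  p <- colMeans(geno) / 2
  maf <- pmin(p, 1 - p)
  keep <- rep(TRUE, ncol(geno))
  chrom <- panel$map$chrom
  for (ch in unique(chrom)) {
    cols <- which(chrom == ch)
    m <- length(cols)
    starts <- seq(1L, max(1L, m - 1L), by = step)
    for (s in starts) {
      win <- cols[s:min(s + window - 1L, m)]
      live <- win[keep[win]]
      if (length(live) < 2L) next
      r2 <- suppressWarnings(stats::cor(geno[, live, drop = FALSE]))^2
      r2[!is.finite(r2)] <- 0  # zero-variance columns carry no LD
      diag(r2) <- 0
      repeat {
        mx <- max(r2)
        if (mx <= threshold) break
        idx <- which(r2 == mx, arr.ind = TRUE)[1, ]
        a <- live[idx[1]]
        b <- live[idx[2]]
        drop_col <- if (maf[a] < maf[b]) a else if (maf[b] < maf[a]) b else max(a, b)
        keep[drop_col] <- FALSE
        k <- match(drop_col, live)
        r2[k, ] <- 0
        r2[, k] <- 0
      }
    }
  }
  which(keep)
}
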