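#' Line-specific allele frequencies by direct counting
#'
#' Computes, per SNP, the frequency of the counted allele within each purebred
#' line as the mean allele count among that line's animals divided by two.
#' These are the frequencies used by the sire-adjusted regression estimator
#' ([lr_estimate()]).
#'
#' @param panel A [genotype_panel()] containing at least one animal in each of
#'   lines A, B and C.
#' @return A tibble of class `line_freqs` with columns `snp`, `p_A`, `p_B`,
#'   `p_C`, `blend` (the expected crossbred frequency
#'   `0.5 p_A + 0.25 p_B + 0.25 p_C`) and `provenance`
#'   (`"purebred-count"`).
#' @export
purebred_line_freqs <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  p <- lapply(c("A", "B", "C"), function(ln) {
    g <- line_geno(panel, ln)
    if (nrow(g) == 0) rlang::abort(sprintf("no animals of line %s in panel", ln))
    colMeans(g) / 2
  })
  new_line_freqs(panel$map$snp, p[[1]], p[[2]], p[[3]], "purebred-count")
}

#' Line-specific allele frequencies by regression on expected proportions
#'
#' Estimates line frequencies per SNP by ordinary least squares of all
#' available genotypes (purebreds and crossbreds) on the expected line
#' proportions: a purebred A animal contributes design row (1, 0, 0), B
#' (0, 1, 0), C (0, 0, 1) and an A(BC) crossbred (0.5, 0.25, 0.25), under the
#' model `g = 2 * Pi * p + e`. Solutions are clipped to `[0, 1]`. With no
#' crossbreds in the panel this reduces exactly to [purebred_line_freqs()].
#' These are the frequencies the grandparent-relationship estimators use.
#'
#' @param panel A [genotype_panel()] with purebreds of all three lines
#'   (crossbreds optional).
#' @return A tibble of class `line_freqs` (see [purebred_line_freqs()]),
#'   provenance `"regression"`.
#' @export
regression_line_freqs <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  design_rows <- rbind(A = c(1, 0, 0), B = c(0, 1, 0), C = c(0, 0, 1),
                       ABC = c(0.5, 0.25, 0.25))
  miss <- setdiff(c("A", "B", "C"), unique(panel$line))
  if (length(miss) > 0) {
    rlang::abort(sprintf("design is rank deficient: purebred line %s missing from the panel",
                         paste(miss, collapse = ", ")))
  }
  Pi <- design_rows[panel$line, , drop = FALSE]
  # per-SNP OLS via one shared 3x3 normal-equation solve, coefficients are
  # frequencies because of the factor 2 in g = 2*Pi*p + e
  P <- solve(crossprod(Pi), crossprod(Pi, panel$geno)) / 2
  P <- pmin(pmax(P, 0), 1)
  new_line_freqs(panel$map$snp, P[1, ], P[2, ], P[3, ], "regression")
}

new_line_freqs <- function(snp, p_A, p_B, p_C, provenance) {
  out <- tibble::tibble(
    snp = snp,
    p_A = unname(p_A), p_B = unname(p_B), p_C = unname(p_C),
    blend = 0.5 * unname(p_A) + 0.25 * unname(p_B) + 0.25 * unname(p_C),
    provenance = provenance)
  class(out) <- c("line_freqs", class(tibble::tibble()))
  out
}

#' Expected crossbred blend frequency
#'
#' The allele frequency expected in A(BC) crossbreds: the weighted average of
#' the line-specific frequencies with the expected line proportions 0.5, 0.25
#' and 0.25 as weights.
#'
#' @param freqs A `line_freqs` tibble (from [purebred_line_freqs()] or
#'   [regression_line_freqs()]).
#' @return Numeric vector of per-SNP blend frequencies.
#' @export
crossbred_blend_freqs <- function(freqs) {
  stopifnot(inherits(freqs, "line_freqs"))
  0.5 * freqs$p_A + 0.25 * freqs$p_B + 0.25 * freqs$p_C
}
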