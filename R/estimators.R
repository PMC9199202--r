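#' Dam-line proportions from breed-origin-of-alleles assignments
#'
#' Counts assigned alleles per line: `b_B` is the number of alleles assigned
#' to line B divided by the total number of assigned alleles (both haplotypes,
#' all SNPs), and likewise for `b_C`. With complete assignments this is
#' identical to [true_proportions()]; with unassigned alleles the proportions
#' are computed among the assigned alleles, which is unbiased when
#' unassignment is unrelated to origin.
#'
#' @param origins An [origin_matrix()]; unassigned (`"U"`) entries are
#'   permitted.
#' @return A tibble with columns `animal`, `method` (`"BOA"`), `stage`
#'   (`"raw"`), `b_B`, `b_C` and `n_assigned`.
#' @export
boa_proportions <- function(origins) {
  stopifnot(inherits(origins, "origin_matrix"))
  n_assigned <- count_origins(origins, "A") + count_origins(origins, "B") +
    count_origins(origins, "C")
  if (any(n_assigned == 0)) {
    rlang::abort(sprintf("animals with zero assigned alleles: %s",
      paste(rownames(origins$paternal)[n_assigned == 0], collapse = ", ")))
  }
  tibble::tibble(
    animal = rownames(origins$paternal),
    method = "BOA",
    stage = "raw",
    b_B = unname(count_origins(origins, "B") / n_assigned),
    b_C = unname(count_origins(origins, "C") / n_assigned),
    n_assigned = unname(n_assigned))
}

#' Sire-adjusted linear-regression estimator of dam-line proportions
#'
#' Regresses each crossbred's allele counts on line mean allele counts. The
#' model is `g = x_A b_A + x_B b_B + x_C b_C + e` with `x` the per-line mean
#' allele-count vectors (`x = 2p`). Because the line-A proportion of an A(BC)
#' animal is exactly 0.5, that term is moved to the left-hand side
#' (`g* = g - 0.5 x_A`) and `(b_B, b_C)` is the ordinary least-squares
#' solution of `g*` on `[x_B, x_C]` without intercept. Raw estimates are
#' unconstrained; apply [postprocess_estimates()] afterwards.
#'
#' @param panel A [genotype_panel()]; only its `"ABC"` animals are estimated.
#' @param freqs A `line_freqs` tibble; by convention the purebred counting
#'   frequencies ([purebred_line_freqs()]).
#' @return A tibble with columns `animal`, `method` (`"LR"`), `stage`
#'   (`"raw"`), `b_B`, `b_C` and `resid_norm` (Euclidean norm of the
#'   per-animal residual vector).
#' @export
lr_estimate <- function(panel, freqs) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(freqs, "line_freqs"))
  check_freqs_match(panel, freqs)
  G <- line_geno(panel, "ABC")
  if (nrow(G) == 0) rlang::abort("panel contains no ABC crossbreds")
  x_A <- 2 * freqs$p_A
  X <- cbind(x_B = 2 * freqs$p_B, x_C = 2 * freqs$p_C)
  if (qr(X)$rank < 2) {
    rlang::abort("regressors are collinear: line B and C frequencies are proportional at every SNP")
  }
  Gstar <- sweep(G, 2L, 0.5 * x_A)  # remove the fixed sire-line contribution
  coef <- solve(crossprod(X), crossprod(X, t(Gstar)))  # 2 x n_animals
  resid <- t(Gstar) - X %*% coef
  tibble::tibble(
    animal = rownames(G),
    method = "LR",
    stage = "raw",
    b_B = unname(coef[1, ]),
    b_C = unname(coef[2, ]),
    resid_norm = unname(sqrt(colSums(resid^2))))
}

check_freqs_match <- function(panel, freqs) {
  if (nrow(freqs) != ncol(panel$geno) || !all(freqs$snp == panel$map$snp)) {
    rlang::abort("frequencies do not match the panel's SNP set")
  }
}
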