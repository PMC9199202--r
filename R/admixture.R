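#' Supervised admixture estimation by expectation-maximization
#'
#' Maximum-likelihood ancestry fractions with the ancestral (line) allele
#' frequencies held fixed at the supplied values — the "supervised" admixture
#' model. For an animal with genotypes `g_m` and line frequencies `p_mk`, the
#' log-likelihood is
#' `sum_m [ g_m log(sum_k q_k p_mk) + (2 - g_m) log(sum_k q_k (1 - p_mk)) ]`
#' maximized over the 3-simplex `q = (q_A, q_B, q_C)` by EM
#' (responsibility-weighted allele shares). All animals start at the expected
#' composition `q = (0.5, 0.25, 0.25)` and iterate until the total
#' log-likelihood improves by less than `tol` or `max_iter` is reached; the
#' log-likelihood never decreases across iterations. The model assumes
#' linkage equilibrium between SNPs, so the panel is typically LD-pruned
#' first ([indep_pairwise()]).
#'
#' @param panel A [genotype_panel()]; only its `"ABC"` animals are estimated.
#' @param freqs A `line_freqs` tibble on the panel's SNP set; frequencies are
#'   floored into `[floor, 1 - floor]` so the likelihood stays finite.
#' @param max_iter Maximum EM iterations, default 1000.
#' @param tol Convergence tolerance on the change in total log-likelihood,
#'   default 1e-7.
#' @param floor Frequency floor, default 1e-6.
#' @return A tibble with columns `animal`, `method` (`"ADM"`), `stage`
#'   (`"raw"`), `b_B`, `b_C` (the line-B/C ancestry fractions) and `q_A`; the
#'   per-iteration total log-likelihood is attached as attribute `loglik`.
#' @export
admixture_supervised_em <- function(panel, freqs, max_iter = 1000, tol = 1e-7,
                                    floor = 1e-6) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(freqs, "line_freqs"))
  check_freqs_match(panel, freqs)
  G <- line_geno(panel, "ABC")
  if (nrow(G) == 0) rlang::abort("panel contains no ABC crossbreds")
  n <- nrow(G)
  m <- ncol(G)
  P <- cbind(freqs$p_A, freqs$p_B, freqs$p_C)
  P <- pmin(pmax(P, floor), 1 - floor)  # m x 3
  G2 <- 2 - G
  Q <- matrix(rep(c(0.5, 0.25, 0.25), each = n), n, 3)

  loglik <- function(Q) {
    D1 <- Q %*% t(P)
    D0 <- Q %*% t(1 - P)
    sum(G * log(D1) + G2 * log(D0))
  }
  ll <- numeric(0)
  ll_prev <- loglik(Q)
  for (it in seq_len(max_iter)) {
    D1 <- Q %*% t(P)       # n x m: sum_k q_k p_mk
    D0 <- Q %*% t(1 - P)
    # responsibility-weighted counted / other allele shares per ancestry
    A1 <- (G / D1) %*% P         # n x 3
    A0 <- (G2 / D0) %*% (1 - P)
    Q <- Q * (A1 + A0) / (2 * m)
    Q <- Q / rowSums(Q)  # guard accumulated rounding; EM preserves the simplex
    ll_new <- loglik(Q)
    if (!is.finite(ll_new)) rlang::abort("non-finite admixture likelihood")
    ll <- c(ll, ll_new)
    if (abs(ll_new - ll_prev) < tol) break
    ll_prev <- ll_new
  }
  out <- tibble::tibble(
    animal = rownames(G),
    method = "ADM",
    stage = "raw",
    b_B = unname(Q[, 2]),
    b_C = unname(Q[, 3]),
    q_A = unname(Q[, 1]))
  attr(out, "loglik") <- ll
  out
}

#' Supervised admixture log-likelihood of given ancestry fractions
#'
#' Utility used for likelihood diagnostics and cross-checks: evaluates the
#' supervised admixture log-likelihood of one animal at an arbitrary point of
#' the simplex.
#'
#' @param g Genotype vector (0/1/2).
#' @param P Matrix of line allele frequencies (SNPs x ancestries).
#' @param q Ancestry fractions summing to 1.
#' @param floor Frequency floor, default 1e-6.
#' @return Log-likelihood value.
#' @export
admixture_loglik <- function(g, P, q, floor = 1e-6) {
  P <- pmin(pmax(P, floor), 1 - floor)
  d1 <- as.vector(P %*% q)
  d0 <- as.vector((1 - P) %*% q)
  sum(g * log(d1) + (2 - g) * log(d0))
}
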