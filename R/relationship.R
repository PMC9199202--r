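#' Multi-population genomic relationship between two animals
#'
#' Genomic relationship with population-specific centering and scaling: each
#' animal's genotypes are centered by twice the allele frequencies of its own
#' population, and the cross-product is scaled by the geometric mean of the
#' two populations' `sum 2p(1-p)`:
#' `G_ij = sum_m (g_im - 2 p_im)(g_jm - 2 p_jm) /
#'   sqrt( sum_m 2 p_im (1 - p_im) * sum_m 2 p_jm (1 - p_jm) )`.
#' The self-relationship `G_jj` (with `p_j` on both sides) estimates
#' `1 + F_j`, one plus the genomic inbreeding coefficient of animal `j`.
#'
#' @param g_i,g_j Genotype vectors on the same SNP set.
#' @param p_i,p_j Per-SNP allele frequencies of animal i's and j's
#'   populations.
#' @return A one-row tibble with `G_ij`, `G_jj` (self-relationship of `j`
#'   computed with `p_j`).
#' @export
grm_cross <- function(g_i, g_j, p_i, p_j) {
  stopifnot(length(g_i) == length(g_j), length(p_i) == length(g_i),
            length(p_j) == length(g_j))
  s_i <- sum(2 * p_i * (1 - p_i))
  s_j <- sum(2 * p_j * (1 - p_j))
  if (s_i <= 0 || s_j <= 0) rlang::abort("zero scaling sum: frequencies are all fixed")
  z_i <- g_i - 2 * p_i
  z_j <- g_j - 2 * p_j
  tibble::tibble(G_ij = sum(z_i * z_j) / sqrt(s_i * s_j),
                 G_jj = sum(z_j^2) / s_j)
}

#' Grandparent-relationship estimators of dam-line proportions
#'
#' In an A(BC) crossbred all line-B alleles come from the line-B maternal
#' grandsire and all line-C alleles from the line-C maternal granddam, so the
#' realized dam-line proportion equals the genome fraction inherited from the
#' corresponding grandparent. Two estimators exploit this through the
#' multi-population genomic relationship ([grm_cross()]) between the crossbred
#' (centered with the blend frequencies, see [crossbred_blend_freqs()]) and
#' its grandparent (centered with its line's frequencies):
#'
#' * `REL_GP`: `b_B = G_ij` with the maternal grandsire (and `b_C` with the
#'   granddam), which assumes the grandparent is not inbred;
#' * `REL_GP_noF`: `b_B = G_ij / G_jj`, dividing by the grandparent's
#'   self-relationship — an estimator of `1 + F` — to drop that assumption.
#'
#' Crossbreds lacking a genotyped grandparent (either `mgs`/`mgd` is `NA` or
#' absent from the panel) are excluded and reported.
#'
#' @param panel A [genotype_panel()] holding the crossbreds and their
#'   genotyped grandparents.
#' @param pedigree Crossbred pedigree tibble with columns `id`, `mgs`, `mgd`.
#' @param freqs A `line_freqs` tibble; by convention the regression-based
#'   frequencies ([regression_line_freqs()]), from which the crossbred blend
#'   is derived.
#' @return A list with `estimates` (tibble of methods `"REL_GP"` and
#'   `"REL_GP_noF"`, stage `"raw"`), `relationships` (tibble with `animal`,
#'   `grandparent`, `role`, `G_ij`, `G_jj`) and `excluded` (character vector
#'   of skipped crossbred ids).
#' @export
rel_gp_estimate <- function(panel, pedigree, freqs) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(freqs, "line_freqs"))
  check_freqs_match(panel, freqs)
  ids <- animal_ids(panel)
  ped <- pedigree[pedigree$id %in% ids[panel$line == "ABC"], ]
  ok <- !is.na(ped$mgs) & !is.na(ped$mgd) &
    ped$mgs %in% ids & ped$mgd %in% ids
  excluded <- ped$id[!ok]
  ped <- ped[ok, ]
  if (nrow(ped) == 0) rlang::abort("no crossbred has both maternal grandparents genotyped")

  p_blend <- crossbred_blend_freqs(freqs)
  s_blend <- sum(2 * p_blend * (1 - p_blend))
  s_B <- sum(2 * freqs$p_B * (1 - freqs$p_B))
  s_C <- sum(2 * freqs$p_C * (1 - freqs$p_C))
  if (s_blend <= 0 || s_B <= 0 || s_C <= 0) {
    rlang::abort("zero scaling sum: frequencies are all fixed")
  }

  Zx <- sweep(panel$geno[ped$id, , drop = FALSE], 2L, 2 * p_blend)
  Zs <- sweep(panel$geno[ped$mgs, , drop = FALSE], 2L, 2 * freqs$p_B)
  Zd <- sweep(panel$geno[ped$mgd, , drop = FALSE], 2L, 2 * freqs$p_C)
  G_is <- rowSums(Zx * Zs) / sqrt(s_blend * s_B)
  G_id <- rowSums(Zx * Zd) / sqrt(s_blend * s_C)
  G_ss <- rowSums(Zs^2) / s_B
  G_dd <- rowSums(Zd^2) / s_C

  estimates <- dplyr::bind_rows(
    tibble::tibble(animal = ped$id, method = "REL_GP", stage = "raw",
                   b_B = unname(G_is), b_C = unname(G_id)),
    tibble::tibble(animal = ped$id, method = "REL_GP_noF", stage = "raw",
                   b_B = unname(G_is / G_ss), b_C = unname(G_id / G_dd)))
  relationships <- dplyr::bind_rows(
    tibble::tibble(animal = ped$id, grandparent = ped$mgs, role = "mgs",
                   G_ij = unname(G_is), G_jj = unname(G_ss)),
    tibble::tibble(animal = ped$id, grandparent = ped$mgd, role = "mgd",
                   G_ij = unname(G_id), G_jj = unname(G_dd)))
  list(estimates = estimates, relationships = relationships, excluded = excluded)
}
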