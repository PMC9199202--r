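#' Quality metrics of estimated dam-line proportions
#'
#' Compares estimated against reference (true or gold-standard) proportions
#' for the animals common to both tables, per method:
#'
#' * accuracy — Pearson correlation between estimated and reference values;
#' * dispersion slope — coefficient of the regression of reference on
#'   estimate, `cov(ref, est) / var(est)`; 1 means no dispersion bias, values
#'   below 1 mean inflated (over-dispersed) estimates;
#' * maximum absolute error and root mean squared error.
#'
#' @param est Tibble of estimates (columns `animal`, `method`, `b_B`, `b_C`).
#' @param ref Tibble of reference proportions for the same animals (a single
#'   reference method, e.g. the simulator's truth or BOA-derived values).
#' @param line `"B"` (default) or `"C"`: which dam line's proportions to
#'   compare. After [postprocess_estimates()] both give identical reports.
#' @return A tibble with one row per method: `method`, `reference`, `n`,
#'   `accuracy`, `slope`, `max_error`, `rmse`.
#' @export
evaluate_estimates <- function(est, ref, line = c("B", "C")) {
  line <- match.arg(line)
  col <- paste0("b_", line)
  ref_method <- unique(ref$method)
  if (length(ref_method) != 1) rlang::abort("ref must hold a single method")
  joined <- dplyr::inner_join(
    dplyr::select(est, dplyr::all_of(c("animal", "method", col))),
    dplyr::select(ref, dplyr::all_of(c("animal", col))),
    by = "animal", suffix = c("_est", "_ref"))
  joined |>
    dplyr::group_by(.data$method) |>
    dplyr::group_modify(function(d, key) {
      e <- d[[paste0(col, "_est")]]
      r <- d[[paste0(col, "_ref")]]
      if (length(e) < 2) rlang::abort("need at least 2 common animals")
      if (stats::var(e) == 0) {
        rlang::abort(sprintf("estimates of method %s have zero variance", key$method))
      }
      tibble::tibble(
        reference = ref_method,
        n = length(e),
        accuracy = stats::cor(e, r),
        slope = stats::cov(r, e) / stats::var(e),
        max_error = max(abs(e - r)),
        rmse = sqrt(mean((e - r)^2)))
    }) |>
    dplyr::ungroup()
}

#' Theoretical distribution of a dam-line proportion
#'
#' Mean and variance of the proportion of alleles an A(BC) crossbred inherits
#' from one maternal grandparent, under the Haldane model with a non-inbred
#' grandparent. Along a chromosome of length `l` Morgan, the grandparental
#' origin of a gamete is a two-state process switching at crossover rate 1,
#' giving a gamete-fraction variance of
#' `v(l) = (1 / (2 l^2)) * (l / 2 - (1 - exp(-2 l)) / 4)`.
#' Chromosomes combine weighted by squared length,
#' `V_gamete = sum(l_i^2 v(l_i)) / (sum l_i)^2`, and the line proportion —
#' half the maternal-gamete fraction — has variance `V_gamete / 4` and mean
#' 0.25. As all lengths approach zero the variance approaches 1/16 (a single
#' locus: the proportion is 0 or 0.5 with equal probability).
#'
#' @param lengths_morgan Positive chromosome map lengths in Morgan.
#' @return A one-row tibble: `mean` (0.25), `variance`, `sd` (of the line
#'   proportion), `gamete_variance`; the lengths are attached as attribute
#'   `lengths_morgan`.
#' @export
theoretical_variance <- function(lengths_morgan) {
  l <- as.numeric(lengths_morgan)
  if (any(l <= 0)) rlang::abort("all chromosome lengths must be > 0")
  v <- (1 / (2 * l^2)) * (l / 2 + expm1(-2 * l) / 4)
  v_gamete <- sum(l^2 * v) / sum(l)^2
  out <- tibble::tibble(mean = 0.25, variance = v_gamete / 4,
                        sd = sqrt(v_gamete / 4), gamete_variance = v_gamete)
  attr(out, "lengths_morgan") <- l
  out
}

#' Weir-Cockerham F_ST
#'
#' Per-locus variance-component estimator of the fixation index for `r`
#' populations (theta of Weir & Cockerham 1984), computed from genotype
#' counts, using the observed heterozygosity per population. The reported
#' value is the unweighted mean over loci with a defined denominator
#' (mean of per-locus ratios). With `pairwise = TRUE` the estimator is
#' applied to every pair of lines separately.
#'
#' @param panel A [genotype_panel()].
#' @param lines Which line labels to treat as populations (default the three
#'   purebred lines present in the panel).
#' @param pairwise If `TRUE`, return one row per line pair instead of the
#'   joint multi-population estimate.
#' @return A tibble: either one row (`fst`, `n_loci`) or one row per pair
#'   (`line1`, `line2`, `fst`, `n_loci`).
#' @export
fst_wc <- function(panel, lines = NULL, pairwise = FALSE) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(lines)) lines <- intersect(c("A", "B", "C"), unique(panel$line))
  if (length(lines) < 2) rlang::abort("need at least two populations")
  if (pairwise) {
    pairs <- utils::combn(lines, 2)
    return(purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      r <- fst_wc(panel, lines = pairs[, k], pairwise = FALSE)
      tibble::tibble(line1 = pairs[1, k], line2 = pairs[2, k],
                     fst = r$fst, n_loci = r$n_loci)
    }))
  }
  genos <- lapply(lines, function(ln) line_geno(panel, ln))
  sizes <- vapply(genos, nrow, integer(1))
  if (any(sizes < 2)) rlang::abort("each population needs at least 2 animals")
  r <- length(lines)
  n_i <- sizes  # complete genotypes: same n at every locus
  p_i <- do.call(rbind, lapply(genos, function(g) colMeans(g) / 2))     # r x m
  h_i <- do.call(rbind, lapply(genos, function(g) colMeans(g == 1L)))   # r x m
  n_bar <- mean(n_i)
  n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
  p_bar <- colSums(n_i * p_i) / (r * n_bar)
  s2 <- colSums(n_i * (p_i - rep(p_bar, each = r))^2) / ((r - 1) * n_bar)
  h_bar <- colSums(n_i * h_i) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  denom <- a + b + cc
  ok <- denom != 0
  if (!any(ok)) rlang::abort("F_ST undefined: all loci monomorphic across populations")
  tibble::tibble(fst = mean(a[ok] / denom[ok]), n_loci = sum(ok))
}

#' Correlation of estimates between methods
#'
#' Pearson correlations of the line-B proportions between every pair of
#' methods, over their common animals.
#'
#' @param est_list List of estimate tibbles (or one stacked tibble with
#'   several methods).
#' @param line `"B"` (default) or `"C"`.
#' @return A symmetric correlation matrix with unit diagonal, methods as
#'   dimnames.
#' @export
method_correlation_table <- function(est_list, line = c("B", "C")) {
  line <- match.arg(line)
  col <- paste0("b_", line)
  est <- if (is.data.frame(est_list)) est_list else dplyr::bind_rows(est_list)
  wide <- est |>
    dplyr::select(dplyr::all_of(c("animal", "method", col))) |>
    tidyr::pivot_wider(names_from = "method", values_from = dplyr::all_of(col)) |>
    tidyr::drop_na()
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (nrow(m) < 2) rlang::abort("need at least 2 common animals")
  stats::cor(m)
}
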