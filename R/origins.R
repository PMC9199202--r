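#' Construct a line-of-origin matrix
#'
#' Per crossbred animal, per SNP and per haplotype (paternal / maternal
#' gamete), the line of origin of the allele: `"A"`, `"B"`, `"C"`, or
#' `"U"` for unassigned (as produced by a breed-origin-of-alleles analysis
#' with incomplete assignment; the simulator's truth has no `"U"`).
#'
#' @param paternal,maternal Character matrices (animals x SNPs) with entries
#'   in `c("A","B","C","U")`; rownames are animal ids.
#' @return An object of class `origin_matrix`.
#' @export
origin_matrix <- function(paternal, maternal) {
  if (!is.matrix(paternal) || !is.matrix(maternal) ||
      !all(dim(paternal) == dim(maternal))) {
    rlang::abort("paternal and maternal must be matrices of equal dimension")
  }
  ok <- c("A", "B", "C", "U")
  if (!all(paternal %in% ok) || !all(maternal %in% ok)) {
    rlang::abort('origin labels must be "A", "B", "C" or "U"')
  }
  if (is.null(rownames(paternal))) {
    rownames(paternal) <- sprintf("animal_%d", seq_len(nrow(paternal)))
  }
  rownames(maternal) <- rownames(paternal)
  structure(list(paternal = paternal, maternal = maternal),
            class = "origin_matrix")
}

#' @export
print.origin_matrix <- function(x, ...) {
  n_u <- sum(x$paternal == "U") + sum(x$maternal == "U")
  cat(sprintf("<origin_matrix> %d animals x %d SNPs x 2 haplotypes (%d unassigned)\n",
              nrow(x$paternal), ncol(x$paternal), n_u))
  invisible(x)
}

#' @export
dim.origin_matrix <- function(x) dim(x$paternal)

subset_origins <- function(origins, animals = NULL, snps = NULL) {
  p <- origins$paternal
  m <- origins$maternal
  if (!is.null(animals)) {
    p <- p[animals, , drop = FALSE]
    m <- m[animals, , drop = FALSE]
  }
  if (!is.null(snps)) {
    p <- p[, snps, drop = FALSE]
    m <- m[, snps, drop = FALSE]
  }
  origin_matrix(p, m)
}

count_origins <- function(origins, label) {
  rowSums(origins$paternal == label) + rowSums(origins$maternal == label)
}

#' True line proportions from tracked allele origins
#'
#' Computes, per animal, the proportion of its SNP alleles that originate from
#' each dam line: `b_B = (#B alleles) / (2 * #SNPs)` and likewise for
#' `b_C`. Requires complete origins (no unassigned labels) — use
#' [boa_proportions()] for partially assigned data. For an A(BC) crossbred,
#' whose paternal gamete is entirely line A, `b_B + b_C = 0.5` exactly.
#'
#' @param origins An [origin_matrix()] with no `"U"` entries.
#' @return A tibble with columns `animal`, `method` (`"TRUE"`), `stage`
#'   (`"raw"`), `b_B`, `b_C`.
#' @export
true_proportions <- function(origins) {
  stopifnot(inherits(origins, "origin_matrix"))
  if (any(origins$paternal == "U") || any(origins$maternal == "U")) {
    rlang::abort("origins contain unassigned alleles; use boa_proportions()")
  }
  denom <- 2 * ncol(origins$paternal)
  tibble::tibble(
    animal = rownames(origins$paternal),
    method = "TRUE",
    stage = "raw",
    b_B = unname(count_origins(origins, "B") / denom),
    b_C = unname(count_origins(origins, "C") / denom)
  )
}
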