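#' Construct a marker map
#'
#' A marker map records, per SNP, its chromosome, genetic position and the two
#' allele codes, plus a genetic map length (in Morgan) per chromosome. Genetic
#' positions are in centiMorgan and must be non-decreasing within a chromosome.
#' The first allele code (`a1`) is the counted (reference) allele everywhere in
#' the package: genotypes are numbers of copies of `a1`, and all allele
#' frequencies refer to `a1`.
#'
#' @param chrom Character or integer vector of chromosome labels, one per SNP.
#' @param snp Character vector of SNP identifiers (unique).
#' @param cm Numeric vector of genetic positions in centiMorgan.
#' @param bp Integer vector of physical positions (carried through, never used
#'   by any computation). Defaults to 0.
#' @param a1,a2 Character vectors of allele codes; `a1` is the counted allele.
#' @param lengths_morgan Optional named numeric vector of per-chromosome map
#'   lengths in Morgan. When `NULL`, the length of each chromosome is taken as
#'   the largest genetic position on it (converted from centiMorgan).
#'
#' @return A tibble of class `marker_map` with columns `chrom`, `snp`, `cm`,
#'   `bp`, `a1`, `a2` and an attribute `lengths_morgan`.
#' @export
marker_map <- function(chrom, snp, cm, bp = 0L, a1 = "A", a2 = "B",
                       lengths_morgan = NULL) {
  n <- length(snp)
  map <- tibble::tibble(
    chrom = as.character(rep_len(chrom, n)),
    snp = as.character(snp),
    cm = as.numeric(cm),
    bp = as.integer(rep_len(bp, n)),
    a1 = as.character(rep_len(a1, n)),
    a2 = as.character(rep_len(a2, n))
  )
  if (anyDuplicated(map$snp) > 0) {
    rlang::abort("duplicated SNP identifiers in marker map")
  }
  if (any(map$a1 == map$a2)) {
    rlang::abort("each SNP needs two distinct allele codes")
  }
  for (ch in unique(map$chrom)) {
    pos <- map$cm[map$chrom == ch]
    if (is.unsorted(pos)) {
      rlang::abort(sprintf("positions on chromosome %s are not non-decreasing", ch))
    }
  }
  if (is.null(lengths_morgan)) {
    lengths_morgan <- vapply(split(map$cm, map$chrom), max, numeric(1)) / 100
    lengths_morgan <- lengths_morgan[unique(map$chrom)]
  } else {
    lengths_morgan <- lengths_morgan[unique(map$chrom)]
    if (anyNA(lengths_morgan)) {
      rlang::abort("lengths_morgan must name every chromosome in the map")
    }
  }
  if (any(lengths_morgan <= 0)) {
    rlang::abort("every chromosome length must be > 0")
  }
  attr(map, "lengths_morgan") <- lengths_morgan
  class(map) <- c("marker_map", class(tibble::tibble()))
  map
}

#' Per-chromosome genetic map lengths
#'
#' @param map A [marker_map()].
#' @return Named numeric vector of map lengths in Morgan.
#' @export
chrom_lengths <- function(map) {
  stopifnot(inherits(map, "marker_map"))
  attr(map, "lengths_morgan")
}

subset_map <- function(map, keep) {
  lengths <- attr(map, "lengths_morgan")
  out <- tibble::as_tibble(map)[keep, , drop = FALSE]
  attr(out, "lengths_morgan") <- lengths[unique(out$chrom)]
  class(out) <- c("marker_map", class(tibble::tibble()))
  out
}
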