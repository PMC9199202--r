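#' Construct a genotype panel
#'
#' The universal estimator input: an animals-by-SNPs matrix of allele counts
#' (copies of the counted allele, values 0/1/2), a line label per animal, and
#' the marker map. Lines are `"A"` (sire line), `"B"` and `"C"` (dam lines) and
#' `"ABC"` for the 3-way crossbreds.
#'
#' @param geno Integer matrix, animals in rows (rownames are animal ids), SNPs
#'   in columns; values must be 0, 1 or 2 (no missing values).
#' @param line Character vector of line labels, one per animal, each one of
#'   `"A"`, `"B"`, `"C"`, `"ABC"`.
#' @param map A [marker_map()] whose SNP count matches `ncol(geno)`.
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(geno, line, map) {
  if (!is.matrix(geno)) rlang::abort("geno must be a matrix")
  storage.mode(geno) <- "integer"
  if (anyNA(geno) || any(geno < 0L | geno > 2L)) {
    rlang::abort("genotypes must be 0, 1 or 2 with no missing values")
  }
  if (!inherits(map, "marker_map")) rlang::abort("map must be a marker_map")
  if (ncol(geno) != nrow(map)) {
    rlang::abort(sprintf("geno has %d SNP columns but map describes %d SNPs",
                         ncol(geno), nrow(map)))
  }
  if (length(line) != nrow(geno)) {
    rlang::abort("one line label per animal is required")
  }
  line <- as.character(line)
  bad <- setdiff(unique(line), c("A", "B", "C", "ABC"))
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown line labels: %s", paste(bad, collapse = ", ")))
  }
  if (is.null(rownames(geno))) {
    rownames(geno) <- sprintf("animal_%d", seq_len(nrow(geno)))
  }
  colnames(geno) <- map$snp
  structure(list(geno = geno, line = stats::setNames(line, rownames(geno)),
                 map = map),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  tab <- table(factor(x$line, levels = c("A", "B", "C", "ABC")))
  cat(sprintf("<genotype_panel> %d animals x %d SNPs (%d chromosomes)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))))
  cat("  animals per line:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$geno)

#' Animal identifiers of a panel
#' @param panel A [genotype_panel()].
#' @return Character vector of animal ids.
#' @export
animal_ids <- function(panel) rownames(panel$geno)

#' Subset a genotype panel
#'
#' @param panel A [genotype_panel()].
#' @param animals Animal ids or logical/integer row index (default: all).
#' @param snps SNP ids or logical/integer column index (default: all).
#' @return A [genotype_panel()] restricted to the selection; SNP subsetting
#'   subsets the marker map accordingly.
#' @export
subset_panel <- function(panel, animals = NULL, snps = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  geno <- panel$geno
  line <- panel$line
  map <- panel$map
  if (!is.null(animals)) {
    geno <- geno[animals, , drop = FALSE]
    line <- line[rownames(geno)]
  }
  if (!is.null(snps)) {
    if (is.character(snps)) snps <- match(snps, map$snp)
    geno <- geno[, snps, drop = FALSE]
    map <- subset_map(map, snps)
  }
  genotype_panel(geno, line, map)
}

#' Animals of one line as a genotype matrix
#' @keywords internal
line_geno <- function(panel, line) {
  panel$geno[panel$line == line, , drop = FALSE]
}

#' Filter SNPs on joint minor allele frequency
#'
#' Retains SNPs whose minor allele frequency, computed over all animals in the
#' panel jointly (purebreds and crossbreds together), is strictly greater than
#' `threshold`. The marker map is subset accordingly. The operation is
#' idempotent.
#'
#' @param panel A [genotype_panel()].
#' @param threshold MAF threshold in `[0, 0.5)`; default 0.1.
#' @return The filtered [genotype_panel()], with an attribute `maf_removed`
#'   giving the number of SNPs dropped.
#' @export
maf_filter <- function(panel, threshold = 0.1) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (threshold < 0 || threshold >= 0.5) {
    rlang::abort("threshold must be in [0, 0.5)")
  }
  p <- colMeans(panel$geno) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf > threshold
  out <- subset_panel(panel, snps = which(keep))
  attr(out, "maf_removed") <- sum(!keep)
  out
}
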