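#' Read a PED/MAP genotype panel
#'
#' Reads whitespace-delimited PED/MAP text. The PED file has the usual six
#' leading columns (family, animal id, sire, dam, sex, phenotype — only the
#' animal id is used) followed by two allele tokens per SNP. The MAP file has
#' either the plain four columns (chromosome, SNP id, genetic position in
#' centiMorgan, physical position) or the six-column dialect written by
#' [write_pedmap()] with the two allele codes appended; in the six-column
#' dialect the first listed allele is the counted allele. With a four-column
#' MAP the counted allele of each SNP is the first allele token encountered in
#' the PED file for that SNP.
#'
#' Line labels come from a separate two-column table (`animal_id`, `line`)
#' because PED family fields are unreliable in practice.
#'
#' Missing genotypes (`0` allele codes) are rejected by default; the paper's
#' data are complete. `missing = "impute"` replaces a missing genotype by the
#' rounded within-line mean allele count for that SNP and reports the number of
#' imputed entries via the `n_imputed` attribute.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @param line_table A data frame with columns `animal_id` and `line`, or the
#'   path to a whitespace/tab-delimited file with those two columns.
#' @param missing `"error"` (default) or `"impute"`.
#' @return A [genotype_panel()]; animal order is the PED row order.
#' @export
read_pedmap <- function(ped_path, map_path, line_table, missing = c("error", "impute")) {
  missing <- match.arg(missing)
  if (!file.exists(ped_path)) rlang::abort(sprintf("PED file not found: %s", ped_path))
  if (!file.exists(map_path)) rlang::abort(sprintf("MAP file not found: %s", map_path))

  map_raw <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  if (!ncol(map_raw) %in% c(4L, 6L)) {
    rlang::abort(sprintf("MAP file must have 4 or 6 columns, found %d", ncol(map_raw)))
  }
  n_snp <- nrow(map_raw)
  has_alleles <- ncol(map_raw) == 6L

  lines_raw <- readLines(ped_path)
  lines_raw <- lines_raw[nzchar(trimws(lines_raw))]
  toks <- strsplit(trimws(lines_raw), "[ \t]+")
  n_animal <- length(toks)
  expected <- 6L + 2L * n_snp
  for (i in seq_len(n_animal)) {
    if (length(toks[[i]]) != expected) {
      rlang::abort(sprintf(
        "malformed PED row at line %d: expected %d fields, found %d",
        i, expected, length(toks[[i]])))
    }
  }
  ids <- vapply(toks, `[[`, character(1), 2L)
  # allele tokens as an (2*n_snp) x n_animal matrix
  am <- vapply(toks, function(x) x[-(1:6)], character(2L * n_snp))
  if (n_animal == 1L) am <- matrix(am, ncol = 1L)
  al1 <- am[seq(1L, 2L * n_snp, by = 2L), , drop = FALSE]
  al2 <- am[seq(2L, 2L * n_snp, by = 2L), , drop = FALSE]

  if (has_alleles) {
    a1 <- map_raw[[5]]
    a2 <- map_raw[[6]]
  } else {
    # counted allele = first allele token seen in the PED per SNP
    a1 <- character(n_snp)
    a2 <- character(n_snp)
    for (m in seq_len(n_snp)) {
      seen <- unique(c(rbind(al1[m, ], al2[m, ])))
      seen <- seen[seen != "0"]
      if (length(seen) < 1L || length(seen) > 2L) {
        rlang::abort(sprintf("SNP %s has %d distinct allele codes",
                             map_raw[[2]][m], length(seen)))
      }
      a1[m] <- seen[1]
      a2[m] <- if (length(seen) == 2L) seen[2] else paste0(seen[1], "_alt")
    }
  }

  is_missing <- al1 == "0" | al2 == "0"
  if (missing == "error" && any(is_missing)) {
    w <- which(is_missing, arr.ind = TRUE)[1, ]
    rlang::abort(sprintf(
      "missing genotype at PED line %d, SNP %s (use missing = \"impute\" to mean-impute)",
      w[2], map_raw[[2]][w[1]]))
  }
  valid <- (al1 == a1 | al1 == a2 | al1 == "0") &
           (al2 == a1 | al2 == a2 | al2 == "0")
  if (!all(valid)) {
    w <- which(!valid, arr.ind = TRUE)[1, ]
    rlang::abort(sprintf(
      "allele symbol not in map at PED line %d, SNP %s: saw \"%s %s\", expected %s/%s",
      w[2], map_raw[[2]][w[1]], al1[w[1], w[2]], al2[w[1], w[2]], a1[w[1]], a2[w[1]]))
  }
  geno <- t((al1 == a1) + (al2 == a1))  # animals x SNPs
  rownames(geno) <- ids

  lt <- if (is.character(line_table) && length(line_table) == 1L) {
    utils::read.table(line_table, header = TRUE, colClasses = "character")
  } else {
    as.data.frame(line_table)
  }
  if (!all(c("animal_id", "line") %in% names(lt))) {
    rlang::abort("line table needs columns animal_id and line")
  }
  line <- lt$line[match(ids, lt$animal_id)]
  if (anyNA(line)) {
    rlang::abort(sprintf("no line label for animals: %s",
                         paste(utils::head(ids[is.na(line)], 5), collapse = ", ")))
  }

  n_imputed <- 0L
  if (missing == "impute" && any(is_missing)) {
    miss_t <- t(is_missing)  # animals x SNPs
    geno[miss_t] <- NA_integer_
    for (ln in unique(line)) {
      rows <- which(line == ln)
      sub <- geno[rows, , drop = FALSE]
      mu <- colMeans(sub, na.rm = TRUE)
      mu[is.nan(mu)] <- 1  # whole line missing at a SNP: fall back to heterozygote
      idx <- which(is.na(sub), arr.ind = TRUE)
      if (nrow(idx) > 0) {
        sub[idx] <- as.integer(round(mu[idx[, 2]]))
        geno[rows, ] <- sub
        n_imputed <- n_imputed + nrow(idx)
      }
    }
  }

  map <- marker_map(chrom = map_raw[[1]], snp = map_raw[[2]],
                    cm = as.numeric(map_raw[[3]]),
                    bp = as.integer(as.numeric(map_raw[[4]])),
                    a1 = a1, a2 = a2)
  panel <- genotype_panel(geno, line, map)
  attr(panel, "n_imputed") <- n_imputed
  panel
}

#' Write a genotype panel as PED/MAP
#'
#' Emits whitespace-delimited PED/MAP files parseable by [read_pedmap()] with a
#' bit-exact genotype round trip. The MAP is written in the six-column dialect
#' (chromosome, SNP, centiMorgan, physical position, counted allele, other
#' allele). The PED family column holds the line label; sire/dam/sex/phenotype
#' are written as `0 0 0 -9`.
#'
#' @param panel A [genotype_panel()].
#' @param out_prefix Output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return Invisibly, the two file paths.
#' @export
write_pedmap <- function(panel, out_prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  map <- panel$map
  map_path <- paste0(out_prefix, ".map")
  ped_path <- paste0(out_prefix, ".ped")
  utils::write.table(
    data.frame(map$chrom, map$snp, map$cm, map$bp, map$a1, map$a2),
    map_path, quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)

  g <- panel$geno
  n <- nrow(g)
  m <- ncol(g)
  if (n == 0L) {
    writeLines(character(0), ped_path)
    return(invisible(c(ped = ped_path, map = map_path)))
  }
  # allele pair per genotype: 2 -> a1 a1, 1 -> a1 a2, 0 -> a2 a2
  first <- matrix(map$a2, n, m, byrow = TRUE)
  second <- matrix(map$a2, n, m, byrow = TRUE)
  a1m <- matrix(map$a1, n, m, byrow = TRUE)
  first[g >= 1L] <- a1m[g >= 1L]
  second[g == 2L] <- a1m[g == 2L]
  inter <- matrix("", n, 2L * m)
  inter[, seq(1L, 2L * m, by = 2L)] <- first
  inter[, seq(2L, 2L * m, by = 2L)] <- second
  lead <- cbind(panel$line, rownames(g), "0", "0", "0", "-9")
  con <- file(ped_path, "w")
  on.exit(close(con))
  writeLines(apply(cbind(lead, inter), 1L, paste, collapse = " "), con)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read / write a line table
#'
#' @param path File path.
#' @return `read_line_table()` returns a tibble with columns `animal_id`,
#'   `line`.
#' @export
read_line_table <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, colClasses = "character"))
}

#' @rdname read_line_table
#' @param panel A [genotype_panel()] (for `write_line_table()`).
#' @export
write_line_table <- function(panel, path) {
  utils::write.table(
    data.frame(animal_id = animal_ids(panel), line = unname(panel$line)),
    path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read / write a crossbred pedigree table
#'
#' The pedigree links each A(BC) crossbred to its line-A sire, F1 dam, line-B
#' maternal grandsire (`mgs`) and line-C maternal granddam (`mgd`). `NA` in
#' `mgs`/`mgd` marks a grandparent without genotypes.
#'
#' @param path File path.
#' @return A tibble with columns `id`, `sire`, `dam`, `mgs`, `mgd`.
#' @export
read_pedigree <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, colClasses = "character",
                                      na.strings = "NA"))
}

#' @rdname read_pedigree
#' @param pedigree Pedigree tibble (for `write_pedigree()`).
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.table(as.data.frame(pedigree), path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' Read / write an origin matrix as TSV
#'
#' One row per animal and haplotype; the per-SNP origin labels are stored as a
#' single string over the alphabet `A`, `B`, `C`, `U`.
#'
#' @param path File path.
#' @return `read_origins()` returns an [origin_matrix()].
#' @export
read_origins <- function(path) {
  d <- utils::read.table(path, header = TRUE, colClasses = "character")
  pat <- d[d$hap == "paternal", ]
  mat <- d[d$hap == "maternal", ]
  mat <- mat[match(pat$animal, mat$animal), ]
  to_mat <- function(s) {
    m <- do.call(rbind, strsplit(s, ""))
    m
  }
  p <- to_mat(pat$origins)
  m <- to_mat(mat$origins)
  rownames(p) <- pat$animal
  origin_matrix(p, m)
}

#' @rdname read_origins
#' @param origins An [origin_matrix()] (for `write_origins()`).
#' @export
write_origins <- function(origins, path) {
  d <- data.frame(
    animal = rep(rownames(origins$paternal), 2L),
    hap = rep(c("paternal", "maternal"), each = nrow(origins$paternal)),
    origins = c(apply(origins$paternal, 1L, paste, collapse = ""),
                apply(origins$maternal, 1L, paste, collapse = ""))
  )
  utils::write.table(d, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read / write tabular results (estimates, frequencies, reports)
#'
#' Thin TSV wrappers used by the pipeline and command-line interface.
#'
#' @param x A data frame.
#' @param path File path.
#' @return `read_result_tsv()` returns a tibble.
#' @export
write_result_tsv <- function(x, path) {
  readr::write_tsv(as.data.frame(x), path)
  invisible(path)
}

#' @rdname write_result_tsv
#' @export
read_result_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
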