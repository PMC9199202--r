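#' Run every dam-line estimator on one panel
#'
#' Convenience stage used by the study pipelines: computes purebred counting
#' frequencies and regression frequencies, LD-prunes the panel for the
#' admixture estimator, and runs LR, supervised admixture, both
#' grandparent-relationship estimators and (when origins are available)
#' BOA counting. Estimates are returned raw; apply
#' [postprocess_estimates()] afterwards.
#'
#' @param panel A MAF-filtered [genotype_panel()] with purebreds and
#'   crossbreds.
#' @param pedigree Crossbred pedigree tibble (`id`, `mgs`, `mgd`).
#' @param origins Optional [origin_matrix()] for the BOA estimator.
#' @param r2_threshold LD-pruning threshold for the admixture panel
#'   (default 0.5); `NULL` skips pruning.
#' @param window,step Pruning window and step in SNPs.
#' @return A list with `raw` (stacked estimates tibble), `excluded`
#'   (crossbreds without both grandparents genotyped), `n_snp_full` and
#'   `n_snp_pruned`.
#' @export
estimate_all <- function(panel, pedigree, origins = NULL, r2_threshold = 0.5,
                         window = 50, step = 10) {
  pf <- purebred_line_freqs(panel)
  rf <- regression_line_freqs(panel)
  if (!is.null(r2_threshold)) {
    kept <- indep_pairwise(panel, window = window, step = step,
                           threshold = r2_threshold)
    pruned <- subset_panel(panel, snps = kept)
  } else {
    pruned <- panel
  }
  pieces <- list(
    lr_estimate(panel, pf),
    admixture_supervised_em(pruned, purebred_line_freqs(pruned)))
  rel <- rel_gp_estimate(panel, pedigree, rf)
  pieces <- c(pieces, list(rel$estimates))
  if (!is.null(origins)) pieces <- c(list(boa_proportions(origins)), pieces)
  list(raw = dplyr::bind_rows(pieces),
       excluded = rel$excluded,
       n_snp_full = ncol(panel$geno),
       n_snp_pruned = ncol(pruned$geno))
}

#' Reproduce the simulation study end-to-end
#'
#' For each scenario preset and replicate: simulate the three-way cross,
#' MAF-filter, estimate line frequencies, run all estimators (the admixture
#' estimator on the LD-pruned panel), post-process per method, and evaluate
#' the post-processed estimates against the tracked truth and against the
#' BOA-derived gold standard. By default every method is evaluated on the
#' crossbreds that have both maternal grandparents genotyped, the common
#' subset the relationship estimators require. Deterministic given `seed`.
#'
#' @param presets Scenario presets to run (subset of `"close"`, `"distant"`,
#'   `"unrelated"`).
#' @param replicates Replicates per scenario.
#' @param seed Master seed; each scenario/replicate draws its own sub-seed
#'   from it.
#' @param r2_threshold LD-pruning threshold for the admixture panel.
#' @param config_args Named list of overrides passed to [scenario_config()]
#'   (e.g. smaller population sizes for quick runs).
#' @param postprocess Apply [postprocess_estimates()] before evaluation
#'   (default `TRUE`); `FALSE` evaluates the raw estimates.
#' @param restrict_to_grandparents Evaluate all methods on the crossbreds
#'   with both maternal grandparents genotyped (default `TRUE`).
#' @param out_dir Optional directory: the result tables are written there as
#'   TSV files.
#' @return A list of class `sim_study`: `evaluations` (per replicate),
#'   `summary` (metric means across replicates), `correlations` (mean
#'   between-method correlations of line-B estimates, long format), `fst`
#'   (mean pairwise line F_ST per scenario), `panel_info`, and `seed`.
#' @export
run_simulation_study <- function(presets = c("close", "distant", "unrelated"),
                                 replicates = 1, seed = 1, r2_threshold = 0.5,
                                 config_args = list(), postprocess = TRUE,
                                 restrict_to_grandparents = TRUE,
                                 out_dir = NULL) {
  presets <- match.arg(presets, several.ok = TRUE)
  set.seed(seed)
  sub_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 length(presets) * replicates),
                      nrow = length(presets))
  evaluations <- list()
  correlations <- list()
  fst_rows <- list()
  info_rows <- list()
  for (si in seq_along(presets)) {
    for (rep_i in seq_len(replicates)) {
      cfg <- do.call(scenario_config,
                     c(list(preset = presets[si], seed = sub_seeds[si, rep_i]),
                       config_args))
      sim <- simulate_scenario(cfg)
      res <- estimate_all(sim$panel, sim$pedigree, sim$origins,
                          r2_threshold = r2_threshold)
      est <- res$raw
      truth <- sim$truth
      if (restrict_to_grandparents) {
        cohort <- setdiff(sim$pedigree$id, res$excluded)
        est <- dplyr::filter(est, .data$animal %in% cohort)
        truth <- dplyr::filter(truth, .data$animal %in% cohort)
      }
      if (postprocess) est <- postprocess_estimates(est)

      ev_true <- evaluate_estimates(est, truth)
      refs <- list(ev_true)
      if ("BOA" %in% est$method) {
        boa_ref <- dplyr::filter(est, .data$method == "BOA")
        others <- dplyr::filter(est, .data$method != "BOA")
        refs <- c(refs, list(evaluate_estimates(others, boa_ref)))
      }
      ev <- dplyr::bind_rows(refs)
      ev$scenario <- presets[si]
      ev$replicate <- rep_i
      evaluations[[length(evaluations) + 1L]] <- ev

      cm <- method_correlation_table(est)
      correlations[[length(correlations) + 1L]] <-
        tibble::as_tibble(as.data.frame.table(cm, stringsAsFactors = FALSE)) |>
        stats::setNames(c("method1", "method2", "correlation")) |>
        dplyr::mutate(scenario = presets[si], replicate = rep_i)

      pw <- fst_wc(sim$panel, pairwise = TRUE)
      fst_rows[[length(fst_rows) + 1L]] <- tibble::tibble(
        scenario = presets[si], replicate = rep_i, fst = mean(pw$fst))
      info_rows[[length(info_rows) + 1L]] <- tibble::tibble(
        scenario = presets[si], replicate = rep_i,
        n_snp_full = res$n_snp_full, n_snp_pruned = res$n_snp_pruned,
        n_crossbred = nrow(sim$pedigree),
        n_evaluated = dplyr::n_distinct(truth$animal))
    }
  }
  evaluations <- dplyr::bind_rows(evaluations)
  summary <- evaluations |>
    dplyr::group_by(.data$scenario, .data$reference, .data$method) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(c("accuracy", "slope", "max_error", "rmse")), mean),
      n = mean(.data$n), .groups = "drop")
  correlations <- dplyr::bind_rows(correlations) |>
    dplyr::group_by(.data$scenario, .data$method1, .data$method2) |>
    dplyr::summarise(correlation = mean(.data$correlation), .groups = "drop")
  out <- structure(list(
    evaluations = evaluations, summary = summary, correlations = correlations,
    fst = dplyr::bind_rows(fst_rows), panel_info = dplyr::bind_rows(info_rows),
    seed = seed), class = "sim_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_result_tsv(out$evaluations, file.path(out_dir, "evaluations.tsv"))
    write_result_tsv(out$summary, file.path(out_dir, "summary.tsv"))
    write_result_tsv(out$correlations, file.path(out_dir, "correlations.tsv"))
    write_result_tsv(out$fst, file.path(out_dir, "fst.tsv"))
    write_result_tsv(out$panel_info, file.path(out_dir, "panel_info.tsv"))
  }
  out
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("<sim_study> seed %d\n", x$seed))
  print(as.data.frame(x$summary), digits = 3)
  invisible(x)
}

#' Run the estimation pipeline on genotype files
#'
#' The file-based counterpart of the simulation study: reads a PED/MAP panel,
#' a line table and a crossbred pedigree, applies the joint MAF filter, runs
#' all estimators and the post-processing, and — when a per-allele
#' line-of-origin table is supplied — evaluates every method against the
#' BOA-derived gold standard. Without origins only the between-method
#' correlation table is produced.
#'
#' @param ped_path,map_path,line_table_path,pedigree_path Input files (see
#'   [read_pedmap()], [read_pedigree()]).
#' @param origins_path Optional origins TSV ([write_origins()] format) on the
#'   panel's pre-filter SNP set.
#' @param maf Joint MAF threshold, default 0.1.
#' @param r2_threshold LD-pruning threshold for the admixture panel.
#' @param postprocess Apply [postprocess_estimates()] (default `TRUE`).
#' @param restrict_to_grandparents Restrict all methods to crossbreds with
#'   both maternal grandparents genotyped (default `TRUE`).
#' @param out_dir Optional output directory for TSV results.
#' @return A list: `estimates`, `evaluation` (vs BOA; `NULL` without
#'   origins), `correlations`, `excluded`, `panel`.
#' @export
run_real_data <- function(ped_path, map_path, line_table_path, pedigree_path,
                          origins_path = NULL, maf = 0.1, r2_threshold = 0.5,
                          postprocess = TRUE, restrict_to_grandparents = TRUE,
                          out_dir = NULL) {
  panel <- read_pedmap(ped_path, map_path, line_table_path)
  pedigree <- read_pedigree(pedigree_path)
  missing_ids <- setdiff(pedigree$id, animal_ids(panel))
  if (length(missing_ids) > 0) {
    rlang::abort(sprintf("pedigree crossbreds absent from panel: %s",
                         paste(utils::head(missing_ids, 5), collapse = ", ")))
  }
  pre_snps <- panel$map$snp
  panel <- maf_filter(panel, maf)
  origins <- NULL
  if (!is.null(origins_path)) {
    origins <- read_origins(origins_path)
    if (ncol(origins$paternal) == length(pre_snps)) {
      origins <- subset_origins(origins, snps = match(panel$map$snp, pre_snps))
    } else if (ncol(origins$paternal) != ncol(panel$geno)) {
      rlang::abort("origins table does not match the panel's SNP set")
    }
  }
  res <- estimate_all(panel, pedigree, origins, r2_threshold = r2_threshold)
  est <- res$raw
  if (restrict_to_grandparents) {
    cohort <- setdiff(pedigree$id, res$excluded)
    est <- dplyr::filter(est, .data$animal %in% cohort)
  }
  if (length(res$excluded) > 0) {
    rlang::inform(sprintf(
      "%d crossbred(s) without both maternal grandparents genotyped", length(res$excluded)))
  }
  if (postprocess) est <- postprocess_estimates(est)
  evaluation <- NULL
  if (!is.null(origins)) {
    boa_ref <- dplyr::filter(est, .data$method == "BOA")
    others <- dplyr::filter(est, .data$method != "BOA")
    evaluation <- evaluate_estimates(others, boa_ref)
  }
  correlations <- method_correlation_table(est)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_result_tsv(est, file.path(out_dir, "estimates.tsv"))
    if (!is.null(evaluation)) {
      write_result_tsv(evaluation, file.path(out_dir, "evaluation.tsv"))
    }
    cm <- as.data.frame(correlations)
    cm <- cbind(method = rownames(cm), cm)
    write_result_tsv(cm, file.path(out_dir, "correlations.tsv"))
  }
  list(estimates = est, evaluation = evaluation, correlations = correlations,
       excluded = res$excluded, panel = panel)
}
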