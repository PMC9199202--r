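#' Constraint-enforcing post-processing of raw dam-line estimates
#'
#' Adjusts a cohort of raw estimates so they satisfy what is known about an
#' A(BC) cross: dam-line proportions lie in `[0, 0.5]`, average 0.25 across
#' the cohort, and sum to 0.5 within every animal. The steps are applied once,
#' in order, separately per method:
#'
#' 1. clip `b_B` and `b_C` into `[0, 0.5]`;
#' 2. add `0.25 - mean(b_B)` to every animal's `b_B`, and independently
#'    `0.25 - mean(b_C)` to every `b_C`;
#' 3. clip into `[0, 0.5]` again;
#' 4. per animal, rescale `(b_B, b_C)` by `0.5 / (b_B + b_C)`.
#'
#' After step 4 every evaluation metric computed on line B equals the metric
#' on line C. An animal whose proportions sum to zero at step 4 is set to the
#' expected values (0.25, 0.25) and counted in the `n_degenerate` attribute.
#' The procedure is not idempotent in general (the rescaling can move the
#' cohort means off 0.25); only the stated output constraints are guaranteed.
#'
#' @param est Tibble of raw estimates with columns `animal`, `method`,
#'   `b_B`, `b_C` (several methods may be stacked; each is processed as its
#'   own cohort).
#' @return The tibble with adjusted `b_B`, `b_C` and `stage` set to
#'   `"postprocessed"`.
#' @export
postprocess_estimates <- function(est) {
  stopifnot(all(c("animal", "method", "b_B", "b_C") %in% names(est)))
  n_degenerate <- 0L
  out <- est |>
    dplyr::group_by(.data$method) |>
    dplyr::group_modify(function(d, key) {
      b_B <- pmin(pmax(d$b_B, 0), 0.5)
      b_C <- pmin(pmax(d$b_C, 0), 0.5)
      b_B <- b_B + (0.25 - mean(b_B))
      b_C <- b_C + (0.25 - mean(b_C))
      b_B <- pmin(pmax(b_B, 0), 0.5)
      b_C <- pmin(pmax(b_C, 0), 0.5)
      s <- b_B + b_C
      zero <- s == 0
      n_degenerate <<- n_degenerate + sum(zero)
      b_B[zero] <- 0.25
      b_C[zero] <- 0.25
      s[zero] <- 0.5
      d$b_B <- b_B * 0.5 / s
      d$b_C <- b_C * 0.5 / s
      d
    }) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(names(est)))
  out$stage <- "postprocessed"
  if (n_degenerate > 0) {
    rlang::inform(sprintf(
      "%d animal(s) with b_B + b_C = 0 set to the expected (0.25, 0.25)",
      n_degenerate))
  }
  attr(out, "n_degenerate") <- n_degenerate
  out
}
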