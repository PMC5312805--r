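# Model-vs-behavior agreement: per-cell residuals, Pearson correlations over
# stimulus subsets, and the Fisher r-to-z comparison of two correlations.

align_cells <- function(model, behavior) {
  m <- as_tibble(model)[, c("stimulus_auditory", "stimulus_visual",
                            "response", "proportion")]
  b <- as_tibble(behavior)[, c("stimulus_auditory", "stimulus_visual",
                               "response", "proportion")]
  mism <- setdiff(unique(b$response), unique(m$response))
  if (length(mism)) {
    abort(paste0("response labels missing from the model matrix: ",
                 paste(mism, collapse = ", ")),
          class = "cims_alignment_error")
  }
  j <- dplyr::inner_join(dplyr::rename(m, model = "proportion"),
                         dplyr::rename(b, behavior = "proportion"),
                         by = c("stimulus_auditory", "stimulus_visual",
                                "response"))
  dplyr::filter(j, !is.na(.data$model), !is.na(.data$behavior))
}

apply_subset <- function(cells, subset) {
  switch(subset,
    all = cells,
    congruent = dplyr::filter(cells,
      .data$stimulus_auditory == .data$stimulus_visual),
    incongruent = dplyr::filter(cells,
      .data$stimulus_auditory != .data$stimulus_visual),
    abort(paste0("unknown subset '", subset,
                 "' (use all, congruent or incongruent)"),
          class = "cims_validation_error"))
}

#' Correlate model and behavioral confusion matrices
#'
#' Pearson correlation over the flattened proportion cells of the selected
#' stimuli (cells missing from either matrix are dropped).
#'
#' @param model,behavior `cims_confusion` matrices with aligned label sets.
#' @param subset `"all"`, `"congruent"` or `"incongruent"`.
#' @return A one-row tibble with `subset`, `r` and `n_cells`.
#' @export
correlate_confusions <- function(model, behavior,
                                 subset = c("all", "congruent",
                                            "incongruent")) {
  subset <- match.arg(subset)
  cells <- apply_subset(align_cells(model, behavior), subset)
  if (nrow(cells) < 3L) {
    abort("fewer than 3 overlapping cells; correlation is not meaningful",
          class = "cims_alignment_error")
  }
  if (stats::sd(cells$model) == 0 || stats::sd(cells$behavior) == 0) {
    abort("zero variance in one of the proportion vectors; correlation undefined",
          class = "cims_degenerate_error")
  }
  tibble(subset = subset, r = cor(cells$model, cells$behavior),
         n_cells = nrow(cells))
}

#' Compare two correlations with the Fisher r-to-z transformation
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided p-value from the standard normal.
#'
#' @param r1,r2 The two Pearson correlations, strictly inside (-1, 1).
#' @param n1,n2 The number of observations behind each correlation (`> 3`).
#' @return A one-row tibble with `z` and `p_value`.
#' @examples
#' fisher_r_to_z(0.95, 18, 0.21, 18)
#' @export
fisher_r_to_z <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    abort("correlations must lie strictly inside (-1, 1)",
          class = "cims_validation_error")
  }
  if (n1 <= 3 || n2 <= 3) {
    abort("each correlation needs more than 3 observations",
          class = "cims_validation_error")
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Full model-versus-behavior comparison report
#'
#' Assembles per-cell residuals (model minus behavior), the overall Pearson
#' correlation, per-subset correlations, and — when exactly two subsets are
#' requested — the Fisher r-to-z comparison between them.
#'
#' @inheritParams correlate_confusions
#' @param subsets Character vector of subsets to correlate separately.
#' @return A `cims_comparison`: `residuals` tibble, `r_overall`,
#'   `r_by_subset` tibble, and `fisher` (one-row tibble or `NULL`).
#'   [tidy()] returns the residuals, [glance()] a one-row summary.
#' @export
compare_confusions <- function(model, behavior,
                               subsets = c("congruent", "incongruent")) {
  cells <- align_cells(model, behavior)
  residuals <- dplyr::mutate(cells, residual = .data$model - .data$behavior)
  overall <- correlate_confusions(model, behavior, "all")
  by_subset <- dplyr::bind_rows(
    purrr::map(subsets, function(s) correlate_confusions(model, behavior, s)))
  fisher <- NULL
  if (length(subsets) == 2L) {
    ok <- abs(by_subset$r) < 1
    if (all(ok)) {
      fisher <- fisher_r_to_z(by_subset$r[1], by_subset$n_cells[1],
                              by_subset$r[2], by_subset$n_cells[2])
      fisher <- dplyr::mutate(fisher,
                              subset_1 = subsets[1], subset_2 = subsets[2],
                              .before = 1L)
    }
  }
  structure(list(residuals = residuals,
                 r_overall = overall$r,
                 n_cells_overall = overall$n_cells,
                 r_by_subset = by_subset,
                 fisher = fisher),
            class = "cims_comparison")
}

#' @export
print.cims_comparison <- function(x, ...) {
  cat(sprintf("<cims_comparison> r_overall = %.3f over %d cells\n",
              x$r_overall, x$n_cells_overall))
  print(x$r_by_subset)
  if (!is.null(x$fisher)) {
    cat(sprintf("Fisher r-to-z (%s vs %s): z = %.3f, p = %.3g\n",
                x$fisher$subset_1, x$fisher$subset_2,
                x$fisher$z, x$fisher$p_value))
  }
  invisible(x)
}

#' @rdname compare_confusions
#' @param x A `cims_comparison`.
#' @param ... Unused.
#' @method tidy cims_comparison
#' @export
tidy.cims_comparison <- function(x, ...) x$residuals

#' @rdname compare_confusions
#' @method glance cims_comparison
#' @export
glance.cims_comparison <- function(x, ...) {
  out <- tibble(r_overall = x$r_overall, n_cells = x$n_cells_overall,
                max_abs_residual = max(abs(x$residuals$residual)))
  for (i in seq_len(nrow(x$r_by_subset))) {
    out[[paste0("r_", x$r_by_subset$subset[i])]] <- x$r_by_subset$r[i]
  }
  if (!is.null(x$fisher)) {
    out$fisher_z <- x$fisher$z
    out$fisher_p <- x$fisher$p_value
  }
  out
}

#' Write a comparison report to CSV
#'
#' Residuals as tabular rows plus a key-value summary block (correlations,
#' Fisher z/p, cell counts) appended as comment lines.
#'
#' @param x A `cims_comparison`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(x, path) {
  write.csv(x$residuals, path, row.names = FALSE)
  g <- glance(x)
  lines <- paste0("# ", names(g), " = ",
                  vapply(g, function(v) format(v, digits = 10), ""))
  cat(lines, file = path, sep = "\n", append = TRUE)
  invisible(path)
}
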