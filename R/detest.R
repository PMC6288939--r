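# Per-exon differential-expression tests: the four pairwise sex/treatment
# contrasts, with group-specific variances (Welch-Satterthwaite) so that
# inference stays calibrated under variance heterogeneity between groups,
# followed by Benjamini-Hochberg FDR within each contrast family.

#' The four sex-by-treatment contrasts
#'
#' Sign convention: the estimate is `mean(group_a) - mean(group_b)`, so the
#' within-sex contrasts are control minus perturbed and the between-sex
#' contrasts female minus male.
#'
#' @return Tibble with `contrast`, `sex_a`, `treatment_a`, `sex_b`,
#'   `treatment_b`.
#' @export
sex_treatment_contrasts <- function() {
  tibble(
    contrast = c(
      "F_ctrl_vs_F_pert", "M_ctrl_vs_M_pert",
      "F_ctrl_vs_M_ctrl", "F_pert_vs_M_pert"
    ),
    sex_a = c("F", "M", "F", "F"),
    treatment_a = c("control", "control", "control", "perturbed"),
    sex_b = c("F", "M", "M", "M"),
    treatment_b = c("perturbed", "perturbed", "control", "perturbed")
  )
}

# Vectorised Welch statistics over matrices (rows = regions).
welch_rows <- function(A, B) {
  na <- ncol(A); nb <- ncol(B)
  if (na < 2L || nb < 2L) abort("Each group needs at least 2 replicates.")
  ma <- unname(rowMeans(A)); mb <- unname(rowMeans(B))
  va <- unname(apply(A, 1, var)); vb <- unname(apply(B, 1, var))
  ln_fc <- ma - mb
  se2 <- va / na + vb / nb
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  statistic <- ln_fc / sqrt(se2)
  p <- 2 * pt(-abs(statistic), df)

  zero <- se2 == 0
  degenerate <- zero & ln_fc != 0
  if (any(zero)) {
    eq <- zero & ln_fc == 0
    statistic[eq] <- 0; p[eq] <- 1
    statistic[degenerate] <- sign(ln_fc[degenerate]) * Inf
    p[degenerate] <- 0
    df[zero] <- na + nb - 2
  }
  tibble(ln_fc = ln_fc, statistic = statistic, df = df, p = p,
         degenerate = degenerate)
}

#' Welch two-sample contrast on ln-RPKM replicates
#'
#' Unequal-variance two-sample test: estimate is `mean(a) - mean(b)`, the
#' standard error uses group-specific variances, and the degrees of freedom
#' are Welch-Satterthwaite. Two constant, equal groups give `p = 1`; two
#' constant, unequal groups give `p = 0` and are flagged `degenerate`.
#'
#' @param values_a,values_b Numeric replicate vectors (each length >= 2).
#' @return One-row tibble: `ln_fc`, `statistic`, `df`, `p`, `degenerate`.
#' @export
fit_exon_contrast <- function(values_a, values_b) {
  welch_rows(matrix(values_a, nrow = 1), matrix(values_b, nrow = 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (order-preserving, capped at 1), with input
#' validation.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
adjust_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Run all four contrasts on detected regions
#'
#' For every detected region, tests the four pairwise sex/treatment
#' contrasts on ln-RPKM replicates, adjusts p-values with
#' Benjamini-Hochberg (within each contrast family by default), and flags
#' significance at the requested FDR levels plus the two-fold rule
#' (`|ln_fc| >= ln(fold_threshold)`, boundary inclusive).
#'
#' @param quant An [quantify()] result.
#' @param fdr_levels FDR thresholds to flag (default 1e-4, 0.01, 0.05).
#' @param fold_threshold Fold-change flag threshold (default 2).
#' @param pool_fdr If `TRUE`, adjust across all contrasts jointly instead of
#'   within each contrast family.
#' @return A tibble of class `exon_de`, one row per detected region per
#'   contrast: `region_id`, `contrast`, `ln_fc`, `statistic`, `df`, `p`,
#'   `p_adj`, one `sig_<level>` flag per FDR level, `twofold`,
#'   `degenerate`.
#' @export
run_all_contrasts <- function(quant, fdr_levels = c(1e-4, 0.01, 0.05),
                              fold_threshold = 2, pool_fdr = FALSE) {
  stopifnot(inherits(quant, "expr_quant"))
  if (is.unsorted(fdr_levels)) abort("`fdr_levels` must be sorted ascending.")
  mat <- detected_ln_matrix(quant)
  design <- quant$design
  specs <- sex_treatment_contrasts()

  group_cols <- function(sex, treatment) {
    which(design$sex == sex & design$treatment == treatment)
  }
  res <- purrr::pmap(specs, function(contrast, sex_a, treatment_a, sex_b, treatment_b) {
    A <- mat[, group_cols(sex_a, treatment_a), drop = FALSE]
    B <- mat[, group_cols(sex_b, treatment_b), drop = FALSE]
    welch_rows(A, B) |>
      mutate(region_id = rownames(mat), contrast = contrast, .before = 1)
  }) |>
    bind_rows()

  if (pool_fdr) {
    res$p_adj <- adjust_fdr(res$p)
  } else {
    res <- res |>
      group_by(.data$contrast) |>
      mutate(p_adj = adjust_fdr(.data$p)) |>
      ungroup()
  }
  for (lv in fdr_levels) {
    res[[paste0("sig_", format(lv, scientific = FALSE))]] <- res$p_adj < lv
  }
  res$twofold <- abs(res$ln_fc) >= log(fold_threshold)
  res <- res |>
    select(
      "region_id", "contrast", "ln_fc", "statistic", "df", "p", "p_adj",
      dplyr::starts_with("sig_"), "twofold", "degenerate"
    ) |>
    mutate(contrast = factor(.data$contrast, levels = specs$contrast)) |>
    arrange(.data$contrast, .data$region_id) |>
    mutate(contrast = as.character(.data$contrast))

  structure(
    res,
    fdr_levels = fdr_levels,
    fold_threshold = fold_threshold,
    pool_fdr = pool_fdr,
    class = c("exon_de", class(res))
  )
}

#' @rdname run_all_contrasts
#' @param x An `exon_de` tibble.
#' @param ... Unused.
#' @export
tidy.exon_de <- function(x, ...) {
  as_tibble(unclass_exon_de(x))
}

#' @rdname run_all_contrasts
#' @export
glance.exon_de <- function(x, ...) {
  lv <- attr(x, "fdr_levels")
  headline <- paste0("sig_", format(lv[which.min(abs(lv - 0.01))], scientific = FALSE))
  tb <- as_tibble(unclass_exon_de(x))
  tb |>
    summarise(
      n_regions = dplyr::n_distinct(.data$region_id),
      n_tests = n(),
      n_sig_headline = sum(.data[[headline]]),
      n_twofold_sig = sum(.data[[headline]] & .data$twofold),
      n_degenerate = sum(.data$degenerate)
    )
}

unclass_exon_de <- function(x) {
  class(x) <- setdiff(class(x), "exon_de")
  x
}

# Wide per-region view: one row per region, one column block per contrast.
exon_de_wide <- function(de) {
  tb <- as_tibble(unclass_exon_de(de))
  tb |>
    tidyr::pivot_wider(
      names_from = "contrast",
      values_from = c(
        "ln_fc", "statistic", "df", "p", "p_adj",
        dplyr::starts_with("sig_"), "twofold", "degenerate"
      ),
      names_glue = "{.value}.{contrast}"
    )
}
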