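# Plot data and ggplot2 displays for the fold-change plane and results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Fold-change plane data
#'
#' The per-exon ln-fold-change plane behind the scatter displays: for
#' `type = "within"`, male response (x) against female response (y) with
#' positive values meaning higher in control; for `type = "between"`, the
#' perturbed-condition sex difference (x) against the control-condition sex
#' difference (y) with positive values meaning higher in females.
#'
#' @param de An [run_all_contrasts()] result.
#' @param type `"within"` or `"between"`.
#' @param fdr FDR level used to colour/classify points.
#' @return Tibble: `region_id`, `ln_fc_x`, `ln_fc_y`, `label`.
#' @export
fc_plane_data <- function(de, type = c("within", "between"), fdr = 0.01) {
  type <- match.arg(type)
  if (type == "within") {
    classify_within_sex(de, fdr) |>
      select("region_id", ln_fc_x = "ln_fc_male", ln_fc_y = "ln_fc_female", "label")
  } else {
    classify_between_sex(de, fdr) |>
      select("region_id", ln_fc_x = "ln_fc_perturbed", ln_fc_y = "ln_fc_control", "label")
  }
}

#' Fold-change plane scatter
#'
#' @inheritParams fc_plane_data
#' @return A ggplot.
#' @export
plot_fc_plane <- function(de, type = c("within", "between"), fdr = 0.01) {
  type <- match.arg(type)
  dat <- fc_plane_data(de, type, fdr)
  null_lab <- if (type == "within") "null" else "unbiased"
  dat$label <- factor(dat$label, levels = c(null_lab, setdiff(sort(unique(dat$label)), null_lab)))
  axis_labs <- if (type == "within") {
    c("ln-fold change, male (control - perturbed)",
      "ln-fold change, female (control - perturbed)")
  } else {
    c("ln-fold change, perturbed (F - M)", "ln-fold change, control (F - M)")
  }
  ggplot2::ggplot(dat, ggplot2::aes(.data$ln_fc_x, .data$ln_fc_y, colour = .data$label)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "black", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70", linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70", linewidth = 0.2) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c("grey80", scales_hue(nlevels(dat$label) - 1L)),
      drop = FALSE
    ) +
    ggplot2::labs(x = axis_labs[1], y = axis_labs[2], colour = NULL) +
    ggplot2::theme_minimal()
}

scales_hue <- function(n) {
  if (n <= 0) return(character())
  grDevices::hcl(h = seq(15, 375, length.out = n + 1)[-(n + 1)], c = 100, l = 55)
}

#' @rdname run_all_contrasts
#' @param object An `exon_de` tibble.
#' @param fdr FDR level to colour significant points.
#' @export
autoplot.exon_de <- function(object, fdr = 0.01, ...) {
  tb <- tidy(object) |> mutate(sig = .data$p_adj < fdr)
  ggplot2::ggplot(tb, ggplot2::aes(.data$ln_fc, -log10(pmax(.data$p_adj, 1e-300)),
                                   colour = .data$sig)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.7) +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "ln-fold change", y = expression(-log[10] ~ "adjusted p"),
      colour = sprintf("FDR < %g", fdr)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname run_enrichment
#' @param object An `enrich_res` tibble.
#' @param top Number of top sets to show.
#' @export
autoplot.enrich_res <- function(object, top = 20, ...) {
  tb <- tidy(object) |> arrange(.data$p) |> head(top)
  tb$name <- factor(tb$name, levels = rev(tb$name))
  ggplot2::ggplot(tb, ggplot2::aes(-log10(pmax(.data$p_adj, 1e-300)), .data$name,
                                   size = .data$k, colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = expression(-log[10] ~ "adjusted p"), y = NULL,
      size = "DE genes in set", colour = "significant"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname tabulate_landscape
#' @param object A `landscape_tab` object.
#' @export
autoplot.landscape_tab <- function(object, ...) {
  tb <- object$by_label
  tb$label <- factor(tb$label, levels = rev(tb$label))
  ggplot2::ggplot(tb, ggplot2::aes(.data$n_genes, .data$label)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_col(ggplot2::aes(x = .data$n_twofold), fill = "navy") +
    ggplot2::labs(
      x = "genes (dark: two-fold)", y = NULL
    ) +
    ggplot2::theme_minimal()
}
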