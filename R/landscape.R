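# The sex-differential expression landscape: per-exon classification across
# the two between-sex comparisons (control and perturbed), the within-sex
# response classification, gene-level rollup, and the summary table.

BETWEEN_LABELS <- c(
  "unbiased", "maintained_F", "maintained_M", "gained_F", "gained_M",
  "lost_F", "lost_M", "reversed_F_to_M", "reversed_M_to_F"
)

WITHIN_LABELS <- c(
  "null", "both_up", "both_down", "opposing_MupFdown", "opposing_MdownFup",
  "male_only_up", "male_only_down", "female_only_up", "female_only_down"
)

# status of one between-sex result: F_biased / M_biased / NS
bias_status <- function(sig, ln_fc) {
  dplyr::case_when(
    sig & ln_fc > 0 ~ "F_biased",
    sig & ln_fc < 0 ~ "M_biased",
    .default = "NS"
  )
}

between_label <- function(control_status, perturbed_status) {
  key <- paste(control_status, perturbed_status, sep = "|")
  map <- c(
    "NS|NS" = "unbiased",
    "F_biased|F_biased" = "maintained_F",
    "M_biased|M_biased" = "maintained_M",
    "NS|F_biased" = "gained_F",
    "NS|M_biased" = "gained_M",
    "F_biased|NS" = "lost_F",
    "M_biased|NS" = "lost_M",
    "F_biased|M_biased" = "reversed_F_to_M",
    "M_biased|F_biased" = "reversed_M_to_F"
  )
  unname(map[key])
}

grab_contrast <- function(de, name) {
  tb <- as_tibble(unclass_exon_de(de)) |> filter(.data$contrast == name)
  if (!nrow(tb)) abort(sprintf("Contrast `%s` missing from results.", name))
  tb
}

#' Classify exons by sex bias across conditions
#'
#' Combines the two between-sex comparisons (female vs male in control, and
#' female vs male under perturbation) into the nine-cell landscape: bias
#' maintained, gained, lost, or reversed, in either direction, or unbiased.
#' A region is F-biased in a comparison when significant at `fdr` with
#' `ln_fc (F - M) > 0`, M-biased when significant with `ln_fc < 0`.
#'
#' @param de An [run_all_contrasts()] result.
#' @param fdr FDR level for significance (default 0.01).
#' @return Tibble: `region_id`, `control_status`, `perturbed_status`,
#'   `label`, `ln_fc_control`, `ln_fc_perturbed`, `twofold` (two-fold in a
#'   significant comparison).
#' @export
classify_between_sex <- function(de, fdr = 0.01) {
  ctrl <- grab_contrast(de, "F_ctrl_vs_M_ctrl")
  pert <- grab_contrast(de, "F_pert_vs_M_pert")
  joined <- inner_join(
    ctrl |> select("region_id", ctrl_fc = "ln_fc", ctrl_p = "p_adj", ctrl_2x = "twofold"),
    pert |> select("region_id", pert_fc = "ln_fc", pert_p = "p_adj", pert_2x = "twofold"),
    by = "region_id"
  )
  if (nrow(joined) != nrow(ctrl) || nrow(joined) != nrow(pert)) {
    abort("Control and perturbed between-sex results cover different regions.")
  }
  joined |>
    mutate(
      control_status = bias_status(.data$ctrl_p < fdr, .data$ctrl_fc),
      perturbed_status = bias_status(.data$pert_p < fdr, .data$pert_fc),
      label = between_label(.data$control_status, .data$perturbed_status),
      twofold = (.data$ctrl_p < fdr & .data$ctrl_2x) |
        (.data$pert_p < fdr & .data$pert_2x)
    ) |>
    select(
      "region_id", "control_status", "perturbed_status", "label",
      ln_fc_control = "ctrl_fc", ln_fc_perturbed = "pert_fc", "twofold"
    )
}

#' Classify exons by within-sex response
#'
#' Combines the two within-sex comparisons (control vs perturbed in each
#' sex) into nine response cells. "Up" means higher under perturbation;
#' since the contrast estimate is control minus perturbed, up corresponds
#' to `ln_fc < 0` (the classifier re-signs accordingly).
#'
#' @inheritParams classify_between_sex
#' @return Tibble: `region_id`, `male_status`, `female_status`, `label`
#'   (`both_up`, `both_down`, `opposing_MupFdown`, `opposing_MdownFup`,
#'   `male_only_up/down`, `female_only_up/down`, `null`),
#'   `ln_fc_male`, `ln_fc_female`, `twofold`.
#' @export
classify_within_sex <- function(de, fdr = 0.01) {
  fem <- grab_contrast(de, "F_ctrl_vs_F_pert")
  mal <- grab_contrast(de, "M_ctrl_vs_M_pert")
  status <- function(sig, ln_fc) {
    dplyr::case_when(
      sig & ln_fc < 0 ~ "up",    # higher in perturbed
      sig & ln_fc > 0 ~ "down",
      .default = "NS"
    )
  }
  joined <- inner_join(
    mal |> select("region_id", m_fc = "ln_fc", m_p = "p_adj", m_2x = "twofold"),
    fem |> select("region_id", f_fc = "ln_fc", f_p = "p_adj", f_2x = "twofold"),
    by = "region_id"
  )
  map <- c(
    "NS|NS" = "null",
    "up|up" = "both_up", "down|down" = "both_down",
    "up|down" = "opposing_MupFdown", "down|up" = "opposing_MdownFup",
    "up|NS" = "male_only_up", "down|NS" = "male_only_down",
    "NS|up" = "female_only_up", "NS|down" = "female_only_down"
  )
  joined |>
    mutate(
      male_status = status(.data$m_p < fdr, .data$m_fc),
      female_status = status(.data$f_p < fdr, .data$f_fc),
      label = unname(map[paste(.data$male_status, .data$female_status, sep = "|")]),
      twofold = (.data$m_p < fdr & .data$m_2x) | (.data$f_p < fdr & .data$f_2x)
    ) |>
    select(
      "region_id", "male_status", "female_status", "label",
      ln_fc_male = "m_fc", ln_fc_female = "f_fc", "twofold"
    )
}

#' Roll exon labels up to genes
#'
#' A gene carries every non-null label supported by at least one of its
#' exons (so multi-exon genes may belong to several categories), with
#' per-label exon counts. Genes whose exons are all null/unbiased get no
#' rows.
#'
#' @param exon_labels Tibble with `region_id`, `label`, and optionally
#'   `twofold` (from [classify_between_sex()] or [classify_within_sex()]).
#' @param region_genes Tibble mapping `region_id` to `gene_id`.
#' @param null_labels Labels that do not support a category (default
#'   `"unbiased"` and `"null"`).
#' @return Tibble: `gene_id`, `label`, `n_exons`, `twofold` (any supporting
#'   exon two-fold in a significant comparison).
#' @export
rollup_genes <- function(exon_labels, region_genes,
                         null_labels = c("unbiased", "null")) {
  if (!nrow(exon_labels)) abort("No exon labels to roll up.")
  tb <- exon_labels |>
    inner_join(region_genes |> select("region_id", "gene_id"), by = "region_id")
  if (nrow(tb) < nrow(exon_labels)) {
    abort("Some regions have no gene mapping in `region_genes`.")
  }
  if (!"twofold" %in% names(tb)) tb$twofold <- FALSE
  tb |>
    filter(!.data$label %in% null_labels) |>
    group_by(.data$gene_id, .data$label) |>
    summarise(
      n_exons = n(),
      twofold = any(.data$twofold),
      .groups = "drop"
    )
}

#' Resolve multi-category genes to a single label
#'
#' Optional alternative to multi-assignment counting: each gene keeps the
#' highest-priority label among its exon-supported categories
#' (maintained > reversed > gained > lost).
#'
#' @param assignments A [rollup_genes()] tibble (between-sex labels).
#' @return One row per gene.
#' @export
resolve_gene_categories <- function(assignments) {
  priority <- c(
    "maintained_F", "maintained_M", "reversed_F_to_M", "reversed_M_to_F",
    "gained_F", "gained_M", "lost_F", "lost_M"
  )
  assignments |>
    mutate(.rank = match(.data$label, priority)) |>
    group_by(.data$gene_id) |>
    arrange(.data$.rank, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    select(-".rank")
}

#' Tabulate the landscape
#'
#' Summarises gene-level category assignments: per-label gene counts and
#' two-fold sub-counts, percentages of tested genes and of significant
#' genes (half-up, one decimal), and the headline union counts.
#'
#' @param assignments A [rollup_genes()] tibble.
#' @param n_tested_genes Number of genes tested (the percentage base).
#' @return A list of class `landscape_tab`: `by_label` and one-row
#'   `summary`.
#' @export
tabulate_landscape <- function(assignments, n_tested_genes) {
  sig_genes <- unique(assignments$gene_id)
  n_sig <- length(sig_genes)
  if (n_tested_genes < n_sig) {
    abort(sprintf(
      "n_tested_genes (%d) is smaller than the number of significant genes (%d).",
      n_tested_genes, n_sig
    ))
  }
  n_sig_twofold <- assignments |>
    group_by(.data$gene_id) |>
    summarise(twofold = any(.data$twofold)) |>
    pull(.data$twofold) |>
    sum()

  by_label <- assignments |>
    group_by(.data$label) |>
    summarise(
      n_genes = dplyr::n_distinct(.data$gene_id),
      n_twofold = dplyr::n_distinct(.data$gene_id[.data$twofold]),
      .groups = "drop"
    ) |>
    mutate(
      pct_of_tested = pct1(.data$n_genes, n_tested_genes),
      pct_of_significant = pct1(.data$n_genes, n_sig)
    ) |>
    arrange(dplyr::desc(.data$n_genes))

  summary <- tibble(
    n_tested = as.integer(n_tested_genes),
    n_significant = n_sig,
    pct_significant_of_tested = pct1(n_sig, n_tested_genes),
    n_significant_twofold = as.integer(n_sig_twofold),
    pct_twofold_of_significant = pct1(n_sig_twofold, n_sig)
  )
  structure(
    list(by_label = by_label, summary = summary),
    class = "landscape_tab"
  )
}

#' @export
print.landscape_tab <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<landscape_tab> %d / %d genes significant (%.1f%%); %d two-fold (%.1f%% of significant)\n",
    s$n_significant, s$n_tested, s$pct_significant_of_tested,
    s$n_significant_twofold, s$pct_twofold_of_significant
  ))
  print(x$by_label)
  invisible(x)
}

#' @rdname tabulate_landscape
#' @param x A `landscape_tab` object.
#' @param ... Unused.
#' @export
tidy.landscape_tab <- function(x, ...) x$by_label

#' @rdname tabulate_landscape
#' @export
glance.landscape_tab <- function(x, ...) x$summary
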