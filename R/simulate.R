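# Synthetic data generator: negative-binomial counts with planted
# sex-by-treatment effect structure, standing in for a 2x2 head RNA-seq
# experiment (two sexes x control/perturbed, 4 replicates each).

BIAS_CATEGORIES <- c(
  "unbiased", "maintained_F", "maintained_M", "gained_F", "gained_M",
  "lost_F", "lost_M", "reversed_F_to_M", "reversed_M_to_F"
)

# Default category mix loosely mirroring the relative sizes observed in a
# perturbation that mostly *creates* sex bias: most regions unbiased, gains
# dominating maintained/lost/reversed.
default_category_props <- function() {
  c(
    unbiased = 0.600, gained_F = 0.200, gained_M = 0.120,
    maintained_F = 0.030, maintained_M = 0.010,
    lost_F = 0.012, lost_M = 0.015,
    reversed_F_to_M = 0.0065, reversed_M_to_F = 0.0065
  )
}

#' Define a simulation scenario
#'
#' Collects the knobs of the synthetic generator: design size, gene/exon
#' structure, the mix of planted sex-bias categories, effect magnitude
#' (ln-fold units), per-sex negative-binomial dispersions (unequal values
#' plant variance heterogeneity between the sexes), and sequencing
#' parameters.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene Integer range `c(min, max)`; per-gene exon count is
#'   uniform over it.
#' @param region_length Range (bp) for region lengths.
#' @param category_props Named proportions over the nine bias categories;
#'   must sum to 1.
#' @param effect_size Planted sex effect, natural-log fold units
#'   (default `log(4)`).
#' @param dispersion Named vector `c(F = , M = )` of NB dispersions (or a
#'   single value used for both sexes). `0` gives Poisson counts.
#' @param baseline_mean,baseline_sd Per-region baseline ln-RPKM distribution.
#' @param treatment_shift Average control-minus-perturbed ln-fold effect
#'   shared by both sexes (default 0; sex-specific treatment responses are
#'   implied by the planted bias category).
#' @param n_reps Replicates per sex-by-treatment group.
#' @param library_size Reads per sample.
#' @param read_length Read length (bp); base coverage = counts x read length.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_genes = 1000,
                         exons_per_gene = c(1L, 6L),
                         region_length = c(200L, 2000L),
                         category_props = default_category_props(),
                         effect_size = log(4),
                         dispersion = c(F = 0.05, M = 0.05),
                         baseline_mean = 5,
                         baseline_sd = 1,
                         treatment_shift = 0,
                         n_reps = 4L,
                         library_size = 2e7,
                         read_length = 100L) {
  assert_scalar_number(n_genes, "n_genes", positive = TRUE)
  assert_scalar_number(effect_size, "effect_size")
  assert_scalar_number(library_size, "library_size", positive = TRUE)
  assert_scalar_number(read_length, "read_length", positive = TRUE)
  if (length(dispersion) == 1L && is.null(names(dispersion))) {
    dispersion <- c(F = unname(dispersion), M = unname(dispersion))
  }
  if (!all(c("F", "M") %in% names(dispersion))) {
    abort("`dispersion` must be a single value or named c(F = , M = ).")
  }
  if (any(dispersion < 0)) abort("Dispersions must be >= 0.")
  if (!all(names(category_props) %in% BIAS_CATEGORIES)) {
    abort(sprintf(
      "Unknown category name(s): %s",
      paste(setdiff(names(category_props), BIAS_CATEGORIES), collapse = ", ")
    ))
  }
  if (abs(sum(category_props) - 1) > 1e-8) {
    abort(sprintf("Category proportions must sum to 1 (got %.6f).", sum(category_props)))
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      exons_per_gene = as.integer(exons_per_gene),
      region_length = as.integer(region_length),
      category_props = category_props,
      effect_size = effect_size,
      dispersion = dispersion[c("F", "M")],
      baseline_mean = baseline_mean,
      baseline_sd = baseline_sd,
      treatment_shift = treatment_shift,
      n_reps = as.integer(n_reps),
      library_size = library_size,
      read_length = as.integer(read_length)
    ),
    class = "sim_scenario"
  )
}

#' Build the 2x2 sample design
#'
#' @param n_reps Replicates per sex-by-treatment group.
#' @param library_size Reads per sample (recycled).
#' @return A tibble with `sample_id`, `sex` (`F`/`M`), `treatment`
#'   (`control`/`perturbed`), `replicate`, `library_size`.
#' @export
sim_design <- function(n_reps = 4L, library_size = 2e7) {
  grid <- tidyr::expand_grid(
    sex = c("F", "M"),
    treatment = c("control", "perturbed"),
    replicate = seq_len(n_reps)
  )
  grid |>
    mutate(
      sample_id = sprintf(
        "%s_%s_r%d", .data$sex,
        if_else(.data$treatment == "control", "ctrl", "pert"),
        .data$replicate
      ),
      library_size = library_size
    ) |>
    select("sample_id", "sex", "treatment", "replicate", "library_size")
}

# ln-fold sex effects (F - M) implied by each category at magnitude e.
category_effects <- function(category, e) {
  sc <- c(
    unbiased = 0, maintained_F = e, maintained_M = -e, gained_F = 0,
    gained_M = 0, lost_F = e, lost_M = -e, reversed_F_to_M = e,
    reversed_M_to_F = -e
  )
  sp <- c(
    unbiased = 0, maintained_F = e, maintained_M = -e, gained_F = e,
    gained_M = -e, lost_F = 0, lost_M = 0, reversed_F_to_M = -e,
    reversed_M_to_F = e
  )
  list(sex_control = unname(sc[category]), sex_perturbed = unname(sp[category]))
}

#' Plan per-region simulation truth
#'
#' Draws gene/exon structure and assigns each gene a bias category (shared
#' by all its regions), translating the category into ln-fold sex effects
#' in the control and perturbed conditions. Within-sex treatment effects
#' follow from the factorial identity
#' `effect_treatment_F - effect_treatment_M = effect_sex_control - effect_sex_perturbed`,
#' centred on `treatment_shift`.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Integer seed; the truth is deterministic given it.
#' @return A tibble of class `sim_truth`, one row per region: `region_id`,
#'   `gene_id`, `length`, `baseline_ln_expr`, `effect_sex_control`,
#'   `effect_sex_perturbed`, `effect_treatment_F`, `effect_treatment_M`,
#'   `dispersion_F`, `dispersion_M`, `planted_category`.
#' @export
plan_truth <- function(scenario, seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sample_range <- function(lo, hi, n) {
    if (lo == hi) rep(lo, n) else sample(seq(lo, hi), n, replace = TRUE)
  }
  withr::with_seed(seed, {
    sc <- scenario
    n_exons <- sample_range(sc$exons_per_gene[1], sc$exons_per_gene[2], sc$n_genes)
    gene_id <- sprintf("G%05d", seq_len(sc$n_genes))
    gene_cat <- sample(
      names(sc$category_props), sc$n_genes,
      replace = TRUE, prob = sc$category_props
    )
    truth <- tibble(
      gene_id = rep(gene_id, n_exons),
      exon_index = unlist(lapply(n_exons, seq_len)),
      planted_category = rep(gene_cat, n_exons)
    ) |>
      mutate(
        region_id = sprintf("%s:e%02d", .data$gene_id, .data$exon_index),
        length = sample_range(sc$region_length[1], sc$region_length[2], n()),
        baseline_ln_expr = stats::rnorm(n(), sc$baseline_mean, sc$baseline_sd)
      )
    eff <- category_effects(truth$planted_category, sc$effect_size)
    truth |>
      mutate(
        effect_sex_control = eff$sex_control,
        effect_sex_perturbed = eff$sex_perturbed,
        effect_treatment_F = sc$treatment_shift +
          (.data$effect_sex_control - .data$effect_sex_perturbed) / 2,
        effect_treatment_M = sc$treatment_shift -
          (.data$effect_sex_control - .data$effect_sex_perturbed) / 2,
        dispersion_F = sc$dispersion[["F"]],
        dispersion_M = sc$dispersion[["M"]]
      ) |>
      select(
        "region_id", "gene_id", "length", "baseline_ln_expr",
        "effect_sex_control", "effect_sex_perturbed",
        "effect_treatment_F", "effect_treatment_M",
        "dispersion_F", "dispersion_M", "planted_category"
      ) |>
      structure(class = c("sim_truth", class(tibble())))
  })
}

# Cell means on the ln-RPKM scale for the four sex x treatment groups.
truth_cell_means <- function(truth) {
  b <- truth$baseline_ln_expr
  sc <- truth$effect_sex_control
  sp <- truth$effect_sex_perturbed
  tF <- truth$effect_treatment_F
  Fc <- b + tF / 2 + (sc + sp) / 4
  tibble(
    region_id = truth$region_id,
    F_control = Fc,
    F_perturbed = Fc - tF,
    M_control = Fc - sc,
    M_perturbed = Fc - tF - sp
  )
}

#' Simulate counts and base coverage
#'
#' Counts are negative binomial with mean
#' `exp(cell ln-RPKM) x length_kb x library_size_millions`, so the quantify
#' stage recovers the planted ln-RPKM in expectation; base coverage is
#' `counts x read_length`.
#'
#' @param truth A [plan_truth()] tibble.
#' @param design A [sim_design()] tibble.
#' @param seed Integer seed.
#' @param read_length Read length in bp (default 100).
#' @return A list of class `sim_counts`: `counts` and `coverage` (tibbles,
#'   `region_id` plus one column per sample), `design`, `truth`,
#'   `read_length`.
#' @export
simulate_counts <- function(truth, design, seed, read_length = 100L) {
  if (any(design$library_size <= 0)) abort("Library sizes must be positive.")
  check_design(design)
  cells <- truth_cell_means(truth)
  withr::with_seed(seed, {
    n_regions <- nrow(truth)
    counts <- matrix(0L, n_regions, nrow(design))
    for (j in seq_len(nrow(design))) {
      cell <- paste(design$sex[j], design$treatment[j], sep = "_")
      mu_ln <- cells[[cell]]
      mu <- exp(mu_ln) * (truth$length / 1000) * (design$library_size[j] / 1e6)
      disp <- if (design$sex[j] == "F") truth$dispersion_F else truth$dispersion_M
      pois <- disp < 1e-12
      x <- integer(n_regions)
      if (any(pois)) x[pois] <- rpois(sum(pois), mu[pois])
      if (any(!pois)) {
        x[!pois] <- rnbinom(sum(!pois), mu = mu[!pois], size = 1 / disp[!pois])
      }
      counts[, j] <- x
    }
    colnames(counts) <- design$sample_id
    counts_tbl <- bind_cols(tibble(region_id = truth$region_id), as_tibble(counts))
    coverage_tbl <- bind_cols(
      tibble(region_id = truth$region_id),
      as_tibble(counts * as.numeric(read_length))
    )
    structure(
      list(
        counts = counts_tbl, coverage = coverage_tbl,
        design = design, truth = truth, read_length = as.integer(read_length)
      ),
      class = "sim_counts"
    )
  })
}

#' Simulate a full dataset from a scenario
#'
#' Convenience wrapper: [plan_truth()] then [simulate_counts()].
#'
#' @inheritParams plan_truth
#' @return A `sim_counts` list (see [simulate_counts()]).
#' @export
simulate_dataset <- function(scenario, seed) {
  design <- sim_design(scenario$n_reps, scenario$library_size)
  truth <- plan_truth(scenario, seed)
  # distinct sub-seed so truth and counts draws are independent streams
  simulate_counts(truth, design, seed + 1L, read_length = scenario$read_length)
}

check_design <- function(design, min_reps = 2L) {
  tab <- design |> count(.data$sex, .data$treatment)
  full <- tidyr::expand_grid(sex = c("F", "M"), treatment = c("control", "perturbed")) |>
    left_join(tab, by = c("sex", "treatment")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L))
  low <- full |> filter(.data$n < min_reps)
  if (nrow(low)) {
    abort(sprintf(
      "Group(s) with fewer than %d replicates: %s",
      min_reps,
      paste(sprintf("%s-%s (n=%d)", low$sex, low$treatment, low$n), collapse = ", ")
    ))
  }
  invisible(design)
}

#' Remove samples from a simulated (or assembled) dataset
#'
#' Drops the named samples from counts, coverage and the design, erroring if
#' any sex-by-treatment group would fall below `min_reps` replicates.
#'
#' @param sim A `sim_counts` list.
#' @param sample_ids Character vector of samples to remove.
#' @param min_reps Minimum replicates that must remain per group.
#' @return The reduced `sim_counts` object.
#' @export
drop_samples <- function(sim, sample_ids, min_reps = 2L) {
  if (!length(sample_ids)) return(sim)
  unknown <- setdiff(sample_ids, sim$design$sample_id)
  if (length(unknown)) {
    abort(sprintf("Unknown sample id(s): %s", paste(unknown, collapse = ", ")))
  }
  design <- sim$design |> filter(!.data$sample_id %in% sample_ids)
  check_design(design, min_reps)
  keep <- c("region_id", design$sample_id)
  sim$counts <- sim$counts |> select(dplyr::all_of(keep))
  sim$coverage <- sim$coverage |> select(dplyr::all_of(keep))
  sim$design <- design
  sim
}
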