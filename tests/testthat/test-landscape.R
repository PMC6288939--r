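# Hand-built contrast results for controlled classification inputs.
fake_de <- function(rows) {
  defaults <- tibble::tibble(
    region_id = "r1", contrast = "F_ctrl_vs_M_ctrl",
    ln_fc = 0, statistic = 0, df = 6, p = 1, p_adj = 1, twofold = FALSE,
    degenerate = FALSE
  )
  purrr::map_dfr(rows, function(r) {
    out <- defaults
    for (nm in names(r)) out[[nm]] <- r[[nm]]
    out
  })
}

pair_between <- function(region, ctrl_fc, ctrl_p, pert_fc, pert_p,
                         ctrl_2x = FALSE, pert_2x = FALSE) {
  list(
    list(region_id = region, contrast = "F_ctrl_vs_M_ctrl",
         ln_fc = ctrl_fc, p_adj = ctrl_p, twofold = ctrl_2x),
    list(region_id = region, contrast = "F_pert_vs_M_pert",
         ln_fc = pert_fc, p_adj = pert_p, twofold = pert_2x)
  )
}

test_that("between-sex classification maps the nine status pairs", {
  de <- fake_de(c(
    pair_between("r1", 1.0, 0.001, 0.8, 0.001),    # maintained_F
    pair_between("r2", 0.3, 0.600, -1.2, 0.001),   # gained_M
    pair_between("r3", 0.1, 0.900, 0.2, 0.700),    # unbiased
    pair_between("r4", -0.9, 0.001, -1.1, 0.002),  # maintained_M
    pair_between("r5", 0.0, 0.900, 1.4, 0.0001),   # gained_F
    pair_between("r6", 1.2, 0.001, 0.2, 0.800),    # lost_F
    pair_between("r7", -1.2, 0.004, -0.1, 0.300),  # lost_M
    pair_between("r8", 0.8, 0.001, -0.8, 0.001),   # reversed_F_to_M
    pair_between("r9", -0.8, 0.001, 0.8, 0.001)    # reversed_M_to_F
  ))
  got <- classify_between_sex(de, fdr = 0.01)
  expect_equal(
    got$label[match(sprintf("r%d", 1:9), got$region_id)],
    c("maintained_F", "gained_M", "unbiased", "maintained_M", "gained_F",
      "lost_F", "lost_M", "reversed_F_to_M", "reversed_M_to_F")
  )
  # significant but exactly zero estimate maps to NS defensively
  zero <- fake_de(pair_between("z1", 0.0, 0.001, 0.0, 0.001))
  expect_equal(classify_between_sex(zero)$label, "unbiased")

  expect_error(
    classify_between_sex(fake_de(list(list(region_id = "r1")))),
    "F_pert_vs_M_pert"
  )
})

pair_within <- function(region, f_fc, f_p, m_fc, m_p) {
  list(
    list(region_id = region, contrast = "F_ctrl_vs_F_pert", ln_fc = f_fc, p_adj = f_p),
    list(region_id = region, contrast = "M_ctrl_vs_M_pert", ln_fc = m_fc, p_adj = m_p)
  )
}

test_that("within-sex classification re-signs control-minus-perturbed correctly", {
  # contrast sign: positive ln_fc = higher in control = DOWN under perturbation
  de <- fake_de(c(
    pair_within("r1", -1.0, 0.001, -0.9, 0.001),  # both up
    pair_within("r2", 0.2, 0.500, 1.1, 0.001),    # male only down
    pair_within("r3", -0.8, 0.002, 0.9, 0.003),   # M up... F?  -> see below
    pair_within("r4", 0.0, 1.000, 0.0, 1.000)     # null
  ))
  got <- classify_within_sex(de, fdr = 0.01)
  lab <- got$label[match(sprintf("r%d", 1:4), got$region_id)]
  expect_equal(lab[1], "both_up")
  expect_equal(lab[2], "male_only_down")
  # r3: male ln_fc > 0 -> down in perturbed; female ln_fc < 0 -> up
  expect_equal(lab[3], "opposing_MdownFup")
  expect_equal(lab[4], "null")
})

test_that("gene rollup keeps every exon-supported label", {
  labels <- tibble::tibble(
    region_id = c("a1", "a2", "a3", "b1", "b2", "c1"),
    label = c("gained_F", "unbiased", "unbiased", "gained_F", "maintained_M",
              "unbiased"),
    twofold = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
  map <- tibble::tibble(
    region_id = c("a1", "a2", "a3", "b1", "b2", "c1"),
    gene_id = c("A", "A", "A", "B", "B", "C")
  )
  roll <- rollup_genes(labels, map)
  expect_equal(roll$gene_id[roll$label == "gained_F"], c("A", "B"))
  expect_setequal(roll$label[roll$gene_id == "B"], c("gained_F", "maintained_M"))
  expect_false("C" %in% roll$gene_id)  # all-unbiased gene drops out
  expect_true(roll$twofold[roll$gene_id == "A"])

  resolved <- resolve_gene_categories(roll)
  expect_equal(nrow(resolved), 2)
  expect_equal(resolved$label[resolved$gene_id == "B"], "maintained_M")

  expect_error(
    rollup_genes(labels, map[-1, ]),
    "no gene mapping"
  )
})

test_that("landscape tabulation reports counts and half-up percentages", {
  assignments <- tibble::tibble(
    gene_id = c("g1", "g2", "g2", "g3"),
    label = c("gained_F", "gained_F", "lost_M", "maintained_F"),
    n_exons = 1L,
    twofold = c(TRUE, FALSE, FALSE, FALSE)
  )
  tab <- tabulate_landscape(assignments, n_tested_genes = 8)
  expect_equal(tab$summary$n_significant, 3)
  expect_equal(tab$summary$pct_significant_of_tested, 37.5)
  expect_equal(tab$summary$n_significant_twofold, 1)
  expect_equal(tab$summary$pct_twofold_of_significant, 33.3)
  expect_equal(
    tab$by_label$n_genes[tab$by_label$label == "gained_F"], 2
  )
  expect_error(tabulate_landscape(assignments, 2), "smaller")

  none <- tabulate_landscape(assignments[0, ], 10)
  expect_equal(none$summary$pct_significant_of_tested, 0)
})

test_that("half-up rounding differs from banker's rounding where it matters", {
  expect_equal(round_half_up(35.45, 1), 35.5)
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(27.2489, 1), 27.2)
})

test_that("labels partition tested exons and tighten monotonically with FDR", {
  sc <- sim_scenario(n_genes = 150)
  dq <- default_sim_quant(sc, 19)
  de <- run_all_contrasts(dq$quant)

  loose <- classify_between_sex(de, fdr = 0.05)
  strict <- classify_between_sex(de, fdr = 0.01)
  n_detected <- sum(dq$quant$detected$detected)
  expect_equal(nrow(loose), n_detected)
  expect_true(all(loose$label %in% c(
    "unbiased", "maintained_F", "maintained_M", "gained_F", "gained_M",
    "lost_F", "lost_M", "reversed_F_to_M", "reversed_M_to_F"
  )))
  expect_equal(sum(table(loose$label)), n_detected)

  # a status under the stricter level is either unchanged or NS
  joined <- dplyr::inner_join(
    loose, strict, by = "region_id", suffix = c("_loose", "_strict")
  )
  expect_true(all(
    joined$control_status_strict == joined$control_status_loose |
      joined$control_status_strict == "NS"
  ))
  expect_true(all(
    joined$perturbed_status_strict == joined$perturbed_status_loose |
      joined$perturbed_status_strict == "NS"
  ))
})

test_that("fold-change plane data aligns with classification output", {
  sc <- sim_scenario(n_genes = 60)
  dq <- default_sim_quant(sc, 23)
  de <- run_all_contrasts(dq$quant)
  w <- fc_plane_data(de, "within")
  b <- fc_plane_data(de, "between")
  expect_named(w, c("region_id", "ln_fc_x", "ln_fc_y", "label"))
  expect_equal(nrow(w), nrow(b))
  cls <- classify_between_sex(de)
  expect_equal(
    b$ln_fc_y[match(cls$region_id, b$region_id)],
    cls$ln_fc_control
  )
  p1 <- plot_fc_plane(de, "between")
  p2 <- autoplot(run_enrichment(
    de_genes = c("G00001"),
    gene_sets = list(S1 = c("G00001", "G00002")),
    universe = c("G00001", "G00002", "G00003")
  ))
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
})
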