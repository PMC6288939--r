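# Brute-force oracles and fixture builders shared across tests.

# --- GFF fixture ------------------------------------------------------

write_gff <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

gff_line <- function(chrom, type, start, end, strand = "+", attrs = "") {
  paste(chrom, "test", type, start, end, ".", strand, ".", attrs, sep = "\t")
}

# A three-exon gene with a Parent chain exon -> mRNA -> gene.
three_exon_gff <- function() {
  write_gff(c(
    gff_line("2L", "gene", 100, 1000, "+", "ID=G1"),
    gff_line("2L", "mRNA", 100, 1000, "+", "ID=T1;Parent=G1"),
    gff_line("2L", "exon", 100, 200, "+", "ID=E1;Parent=T1"),
    gff_line("2L", "exon", 300, 400, "+", "ID=E2;Parent=T1"),
    gff_line("2L", "exon", 500, 600, "+", "ID=E3;Parent=T1")
  ))
}

# --- per-base flattening oracle --------------------------------------

# Independent brute force: exons of one gene are connected when they share
# at least one base (checked base-by-base); connected components give the
# merged intervals; merged intervals of different genes sharing a base are
# ambiguous, in connected groups.
oracle_flatten <- function(exons) {
  bases <- function(s, e) seq.int(s, e)
  merged <- list()
  for (key in unique(paste(exons$gene_id, exons$chrom))) {
    idx <- which(paste(exons$gene_id, exons$chrom) == key)
    n <- length(idx)
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (comp[i] != comp[j] &&
            length(intersect(bases(exons$start[idx[i]], exons$end[idx[i]]),
                             bases(exons$start[idx[j]], exons$end[idx[j]]))) > 0) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (cc in unique(comp)) {
      members <- idx[comp == cc]
      merged[[length(merged) + 1L]] <- data.frame(
        gene_id = exons$gene_id[members[1]],
        chrom = exons$chrom[members[1]],
        start = min(exons$start[members]),
        end = max(exons$end[members]),
        n_source_exons = length(members)
      )
    }
  }
  merged <- do.call(rbind, merged)
  n <- nrow(merged)
  amb_edge <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && merged$chrom[i] == merged$chrom[j] &&
        merged$gene_id[i] != merged$gene_id[j] &&
        length(intersect(bases(merged$start[i], merged$end[i]),
                         bases(merged$start[j], merged$end[j]))) > 0) {
      amb_edge[i, j] <- amb_edge[j, i] <- TRUE
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (amb_edge[i, j] && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  ambiguous <- rowSums(amb_edge) > 0
  merged$kind <- ifelse(merged$n_source_exons >= 2, "overlap", "single")
  merged$component <- comp
  list(
    retained = merged[!ambiguous, , drop = FALSE],
    dropped = merged[ambiguous, , drop = FALSE]
  )
}

random_annotation <- function(seed, max_genes = 5, max_exons = 10, max_coord = 2000) {
  withr::with_seed(seed, {
    n_genes <- sample(max_genes, 1)
    rows <- lapply(seq_len(n_genes), function(g) {
      n_ex <- sample(max_exons, 1)
      start <- sample(max_coord - 100, n_ex, replace = TRUE)
      len <- sample(80, n_ex, replace = TRUE)
      data.frame(
        exon_id = sprintf("g%d_e%d", g, seq_len(n_ex)),
        gene_id = sprintf("g%d", g),
        chrom = "chr1",
        start = start,
        end = start + len,
        strand = "+"
      )
    })
    tibble::as_tibble(do.call(rbind, rows))
  })
}

# Compare build_exonic_regions() against the per-base oracle; errors with
# an informative message on the first mismatch.
expect_flatten_matches_oracle <- function(exons) {
  got <- build_exonic_regions(exons)
  want <- oracle_flatten(exons)
  key <- function(d) sort(sprintf("%s:%s:%d-%d:%s:%d",
                                  d$gene_id, d$chrom, d$start, d$end,
                                  d$kind, d$n_source_exons))
  expect_identical(
    key(got$retained),
    key(want$retained)
  )
  expect_identical(
    sort(sprintf("%s:%d-%d", got$ambiguous$gene_id, got$ambiguous$start, got$ambiguous$end)),
    sort(sprintf("%s:%d-%d", want$dropped$gene_id, want$dropped$start, want$dropped$end))
  )
  # the grouped gene sets must agree too
  if (nrow(want$dropped)) {
    want_sets <- sort(unique(vapply(
      split(want$dropped$gene_id, want$dropped$component),
      function(g) paste(sort(unique(g)), collapse = ","), character(1)
    )))
    got_sets <- sort(unique(got$ambiguous$gene_ids))
    expect_identical(got_sets, want_sets)
  }
  invisible(got)
}

# --- BH step-up oracle ------------------------------------------------

bh_adjust_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  adj
}

bh_reject_oracle <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  ks <- which(ps <= seq_len(m) * alpha / m)
  if (!length(ks)) return(rep(FALSE, m))
  p <= ps[max(ks)]
}

# --- hypergeometric enumeration oracle --------------------------------

hyper_upper_oracle <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# --- quantification fixture -------------------------------------------

# An expr_quant built directly from an ln-RPKM matrix (all regions
# detected), for controlled inputs to the contrast machinery.
quant_from_ln <- function(mat, design) {
  stopifnot(ncol(mat) == nrow(design))
  colnames(mat) <- design$sample_id
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("r%03d", seq_len(nrow(mat)))
  values <- tibble::tibble(
    region_id = rep(rownames(mat), times = ncol(mat)),
    sample_id = rep(design$sample_id, each = nrow(mat)),
    count = NA_real_,
    apn = NA_real_,
    ln_rpkm = as.vector(mat)
  )
  values <- dplyr::left_join(
    values, design[, c("sample_id", "sex", "treatment")], by = "sample_id"
  )
  structure(
    list(
      values = values[, c("region_id", "sample_id", "sex", "treatment",
                          "count", "apn", "ln_rpkm")],
      detected = tibble::tibble(region_id = rownames(mat), detected = TRUE),
      design = design,
      apn_threshold = 5, min_reps = 2, pseudocount = 0.5
    ),
    class = "expr_quant"
  )
}

default_sim_quant <- function(scenario, seed) {
  sim <- simulate_dataset(scenario, seed)
  quant <- quantify(
    sim$counts, sim$coverage, sim$truth, sim$design,
    library_sizes = stats::setNames(sim$design$library_size, sim$design$sample_id)
  )
  list(sim = sim, quant = quant)
}

# True ln-fold change per contrast implied by the planted effects.
truth_contrast_fc <- function(truth) {
  tibble::tibble(
    region_id = rep(truth$region_id, 4),
    contrast = rep(
      c("F_ctrl_vs_F_pert", "M_ctrl_vs_M_pert",
        "F_ctrl_vs_M_ctrl", "F_pert_vs_M_pert"),
      each = nrow(truth)
    ),
    true_fc = c(
      truth$effect_treatment_F, truth$effect_treatment_M,
      truth$effect_sex_control, truth$effect_sex_perturbed
    )
  )
}
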