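# Quantification: average per-nucleotide coverage (APN), the detection
# filter, and ln-RPKM expression.

#' Average per-nucleotide coverage
#'
#' @param base_coverage Total bases mapped to the region (numeric, >= 0).
#' @param region_length Region length in bp (> 0).
#' @return `base_coverage / region_length`, vectorised.
#' @export
compute_apn <- function(base_coverage, region_length) {
  if (any(base_coverage < 0)) abort("Negative base coverage.")
  if (any(region_length <= 0)) abort("Region length must be positive.")
  base_coverage / region_length
}

#' Natural-log RPKM
#'
#' `ln((count + pseudocount) / (length_kb x library_millions))`. The
#' pseudocount (default 0.5) keeps zero-count regions finite.
#'
#' @param count Read count.
#' @param region_length Region length (bp, > 0).
#' @param library_size Mapped reads in the sample (> 0).
#' @param pseudocount Added to every count before the ratio (default 0.5).
#' @return ln-RPKM, vectorised.
#' @export
ln_rpkm <- function(count, region_length, library_size, pseudocount = 0.5) {
  if (any(region_length <= 0)) abort("Region length must be positive.")
  if (any(library_size <= 0)) abort("Library size must be positive.")
  log((count + pseudocount) / ((region_length / 1000) * (library_size / 1e6)))
}

#' Detection filter on APN
#'
#' A region is detected when at least one of the four sex-by-treatment
#' groups has `min_reps` or more replicates with APN strictly greater than
#' `threshold`.
#'
#' @param apn Tibble: `region_id` plus one numeric column per sample.
#' @param design Sample design tibble (`sample_id`, `sex`, `treatment`).
#' @param threshold APN threshold; strict inequality (default 5).
#' @param min_reps Minimum qualifying replicates in a group (default 2).
#' @return Tibble `region_id`, `detected` (logical).
#' @export
detection_filter <- function(apn, design, threshold = 5, min_reps = 2L) {
  check_design(design, min_reps)
  mat <- as.matrix(apn[, design$sample_id, drop = FALSE])
  groups <- split(seq_len(nrow(design)), paste(design$sex, design$treatment))
  hits <- vapply(groups, function(cols) {
    rowSums(mat[, cols, drop = FALSE] > threshold) >= min_reps
  }, logical(nrow(mat)))
  if (is.null(dim(hits))) hits <- matrix(hits, nrow = nrow(mat))
  tibble(region_id = apn$region_id, detected = rowSums(hits) > 0)
}

#' Quantify expression from counts and coverage
#'
#' Computes APN, applies the detection filter, and computes ln-RPKM for
#' every region/sample. Library sizes default to the per-sample total of
#' counts over the supplied regions; pass `library_sizes` (named by sample)
#' to use externally determined totals.
#'
#' @param counts,coverage Tibbles: `region_id` plus one column per sample.
#' @param lengths Tibble `region_id`, `length` (bp).
#' @param design Sample design tibble.
#' @param apn_threshold,min_reps Detection-filter parameters.
#' @param pseudocount Passed to [ln_rpkm()].
#' @param library_sizes Optional named numeric vector of mapped-read totals.
#' @return A list of class `expr_quant`: `values` (long tibble with
#'   `region_id`, `sample_id`, `sex`, `treatment`, `count`, `apn`,
#'   `ln_rpkm`), `detected`, `lengths`, `design`, `library_sizes`, and the
#'   filter parameters.
#' @export
quantify <- function(counts, coverage, lengths, design,
                     apn_threshold = 5, min_reps = 2L,
                     pseudocount = 0.5, library_sizes = NULL) {
  stopifnot(identical(counts$region_id, coverage$region_id))
  lengths <- lengths |> select("region_id", "length")
  ord <- match(counts$region_id, lengths$region_id)
  if (anyNA(ord)) abort("Some regions in `counts` are missing from `lengths`.")
  len <- lengths$length[ord]

  cmat <- as.matrix(counts[, design$sample_id, drop = FALSE])
  vmat <- as.matrix(coverage[, design$sample_id, drop = FALSE])

  if (is.null(library_sizes)) {
    library_sizes <- colSums(cmat)
  } else {
    if (!all(design$sample_id %in% names(library_sizes))) {
      abort("`library_sizes` must be named and cover every sample.")
    }
    library_sizes <- library_sizes[design$sample_id]
  }
  if (any(library_sizes <= 0)) abort("Library size must be positive.")

  apn_mat <- matrix(
    compute_apn(as.numeric(vmat), rep(len, ncol(vmat))),
    nrow(vmat), ncol(vmat), dimnames = dimnames(vmat)
  )
  ln_mat <- ln_rpkm(
    cmat, matrix(len, nrow(cmat), ncol(cmat)),
    matrix(library_sizes, nrow(cmat), ncol(cmat), byrow = TRUE),
    pseudocount
  )

  apn_tbl <- bind_cols(tibble(region_id = counts$region_id), as_tibble(apn_mat))
  detected <- detection_filter(apn_tbl, design, apn_threshold, min_reps)

  values <- tibble(
    region_id = rep(counts$region_id, times = ncol(cmat)),
    sample_id = rep(design$sample_id, each = nrow(cmat)),
    count = as.vector(cmat),
    apn = as.vector(apn_mat),
    ln_rpkm = as.vector(ln_mat)
  ) |>
    left_join(design |> select("sample_id", "sex", "treatment"), by = "sample_id") |>
    select("region_id", "sample_id", "sex", "treatment", "count", "apn", "ln_rpkm")

  structure(
    list(
      values = values,
      detected = detected,
      lengths = tibble(region_id = counts$region_id, length = len),
      design = design,
      library_sizes = tibble(
        sample_id = design$sample_id,
        library_size = unname(library_sizes)
      ),
      apn_threshold = apn_threshold,
      min_reps = min_reps,
      pseudocount = pseudocount
    ),
    class = "expr_quant"
  )
}

#' @export
print.expr_quant <- function(x, ...) {
  cat(sprintf(
    "<expr_quant> %d regions (%d detected) x %d samples\n",
    nrow(x$detected), sum(x$detected$detected), nrow(x$design)
  ))
  invisible(x)
}

#' @rdname quantify
#' @param x An `expr_quant` object.
#' @param ... Unused.
#' @export
tidy.expr_quant <- function(x, ...) {
  x$values |> left_join(x$detected, by = "region_id")
}

#' @rdname quantify
#' @export
glance.expr_quant <- function(x, ...) {
  tibble(
    n_regions = nrow(x$detected),
    n_detected = sum(x$detected$detected),
    n_samples = nrow(x$design),
    apn_threshold = x$apn_threshold,
    min_reps = x$min_reps
  )
}

# ln-RPKM matrix of detected regions (rows) x samples (columns).
detected_ln_matrix <- function(quant) {
  keep <- quant$detected$region_id[quant$detected$detected]
  wide <- quant$values |>
    select("region_id", "sample_id", "ln_rpkm") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "ln_rpkm")
  wide <- wide |> filter(.data$region_id %in% keep)
  mat <- as.matrix(wide[, quant$design$sample_id, drop = FALSE])
  rownames(mat) <- wide$region_id
  mat
}
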