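# Hypergeometric over-representation of DE gene lists in gene sets, with
# the background restricted to tested genes that carry at least one
# annotation of the tested type.

#' Read a GMT gene-set file
#'
#' Tab-delimited: set id, description, then member genes. Duplicate member
#' genes within a set are dropped.
#'
#' @param path Path to a GMT file.
#' @return Tibble: `set_id`, `name`, `genes` (list column).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    abort(sprintf("GMT line %d has fewer than 3 fields.", bad[1]))
  }
  tibble(
    set_id = vapply(fields, `[[`, character(1), 1L),
    name = vapply(fields, `[[`, character(1), 2L),
    genes = lapply(fields, function(f) unique(f[-(1:2)]))
  )
}

#' Upper-tail hypergeometric p-value
#'
#' Probability of observing `k` or more annotated genes in a draw of `n`
#' from a background of `N` genes of which `K` are annotated:
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param k Annotated genes among the drawn (DE) genes.
#' @param K Annotated genes in the background.
#' @param n Drawn (DE) genes in the background.
#' @param N Background size.
#' @return Upper-tail p-value, vectorised over the arguments.
#' @export
hypergeom_upper_p <- function(k, K, n, N) {
  bad <- k < 0 | K > N | n > N | k > pmin(K, n)
  if (any(bad)) {
    abort("Inconsistent hypergeometric margins (need 0 <= k <= min(K, n); K, n <= N).")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation of a DE gene list
#'
#' The background (universe) is restricted to genes carrying at least one
#' annotation among the supplied sets; the DE list is intersected with that
#' background. One upper-tail hypergeometric test per set with at least one
#' background member, Benjamini-Hochberg adjusted across sets.
#'
#' @param de_genes Character vector of differentially expressed genes.
#' @param gene_sets A [read_gmt()] tibble (or named list of gene vectors).
#' @param universe Character vector of tested genes.
#' @param fdr Significance level on the adjusted p (default 0.05).
#' @return A tibble of class `enrich_res`: `set_id`, `name`, `k`, `K`,
#'   `n`, `N`, `p`, `p_adj`, `significant`.
#' @export
run_enrichment <- function(de_genes, gene_sets, universe, fdr = 0.05) {
  if (is.list(gene_sets) && !is.data.frame(gene_sets)) {
    gene_sets <- tibble(
      set_id = names(gene_sets), name = names(gene_sets),
      genes = unname(gene_sets)
    )
  }
  annotated <- unique(unlist(gene_sets$genes))
  bg <- intersect(unique(universe), annotated)
  if (!length(bg)) abort("Empty background: no tested gene carries an annotation.")
  de <- intersect(unique(de_genes), bg)

  res <- gene_sets |>
    mutate(
      K = vapply(.data$genes, function(g) length(intersect(g, bg)), integer(1)),
      k = vapply(.data$genes, function(g) length(intersect(g, de)), integer(1)),
      n = length(de),
      N = length(bg)
    ) |>
    filter(.data$K >= 1L)
  if (!nrow(res)) {
    return(structure(
      tibble(
        set_id = character(), name = character(), k = integer(),
        K = integer(), n = integer(), N = integer(), p = numeric(),
        p_adj = numeric(), significant = logical()
      ),
      fdr = fdr, class = c("enrich_res", class(tibble()))
    ))
  }
  res <- res |>
    mutate(
      p = hypergeom_upper_p(.data$k, .data$K, .data$n, .data$N),
      p_adj = adjust_fdr(.data$p),
      significant = .data$p_adj < fdr
    ) |>
    select("set_id", "name", "k", "K", "n", "N", "p", "p_adj", "significant") |>
    arrange(.data$p)
  structure(res, fdr = fdr, class = c("enrich_res", class(res)))
}

#' @rdname run_enrichment
#' @param x An `enrich_res` tibble.
#' @param ... Unused.
#' @export
tidy.enrich_res <- function(x, ...) {
  class(x) <- setdiff(class(x), "enrich_res")
  as_tibble(x)
}

#' @rdname run_enrichment
#' @export
glance.enrich_res <- function(x, ...) {
  tb <- tidy(x)
  tibble(
    n_sets = nrow(tb),
    n_significant = sum(tb$significant),
    n_de = if (nrow(tb)) tb$n[1] else 0L,
    n_background = if (nrow(tb)) tb$N[1] else 0L,
    fdr = attr(x, "fdr")
  )
}
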