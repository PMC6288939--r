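# Annotation flattening: GFF3 exons -> unique exonic regions per gene.
#
# Reads are assigned to "exonic regions": maximal intervals formed from a
# single exon or from overlapping exons of the same gene. Any merged interval
# that shares bases with a merged interval of a *different* gene is ambiguous
# with respect to gene identity and is excluded from analysis.

#' Read exon records from a GFF3 file
#'
#' Parses a GFF3 annotation and returns one row per feature of the requested
#' type, with gene attribution resolved either from a `gene_id` attribute or
#' by walking the `Parent` chain (exon -> transcript -> gene).
#'
#' @param path Path to a GFF3 file.
#' @param feature Feature type to keep (third GFF column), default `"exon"`.
#' @return A tibble with columns `exon_id`, `gene_id`, `chrom`, `start`,
#'   `end` (1-based, inclusive) and `strand` (`+`, `-` or `.`).
#' @export
read_exon_gff <- function(path, feature = "exon") {
  if (!file.exists(path)) abort(sprintf("GFF file not found: %s", path))
  validate_gff_lines(path)
  gff <- as.data.frame(rtracklayer::readGFF(path))

  keep <- gff$type == feature
  if (!any(keep)) {
    return(tibble(
      exon_id = character(), gene_id = character(), chrom = character(),
      start = integer(), end = integer(), strand = character()
    ))
  }

  gene_ids <- resolve_gene_ids(gff, which(keep))
  sub <- gff[keep, , drop = FALSE]

  strand <- as.character(sub$strand)
  strand[is.na(strand) | strand == "*"] <- "."

  ids <- if ("ID" %in% names(sub)) as.character(sub$ID) else rep(NA_character_, nrow(sub))
  fallback <- sprintf("%s:%s:%d-%d", gene_ids, as.character(sub$seqid), sub$start, sub$end)
  ids[is.na(ids) | ids == ""] <- fallback[is.na(ids) | ids == ""]

  tibble(
    exon_id = ids,
    gene_id = gene_ids,
    chrom = as.character(sub$seqid),
    start = as.integer(sub$start),
    end = as.integer(sub$end),
    strand = strand
  )
}

# Cheap structural check so malformed lines are reported by line number
# (readGFF's own errors do not carry one).
validate_gff_lines <- function(path) {
  lines <- readr::read_lines(path)
  fasta <- which(lines == "##FASTA")
  if (length(fasta)) lines <- head(lines, fasta[1] - 1L)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  nfield <- stringr::str_count(lines[body], stringr::fixed("\t")) + 1L
  bad <- which(body)[nfield != 9L]
  if (length(bad)) {
    abort(sprintf(
      "Malformed GFF3: line %d has %d fields (expected 9).",
      bad[1], nfield[which(body) %in% bad][1]
    ))
  }
  invisible(TRUE)
}

# Resolve the owning gene of each kept feature: a gene_id attribute wins,
# otherwise the Parent chain is walked until a gene feature (or a feature
# carrying gene_id) is reached.
resolve_gene_ids <- function(gff, rows) {
  has_gene_attr <- "gene_id" %in% names(gff)
  has_parent <- "Parent" %in% names(gff)
  ids <- if ("ID" %in% names(gff)) as.character(gff$ID) else rep(NA_character_, nrow(gff))
  id_row <- setNames(seq_len(nrow(gff)), ids)
  id_row <- id_row[!is.na(ids) & nzchar(ids)]

  gene_of <- function(row, depth = 0L) {
    if (depth > 25L) return(NA_character_)
    if (has_gene_attr) {
      g <- gff$gene_id[row]
      if (!is.na(g) && nzchar(g)) return(as.character(g))
    }
    if (gff$type[row] == "gene") {
      return(if (!is.na(ids[row])) ids[row] else NA_character_)
    }
    if (!has_parent) return(NA_character_)
    parents <- unlist(gff$Parent[row])
    parents <- parents[!is.na(parents) & nzchar(parents)]
    if (!length(parents)) return(NA_character_)
    genes <- unique(vapply(parents, function(p) {
      prow <- id_row[p]
      if (is.na(prow)) NA_character_ else gene_of(prow, depth + 1L)
    }, character(1)))
    genes <- genes[!is.na(genes)]
    if (length(genes) == 1L) genes else NA_character_
  }

  out <- vapply(rows, gene_of, character(1))
  if (anyNA(out)) {
    missing <- rows[is.na(out)]
    lab <- ids[missing]
    lab[is.na(lab)] <- sprintf("%s:%d-%d", gff$seqid[missing], gff$start[missing], gff$end[missing])
    abort(sprintf(
      "Exon feature(s) without resolvable gene attribution: %s",
      paste(head(lab, 5), collapse = ", ")
    ))
  }
  out
}

#' Flatten exons into unique exonic regions
#'
#' Per gene, exons sharing at least one base are merged into maximal
#' intervals; merely adjacent exons (`end + 1 == start`) are not merged.
#' A merged interval built from one exon has `kind = "single"`, from two or
#' more `kind = "overlap"`. Any merged interval that shares bases with a
#' merged interval of a different gene is ambiguous: by default the whole
#' interval of every gene involved is dropped and reported; with
#' `trim_ambiguous = TRUE` only the shared bases are removed and the
#' gene-unique remainder is retained.
#'
#' @param exons A tibble of exon records as from [read_exon_gff()].
#' @param trim_ambiguous If `TRUE`, trim shared bases instead of dropping
#'   whole intervals (default `FALSE`).
#' @return An object of class `exonic_regions`: a list with tibbles
#'   `retained` (columns `region_id`, `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `kind`, `n_source_exons`, `length`) and `ambiguous`
#'   (one row per excluded interval, with the set of genes involved in
#'   `gene_ids` and a shared `ambiguity_group` index).
#' @export
build_exonic_regions <- function(exons, trim_ambiguous = FALSE) {
  empty <- list(
    retained = tibble(
      region_id = character(), gene_id = character(), chrom = character(),
      start = integer(), end = integer(), strand = character(),
      kind = character(), n_source_exons = integer(), length = integer()
    ),
    ambiguous = tibble(
      chrom = character(), start = integer(), end = integer(),
      gene_id = character(), ambiguity_group = integer(), gene_ids = character()
    )
  )
  if (nrow(exons) == 0L) {
    return(structure(empty, trim_ambiguous = trim_ambiguous, class = "exonic_regions"))
  }
  if (any(exons$start > exons$end)) abort("Exon with start > end.")
  if (any(is.na(exons$gene_id) | !nzchar(exons$gene_id))) abort("Exon with empty gene_id.")

  multi <- exons |>
    distinct(.data$gene_id, .data$chrom) |>
    count(.data$gene_id) |>
    filter(n > 1L)
  if (nrow(multi)) {
    warn(sprintf(
      "Gene(s) with exons on multiple chromosomes (processed per chromosome): %s",
      paste(head(multi$gene_id, 5), collapse = ", ")
    ))
  }

  gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(exons$start, exons$end),
    gene_id = exons$gene_id,
    exon_strand = exons$strand %||% "."
  )

  # min.gapwidth = 0 merges overlapping but not book-ended intervals
  merged_l <- GenomicRanges::reduce(
    S4Vectors::split(gr, gr$gene_id),
    min.gapwidth = 0L, with.revmap = TRUE
  )
  merged <- unlist(merged_l, use.names = TRUE)
  gene <- names(merged)
  revmap <- S4Vectors::mcols(merged)$revmap

  # revmap indexes within each gene's split; map back to original rows
  idx_by_gene <- S4Vectors::split(seq_along(gr), gr$gene_id)
  src_rows <- lapply(seq_along(merged), function(i) {
    idx_by_gene[[gene[i]]][revmap[[i]]]
  })
  n_src <- lengths(src_rows)
  strand <- vapply(src_rows, function(rows) {
    s <- unique(gr$exon_strand[rows])
    if (length(s) == 1L) s else "."
  }, character(1))

  merged_tbl <- tibble(
    gene_id = gene,
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged),
    end = GenomicRanges::end(merged),
    strand = strand,
    kind = if_else(n_src >= 2L, "overlap", "single"),
    n_source_exons = as.integer(n_src)
  )

  # cross-gene ambiguity: connected components of the overlap graph over
  # merged intervals of different genes
  hits <- GenomicRanges::findOverlaps(merged, merged, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  cross <- gene[q] != gene[s]
  comp <- components_from_edges(nrow(merged_tbl), q[cross], s[cross])
  in_cross <- seq_len(nrow(merged_tbl)) %in% c(q[cross], s[cross])

  if (!trim_ambiguous) {
    retained <- merged_tbl[!in_cross, , drop = FALSE]
    dropped <- merged_tbl[in_cross, , drop = FALSE]
    dropped$ambiguity_group <- match(comp[in_cross], sort(unique(comp[in_cross])))
    dropped <- dropped |>
      group_by(.data$ambiguity_group) |>
      mutate(gene_ids = paste(sort(unique(.data$gene_id)), collapse = ",")) |>
      ungroup() |>
      select("chrom", "start", "end", "gene_id", "ambiguity_group", "gene_ids") |>
      arrange(.data$ambiguity_group, .data$chrom, .data$start)
  } else {
    trimmed <- trim_shared_bases(merged_tbl, merged, gene, in_cross, comp)
    retained <- trimmed$retained
    dropped <- trimmed$ambiguous
  }

  retained <- retained |>
    mutate(
      region_id = sprintf("%s:%d-%d", .data$gene_id, .data$start, .data$end),
      length = .data$end - .data$start + 1L
    ) |>
    select(
      "region_id", "gene_id", "chrom", "start", "end", "strand",
      "kind", "n_source_exons", "length"
    ) |>
    arrange(.data$chrom, .data$start, .data$gene_id)

  structure(
    list(retained = retained, ambiguous = dropped),
    trim_ambiguous = trim_ambiguous,
    class = "exonic_regions"
  )
}

# Union-find over overlap edges; returns a component id per node.
components_from_edges <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(from)) {
    a <- find(from[k]); b <- find(to[k])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

# Base-level trimming alternative: remove only bases covered by >= 2 genes.
trim_shared_bases <- function(merged_tbl, merged, gene, in_cross, comp) {
  keep <- merged_tbl[!in_cross, , drop = FALSE]

  amb_idx <- which(in_cross)
  amb_rows <- list()
  kept_pieces <- list()
  for (g in unique(comp[in_cross])) {
    members <- which(comp == g & in_cross)
    grs <- merged[members]
    genes_here <- gene[members]
    cov <- GenomicRanges::coverage(grs)
    shared <- GenomicRanges::GRanges(IRanges::slice(cov, lower = 2L, rangesOnly = TRUE))
    for (j in seq_along(members)) {
      uniq <- GenomicRanges::setdiff(grs[j], shared, ignore.strand = TRUE)
      if (length(uniq)) {
        kept_pieces[[length(kept_pieces) + 1L]] <- tibble(
          gene_id = genes_here[j],
          chrom = as.character(GenomicRanges::seqnames(uniq)),
          start = GenomicRanges::start(uniq),
          end = GenomicRanges::end(uniq),
          strand = merged_tbl$strand[members[j]],
          kind = merged_tbl$kind[members[j]],
          n_source_exons = merged_tbl$n_source_exons[members[j]]
        )
      }
    }
    amb_rows[[length(amb_rows) + 1L]] <- tibble(
      chrom = as.character(GenomicRanges::seqnames(shared)),
      start = GenomicRanges::start(shared),
      end = GenomicRanges::end(shared),
      gene_id = NA_character_,
      ambiguity_group = match(g, sort(unique(comp[in_cross]))),
      gene_ids = paste(sort(unique(genes_here)), collapse = ",")
    )
  }
  list(
    retained = bind_rows(keep, bind_rows(kept_pieces)),
    ambiguous = bind_rows(amb_rows)
  )
}

#' @export
print.exonic_regions <- function(x, ...) {
  cat(sprintf(
    "<exonic_regions> %d retained (%d single, %d overlap), %d ambiguous interval(s)\n",
    nrow(x$retained),
    sum(x$retained$kind == "single"),
    sum(x$retained$kind == "overlap"),
    nrow(x$ambiguous)
  ))
  invisible(x)
}

#' @rdname build_exonic_regions
#' @param x An `exonic_regions` object.
#' @param ... Unused.
#' @export
tidy.exonic_regions <- function(x, ...) {
  bind_rows(
    x$retained |> mutate(status = "retained"),
    x$ambiguous |>
      mutate(
        status = "ambiguous",
        region_id = sprintf("%s:%d-%d", .data$gene_ids, .data$start, .data$end)
      )
  )
}

#' @rdname build_exonic_regions
#' @export
glance.exonic_regions <- function(x, ...) {
  tibble(
    n_retained = nrow(x$retained),
    n_single = sum(x$retained$kind == "single"),
    n_overlap = sum(x$retained$kind == "overlap"),
    n_ambiguous = nrow(x$ambiguous),
    n_genes = dplyr::n_distinct(x$retained$gene_id)
  )
}

#' Write retained regions as BED6
#'
#' GFF3 coordinates are 1-based inclusive; BED is 0-based half-open, so
#' `start` is decremented and `end` kept.
#'
#' @param regions A tibble of retained regions (from [build_exonic_regions()]).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  if (inherits(regions, "exonic_regions")) regions <- regions$retained
  bed <- tibble(
    chrom = regions$chrom,
    start = regions$start - 1L,
    end = regions$end,
    name = regions$region_id,
    score = 0L,
    strand = if_else(regions$strand %in% c("+", "-"), regions$strand, ".")
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write retained regions as TSV
#'
#' @inheritParams write_regions_bed
#' @export
write_regions_tsv <- function(regions, path) {
  if (inherits(regions, "exonic_regions")) regions <- regions$retained
  readr::write_tsv(
    regions |> select("region_id", "gene_id", "kind", "n_source_exons", "length"),
    path
  )
  invisible(path)
}
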