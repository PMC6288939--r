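test_that("GFF exons parse with gene attribution via the Parent chain", {
  path <- three_exon_gff()
  exons <- read_exon_gff(path)
  expect_equal(nrow(exons), 3)
  expect_equal(unique(exons$gene_id), "G1")
  expect_equal(exons$start, c(100, 300, 500))
  expect_equal(exons$end, c(200, 400, 600))

  # feature filter excludes CDS-only files
  cds_only <- write_gff(c(
    gff_line("2L", "gene", 100, 400, "+", "ID=G1"),
    gff_line("2L", "CDS", 100, 200, "+", "ID=C1;Parent=G1")
  ))
  expect_equal(nrow(read_exon_gff(cds_only)), 0)

  # two-step Parent chain: exon -> mRNA1 -> G2
  chain <- write_gff(c(
    gff_line("3R", "gene", 1, 900, "-", "ID=G2"),
    gff_line("3R", "mRNA", 1, 900, "-", "ID=mRNA1;Parent=G2"),
    gff_line("3R", "exon", 10, 90, "-", "Parent=mRNA1")
  ))
  rec <- read_exon_gff(chain)
  expect_equal(rec$gene_id, "G2")
  expect_equal(rec$strand, "-")
})

test_that("malformed GFF lines and unattributable exons are reported", {
  bad <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    gff_line("2L", "gene", 100, 400, "+", "ID=G1"),
    "2L\ttest\texon\t100"
  ), bad)
  expect_error(read_exon_gff(bad), "line 3")

  orphan <- write_gff(gff_line("2L", "exon", 100, 200, "+", "ID=E1"))
  expect_error(read_exon_gff(orphan), "gene attribution")
})

test_that("overlapping exons of one gene merge; adjacent exons do not", {
  exons <- tibble::tibble(
    exon_id = c("e1", "e2"), gene_id = "G1", chrom = "chr1",
    start = c(100L, 150L), end = c(200L, 250L), strand = "+"
  )
  res <- build_exonic_regions(exons)
  expect_equal(nrow(res$retained), 1)
  expect_equal(res$retained$start, 100)
  expect_equal(res$retained$end, 250)
  expect_equal(res$retained$kind, "overlap")
  expect_equal(res$retained$n_source_exons, 2L)
  expect_equal(res$retained$length, 151L)
  expect_equal(nrow(res$ambiguous), 0)

  adjacent <- tibble::tibble(
    exon_id = c("e1", "e2"), gene_id = "G1", chrom = "chr1",
    start = c(100L, 201L), end = c(200L, 300L), strand = "+"
  )
  res2 <- build_exonic_regions(adjacent)
  expect_equal(nrow(res2$retained), 2)
  expect_true(all(res2$retained$kind == "single"))
})

test_that("cross-gene overlap drops whole merged intervals as one ambiguity group", {
  exons <- tibble::tibble(
    exon_id = c("a", "b"), gene_id = c("G1", "G2"), chrom = "chr1",
    start = c(300L, 350L), end = c(400L, 450L), strand = "+"
  )
  res <- build_exonic_regions(exons)
  expect_equal(nrow(res$retained), 0)
  expect_equal(nrow(res$ambiguous), 2)
  expect_equal(unique(res$ambiguous$gene_ids), "G1,G2")
  expect_equal(unique(res$ambiguous$ambiguity_group), 1L)

  # gene-unique merged intervals survive alongside an ambiguity
  exons3 <- tibble::tibble(
    exon_id = c("a1", "a2", "a3", "b1"),
    gene_id = c("G1", "G1", "G1", "G2"), chrom = "chr1",
    start = c(100L, 150L, 300L, 350L), end = c(200L, 250L, 400L, 450L),
    strand = "+"
  )
  res3 <- build_exonic_regions(exons3)
  expect_equal(nrow(res3$retained), 1)
  expect_equal(res3$retained$region_id, "G1:100-250")
  expect_equal(res3$retained$kind, "overlap")
  expect_setequal(
    sprintf("%s:%d-%d", res3$ambiguous$gene_id, res3$ambiguous$start, res3$ambiguous$end),
    c("G1:300-400", "G2:350-450")
  )
})

test_that("empty input gives empty outputs and a multi-chromosome gene warns", {
  res <- build_exonic_regions(tibble::tibble(
    exon_id = character(), gene_id = character(), chrom = character(),
    start = integer(), end = integer(), strand = character()
  ))
  expect_equal(nrow(res$retained), 0)
  expect_equal(nrow(res$ambiguous), 0)

  split_gene <- tibble::tibble(
    exon_id = c("e1", "e2"), gene_id = "G1", chrom = c("chr1", "chr2"),
    start = c(1L, 1L), end = c(50L, 50L), strand = "+"
  )
  expect_warning(build_exonic_regions(split_gene), "multiple chromosomes")
})

test_that("flattening matches the per-base oracle on random annotations", {
  for (seed in 1:60) {
    exons <- random_annotation(seed)
    expect_flatten_matches_oracle(exons)
  }
})

test_that("flattening is idempotent and conserves per-gene exonic bases", {
  for (seed in c(3, 17, 29)) {
    exons <- random_annotation(seed)
    res <- build_exonic_regions(exons)

    # idempotence on boundaries: retained regions re-flattened are unchanged
    again <- build_exonic_regions(
      res$retained |>
        dplyr::transmute(
          exon_id = region_id, gene_id, chrom, start, end, strand
        )
    )
    expect_identical(
      again$retained[, c("gene_id", "chrom", "start", "end")],
      res$retained[, c("gene_id", "chrom", "start", "end")]
    )
    expect_equal(nrow(again$ambiguous), 0)

    # conservation: per-gene union bases = retained + dropped bases
    want <- oracle_flatten(exons)
    union_bases <- sum(want$retained$end - want$retained$start + 1) +
      sum(want$dropped$end - want$dropped$start + 1)
    got_bases <- sum(res$retained$length) +
      sum(res$ambiguous$end - res$ambiguous$start + 1)
    expect_equal(got_bases, union_bases)
  }
})

test_that("base-level trimming keeps gene-unique remainders", {
  exons <- tibble::tibble(
    exon_id = c("a", "b"), gene_id = c("G1", "G2"), chrom = "chr1",
    start = c(300L, 350L), end = c(400L, 450L), strand = "+"
  )
  res <- build_exonic_regions(exons, trim_ambiguous = TRUE)
  expect_setequal(res$retained$region_id, c("G1:300-349", "G2:401-450"))
  expect_equal(res$ambiguous$start, 350)
  expect_equal(res$ambiguous$end, 400)
  expect_equal(res$ambiguous$gene_ids, "G1,G2")
})

test_that("BED output is 0-based half-open; TSV carries region metadata", {
  exons <- tibble::tibble(
    exon_id = c("e1", "e2"), gene_id = "G1", chrom = "chr1",
    start = c(100L, 150L), end = c(200L, 250L), strand = "+"
  )
  res <- build_exonic_regions(exons)
  bed_path <- tempfile(fileext = ".bed")
  write_regions_bed(res, bed_path)
  bed <- readr::read_tsv(
    bed_path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    show_col_types = FALSE
  )
  expect_equal(bed$start, 99)
  expect_equal(bed$end, 250)
  expect_equal(bed$end - bed$start, res$retained$length)

  tsv_path <- tempfile(fileext = ".tsv")
  write_regions_tsv(res, tsv_path)
  tsv <- readr::read_tsv(tsv_path, show_col_types = FALSE)
  expect_named(tsv, c("region_id", "gene_id", "kind", "n_source_exons", "length"))
})
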