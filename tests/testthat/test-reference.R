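test_that("load_genome exposes lengths, sequence access and bounds", {
  fa <- write_fasta(list(chr1 = "ACGT", chr2 = "acgtacgtNN"))
  g <- load_genome(fa)
  expect_equal(unname(chrom_lengths(g)), c(4L, 10L))
  expect_equal(genome_seq(g, "chr1", 1, 3), "CG")
  # lowercase input is normalized to uppercase
  expect_equal(genome_seq(g, "chr2", 0, 5), "ACGTA")
  expect_equal(genome_seq(g, "chr2", 8, 10), "NN")
  expect_error(genome_seq(g, "chr1", 2, 9), "out of range")
  expect_error(genome_seq(g, "chrX", 0, 1), "unknown chromosome")
})

test_that("duplicate FASTA identifiers and empty files are fatal", {
  dup <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT", ">chr1", "GGGG"), dup)
  expect_error(load_genome(dup), "duplicate")
  empty <- tempfile(fileext = ".fa")
  writeLines(character(), empty)
  expect_error(load_genome(empty))
})

test_that("GFF3 coordinates convert to 0-based half-open and back", {
  fa <- write_fasta(list(chr1 = random_seq(300)))
  g <- load_genome(fa)
  rows <- c(
    gff_row("chr1", "gene", 1, 100, "+", "ID=g1"),
    gff_row("chr1", "mRNA", 1, 100, "+", "ID=t1;Parent=g1"),
    gff_row("chr1", "exon", 1, 60, "+", "Parent=t1"),
    gff_row("chr1", "exon", 81, 100, "+", "Parent=t1"),
    gff_row("chr1", "CDS", 11, 60, "+", "Parent=t1", "0"),
    gff_row("chr1", "CDS", 81, 90, "+", "Parent=t1", "2")
  )
  m <- load_gene_models(write_gff3(rows), g)
  expect_equal(nrow(m$transcripts), 1)
  expect_equal(m$genes$start0, 0L)
  expect_equal(m$genes$end0, 100L)
  tx <- m$transcripts
  # round-trip: internal 0-based half-open back to GFF3 1-based inclusive
  ex <- tx$exons[[1]]
  expect_equal(ex$start0 + 1L, c(1L, 81L))
  expect_equal(ex$end0, c(60L, 100L))
  cds <- tx$cds[[1]]
  expect_equal(cds$start0 + 1L, c(11L, 81L))
  expect_equal(cds$end0, c(60L, 90L))
})

test_that("UTRs derive as exonic-minus-CDS flanks, checked by enumeration", {
  fa <- write_fasta(list(chr1 = random_seq(300)))
  g <- load_genome(fa)
  rows <- c(
    gff_row("chr1", "gene", 1, 100, "+", "ID=g1"),
    gff_row("chr1", "mRNA", 1, 100, "+", "ID=t1;Parent=g1"),
    gff_row("chr1", "exon", 1, 60, "+", "Parent=t1"),
    gff_row("chr1", "exon", 81, 100, "+", "Parent=t1"),
    gff_row("chr1", "CDS", 11, 60, "+", "Parent=t1", "0"),
    gff_row("chr1", "CDS", 81, 90, "+", "Parent=t1", "2")
  )
  m <- load_gene_models(write_gff3(rows), g)
  tx <- m$transcripts
  # brute-force enumeration of exonic bases minus CDS bases (0-based)
  exonic <- c(0:59, 80:99)
  cds_b <- c(10:59, 80:89)
  non_cds <- setdiff(exonic, cds_b)
  utr5_b <- unlist(purrr::map2(tx$utr5[[1]]$start0, tx$utr5[[1]]$end0 - 1,
                               seq))
  utr3_b <- unlist(purrr::map2(tx$utr3[[1]]$start0, tx$utr3[[1]]$end0 - 1,
                               seq))
  expect_setequal(c(utr5_b, utr3_b), non_cds)
  # 5' side precedes CDS on the + strand
  expect_setequal(utr5_b, 0:9)
  expect_setequal(utr3_b, 90:99)
})

test_that("UTR sides swap on the minus strand", {
  fa <- write_fasta(list(chr1 = random_seq(300)))
  g <- load_genome(fa)
  rows <- c(
    gff_row("chr1", "gene", 1, 100, "-", "ID=g1"),
    gff_row("chr1", "mRNA", 1, 100, "-", "ID=t1;Parent=g1"),
    gff_row("chr1", "exon", 1, 100, "-", "Parent=t1"),
    gff_row("chr1", "CDS", 11, 90, "-", "Parent=t1", "2")
  )
  m <- load_gene_models(write_gff3(rows), g)
  tx <- m$transcripts
  expect_equal(tx$utr5[[1]], tibble::tibble(start0 = 90L, end0 = 100L))
  expect_equal(tx$utr3[[1]], tibble::tibble(start0 = 0L, end0 = 10L))
  # first CDS segment phase in transcription order (rightmost on -)
  expect_equal(tx$phase_first, 2L)
  expect_false(tx$complete)  # 80 bp CDS with phase 2
})

test_that("overlapping genes are both retained", {
  fa <- write_fasta(list(chr1 = random_seq(300)))
  g <- load_genome(fa)
  rows <- c(
    gff_row("chr1", "gene", 51, 150, "+", "ID=g1"),
    gff_row("chr1", "mRNA", 51, 150, "+", "ID=t1;Parent=g1"),
    gff_row("chr1", "exon", 51, 150, "+", "Parent=t1"),
    gff_row("chr1", "gene", 101, 200, "+", "ID=g2"),
    gff_row("chr1", "mRNA", 101, 200, "+", "ID=t2;Parent=g2"),
    gff_row("chr1", "exon", 101, 200, "+", "Parent=t2")
  )
  m <- load_gene_models(write_gff3(rows), g)
  expect_equal(nrow(m$genes), 2)
  expect_equal(sort(m$genes$gene_id), c("g1", "g2"))
})

test_that("transcripts with bad Parent or unknown chromosome are skipped", {
  fa <- write_fasta(list(chr1 = random_seq(300)))
  g <- load_genome(fa)
  rows <- c(
    gff_row("chr1", "gene", 1, 100, "+", "ID=g1"),
    gff_row("chr1", "mRNA", 1, 100, "+", "ID=t1"),          # no Parent
    gff_row("chr9", "gene", 1, 100, "+", "ID=g2"),
    gff_row("chr9", "mRNA", 1, 100, "+", "ID=t2;Parent=g2") # bad chrom
  )
  expect_warning(expect_warning(
    m <- load_gene_models(write_gff3(rows), g)))
  expect_equal(nrow(m$transcripts), 0)
})

test_that("CDS concatenation matches segment lengths on both strands", {
  for (i in 1:10) {
    toy <- withr::with_seed(i, random_toy_transcript())
    s <- transcript_cds_seq(toy$tx[1, ], toy$genome)
    expect_equal(nchar(s), toy$tx$cds_len)
    # complete toy CDS length is a multiple of 3
    expect_equal(nchar(s) %% 3, 0)
  }
})

test_that("gene cds_union_length counts shared bases once", {
  fa <- write_fasta(list(chr1 = random_seq(400)))
  g <- load_genome(fa)
  # two transcripts of one gene with overlapping CDS 21..80 and 51..110
  rows <- c(
    gff_row("chr1", "gene", 1, 200, "+", "ID=g1"),
    gff_row("chr1", "mRNA", 1, 150, "+", "ID=t1;Parent=g1"),
    gff_row("chr1", "exon", 1, 150, "+", "Parent=t1"),
    gff_row("chr1", "CDS", 21, 80, "+", "Parent=t1", "0"),
    gff_row("chr1", "mRNA", 1, 200, "+", "ID=t2;Parent=g1"),
    gff_row("chr1", "exon", 1, 200, "+", "Parent=t2"),
    gff_row("chr1", "CDS", 51, 110, "+", "Parent=t2", "0")
  )
  m <- load_gene_models(write_gff3(rows), g)
  # brute-force union of covered bases
  expect_equal(m$genes$cds_union_length, length(union(20:79, 50:109)))
})
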