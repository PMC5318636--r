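# hand-drawn fixture: one + gene at 10000, one - gene at 30000, 12-kb gap
annot_fixture <- function() {
  L <- 60000
  base <- random_seq(L, seed = 77)
  # + gene: utr5 10000..10049, CDS 10050..10949 (900 bp, one exon),
  # utr3 10950..11049
  cds_plus <- paste0("ATG", strrep("GCT", 298), "TAA")
  seq <- base
  substr(seq, 10001, 10050) <- strrep("C", 50)
  substr(seq, 10051, 10950) <- cds_plus
  substr(seq, 10951, 11050) <- strrep("G", 100)
  # - gene at 30000..31050 same layout, reverse-complemented
  body <- paste0(strrep("C", 50), cds_plus, strrep("G", 100))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(body)))
  substr(seq, 30001, 31050) <- rc
  fa <- write_fasta(list(chr1 = seq))
  g <- load_genome(fa)
  rows <- c(
    gff_row("chr1", "gene", 10001, 11050, "+", "ID=gA"),
    gff_row("chr1", "mRNA", 10001, 11050, "+", "ID=gA.t1;Parent=gA"),
    gff_row("chr1", "exon", 10001, 11050, "+", "Parent=gA.t1"),
    gff_row("chr1", "five_prime_UTR", 10001, 10050, "+", "Parent=gA.t1"),
    gff_row("chr1", "CDS", 10051, 10950, "+", "Parent=gA.t1", "0"),
    gff_row("chr1", "three_prime_UTR", 10951, 11050, "+", "Parent=gA.t1"),
    gff_row("chr1", "gene", 30001, 31050, "-", "ID=gB"),
    gff_row("chr1", "mRNA", 30001, 31050, "-", "ID=gB.t1;Parent=gB"),
    gff_row("chr1", "exon", 30001, 31050, "-", "Parent=gB.t1"),
    gff_row("chr1", "three_prime_UTR", 30001, 30100, "-", "Parent=gB.t1"),
    gff_row("chr1", "CDS", 30101, 31000, "-", "Parent=gB.t1", "0"),
    gff_row("chr1", "five_prime_UTR", 31001, 31050, "-", "Parent=gB.t1")
  )
  m <- load_gene_models(write_gff3(rows), g)
  list(genome = g, models = m, index = build_gene_index(m, g))
}

test_that("positional categories follow the flank and feature rules", {
  fx <- annot_fixture()
  rec <- variants("chr1",
                  c(5002, 10020, 10980, 16050, 23000, 31060, 36050),
                  ref = "A", alt = "G")
  rec$ref <- vapply(rec$pos1, function(p) genome_seq(fx$genome, "chr1",
                                                     p - 1, p), character(1))
  rec$alt <- ifelse(rec$ref == "A", "G", "A")
  eff <- annotate_variants(rec, fx$index, fx$genome)
  by_pos <- split(eff$category, eff$pos1)
  expect_equal(by_pos[["5002"]], "regulatory_up")      # 4999 bp before gA
  expect_equal(by_pos[["10020"]], "utr5")
  expect_equal(by_pos[["10980"]], "utr3")
  expect_equal(by_pos[["16050"]], "regulatory_down")   # just inside gA flank
  expect_equal(by_pos[["23000"]], "intergenic")        # >5 kb from both
  expect_equal(by_pos[["31060"]], "regulatory_up")     # upstream of - gene
  expect_equal(by_pos[["36050"]], "regulatory_up")     # wait: downstream?
})

test_that("codon-level classification matches the hand example", {
  fx <- annot_fixture()
  # + gene CDS starts at 1-based 10051: ATG GCT GCT ... codon2 = 10054..10056
  rec <- variants("chr1", c(10054, 10056), ref = c("G", "T"),
                  alt = c("A", "C"))
  eff <- annotate_variants(rec, fx$index, fx$genome)
  expect_equal(eff$category[eff$pos1 == 10054], "cds_nonsynonymous") # GCT->ACT
  expect_equal(eff$category[eff$pos1 == 10056], "cds_synonymous")    # GCT->GCC
  # same codon positions on the - strand gene: genomic 31000 is CDS base 1
  # codon2 first base (G) sits at genomic 30997..30995 reverse
  rec2 <- variants("chr1", c(30997, 30995), ref = c("C", "A"),
                   alt = c("T", "G"))
  eff2 <- annotate_variants(rec2, fx$index, fx$genome)
  expect_equal(eff2$category[eff2$pos1 == 30997], "cds_nonsynonymous")
  expect_equal(eff2$category[eff2$pos1 == 30995], "cds_synonymous")
})

test_that("one record per overlapping gene, intergenic never mixed in", {
  fx <- annot_fixture()
  # position in gA's downstream flank AND gB's downstream flank region?
  # 23000 is intergenic; 16000 only gA. Build a variant inside gA's body
  # that also lies in no other gene: exactly one record expected
  rec <- variants("chr1", c(10500, 23000), ref = "A", alt = "G")
  rec$ref <- vapply(rec$pos1, function(p) genome_seq(fx$genome, "chr1",
                                                     p - 1, p), character(1))
  rec$alt <- ifelse(rec$ref == "A", "G", "A")
  eff <- annotate_variants(rec, fx$index, fx$genome)
  expect_equal(nrow(eff), 2)
  expect_true(all(!is.na(eff$gene_id[eff$pos1 == 10500])))
  expect_true(is.na(eff$gene_id[eff$pos1 == 23000]))
  # every variant yields at least one record
  expect_setequal(unique(eff$pos1), rec$pos1)
})

test_that("a variant in two genes' territory yields two records", {
  # two overlapping genes: intron of A, upstream flank of B
  L <- 40000
  seq <- random_seq(L, seed = 78)
  fa <- write_fasta(list(chr1 = seq))
  g <- load_genome(fa)
  rows <- c(
    gff_row("chr1", "gene", 10001, 12000, "+", "ID=gA"),
    gff_row("chr1", "mRNA", 10001, 12000, "+", "ID=gA.t1;Parent=gA"),
    gff_row("chr1", "exon", 10001, 10300, "+", "Parent=gA.t1"),
    gff_row("chr1", "exon", 11701, 12000, "+", "Parent=gA.t1"),
    gff_row("chr1", "CDS", 10001, 10300, "+", "Parent=gA.t1", "0"),
    gff_row("chr1", "CDS", 11701, 12000, "+", "Parent=gA.t1", "0"),
    gff_row("chr1", "gene", 13001, 14000, "+", "ID=gB"),
    gff_row("chr1", "mRNA", 13001, 14000, "+", "ID=gB.t1;Parent=gB"),
    gff_row("chr1", "exon", 13001, 14000, "+", "Parent=gB.t1")
  )
  m <- load_gene_models(write_gff3(rows), g)
  idx <- build_gene_index(m, g)
  rec <- variants("chr1", 11000, ref = genome_seq(g, "chr1", 10999, 11000),
                  alt = "A")
  rec$alt <- ifelse(rec$ref == "A", "G", "A")
  eff <- annotate_variants(rec, idx, g)
  expect_equal(nrow(eff), 2)
  expect_equal(sort(eff$category),
               sort(c("intron", "regulatory_up")))
  expect_equal(eff$gene_id[eff$category == "intron"], "gA")
  expect_equal(eff$gene_id[eff$category == "regulatory_up"], "gB")
})

test_that("nonsynonymous outranks synonymous across transcripts of a gene", {
  # two transcripts sharing a CDS base in different frames
  L <- 20000
  seq <- random_seq(L, seed = 79)
  cds <- paste0("ATG", strrep("GCT", 30), "TAA")   # 96 bp
  substr(seq, 10001, 10096) <- cds
  fa <- write_fasta(list(chr1 = seq))
  g <- load_genome(fa)
  rows <- c(
    gff_row("chr1", "gene", 10001, 10096, "+", "ID=gA"),
    gff_row("chr1", "mRNA", 10001, 10096, "+", "ID=t1;Parent=gA"),
    gff_row("chr1", "exon", 10001, 10096, "+", "Parent=t1"),
    gff_row("chr1", "CDS", 10001, 10096, "+", "Parent=t1", "0"),
    # second transcript: same CDS shifted by one codon (frame preserved,
    # different codon boundaries relative to the variant below)
    gff_row("chr1", "mRNA", 10001, 10096, "+", "ID=t2;Parent=gA"),
    gff_row("chr1", "exon", 10001, 10096, "+", "Parent=t2"),
    gff_row("chr1", "CDS", 10005, 10094, "+", "Parent=t2", "0")
  )
  m <- load_gene_models(write_gff3(rows), g)
  idx <- build_gene_index(m, g)
  # third base of codon 2 of t1 (synonymous GCT->GCC there)
  rec <- variants("chr1", 10009, ref = "T", alt = "C")
  eff <- annotate_variants(rec, idx, g)
  expect_equal(nrow(eff), 1)
  # t1 says synonymous; t2 reads the same base in another frame -> if any
  # transcript calls it nonsynonymous, the gene record is nonsynonymous
  one_t1 <- classify_cds_snp(m$transcripts[m$transcripts$transcript_id ==
                                             "t1", ], 10009, "T", "C", idx)
  one_t2 <- classify_cds_snp(m$transcripts[m$transcripts$transcript_id ==
                                             "t2", ], 10009, "T", "C", idx)
  expect_equal(one_t1, "cds_synonymous")
  expect_equal(one_t2, "cds_nonsynonymous")
  expect_equal(eff$category, "cds_nonsynonymous")
})

test_that("CDS InDels and incomplete models classify as specified", {
  fx <- annot_fixture()
  rec <- variants("chr1", c(10500, 10500),
                  ref = c("AG", "A"), alt = c("A", "AGG"))
  rec$ref[1] <- genome_seq(fx$genome, "chr1", 10499, 10501)
  rec$ref[2] <- genome_seq(fx$genome, "chr1", 10499, 10500)
  rec$alt[2] <- paste0(rec$ref[2], "GG")
  rec$vtype <- varscape:::classify_vtype(rec$ref, rec$alt)
  eff <- annotate_variants(rec, fx$index, fx$genome)
  expect_true(all(eff$category == "cds_indel"))
})

test_that("classify_cds_snp agrees with the full-translation oracle", {
  set.seed(43)
  n_ok <- 0
  for (i in 1:250) {
    toy <- random_toy_transcript()
    models <- list(transcripts = toy$tx,
                   genes = tibble::tibble(
                     gene_id = "toy", chrom = "chrT", strand = toy$tx$strand,
                     start0 = toy$tx$start0, end0 = toy$tx$end0,
                     cds_union_length = toy$tx$cds_len))
    idx <- build_gene_index(models, toy$genome, flank_bp = 0L)
    cds <- toy$tx$cds[[1]]
    # pick a random CDS base and a random different alt
    seg <- cds[sample.int(nrow(cds), 1), ]
    pos1 <- sample(seq(seg$start0 + 1, seg$end0), 1)
    ref_b <- genome_seq(toy$genome, "chrT", pos1 - 1, pos1)
    alt_b <- sample(setdiff(c("A", "C", "G", "T"), ref_b), 1)
    got <- classify_cds_snp(toy$tx[1, ], pos1, ref_b, alt_b, idx)
    want <- oracle_classify_snp(toy$genome, toy$tx[1, ], pos1, alt_b)
    expect_equal(got, want,
                 info = sprintf("i=%d strand=%s pos=%d %s>%s", i,
                                toy$tx$strand, pos1, ref_b, alt_b))
    n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 250)
})

test_that("published category counts reproduce the printed percentages", {
  mk_effects <- function(sample_id, intergenic, intron_reg, utrs, nonsyn,
                         syn) {
    tibble::tibble(
      sample_id = sample_id,
      category = c(rep("intergenic", intergenic),
                   rep("intron", intron_reg),
                   rep("utr5", utrs),
                   rep("cds_nonsynonymous", nonsyn),
                   rep("cds_synonymous", syn)))
  }
  r2 <- function(x) varscape:::round_half_up(x, 2)
  s12 <- summarize_effects(mk_effects("indica_12", 1374419, 288375, 85749,
                                      151998, 107286))
  expect_equal(r2(s12$pct_intergenic), 68.45)
  expect_equal(r2(s12$pct_nonsynonymous), 58.62)
  s13 <- summarize_effects(mk_effects("indica_13", 1329647, 279350, 82611,
                                      131754, 90790))
  expect_equal(r2(s13$pct_intergenic), 69.46)
  s11 <- summarize_effects(mk_effects("japonica_11", 488888, 109191, 29587,
                                      66645, 45343))
  expect_equal(r2(s11$pct_genic), 33.90)
  s14 <- summarize_effects(mk_effects("japonica_14", 454811, 101187, 28138,
                                      63962, 42817))
  expect_equal(r2(s14$pct_nonsynonymous), 59.90)
  # degenerate cases
  one <- summarize_effects(tibble::tibble(sample_id = "s",
                                          category = "intergenic"))
  expect_equal(one$pct_intergenic, 100)
  empty <- summarize_effects(tibble::tibble(sample_id = character(),
                                            category = character()))
  expect_equal(nrow(empty), 0)
})

test_that("reference-allele mismatches are tallied but classified", {
  fx <- annot_fixture()
  true_base <- genome_seq(fx$genome, "chr1", 10499, 10500)
  wrong <- setdiff(c("A", "C", "G", "T"), true_base)[1]
  rec <- variants("chr1", 10500, ref = wrong,
                  alt = setdiff(c("A", "C", "G", "T"), wrong)[1])
  expect_warning(eff <- annotate_variants(rec, fx$index, fx$genome),
                 "reference")
  expect_equal(attr(eff, "n_ref_mismatch"), 1L)
  expect_match(eff$category, "^cds_")
})
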