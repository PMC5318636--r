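# simulation-based tests use one small shared dataset to keep the suite fast
sim_env <- new.env()
get_small_sim <- function() {
  if (is.null(sim_env$sim)) {
    dir <- file.path(tempdir(), "varscape_sim_small")
    sim_env$sim <- simulate_dataset(small_sim_config(), dir)
  }
  sim_env$sim
}

test_that("the reference generator is deterministic and structurally valid", {
  cfg <- sim_config(n_chromosomes = 1L, chrom_length = 60000L, n_genes = 6L,
                    deserts = tibble::tibble(chrom = character(),
                                             start0 = integer(),
                                             end0 = integer(),
                                             multiplier = double()),
                    n_hot_genes = 2L, seed = 5L)
  d1 <- file.path(tempdir(), "ref_a")
  d2 <- file.path(tempdir(), "ref_b")
  r1 <- generate_reference(cfg, d1)
  r2 <- generate_reference(cfg, d2)
  expect_identical(readLines(r1$fasta), readLines(r2$fasta))
  expect_identical(readLines(r1$gff3), readLines(r2$gff3))
  # every emitted CDS starts ATG, ends on a stop, no internal stop
  m <- load_gene_models(r1$gff3, r1$genome)
  expect_equal(nrow(m$transcripts), 6)
  expect_true(all(m$transcripts$complete))
  for (i in seq_len(nrow(m$transcripts))) {
    cds <- transcript_cds_seq(m$transcripts[i, ], r1$genome)
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_equal(substr(prot, nchar(prot), nchar(prot)), "*")
    expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)))
  }
})

test_that("a gene-free configuration yields an empty GFF3 body", {
  cfg <- sim_config(n_chromosomes = 1L, chrom_length = 20000L, n_genes = 0L,
                    deserts = tibble::tibble(chrom = character(),
                                             start0 = integer(),
                                             end0 = integer(),
                                             multiplier = double()),
                    n_hot_genes = 0L, seed = 5L)
  r <- generate_reference(cfg, file.path(tempdir(), "ref_nogene"))
  body <- grep("^[^#]", readLines(r$gff3), value = TRUE)
  expect_equal(length(body), 0)
})

test_that("genes that cannot fit are a clear fatal error", {
  cfg <- sim_config(n_chromosomes = 1L, chrom_length = 5000L, n_genes = 10L,
                    deserts = tibble::tibble(chrom = character(),
                                             start0 = integer(),
                                             end0 = integer(),
                                             multiplier = double()),
                    seed = 5L)
  expect_error(generate_reference(cfg, tempdir()), "fit")
})

test_that("planted SNP counts follow the configured Poisson rate", {
  # flat-rate configuration so the pure Poisson oracle applies
  cfg <- sim_config(
    n_chromosomes = 1L, chrom_length = 2000000L, n_genes = 0L,
    groups = list(g = "s1"), snp_rate_per_kb = c(g = 7.7),
    shared_fraction = 0, rate_profile_sd = 0, fail_fraction = 0,
    deserts = tibble::tibble(chrom = character(), start0 = integer(),
                             end0 = integer(), multiplier = double()),
    n_hot_genes = 0L, seed = 13L)
  ref <- generate_reference(cfg, file.path(tempdir(), "flat"))
  rec <- simulate_sample_variants(cfg, ref, "s1")
  n_snp <- sum(rec$vtype == "SNP")
  lambda <- 7.7 / 1000 * 2000000
  expect_lt(abs(n_snp - lambda), 3 * sqrt(lambda))
  # transition fraction within 3 s.e. of p_transition
  cls <- classify_base_change(rec$ref[rec$vtype == "SNP"],
                              rec$alt[rec$vtype == "SNP"])
  p_hat <- mean(cls$class == "transition")
  expect_lt(abs(p_hat - 0.70), 3 * sqrt(0.7 * 0.3 / n_snp))
})

test_that("a zero-multiplier desert contains no planted SNPs", {
  cfg <- sim_config(
    n_chromosomes = 1L, chrom_length = 500000L, n_genes = 0L,
    groups = list(g = "s1"), snp_rate_per_kb = c(g = 7.7),
    rate_profile_sd = 0, n_hot_genes = 0L,
    deserts = tibble::tibble(chrom = "chr1", start0 = 200000L,
                             end0 = 300000L, multiplier = 0),
    seed = 17L)
  ref <- generate_reference(cfg, file.path(tempdir(), "zdesert"))
  rec <- simulate_sample_variants(cfg, ref, "s1")
  snp <- rec[rec$vtype == "SNP", ]
  expect_equal(sum(snp$pos1 > 200000 & snp$pos1 <= 300000), 0)
  expect_gt(nrow(snp), 0)
})

test_that("simulation is deterministic with per-sample substreams", {
  cfg <- small_sim_config(seed = 19L)
  ref <- generate_reference(cfg, file.path(tempdir(), "det"))
  a <- simulate_sample_variants(cfg, ref, "indica_1")
  b <- simulate_sample_variants(cfg, ref, "indica_1")
  expect_identical(a, b)
  c_ <- simulate_sample_variants(cfg, ref, "indica_2")
  # same group: shared pool identical, private variants differ
  shared_a <- a[a$shared, c("chrom", "pos1", "ref", "alt")]
  shared_c <- c_[c_$shared, c("chrom", "pos1", "ref", "alt")]
  expect_gt(nrow(dplyr::inner_join(shared_a, shared_c,
                                   by = c("chrom", "pos1", "ref", "alt"))),
            0.9 * min(nrow(shared_a), nrow(shared_c)))
  expect_false(identical(a$pos1, c_$pos1))
})

test_that("emitted VCFs round-trip through read_vcf and conserve truth", {
  sim <- get_small_sim()
  for (s in c("indica_1", "japonica_1")) {
    truth_s <- sim$truth$variants %>% dplyr::filter(sample_id == s)
    v <- read_vcf(sim$vcfs[[s]], s)
    expect_equal(nrow(v), nrow(truth_s))
    expect_equal(attr(v, "n_malformed"), 0L)
    tv <- dplyr::arrange(truth_s, chrom, pos1, alt)
    vv <- dplyr::arrange(v, chrom, pos1, alt)
    expect_equal(vv$pos1, tv$pos1)
    expect_equal(vv$ref, tv$ref)
    expect_equal(vv$alt, tv$alt)
    expect_equal(vv$vaf, tv$vaf, tolerance = 1e-4)
  }
})

test_that("records planted to fail the filter do fail, and only those", {
  sim <- get_small_sim()
  s <- "indica_1"
  truth_s <- sim$truth$variants %>% dplyr::filter(sample_id == s)
  v <- read_vcf(sim$vcfs[[s]], s)
  kept <- filter_variants(v)
  expect_equal(nrow(kept), sum(truth_s$planted_pass))
  planted_fail <- truth_s %>% dplyr::filter(!planted_pass)
  kept_key <- paste(kept$pos1, kept$alt)
  expect_false(any(paste(planted_fail$pos1, planted_fail$alt) %in% kept_key))
})

test_that("truth categories agree with the annotator per (variant, gene)", {
  sim <- get_small_sim()
  models <- load_gene_models(sim$gff3, sim$genome)
  idx <- build_gene_index(models, sim$genome)
  tv <- sim$truth$variants %>% dplyr::filter(sample_id == "japonica_1")
  eff <- annotate_variants(tv, idx, sim$genome)
  key <- function(d) paste(d$chrom, d$pos1, d$ref, d$alt)
  eff$gkey <- ifelse(is.na(eff$gene_id), "none", eff$gene_id)
  tv$gkey <- ifelse(is.na(tv$gene_id), "none", tv$gene_id)
  m <- dplyr::inner_join(
    tv %>% dplyr::select(chrom, pos1, ref, alt, gkey, category),
    eff %>% dplyr::select(chrom, pos1, ref, alt, gkey, category),
    by = c("chrom", "pos1", "ref", "alt", "gkey"),
    suffix = c("_truth", "_ann"))
  # every planted variant has an annotator record for its truth gene
  expect_equal(nrow(m), nrow(tv))
  expect_gte(mean(m$category_truth == m$category_ann), 0.99)
})

test_that("truth_report writes consistent machine-readable files", {
  sim <- get_small_sim()
  out <- file.path(tempdir(), "truth_rep")
  paths <- truth_report(sim$truth, out)
  expect_true(all(file.exists(unlist(paths))))
  tv <- readr::read_tsv(file.path(out, "truth_variants.tsv"),
                        show_col_types = FALSE)
  expect_equal(nrow(tv), nrow(sim$truth$variants))
  groups <- readr::read_tsv(file.path(out, "truth_groups.tsv"),
                            show_col_types = FALSE)
  expect_setequal(groups$sample_id, names(sim$vcfs))
  bed <- readLines(file.path(out, "truth_deserts.bed"))
  expect_equal(length(bed), nrow(sim$truth$deserts))
})

test_that("group densities differ by the configured ratio on average", {
  sim <- get_small_sim()
  counts <- sim$truth$variants %>%
    dplyr::filter(vtype == "SNP") %>%
    dplyr::count(sample_id) %>%
    dplyr::left_join(sim$truth$groups, by = "sample_id") %>%
    dplyr::group_by(group) %>%
    dplyr::summarise(mean_n = mean(n))
  ratio <- counts$mean_n[counts$group == "indica_like"] /
    counts$mean_n[counts$group == "japonica_like"]
  # 7.7 / 3.0 with group-level landscape noise
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 4.1)
})
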