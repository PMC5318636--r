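# Shared fixtures: tiny genomes, hand-drawn gene models, and independent
# oracles used across the suite. Everything is built in code at test time.

write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  }
  path
}

# A deterministic random chromosome (fixed local seed, no RNG leakage).
random_seq <- function(n, seed = 99) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = ""))
}

write_gff3 <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

gff_row <- function(chrom, type, start1, end1, strand, attrs, phase = ".") {
  sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t%s\t%s", chrom, type, start1, end1,
          strand, phase, attrs)
}

# variant tibble constructor with passing quality values by default
variants <- function(chrom, pos1, ref, alt, sample_id = "s1",
                     mapq = 50, depth = 30, base_qual = 35, vaf = 0.9) {
  n <- length(pos1)
  tibble::tibble(
    sample_id = rep_len(sample_id, n), chrom = rep_len(chrom, n),
    pos1 = as.integer(pos1), ref = ref, alt = alt,
    vtype = varscape:::classify_vtype(ref, alt),
    mapq = rep_len(mapq, n), depth = rep_len(depth, n),
    base_qual = rep_len(base_qual, n), vaf = rep_len(vaf, n))
}

# --- independent oracles -------------------------------------------------

# Full-protein translation oracle: rebuild the entire coding sequence with
# the variant applied at the genomic level, then translate both proteins
# with Biostrings and compare.
oracle_classify_snp <- function(genome, transcript, pos1, alt) {
  chrom_seq <- as.character(genome$seq[[transcript$chrom]])
  mut_chrom <- chrom_seq
  substr(mut_chrom, pos1, pos1) <- alt
  build_cds <- function(chseq) {
    cds <- transcript$cds[[1]]
    cds <- cds[order(cds$start0), ]
    s <- paste(substring(chseq, cds$start0 + 1, cds$end0), collapse = "")
    if (transcript$strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }
  ref_p <- as.character(Biostrings::translate(
    Biostrings::DNAString(build_cds(chrom_seq)), no.init.codon = TRUE))
  alt_p <- as.character(Biostrings::translate(
    Biostrings::DNAString(build_cds(mut_chrom)), no.init.codon = TRUE))
  if (identical(ref_p, alt_p)) "cds_synonymous" else "cds_nonsynonymous"
}

# Exhaustive maximal-run scan for deserts: test every window, walk runs.
oracle_desert_scan <- function(counts, widths, threshold_per_kb = 1) {
  qual <- counts < threshold_per_kb * widths / 1000
  runs <- list()
  i <- 1
  n <- length(qual)
  while (i <= n) {
    if (qual[i]) {
      j <- i
      while (j < n && qual[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  runs
}

# Textbook Pearson r computed from first principles.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Second implementation of Tukey hinges, written directly from the
# half-with-median definition.
oracle_tukey <- function(v) {
  v <- sort(v)
  n <- length(v)
  med_of <- function(u) {
    m <- length(u)
    if (m %% 2 == 1) u[(m + 1) / 2] else (u[m / 2] + u[m / 2 + 1]) / 2
  }
  lower <- v[seq_len(ceiling(n / 2))]
  upper <- v[seq(n - ceiling(n / 2) + 1, n)]
  list(q1 = med_of(lower), q3 = med_of(upper))
}

# Random toy transcript on a fresh tiny genome, for translation-oracle
# tests: 2-3 exons, either strand, valid complete CDS.
random_toy_transcript <- function() {
  n_ex <- sample(2:3, 1)
  cds_lens <- sample(c(6L, 9L, 12L, 15L), n_ex, replace = TRUE)
  total <- sum(cds_lens)
  rem <- (3L - total %% 3L) %% 3L
  cds_lens[n_ex] <- cds_lens[n_ex] + rem
  strand <- sample(c("+", "-"), 1)
  intron <- 7L
  margin <- 10L
  # lay CDS segments with introns between, inside a random chromosome
  starts <- integer(n_ex)
  pos <- margin
  for (i in seq_len(n_ex)) {
    starts[i] <- pos
    pos <- pos + cds_lens[i] + intron
  }
  L <- pos + margin
  chseq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
  fa <- write_fasta(list(chrT = chseq))
  genome <- varscape::load_genome(fa)
  cds_tb <- tibble::tibble(start0 = starts, end0 = starts + cds_lens,
                           phase = 0L)
  empty_iv <- cds_tb[0, c("start0", "end0")]
  tx <- tibble::tibble(
    transcript_id = "toy.t1", gene_id = "toy", chrom = "chrT",
    strand = strand, start0 = min(cds_tb$start0), end0 = max(cds_tb$end0),
    cds_len = sum(cds_lens), phase_first = 0L, complete = TRUE,
    exons = list(cds_tb[, c("start0", "end0")]), cds = list(cds_tb),
    utr5 = list(empty_iv), utr3 = list(empty_iv))
  list(genome = genome, tx = tx)
}

# Small simulation config reused by recovery tests (kept modest so the
# suite stays fast; the acceptance checks use the full defaults).
small_sim_config <- function(seed = 11L, ...) {
  varscape::sim_config(
    n_chromosomes = 1L, chrom_length = 1000000L, n_genes = 60L,
    deserts = tibble::tibble(chrom = "chr1", start0 = 600000L,
                             end0 = 800000L, multiplier = 0.05),
    n_hot_genes = 5L, seed = seed, ...)
}
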