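#' Configuration for the synthetic variant-landscape simulator
#'
#' The defaults emulate the statistical structure of a two-subspecies rice
#' resequencing panel: two sample groups whose SNP densities differ about
#' 2.5-fold (7.7 vs 3.0 SNPs/kb), strong within-group sharing of variants
#' (80% of each sample's variants drawn from a group-shared pool), a
#' transition bias of p = 0.70 (expected Ts/Tv = 7/3 ≈ 2.33), geometric
#' InDel lengths dominated by mononucleotides (p = 0.55), planted
#' low-density intervals that downstream desert detection should recover,
#' and a small set of "hot" genes with elevated nonsynonymous SNP density
#' for outlier-gene recovery.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param n_genes Genes per chromosome, placed without overlap on
#'   alternating strands.
#' @param exons_per_gene,cds_len,intron_len,utr5_len,utr3_len Gene structure
#'   in bp; `cds_len` must be a positive multiple of 3.
#' @param groups Named list: group name -> character vector of sample names.
#' @param snp_rate_per_kb Named numeric, SNP rate per kb per group.
#' @param shared_fraction Fraction of each sample's variants drawn from its
#'   group's shared pool, in `[0,1]`.
#' @param rate_profile_sd Standard deviation (log scale) of the group-level
#'   SNP rate profile: each group gets its own mean-one log-normal rate
#'   multiplier per `profile_block_bp` block, giving the two subspecies
#'   distinct polymorphism landscapes along the genome — within-group
#'   windowed densities then correlate near one and between-group near
#'   zero, the qualitative pattern real panels show. Set 0 to disable.
#' @param profile_block_bp Block size of the rate profile.
#' @param p_transition Probability that a SNP is a transition.
#' @param indel_rate_per_kb InDel rate per kb (all groups).
#' @param p_deletion Probability an InDel is a deletion rather than an
#'   insertion (deletions slightly outnumber insertions in resequencing
#'   panels).
#' @param indel_p_geom Geometric parameter of InDel length (length =
#'   1 + Geom(p)); `p = 0.55` makes ~55% of InDels mononucleotide.
#' @param deserts Tibble `chrom, start0, end0, multiplier` of planted
#'   low-rate intervals (SNP rate multiplied inside).
#' @param n_hot_genes Number of genes whose CDS SNP rate is amplified.
#' @param hot_multiplier CDS SNP rate multiplier inside hot genes.
#' @param fail_fraction Fraction of emitted records deliberately given a
#'   failing quality field, to exercise variant filtering end-to-end.
#' @param seed Master seed; every stage derives its own substream from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 2L,
                       chrom_length = 2000000L,
                       n_genes = 250L,
                       exons_per_gene = 3L,
                       cds_len = 900L,
                       intron_len = 150L,
                       utr5_len = 60L,
                       utr3_len = 90L,
                       groups = list(
                         indica_like = c("indica_1", "indica_2", "indica_3"),
                         japonica_like = c("japonica_1", "japonica_2")),
                       snp_rate_per_kb = c(indica_like = 7.7,
                                           japonica_like = 3.0),
                       shared_fraction = 0.8,
                       rate_profile_sd = 0.6,
                       profile_block_bp = 100000L,
                       p_transition = 0.70,
                       indel_rate_per_kb = 1.0,
                       p_deletion = 0.55,
                       indel_p_geom = 0.55,
                       deserts = tibble(chrom = "chr1", start0 = 1200000L,
                                        end0 = 1500000L, multiplier = 0.05),
                       n_hot_genes = 10L,
                       hot_multiplier = 5,
                       fail_fraction = 0.05,
                       seed = 1L) {
  stopifnot(cds_len > 0, cds_len %% 3 == 0, exons_per_gene >= 1,
            shared_fraction >= 0, shared_fraction <= 1,
            p_transition >= 0, p_transition <= 1,
            all(snp_rate_per_kb >= 0), indel_rate_per_kb >= 0,
            all(names(groups) %in% names(snp_rate_per_kb)))
  if (nrow(deserts) > 0) {
    stopifnot(all(deserts$start0 >= 0), all(deserts$end0 <= chrom_length),
              all(deserts$multiplier >= 0))
  }
  structure(as.list(environment()), class = "sim_config")
}

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

rand_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Split the CDS across exons into near-equal chunks.
cds_chunks <- function(cds_len, k) {
  base <- cds_len %/% k
  sizes <- rep(base, k)
  extra <- cds_len - base * k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

# Transcription-order segment table for the fixed gene architecture:
# [utr5 + cds1] intron [cds2] intron ... [cds_k + utr3]
gene_segments <- function(cfg) {
  k <- cfg$exons_per_gene
  chunks <- cds_chunks(cfg$cds_len, k)
  segs <- list(tibble(type = "utr5", len = cfg$utr5_len))
  for (i in seq_len(k)) {
    segs[[length(segs) + 1]] <- tibble(type = "cds", len = chunks[i])
    if (i < k) {
      segs[[length(segs) + 1]] <- tibble(type = "intron",
                                         len = cfg$intron_len)
    }
  }
  segs[[length(segs) + 1]] <- tibble(type = "utr3", len = cfg$utr3_len)
  out <- bind_rows(segs) %>% filter(.data$len > 0)
  out$t_start <- cumsum(c(0L, out$len))[seq_len(nrow(out))]
  out$t_end <- out$t_start + out$len
  cds_rows <- out$type == "cds"
  out$cds_off <- NA_integer_
  out$cds_off[cds_rows] <-
    cumsum(c(0L, out$len[cds_rows]))[seq_len(sum(cds_rows))]
  out
}

# Map a transcription-order interval [a,b) of a gene to genomic 0-based
# half-open coordinates. The minus strand reverses the gene body.
tx2genomic <- function(a, b, gstart, glen, strand) {
  if (strand == "-") c(gstart + glen - b, gstart + glen - a)
  else c(gstart + a, gstart + b)
}

#' Generate a synthetic reference genome and gene models
#'
#' Builds i.i.d. uniform A/C/G/T chromosomes, then stamps non-overlapping
#' genes on alternating strands into them. Every gene has a fixed
#' architecture (UTR5, CDS split over exons by introns, UTR3); its CDS
#' starts with ATG, ends with a stop codon, contains no internal stop, and
#' its length is a multiple of 3, so every emitted model is complete and
#' translatable. Hot genes (elevated nonsynonymous rate targets) are chosen
#' here so all samples share them. Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param dir Directory to write `reference.fa` and `genes.gff3` into.
#' @return List: `fasta`, `gff3` (paths), `genome` (a `genome_ref`),
#'   `gene_map` (internal per-gene bookkeeping used for ground-truth
#'   labels), `hot_genes` (character vector).
#' @export
generate_reference <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(derive_seed(cfg$seed, "reference"))
  segs <- gene_segments(cfg)
  glen <- sum(segs$len)
  L <- cfg$chrom_length
  free <- L - cfg$n_genes * glen
  if (cfg$n_genes > 0 && free < cfg$n_genes) {
    abort(sprintf(
      "genes do not fit: need >= %d bp per chromosome, have %d",
      cfg$n_genes * (glen + 1), L))
  }

  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  seq_list <- list()
  gene_map <- list()
  gff <- c("##gff-version 3")
  sense <- sense_codons()
  stops <- c("TAA", "TAG", "TGA")

  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    chseq <- rand_bases(L)
    gff <- c(gff, sprintf("##sequence-region %s 1 %d", ch, L))
    if (cfg$n_genes > 0) {
      u <- sort(sample.int(free - 1L, cfg$n_genes))
      starts <- u + (seq_len(cfg$n_genes) - 1L) * glen
      for (gi in seq_len(cfg$n_genes)) {
        gene_id <- sprintf("%s_g%03d", ch, gi)
        strand <- if (gi %% 2 == 1) "+" else "-"
        gstart <- starts[gi]

        n_codons <- cfg$cds_len %/% 3L
        cds_seq <- paste0(
          "ATG",
          paste(sample(sense, n_codons - 2L, replace = TRUE), collapse = ""),
          sample(stops, 1))
        # transcription-order genomic sequence of the whole gene body
        tseq <- character(nrow(segs))
        for (si in seq_len(nrow(segs))) {
          s <- segs[si, ]
          tseq[si] <- switch(s$type,
            cds = substr(cds_seq, s$cds_off + 1L, s$cds_off + s$len),
            rand_bases(s$len))
        }
        body <- paste(tseq, collapse = "")
        if (strand == "-") body <- revcomp(body)
        substr(chseq, gstart + 1L, gstart + glen) <- body

        gene_map[[gene_id]] <- list(
          gene_id = gene_id, chrom = ch, strand = strand,
          gstart = gstart, glen = glen, segs = segs, cds_seq = cds_seq)
        gff <- c(gff, gene_gff_rows(gene_id, ch, strand, gstart, glen, segs))
      }
    }
    seq_list[[ch]] <- chseq
  }

  fasta <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(seq_list)), fasta, width = 70)
  gff3 <- file.path(dir, "genes.gff3")
  writeLines(gff, gff3)

  all_genes <- names(gene_map)
  # genes inside a planted desert cannot carry a realized hot effect (the
  # desert override wins), so they are not eligible
  if (!is.null(cfg$deserts) && nrow(cfg$deserts) > 0 &&
      length(all_genes) > 0) {
    in_desert <- purrr::map_lgl(gene_map, function(gm) {
      any(cfg$deserts$chrom == gm$chrom &
            cfg$deserts$start0 < gm$gstart + gm$glen &
            cfg$deserts$end0 > gm$gstart)
    })
    all_genes <- all_genes[!in_desert]
  }
  hot <- character()
  if (cfg$n_hot_genes > 0 && length(all_genes) > 0) {
    set.seed(derive_seed(cfg$seed, "hot_genes"))
    hot <- sort(sample(all_genes, min(cfg$n_hot_genes, length(all_genes))))
  }
  list(fasta = fasta, gff3 = gff3, genome = load_genome(fasta),
       gene_map = gene_map, hot_genes = hot)
}

gene_gff_rows <- function(gene_id, ch, strand, gstart, glen, segs) {
  tx_id <- paste0(gene_id, ".t1")
  row <- function(type, g, attrs, phase = ".") {
    sprintf("%s\tvarscape_sim\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            ch, type, as.integer(g[1]) + 1L, as.integer(g[2]), strand,
            phase, attrs)
  }
  lines <- c(
    row("gene", c(gstart, gstart + glen), paste0("ID=", gene_id)),
    row("mRNA", c(gstart, gstart + glen),
        paste0("ID=", tx_id, ";Parent=", gene_id))
  )
  # exons = maximal runs of non-intron segments
  is_ex <- segs$type != "intron"
  r <- rle(is_ex)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    a <- segs$t_start[starts[k]]
    b <- segs$t_end[ends[k]]
    g <- tx2genomic(a, b, gstart, glen, strand)
    lines <- c(lines, row("exon", g, paste0("Parent=", tx_id)))
  }
  for (si in seq_len(nrow(segs))) {
    s <- segs[si, ]
    if (s$type == "intron") next
    g <- tx2genomic(s$t_start, s$t_end, gstart, glen, strand)
    type <- switch(s$type, utr5 = "five_prime_UTR",
                   utr3 = "three_prime_UTR", cds = "CDS")
    phase <- if (s$type == "cds") {
      as.character((3L - s$cds_off %% 3L) %% 3L)
    } else "."
    lines <- c(lines, row(type, g, paste0("Parent=", tx_id), phase))
  }
  lines
}

# Piecewise-constant SNP rate over one chromosome: rate-profile and
# hot-gene multipliers compound; planted deserts override everything inside
# them (a desert is a fixed known-rate interval by construction). Returns
# tibble(start0, end0, mult).
rate_segments <- function(L, mult_intervals = NULL, override_intervals = NULL) {
  bp <- c(0L, L)
  for (iv in list(mult_intervals, override_intervals)) {
    if (!is.null(iv) && nrow(iv) > 0) bp <- c(bp, iv$start0, iv$end0)
  }
  bp <- sort(unique(bp[bp >= 0 & bp <= L]))
  out <- tibble(start0 = bp[-length(bp)], end0 = bp[-1], mult = 1)
  if (!is.null(mult_intervals) && nrow(mult_intervals) > 0) {
    for (i in seq_len(nrow(mult_intervals))) {
      hit <- out$start0 >= mult_intervals$start0[i] &
        out$end0 <= mult_intervals$end0[i]
      out$mult[hit] <- out$mult[hit] * mult_intervals$multiplier[i]
    }
  }
  if (!is.null(override_intervals) && nrow(override_intervals) > 0) {
    for (i in seq_len(nrow(override_intervals))) {
      hit <- out$start0 >= override_intervals$start0[i] &
        out$end0 <= override_intervals$end0[i]
      out$mult[hit] <- override_intervals$multiplier[i]
    }
  }
  out
}

# Group-level SNP-rate landscape: mean-one log-normal multiplier per block,
# deterministic given (seed, group, chromosome).
group_rate_profile <- function(cfg, L, group, ch) {
  if (cfg$rate_profile_sd <= 0) return(NULL)
  set.seed(derive_seed(cfg$seed, paste0("profile|", group, "|", ch)))
  nb <- ceiling(L / cfg$profile_block_bp)
  start0 <- as.integer((seq_len(nb) - 1L) * cfg$profile_block_bp)
  tibble(start0 = start0,
         end0 = as.integer(pmin(start0 + cfg$profile_block_bp, L)),
         multiplier = exp(stats::rnorm(nb, -cfg$rate_profile_sd^2 / 2,
                                       cfg$rate_profile_sd)))
}

# Poisson-process draw of distinct positions (1-based) under a piecewise
# rate (per bp).
draw_positions <- function(rate_per_bp, segments) {
  pos <- integer()
  for (i in seq_len(nrow(segments))) {
    w <- segments$end0[i] - segments$start0[i]
    lambda <- w * rate_per_bp * segments$mult[i]
    if (lambda <= 0 || w <= 0) next
    n <- stats::rpois(1, lambda)
    if (n == 0) next
    n <- min(n, w)
    pos <- c(pos, segments$start0[i] + sample.int(w, n))
  }
  sort(pos)
}

transition_of <- c(A = "G", G = "A", C = "T", T = "C")
transversions_of <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

draw_alt <- function(ref, p_transition) {
  is_ts <- stats::runif(length(ref)) < p_transition
  alt <- character(length(ref))
  alt[is_ts] <- transition_of[ref[is_ts]]
  if (any(!is_ts)) {
    pick <- stats::runif(sum(!is_ts)) < 0.5
    tv <- purrr::map2_chr(ref[!is_ts], pick, function(b, first) {
      transversions_of[[b]][if (first) 1 else 2]
    })
    alt[!is_ts] <- tv
  }
  alt
}

# Draw the SNP/indel pool for one rate multiplier map; alt alleles and indel
# shapes are drawn here so a shared pool is identical across the samples
# that inherit it.
draw_pool <- function(cfg, ref, chrom, snp_rate_kb, indel_rate_kb,
                      profile = NULL) {
  lens <- chrom_lengths(ref$genome)
  mods <- list()
  if (!is.null(profile) && nrow(profile) > 0) {
    mods[[1]] <- profile
  }
  # hot-gene CDS and planted deserts are overrides (desert wins), so the
  # planted effect sizes are realized regardless of the landscape profile
  overrides <- list()
  if (length(ref$hot_genes) > 0 && cfg$hot_multiplier != 1) {
    hot_cds <- purrr::map(ref$hot_genes, function(g) {
      gm <- ref$gene_map[[g]]
      if (gm$chrom != chrom) return(NULL)
      cds <- gm$segs %>% filter(.data$type == "cds")
      purrr::map2(cds$t_start, cds$t_end, function(a, b) {
        gi <- tx2genomic(a, b, gm$gstart, gm$glen, gm$strand)
        tibble(start0 = gi[1], end0 = gi[2],
               multiplier = cfg$hot_multiplier)
      }) %>% bind_rows()
    }) %>% bind_rows()
    if (nrow(hot_cds) > 0) overrides[[length(overrides) + 1]] <- hot_cds
  }
  if (!is.null(cfg$deserts) && nrow(cfg$deserts) > 0) {
    overrides[[length(overrides) + 1]] <- cfg$deserts %>%
      filter(.data$chrom == !!chrom) %>%
      select("start0", "end0", "multiplier")
  }
  segs <- rate_segments(unname(lens[chrom]), bind_rows(mods),
                        override_intervals = bind_rows(overrides))

  snp_pos <- draw_positions(snp_rate_kb / 1000, segs)
  snp_ref <- chr_bases(ref$genome, chrom, snp_pos)
  snp <- tibble(chrom = chrom, pos1 = snp_pos, ref = snp_ref,
                alt = draw_alt(snp_ref, cfg$p_transition), vtype = "SNP")

  flat <- tibble(start0 = 0L, end0 = unname(lens[chrom]), mult = 1)
  ind_pos <- draw_positions(indel_rate_kb / 1000, flat)
  ind_pos <- ind_pos[ind_pos < lens[chrom] - 50]  # room for deletions
  n <- length(ind_pos)
  if (n > 0) {
    is_del <- stats::runif(n) < cfg$p_deletion
    len <- 1L + stats::rgeom(n, cfg$indel_p_geom)
    anchor <- chr_bases(ref$genome, chrom, ind_pos)
    ref_al <- ifelse(is_del,
                     substring(as.character(ref$genome$seq[[chrom]]),
                               ind_pos, ind_pos + len),
                     anchor)
    ins_tail <- vapply(len, rand_bases, character(1))
    alt_al <- ifelse(is_del, anchor, paste0(anchor, ins_tail))
    ind <- tibble(chrom = chrom, pos1 = ind_pos, ref = ref_al, alt = alt_al,
                  vtype = ifelse(is_del, "DEL", "INS"))
  } else {
    ind <- tibble(chrom = character(), pos1 = integer(), ref = character(),
                  alt = character(), vtype = character())
  }
  bind_rows(snp, ind) %>% arrange(.data$pos1)
}

chr_bases <- function(genome, chrom, pos1) {
  if (length(pos1) == 0) return(character())
  as.character(Biostrings::extractAt(
    genome$seq[[chrom]], IRanges::IRanges(start = pos1, width = 1)))
}

#' Simulate the variant calls of one sample
#'
#' Each sample draws `shared_fraction` of its variant rate from its group's
#' pool (regenerated deterministically from the master seed, so all group
#' members inherit exactly the same shared variants) plus a private Poisson
#' pool at the remaining rate. SNP positions follow a piecewise Poisson
#' process: the group rate, thinned inside planted deserts and amplified in
#' hot-gene CDS. Quality fields are drawn to pass the default
#' [filter_thresholds()]; a `fail_fraction` of records get one deliberately
#' failing field.
#'
#' @param cfg A [sim_config()].
#' @param ref Output of [generate_reference()].
#' @param sample Sample name (must appear in `cfg$groups`).
#' @return Tibble of planted records: the variant columns plus `group`,
#'   `shared`, `planted_pass` (whether the record was given passing quality
#'   values) and the true `category`/`gene_id` labels.
#' @export
simulate_sample_variants <- function(cfg, ref, sample) {
  group <- NULL
  for (g in names(cfg$groups)) {
    if (sample %in% cfg$groups[[g]]) group <- g
  }
  if (is.null(group)) abort(paste0("sample not in any group: ", sample))
  rate <- unname(cfg$snp_rate_per_kb[group])
  irate <- cfg$indel_rate_per_kb
  chroms <- ref$genome$chrom$chrom

  pools <- purrr::map(chroms, function(ch) {
    prof <- group_rate_profile(cfg, unname(chrom_lengths(ref$genome)[ch]),
                               group, ch)
    set.seed(derive_seed(cfg$seed, paste0("shared|", group, "|", ch)))
    shared <- draw_pool(cfg, ref, ch, rate * cfg$shared_fraction,
                        irate * cfg$shared_fraction, profile = prof)
    set.seed(derive_seed(cfg$seed, paste0("private|", sample, "|", ch)))
    private <- draw_pool(cfg, ref, ch, rate * (1 - cfg$shared_fraction),
                         irate * (1 - cfg$shared_fraction), profile = prof)
    bind_rows(shared %>% mutate(shared = TRUE),
              private %>% mutate(shared = FALSE)) %>%
      dplyr::distinct(.data$pos1, .data$vtype, .keep_all = TRUE) %>%
      arrange(.data$pos1)
  })
  rec <- bind_rows(pools) %>%
    mutate(sample_id = sample, group = group)

  # quality fields: passing by construction, then a deliberate failing slice
  set.seed(derive_seed(cfg$seed, paste0("quality|", sample)))
  n <- nrow(rec)
  rec$mapq <- pmin(60, pmax(25, round(stats::rnorm(n, 45, 4), 2)))
  rec$depth <- pmax(10L, stats::rpois(n, 30))
  rec$base_qual <- pmin(41, pmax(30, round(stats::rnorm(n, 35, 2), 2)))
  rec$vaf <- round(stats::runif(n, 0.35, 1), 4)
  rec$planted_pass <- TRUE
  n_fail <- floor(cfg$fail_fraction * n)
  if (n_fail > 0) {
    idx <- sample.int(n, n_fail)
    crit <- sample(c("mapq", "depth", "base_qual", "vaf"), n_fail,
                   replace = TRUE)
    rec$mapq[idx[crit == "mapq"]] <-
      round(stats::runif(sum(crit == "mapq"), 0, 19.9), 2)
    rec$depth[idx[crit == "depth"]] <-
      sample(0:9, sum(crit == "depth"), replace = TRUE)
    rec$base_qual[idx[crit == "base_qual"]] <-
      round(stats::runif(sum(crit == "base_qual"), 0, 29.9), 2)
    v <- idx[crit == "vaf"]
    rec$vaf[v] <- ifelse(rec$vtype[v] == "SNP",
                         round(stats::runif(length(v), 0, 0.099), 4),
                         round(stats::runif(length(v), 0, 0.299), 4))
    rec$planted_pass[idx] <- FALSE
  }
  tc <- truth_categories(rec, ref, flank_bp = 5000L)
  rec$category <- tc$category
  rec$gene_id <- tc$gene_id
  rec %>% select("sample_id", "group", "chrom", "pos1", "ref", "alt",
                 "vtype", "mapq", "depth", "base_qual", "vaf", "shared",
                 "planted_pass", "category", "gene_id")
}

# True consequence labels from the simulator's own transcription-order
# bookkeeping (independent of the annotator's genome-sequence path for the
# codon arithmetic).
truth_categories <- function(rec, ref, flank_bp = 5000L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  gc <- Biostrings::GENETIC_CODE
  out_cat <- rep("intergenic", nrow(rec))
  out_gene <- rep(NA_character_, nrow(rec))
  if (length(ref$gene_map) == 0 || nrow(rec) == 0) {
    return(tibble(category = out_cat, gene_id = out_gene))
  }
  genes <- purrr::map(ref$gene_map, function(gm) {
    tibble(gene_id = gm$gene_id, chrom = gm$chrom, strand = gm$strand,
           gstart = gm$gstart, gend = gm$gstart + gm$glen)
  }) %>% bind_rows()
  # per-chromosome sorted arrays for fast candidate lookup
  by_chrom <- split(genes, genes$chrom)
  by_chrom <- purrr::map(by_chrom, function(g) g[order(g$gstart), ])
  sev <- c(cds_nonsynonymous = 8, cds_indel = 8, cds_synonymous = 7,
           cds_unclassified = 6, utr5 = 5, utr3 = 5, intron = 4,
           regulatory_up = 2, regulatory_down = 2)

  label_one_gene <- function(gm, p0, ref_al, alt_al, vtype) {
    span0 <- p0
    span1 <- p0 + nchar(ref_al)  # half-open REF span
    gs <- gm$gstart
    ge <- gm$gstart + gm$glen
    if (span1 <= gs || span0 >= ge) {
      # flank only
      before <- span0 < gs
      up <- (gm$strand == "+") == before
      return(if (up) "regulatory_up" else "regulatory_down")
    }
    # transcription coordinate of the anchor base (clip into the body)
    p <- min(max(p0, gs), ge - 1L)
    tc <- if (gm$strand == "-") ge - 1L - p else p - gs
    seg_i <- which(gm$segs$t_start <= tc & gm$segs$t_end > tc)[1]
    type <- gm$segs$type[seg_i]
    if (vtype != "SNP") {
      # does the REF span touch any CDS segment (genomic)?
      touches_cds <- any(purrr::map_lgl(which(gm$segs$type == "cds"),
        function(si) {
          g <- tx2genomic(gm$segs$t_start[si], gm$segs$t_end[si], gm$gstart,
                          gm$glen, gm$strand)
          span0 < g[2] && span1 > g[1]
        }))
      if (touches_cds) return("cds_indel")
      return(switch(type, utr5 = "utr5", utr3 = "utr3", "intron"))
    }
    if (type != "cds") return(switch(type, utr5 = "utr5", utr3 = "utr3",
                                     "intron"))
    off <- gm$segs$cds_off[seg_i] + (tc - gm$segs$t_start[seg_i])
    codon_i <- off %/% 3L
    codon <- substr(gm$cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
    alt_t <- if (gm$strand == "-") unname(comp[alt_al]) else alt_al
    mut <- codon
    substr(mut, off %% 3L + 1L, off %% 3L + 1L) <- alt_t
    if (gc[[codon]] == gc[[mut]]) "cds_synonymous" else "cds_nonsynonymous"
  }

  v_chrom <- rec$chrom
  v_p0 <- rec$pos1 - 1L
  v_ref <- rec$ref
  v_alt <- rec$alt
  v_type <- rec$vtype
  for (ch in names(by_chrom)) {
    g <- by_chrom[[ch]]
    gs <- g$gstart
    ge <- g$gend
    ids <- g$gene_id
    rows <- which(v_chrom == ch)
    # rightmost gene whose extended start is <= p0; extended intervals can
    # overlap only a few neighbours, so scan back a bounded window
    ji <- findInterval(v_p0[rows], gs - flank_bp)
    for (k in seq_along(rows)) {
      i <- rows[k]
      p0 <- v_p0[i]
      cand <- integer()
      j <- ji[k]
      while (j >= 1) {
        # gene ends are increasing (non-overlapping genes), so stop at the
        # first one whose extended end no longer reaches p0
        if (ge[j] + flank_bp > p0) cand <- c(cand, j) else break
        j <- j - 1L
      }
      if (length(cand) == 0) next
      labs <- vapply(cand, function(ci) {
        label_one_gene(ref$gene_map[[ids[ci]]], p0, v_ref[i], v_alt[i],
                       v_type[i])
      }, character(1))
      best <- which.max(sev[labs])
      out_cat[i] <- labs[best]
      out_gene[i] <- ids[cand[best]]
    }
  }
  tibble(category = out_cat, gene_id = out_gene)
}

#' Simulate a complete multi-sample dataset on disk
#'
#' Runs [generate_reference()] and [simulate_sample_variants()] for every
#' sample, writes one VCF per sample plus the ground-truth report, and
#' returns everything needed for recovery tests.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory.
#' @return List: `fasta`, `gff3`, `vcfs` (named paths), `genome`, `truth`
#'   (a `sim_truth` list: `variants` tibble, `deserts`, `groups`,
#'   `hot_genes`, `config`).
#' @export
simulate_dataset <- function(cfg, dir) {
  ref <- generate_reference(cfg, dir)
  samples <- unlist(cfg$groups, use.names = FALSE)
  planted <- purrr::map(samples, function(s) {
    simulate_sample_variants(cfg, ref, s)
  })
  names(planted) <- samples
  vcfs <- purrr::map_chr(samples, function(s) {
    path <- file.path(dir, paste0(s, ".vcf"))
    write_sim_vcf(planted[[s]], path, ref$genome)
    path
  })
  names(vcfs) <- samples
  truth <- structure(list(
    variants = bind_rows(planted),
    deserts = cfg$deserts,
    groups = tibble(
      sample_id = samples,
      group = rep(names(cfg$groups), lengths(cfg$groups))),
    hot_genes = ref$hot_genes,
    config = cfg
  ), class = "sim_truth")
  list(fasta = ref$fasta, gff3 = ref$gff3, vcfs = vcfs,
       genome = ref$genome, gene_map = ref$gene_map, truth = truth)
}

# VarScan-flavoured VCF: DP/MQ/BQ in INFO, FREQ as a FORMAT percent string,
# so the reader's dialect handling is exercised end-to-end.
write_sim_vcf <- function(rec, path, genome) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=varscape_sim",
    sprintf("##contig=<ID=%s,length=%d>", genome$chrom$chrom,
            genome$chrom$length),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mean mapping quality\">",
    "##INFO=<ID=BQ,Number=1,Type=Float,Description=\"Average base quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=FREQ,Number=1,Type=String,Description=\"Variant allele frequency (percent)\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           rec$sample_id[1] %||% "sample")
  )
  rec <- rec %>% arrange(.data$chrom, .data$pos1)
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;MQ=%.2f;BQ=%.2f\tGT:FREQ\t1/1:%.2f%%",
    rec$chrom, rec$pos1, rec$ref, rec$alt, rec$depth,
    rec$mapq, rec$base_qual, rec$vaf * 100)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write machine-readable ground truth
#'
#' Emits `truth_deserts.bed` (planted low-rate intervals), `truth_groups.tsv`
#' and `truth_variants.tsv` (per-sample planted records with true category
#' labels) for recovery tests against pipeline output.
#'
#' @param truth `truth` element of [simulate_dataset()] output.
#' @param dir Output directory.
#' @return Named list of file paths, invisibly.
#' @export
truth_report <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bed <- file.path(dir, "truth_deserts.bed")
  d <- truth$deserts
  writeLines(sprintf("%s\t%d\t%d\tplanted_desert\t%g", d$chrom, d$start0,
                     d$end0, d$multiplier), bed)
  groups <- file.path(dir, "truth_groups.tsv")
  readr::write_tsv(truth$groups, groups)
  variants <- file.path(dir, "truth_variants.tsv")
  readr::write_tsv(truth$variants, variants)
  invisible(list(deserts = bed, groups = groups, variants = variants))
}
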