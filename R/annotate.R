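effect_categories <- c("intergenic", "regulatory_up", "regulatory_down",
                       "intron", "utr5", "utr3", "cds_synonymous",
                       "cds_nonsynonymous", "cds_unclassified", "cds_indel")

# severity used when one variant hits several features of the same gene:
# cds > utr > intron > regulatory; within cds, nonsyn > syn > unclassified
severity_rank <- c(
  cds_nonsynonymous = 8, cds_synonymous = 7, cds_indel = 8,
  cds_unclassified = 6, utr5 = 5, utr3 = 5, intron = 4,
  regulatory_up = 2, regulatory_down = 2, intergenic = 0
)

# pre-classification rank of raw feature labels from the interval index
feature_rank <- c(cds = 6, utr5 = 5, utr3 = 5, intron = 4,
                  regulatory_up = 2, regulatory_down = 2)

#' Build an interval index of gene features for consequence annotation
#'
#' Precomputes, for fast positional lookup: per-transcript CDS / UTR
#' intervals, per-transcript introns (transcript span minus exons), gene
#' spans, and each gene's regulatory flanks — `flank_bp` upstream and
#' downstream of the gene span, oriented by strand and clipped to the
#' chromosome. Also caches each complete transcript's coding sequence and
#' segment offsets so CDS SNP classification is a vectorized lookup.
#'
#' @param models List from [load_gene_models()].
#' @param genome A `genome_ref`.
#' @param flank_bp Regulatory flank size in bp on each side of a gene span
#'   (default 5000, the common annotation-tool default; the source studies
#'   rarely state it).
#' @return A `gene_index` object.
#' @export
build_gene_index <- function(models, genome, flank_bp = 5000L) {
  tx <- models$transcripts
  genes <- models$genes
  lens <- chrom_lengths(genome)

  feat <- purrr::map(seq_len(nrow(tx)), function(i) {
    t <- tx[i, ]
    parts <- list()
    add <- function(d, feature) {
      if (!is.null(d) && nrow(d) > 0) {
        parts[[length(parts) + 1]] <<- d %>%
          select("start0", "end0") %>%
          mutate(feature = feature)
      }
    }
    add(t$cds[[1]], "cds")
    add(t$utr5[[1]], "utr5")
    add(t$utr3[[1]], "utr3")
    ex <- t$exons[[1]]
    if (nrow(ex) > 0) {
      span <- IRanges::IRanges(start = t$start0 + 1L, end = t$end0)
      exr <- IRanges::IRanges(start = ex$start0 + 1L, end = ex$end0)
      intr <- IRanges::setdiff(span, exr)
      if (length(intr) > 0) {
        add(tibble(start0 = BiocGenerics::start(intr) - 1L,
                   end0 = BiocGenerics::end(intr)), "intron")
      }
    }
    if (length(parts) == 0) return(NULL)
    bind_rows(parts) %>%
      mutate(gene_id = t$gene_id, transcript_id = t$transcript_id,
             chrom = t$chrom, strand = t$strand)
  }) %>% bind_rows()

  gene_rows <- genes %>%
    mutate(feature = "gene_span", transcript_id = NA_character_) %>%
    select("start0", "end0", "feature", "gene_id", "transcript_id",
           "chrom", "strand")

  flanks <- purrr::pmap(
    genes %>% select("gene_id", "chrom", "strand", "start0", "end0"),
    function(gene_id, chrom, strand, start0, end0) {
      L <- unname(lens[chrom])
      fs <- as.integer(c(max(0L, start0 - flank_bp), end0))
      fe <- as.integer(c(start0, min(L, end0 + flank_bp)))
      tibble(
        start0 = fs,
        end0 = fe,
        feature = if (strand == "-") c("regulatory_down", "regulatory_up")
                  else c("regulatory_up", "regulatory_down"),
        gene_id = gene_id, transcript_id = NA_character_,
        chrom = chrom, strand = strand
      ) %>% filter(.data$end0 > .data$start0)
    }) %>% bind_rows()

  features <- bind_rows(feat, gene_rows, flanks)
  if (nrow(features) == 0) {
    features <- tibble(start0 = integer(), end0 = integer(),
                       feature = character(), gene_id = character(),
                       transcript_id = character(), chrom = character(),
                       strand = character())
  }

  structure(list(
    features = features,
    transcripts = tx,
    genes = genes,
    tx_cache = build_tx_cache(tx, genome),
    flank_bp = as.integer(flank_bp)
  ), class = "gene_index")
}

# For each transcript with CDS: coding sequence (transcription order,
# uppercase) and a segment table mapping genomic intervals to CDS offsets.
build_tx_cache <- function(tx, genome) {
  cache <- list()
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    cds <- t$cds[[1]]
    if (is.null(cds) || nrow(cds) == 0) next
    cds <- cds %>% arrange(.data$start0)
    w <- cds$end0 - cds$start0
    if (t$strand == "-") {
      ord <- rev(seq_len(nrow(cds)))
    } else {
      ord <- seq_len(nrow(cds))
    }
    cum <- cumsum(c(0L, w[ord]))[seq_len(nrow(cds))]
    offs <- integer(nrow(cds))
    offs[ord] <- cum
    cache[[t$transcript_id]] <- list(
      cds_seq = transcript_cds_seq(t, genome),
      segs = tibble(start0 = cds$start0, end0 = cds$end0, cds_off = offs),
      strand = t$strand,
      complete = t$complete
    )
  }
  cache
}

#' Annotate variant consequences against gene models
#'
#' For every variant, emits one effect record per overlapping gene (a gene
#' overlaps when the variant touches its span or its regulatory flanks); the
#' record's category is the most severe consequence across that gene's
#' transcripts, under precedence cds > UTR > intron > regulatory. CDS SNPs
#' are sub-classified synonymous / nonsynonymous by codon translation
#' ([classify_cds_snp()]); stop gains and losses count as nonsynonymous;
#' CDS-overlapping InDels get `cds_indel`; CDS SNPs on incomplete gene
#' models get `cds_unclassified`. A variant overlapping no gene and no flank
#' yields a single `intergenic` record with `gene_id = NA`. Because a
#' variant can hit several overlapping genes, the number of effect records
#' can exceed the number of variants.
#'
#' @param records Filtered variant tibble.
#' @param index A `gene_index` from [build_gene_index()].
#' @param genome A `genome_ref`, used to check the REF allele against the
#'   reference sequence (mismatches are tallied in attribute
#'   `n_ref_mismatch` and classified positionally anyway).
#' @return Tibble of effect records: `sample_id, chrom, pos1, ref, alt,
#'   vtype, gene_id, transcript_id, category`.
#' @export
annotate_variants <- function(records, index, genome) {
  if (nrow(records) == 0) {
    out <- tibble(sample_id = character(), chrom = character(),
                  pos1 = integer(), ref = character(), alt = character(),
                  vtype = character(), gene_id = character(),
                  transcript_id = character(), category = character())
    attr(out, "n_ref_mismatch") <- 0L
    return(out)
  }
  rec <- records %>% mutate(.vid = row_number())
  # variant anchor interval: the REF span, 0-based half-open
  rec$a_start0 <- rec$pos1 - 1L
  rec$a_end0 <- rec$pos1 - 1L + nchar(rec$ref)

  n_mismatch <- check_ref_alleles(rec, genome)
  if (n_mismatch > 0) {
    warn(sprintf("%d variant(s) disagree with the reference allele", n_mismatch))
  }

  hits <- overlap_hits(rec, index$features)

  genic <- hits %>%
    mutate(rank = feature_rank[.data$feature_cat]) %>%
    group_by(.data$.vid, .data$gene_id) %>%
    dplyr::slice_max(.data$rank, n = 1, with_ties = FALSE) %>%
    ungroup()

  # sub-classify CDS hits
  cds_rows <- genic %>% filter(.data$feature_cat == "cds")
  if (nrow(cds_rows) > 0) {
    cls <- classify_cds_hits(cds_rows, rec, hits, index)
    genic <- genic %>%
      left_join(cls, by = c(".vid", "gene_id")) %>%
      mutate(category = dplyr::coalesce(.data$cds_category,
                                        .data$feature_cat),
             transcript_id = dplyr::coalesce(.data$cds_transcript,
                                             .data$transcript_id)) %>%
      select(-"cds_category", -"cds_transcript")
  } else {
    genic <- genic %>% mutate(category = .data$feature_cat)
  }

  genic_out <- genic %>%
    inner_join(rec %>%
                 select(".vid", "sample_id", "chrom", "pos1", "ref", "alt",
                        "vtype"),
               by = ".vid") %>%
    select("sample_id", "chrom", "pos1", "ref", "alt", "vtype", "gene_id",
           "transcript_id", "category", ".vid")

  inter <- rec %>%
    filter(.data$.vid %not_in% genic$.vid) %>%
    mutate(gene_id = NA_character_, transcript_id = NA_character_,
           category = "intergenic") %>%
    select("sample_id", "chrom", "pos1", "ref", "alt", "vtype", "gene_id",
           "transcript_id", "category", ".vid")

  out <- bind_rows(genic_out, inter) %>%
    arrange(.data$.vid, .data$gene_id) %>%
    select(-".vid")
  attr(out, "n_ref_mismatch") <- n_mismatch
  out
}

check_ref_alleles <- function(rec, genome) {
  lens <- chrom_lengths(genome)
  n <- 0L
  for (ch in unique(rec$chrom)) {
    sub <- rec[rec$chrom == ch, ]
    L <- lens[ch]
    if (is.na(L)) {
      n <- n + nrow(sub)
      next
    }
    inb <- sub$a_end0 <= L
    n <- n + sum(!inb)
    sub <- sub[inb, ]
    if (nrow(sub) == 0) next
    obs <- as.character(Biostrings::extractAt(
      genome$seq[[ch]],
      IRanges::IRanges(start = sub$a_start0 + 1L, end = sub$a_end0)))
    n <- n + sum(obs != sub$ref)
  }
  n
}

# Overlap variants against the feature table; returns one row per
# (variant, gene, transcript, feature) with feature_cat collapsing
# gene_span hits (genic but outside any modelled feature) to intron.
overlap_hits <- function(rec, features) {
  out <- purrr::map(unique(rec$chrom), function(ch) {
    fr <- features %>% filter(.data$chrom == ch)
    vr <- rec %>% filter(.data$chrom == ch)
    if (nrow(fr) == 0 || nrow(vr) == 0) return(NULL)
    q <- IRanges::IRanges(start = vr$a_start0 + 1L, end = vr$a_end0)
    s <- IRanges::IRanges(start = fr$start0 + 1L, end = fr$end0)
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov) == 0) return(NULL)
    tibble(
      .vid = vr$.vid[S4Vectors::queryHits(ov)],
      gene_id = fr$gene_id[S4Vectors::subjectHits(ov)],
      transcript_id = fr$transcript_id[S4Vectors::subjectHits(ov)],
      feature = fr$feature[S4Vectors::subjectHits(ov)]
    )
  }) %>% bind_rows()
  if (nrow(out) == 0) {
    return(tibble(.vid = integer(), gene_id = character(),
                  transcript_id = character(), feature = character(),
                  feature_cat = character()))
  }
  out %>%
    mutate(feature_cat = dplyr::recode(.data$feature,
                                       gene_span = "intron")) %>%
    dplyr::distinct()
}

# Decide the CDS category for each (variant, gene): SNPs by codon
# translation over every CDS-overlapping transcript of the gene, InDels as
# cds_indel. Returns tibble(.vid, gene_id, cds_category, cds_transcript).
classify_cds_hits <- function(cds_rows, rec, hits, index) {
  pairs <- hits %>%
    filter(.data$feature == "cds") %>%
    dplyr::semi_join(cds_rows, by = c(".vid", "gene_id")) %>%
    select(".vid", "gene_id", "transcript_id") %>%
    dplyr::distinct() %>%
    left_join(rec %>% select(".vid", "pos1", "ref", "alt", "vtype"),
              by = ".vid")

  indel <- pairs %>%
    filter(.data$vtype %in% c("INS", "DEL", "OTHER")) %>%
    dplyr::distinct(.data$.vid, .data$gene_id) %>%
    mutate(cds_category = "cds_indel", cds_transcript = NA_character_)

  snp <- pairs %>% filter(.data$vtype == "SNP")
  if (nrow(snp) > 0) {
    snp$one <- classify_cds_snp_vec(snp$transcript_id, snp$pos1, snp$ref,
                                    snp$alt, index)
    snp_out <- snp %>%
      mutate(rank = dplyr::case_when(
        .data$one == "cds_nonsynonymous" ~ 3L,
        .data$one == "cds_synonymous" ~ 2L,
        TRUE ~ 1L)) %>%
      group_by(.data$.vid, .data$gene_id) %>%
      dplyr::slice_max(.data$rank, n = 1, with_ties = FALSE) %>%
      ungroup() %>%
      select(".vid", "gene_id", cds_category = "one",
             cds_transcript = "transcript_id")
  } else {
    snp_out <- tibble(.vid = integer(), gene_id = character(),
                      cds_category = character(),
                      cds_transcript = character())
  }
  bind_rows(indel, snp_out)
}

#' Classify one CDS SNP as synonymous or nonsynonymous
#'
#' Rebuilds the transcript's coding sequence (reverse-complemented on the
#' minus strand), locates the substituted base's offset, substitutes the
#' alternate base (complemented on minus-strand transcripts), and translates
#' the affected codon with the standard genetic code. Equal amino acids →
#' `cds_synonymous`; different, including stop gain/loss →
#' `cds_nonsynonymous`; incomplete gene models, codons containing N, or an
#' incomplete terminal codon → `cds_unclassified`.
#'
#' @param transcript One row of the `transcripts` tibble.
#' @param pos1 1-based genomic position of the SNP.
#' @param ref,alt Reference and alternate bases (plus-strand, as in VCF).
#' @param index A `gene_index` holding the transcript cache.
#' @return One of `"cds_synonymous"`, `"cds_nonsynonymous"`,
#'   `"cds_unclassified"`.
#' @export
classify_cds_snp <- function(transcript, pos1, ref, alt, index) {
  classify_cds_snp_vec(transcript$transcript_id, pos1, ref, alt, index)
}

classify_cds_snp_vec <- function(transcript_id, pos1, ref, alt, index) {
  gc <- Biostrings::GENETIC_CODE
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- character(length(pos1))
  for (i in seq_along(pos1)) {
    tc <- index$tx_cache[[transcript_id[i]]]
    if (is.null(tc) || !isTRUE(tc$complete)) {
      out[i] <- "cds_unclassified"
      next
    }
    p0 <- pos1[i] - 1L
    j <- which(tc$segs$start0 <= p0 & tc$segs$end0 > p0)[1]
    if (is.na(j)) {
      out[i] <- "cds_unclassified"
      next
    }
    off <- if (tc$strand == "-") {
      tc$segs$cds_off[j] + (tc$segs$end0[j] - 1L - p0)
    } else {
      tc$segs$cds_off[j] + (p0 - tc$segs$start0[j])
    }
    codon_i <- off %/% 3L
    within <- off %% 3L
    codon <- substr(tc$cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
    if (nchar(codon) < 3 || grepl("N", codon)) {
      out[i] <- "cds_unclassified"
      next
    }
    alt_b <- if (tc$strand == "-") unname(comp[alt[i]]) else alt[i]
    if (is.na(alt_b) || !alt_b %in% c("A", "C", "G", "T")) {
      out[i] <- "cds_unclassified"
      next
    }
    mut <- codon
    substr(mut, within + 1L, within + 1L) <- alt_b
    out[i] <- if (gc[[codon]] == gc[[mut]]) "cds_synonymous"
              else "cds_nonsynonymous"
  }
  out
}

#' Summarize effect records into the standard partition table
#'
#' Percentages follow the conventional nested layout of resequencing
#' annotation tables: intergenic vs genic over all effect records; intron &
#' regulatory, UTRs and CDS as shares of genic records; nonsynonymous vs
#' synonymous as shares of classified CDS SNP records. Counts can exceed the
#' variant count because overlapping genes each contribute a record.
#'
#' @param effects Effect tibble from [annotate_variants()] (one sample, one
#'   variant class is the conventional use).
#' @return An `effect_summary` tibble (one row per sample) with counts and
#'   percentages (`pct_*`, unrounded; exports round half-up to 2 decimals).
#' @export
summarize_effects <- function(effects) {
  if (nrow(effects) == 0) {
    effects <- tibble(sample_id = character(), category = character())
  }
  out <- effects %>%
    group_by(.data$sample_id) %>%
    summarise(
      n_records = dplyr::n(),
      intergenic = sum(.data$category == "intergenic"),
      genic = sum(.data$category != "intergenic"),
      intron_and_regulatory = sum(.data$category %in%
        c("intron", "regulatory_up", "regulatory_down")),
      utrs = sum(.data$category %in% c("utr5", "utr3")),
      cds = sum(.data$category %in%
        c("cds_synonymous", "cds_nonsynonymous", "cds_unclassified",
          "cds_indel")),
      nonsynonymous = sum(.data$category == "cds_nonsynonymous"),
      synonymous = sum(.data$category == "cds_synonymous"),
      cds_unclassified = sum(.data$category == "cds_unclassified"),
      .groups = "drop") %>%
    mutate(
      pct_intergenic = 100 * .data$intergenic / .data$n_records,
      pct_genic = 100 * .data$genic / .data$n_records,
      pct_intron_and_regulatory =
        100 * .data$intron_and_regulatory / .data$genic,
      pct_utrs = 100 * .data$utrs / .data$genic,
      pct_cds = 100 * .data$cds / .data$genic,
      pct_nonsynonymous = 100 * .data$nonsynonymous /
        (.data$nonsynonymous + .data$synonymous),
      pct_synonymous = 100 * .data$synonymous /
        (.data$nonsynonymous + .data$synonymous)
    )
  out[is.na(as.data.frame(out))] <- NA  # keep NaN-free: 0/0 shares -> NA
  class(out) <- c("effect_summary", class(out))
  out
}

#' Export an effect summary as TSV (percentages rounded half-up, 2 dp)
#' @param summary An `effect_summary`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_effect_summary <- function(summary, path) {
  summary %>%
    as_tibble() %>%
    mutate(across(dplyr::starts_with("pct_"), ~ round_half_up(.x, 2))) %>%
    readr::write_tsv(path)
  invisible(path)
}
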