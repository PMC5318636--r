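#' Load a reference genome from FASTA
#'
#' Reads a FASTA file into a `genome_ref` object giving ordered chromosome
#' names, lengths, and random access to uppercase sequence. All coordinates
#' taken by [genome_seq()] are 0-based half-open; the 1-based conventions of
#' VCF and GFF3 are converted at the I/O boundary, never internally.
#'
#' @param fasta_path Path to a FASTA file with unique record identifiers.
#' @return A `genome_ref` object: list with `seq` (a
#'   [Biostrings::DNAStringSet], uppercased) and `chrom`, a tibble with
#'   columns `chrom` and `length`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTACGT"), fa)
#' g <- load_genome(fa)
#' chrom_lengths(g)
#' genome_seq(g, "chr1", 1, 3)
#' @export
load_genome <- function(fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0) abort("empty FASTA: no records found")
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA identifiers: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  names(seqs) <- ids
  # normalize case once so downstream codon lookups never see lowercase
  seqs <- Biostrings::DNAStringSet(toupper(seqs))
  structure(
    list(seq = seqs,
         chrom = tibble(chrom = ids, length = BiocGenerics::width(seqs))),
    class = "genome_ref"
  )
}

#' @export
print.genome_ref <- function(x, ...) {
  cat("<genome_ref> ", nrow(x$chrom), " chromosome(s), ",
      format(sum(x$chrom$length), big.mark = ","), " bp total\n", sep = "")
  print(x$chrom, ...)
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome A `genome_ref` from [load_genome()].
#' @return Named integer vector of chromosome lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(genome$chrom$length, genome$chrom$chrom)
}

#' Extract genome sequence over a 0-based half-open interval
#'
#' @param genome A `genome_ref`.
#' @param chrom Chromosome name.
#' @param start0,end0 0-based half-open interval bounds; must satisfy
#'   `0 <= start0 <= end0 <= length(chrom)`.
#' @return Uppercase nucleotide string of length `end0 - start0`.
#' @export
genome_seq <- function(genome, chrom, start0, end0) {
  len <- chrom_lengths(genome)[chrom]
  if (is.na(len)) abort(paste0("unknown chromosome: ", chrom))
  if (start0 < 0 || end0 > len || start0 > end0) {
    abort(sprintf("interval [%d,%d) out of range for %s (length %d)",
                  start0, end0, chrom, len))
  }
  as.character(Biostrings::subseq(genome$seq[[chrom]], start0 + 1L, end0))
}

#' Load gene models from GFF3
#'
#' Parses gene / mRNA / exon / CDS / UTR features into per-transcript and
#' per-gene tables. GFF3's 1-based inclusive coordinates are converted to
#' 0-based half-open on input. Transcripts are linked to genes through their
#' `Parent` attributes. Explicit `five_prime_UTR` / `three_prime_UTR`
#' features are used when present; otherwise UTRs are derived as the exonic
#' bases not covered by CDS, split by transcription order around the CDS.
#'
#' A transcript is flagged `complete` when it has CDS, its total CDS length
#' is a multiple of 3 and the first CDS segment (in transcription order) has
#' phase 0. Incomplete transcripts are retained — downstream CDS SNP
#' classification reports them as `cds_unclassified` rather than silently
#' dropping them.
#'
#' @param gff3_path Path to a GFF3 file.
#' @param genome A `genome_ref`; transcripts on chromosomes absent from it
#'   are skipped with a warning.
#' @return A list with two tibbles: `transcripts` (one row per mRNA, interval
#'   list-columns `exons`, `cds`, `utr5`, `utr3`, all 0-based half-open and
#'   sorted by genomic coordinate) and `genes` (one row per gene with `span`
#'   bounds and `cds_union_length`, the bp in the union of all its
#'   transcripts' CDS intervals).
#' @export
load_gene_models <- function(gff3_path, genome) {
  gff <- as_tibble(rtracklayer::readGFF(
    gff3_path,
    columns = c("seqid", "start", "end", "strand", "type", "phase"),
    tags = c("ID", "Parent")
  ))
  gff$Parent <- purrr::map_chr(gff$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  })
  gff <- gff %>%
    mutate(seqid = as.character(.data$seqid), type = as.character(.data$type),
           strand = as.character(.data$strand),
           start0 = as.integer(.data$start - 1L), end0 = as.integer(.data$end))

  known <- genome$chrom$chrom
  genes_raw <- gff %>% filter(.data$type == "gene")
  mrnas <- gff %>% filter(.data$type %in% c("mRNA", "transcript"))

  orphan <- is.na(mrnas$Parent)
  if (any(orphan)) {
    warn(sprintf("%d transcript(s) without Parent skipped", sum(orphan)))
    mrnas <- mrnas[!orphan, ]
  }
  off_chrom <- mrnas$seqid %not_in% known
  if (any(off_chrom)) {
    warn(sprintf("%d transcript(s) on unknown chromosome skipped",
                 sum(off_chrom)))
    mrnas <- mrnas[!off_chrom, ]
  }

  kids <- gff %>%
    filter(.data$type %in% c("exon", "CDS", "five_prime_UTR",
                             "three_prime_UTR"),
           !is.na(.data$Parent), .data$Parent %in% mrnas$ID)

  tx <- purrr::map(seq_len(nrow(mrnas)), function(i) {
    m <- mrnas[i, ]
    k <- kids %>% filter(.data$Parent == m$ID) %>% arrange(.data$start0)
    exons <- k %>% filter(.data$type == "exon") %>%
      select("start0", "end0")
    cds <- k %>% filter(.data$type == "CDS") %>%
      select("start0", "end0", "phase")
    if (nrow(exons) == 0 && nrow(cds) > 0) {
      # CDS-only dialects: treat CDS segments as the exons
      exons <- cds %>% select("start0", "end0")
    }
    # clip CDS segments that stick out of every exon (malformed rows)
    if (nrow(cds) > 0 && nrow(exons) > 0) {
      clipped <- purrr::pmap(cds, function(start0, end0, phase) {
        hit <- exons %>%
          filter(.data$end0 > !!start0, .data$start0 < !!end0)
        if (nrow(hit) == 0) {
          warn(sprintf("CDS [%d,%d) of %s outside all exons: dropped",
                       start0, end0, m$ID))
          return(NULL)
        }
        h <- hit[1, ]
        if (start0 < h$start0 || end0 > h$end0) {
          warn(sprintf("CDS [%d,%d) of %s clipped to containing exon",
                       start0, end0, m$ID))
        }
        tibble(start0 = max(start0, h$start0), end0 = min(end0, h$end0),
               phase = phase)
      })
      cds <- bind_rows(clipped)
    }
    utr5 <- k %>% filter(.data$type == "five_prime_UTR") %>%
      select("start0", "end0")
    utr3 <- k %>% filter(.data$type == "three_prime_UTR") %>%
      select("start0", "end0")
    if (nrow(utr5) == 0 && nrow(utr3) == 0 && nrow(cds) > 0) {
      d <- derive_utrs(exons, cds, m$strand)
      utr5 <- d$utr5
      utr3 <- d$utr3
    }
    cds_len <- if (nrow(cds)) sum(cds$end0 - cds$start0) else 0L
    phase_first <- 0L
    if (nrow(cds) > 0) {
      first <- if (m$strand == "-") which.max(cds$end0) else which.min(cds$start0)
      p <- cds$phase[first]
      phase_first <- if (is.na(p)) 0L else as.integer(p)
    }
    tibble(
      transcript_id = m$ID, gene_id = m$Parent, chrom = m$seqid,
      strand = m$strand,
      start0 = min(exons$start0, m$start0), end0 = max(exons$end0, m$end0),
      cds_len = as.integer(cds_len), phase_first = phase_first,
      complete = cds_len > 0L && cds_len %% 3L == 0L && phase_first == 0L,
      exons = list(exons), cds = list(cds), utr5 = list(utr5),
      utr3 = list(utr3)
    )
  }) %>% bind_rows()

  genes <- build_gene_spans(tx, genes_raw, known)
  list(transcripts = tx, genes = genes)
}

# UTRs derived as exonic-minus-CDS, assigned to the 5' or 3' side by the
# genomic extent of the CDS and the strand.
derive_utrs <- function(exons, cds, strand) {
  ex <- IRanges::IRanges(start = exons$start0 + 1L, end = exons$end0)
  cd <- IRanges::IRanges(start = cds$start0 + 1L, end = cds$end0)
  non <- IRanges::setdiff(ex, cd)
  if (length(non) == 0) {
    empty <- tibble(start0 = integer(), end0 = integer())
    return(list(utr5 = empty, utr3 = empty))
  }
  non_tb <- tibble(start0 = BiocGenerics::start(non) - 1L,
                   end0 = BiocGenerics::end(non))
  cds_lo <- min(cds$start0)
  cds_hi <- max(cds$end0)
  left <- non_tb %>% filter(.data$end0 <= cds_lo)
  right <- non_tb %>% filter(.data$start0 >= cds_hi)
  if (strand == "-") list(utr5 = right, utr3 = left)
  else list(utr5 = left, utr3 = right)
}

build_gene_spans <- function(tx, genes_raw, known) {
  if (nrow(tx) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), start0 = integer(), end0 = integer(),
                  cds_union_length = integer()))
  }
  spans <- tx %>%
    group_by(.data$gene_id, .data$chrom, .data$strand) %>%
    summarise(tx_start0 = min(.data$start0), tx_end0 = max(.data$end0),
              .groups = "drop")
  cds_union <- tx %>%
    select("gene_id", "cds") %>%
    tidyr::unnest("cds") %>%
    group_by(.data$gene_id) %>%
    summarise(cds_union_length = union_width(.data$start0, .data$end0),
              .groups = "drop")
  g <- spans %>%
    left_join(cds_union, by = "gene_id") %>%
    mutate(cds_union_length = as.integer(
      dplyr::coalesce(.data$cds_union_length, 0L)))
  # widen to the declared gene row when present (gene may outspan its mRNAs)
  if (nrow(genes_raw) > 0) {
    decl <- genes_raw %>%
      filter(.data$seqid %in% known) %>%
      select(gene_id = "ID", g_start0 = "start0", g_end0 = "end0")
    g <- g %>%
      left_join(decl, by = "gene_id") %>%
      mutate(start0 = pmin(.data$tx_start0, .data$g_start0, na.rm = TRUE),
             end0 = pmax(.data$tx_end0, .data$g_end0, na.rm = TRUE)) %>%
      select(-"g_start0", -"g_end0")
  } else {
    g <- g %>% mutate(start0 = .data$tx_start0, end0 = .data$tx_end0)
  }
  g %>%
    select("gene_id", "chrom", "strand", "start0", "end0",
           "cds_union_length") %>%
    arrange(.data$chrom, .data$start0)
}

#' Coding sequence of a transcript
#'
#' Concatenates the CDS segments in transcription order, reverse-complementing
#' on the minus strand, so the result starts at the first coding base.
#'
#' @param transcript One row of the `transcripts` tibble from
#'   [load_gene_models()].
#' @param genome A `genome_ref`.
#' @return Uppercase coding DNA string.
#' @export
transcript_cds_seq <- function(transcript, genome) {
  cds <- transcript$cds[[1]]
  if (is.null(cds) || nrow(cds) == 0) return("")
  cds <- cds %>% arrange(.data$start0)
  segs <- purrr::map2_chr(cds$start0, cds$end0, function(s, e) {
    genome_seq(genome, transcript$chrom, s, e)
  })
  s <- paste(segs, collapse = "")
  if (transcript$strand == "-") revcomp(s) else s
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
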