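#' Qualification thresholds for called variants
#'
#' The defaults are the VarScan-style minima commonly used to qualify
#' resequencing calls: mapping quality 20, depth of coverage 10, average base
#' quality 30, and variant allele frequency 0.1 for SNPs / 0.3 for InDels.
#' All comparisons are inclusive (`value >= threshold`), reading each number
#' as the minimum acceptable value.
#'
#' @param min_mapq Minimum mean mapping quality (Phred).
#' @param min_depth Minimum read depth at the site.
#' @param min_base_qual Minimum average base quality (Phred).
#' @param min_vaf_snp Minimum variant allele frequency for SNPs, in `[0,1]`.
#' @param min_vaf_indel Minimum variant allele frequency for insertions and
#'   deletions, in `[0,1]`.
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_mapq = 20, min_depth = 10,
                              min_base_qual = 30, min_vaf_snp = 0.1,
                              min_vaf_indel = 0.3) {
  stopifnot(min_mapq >= 0, min_depth >= 0, min_base_qual >= 0,
            min_vaf_snp >= 0, min_vaf_snp <= 1,
            min_vaf_indel >= 0, min_vaf_indel <= 1)
  structure(list(min_mapq = min_mapq, min_depth = min_depth,
                 min_base_qual = min_base_qual, min_vaf_snp = min_vaf_snp,
                 min_vaf_indel = min_vaf_indel),
            class = "filter_thresholds")
}

variant_columns <- function() {
  tibble(sample_id = character(), chrom = character(), pos1 = integer(),
         ref = character(), alt = character(), vtype = character(),
         mapq = double(), depth = double(), base_qual = double(),
         vaf = double())
}

classify_vtype <- function(ref, alt) {
  dplyr::case_when(
    !grepl("^[ACGTN]+$", ref) | !grepl("^[ACGTN]+$", alt) ~ "OTHER",
    nchar(ref) == 1 & nchar(alt) == 1 ~ "SNP",
    nchar(alt) > nchar(ref) &
      substr(alt, 1, nchar(ref)) == ref ~ "INS",
    nchar(ref) > nchar(alt) &
      substr(ref, 1, nchar(alt)) == alt ~ "DEL",
    TRUE ~ "OTHER"
  )
}

# VarScan writes FREQ as a percent string ("12.5%"); other callers write AF
# as a fraction. Parse both to [0,1].
parse_freq <- function(x) {
  pct <- grepl("%", x, fixed = TRUE)
  v <- suppressWarnings(as.numeric(sub("%", "", x, fixed = TRUE)))
  ifelse(pct, v / 100, v)
}

info_field <- function(info, tags) {
  out <- rep(NA_character_, length(info))
  for (tag in tags) {
    idx <- which(is.na(out) & !is.na(info))
    if (length(idx) == 0) next
    m <- regexec(paste0("(?:^|;)", tag, "=([^;]*)"), info[idx])
    res <- regmatches(info[idx], m)
    out[idx] <- vapply(res, function(r) {
      if (length(r) >= 2) r[2] else NA_character_
    }, character(1))
  }
  out
}

#' Read a VCF file into a normalized variant tibble
#'
#' Loads a VCF 4.x file and normalizes every row to biallelic records:
#' multi-allelic rows are decomposed into one record per ALT allele. Records
#' are typed as SNP (`|ref| = |alt| = 1`), INS (alt extends ref), DEL (ref
#' extends alt) or OTHER (symbolic alleles, breakends, block substitutions).
#' Quality annotations are read, when present, from INFO first and then the
#' first sample's FORMAT fields, under configurable tag names; VarScan-style
#' percent frequencies ("45.2%") are parsed to fractions.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @param sample_id Sample label attached to every record.
#' @param tags Named list of candidate tag names for `depth`, `mapq`,
#'   `base_qual` and `vaf`, tried in order.
#' @return Tibble with columns `sample_id, chrom, pos1, ref, alt, vtype,
#'   mapq, depth, base_qual, vaf`, sorted by `(chrom, pos1)`. The number of
#'   malformed rows skipped is attached as attribute `n_malformed`.
#' @export
read_vcf <- function(path, sample_id,
                     tags = list(depth = c("DP"), mapq = c("MQ"),
                                 base_qual = c("ABQ", "BQ"),
                                 vaf = c("FREQ", "AF"))) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    out <- variant_columns()
    attr(out, "n_malformed") <- 0L
    return(out)
  }
  pos <- suppressWarnings(as.integer(fix$POS))
  bad <- is.na(pos) | pos < 1 | is.na(fix$REF) | fix$REF == "" |
    is.na(fix$ALT) | fix$ALT == "" | fix$ALT == "."
  n_malformed <- sum(bad)
  if (n_malformed > 0) {
    warn(sprintf("%d malformed VCF row(s) skipped", n_malformed))
  }
  fix <- fix[!bad, , drop = FALSE]
  pos <- pos[!bad]

  info <- fix$INFO %||% rep(NA_character_, nrow(fix))
  gt_lookup <- NULL
  if (!is.null(v@gt) && ncol(v@gt) >= 2 && nrow(v@gt) == length(bad)) {
    gt <- v@gt[!bad, , drop = FALSE]
    gt_keys <- strsplit(gt[, 1], ":", fixed = TRUE)
    gt_vals <- strsplit(gt[, 2], ":", fixed = TRUE)
    gt_lookup <- function(tag) {
      purrr::map2_chr(gt_keys, gt_vals, function(k, x) {
        i <- match(tag, k)
        if (is.na(i) || i > length(x)) NA_character_ else x[i]
      })
    }
  }
  # INFO first, then the first sample's FORMAT field, first tag name wins
  fmt_val <- function(tag_set) {
    out <- info_field(info, tag_set)
    if (!is.null(gt_lookup)) {
      for (tag in tag_set) {
        if (!any(is.na(out))) break
        got <- gt_lookup(tag)
        out[is.na(out)] <- got[is.na(out)]
      }
    }
    out
  }
  depth_raw <- fmt_val(tags$depth)
  mapq_raw <- fmt_val(tags$mapq)
  bq_raw <- fmt_val(tags$base_qual)
  vaf_raw <- fmt_val(tags$vaf)

  rec <- tibble(
    chrom = fix$CHROM, pos1 = pos, ref = toupper(fix$REF), alt = fix$ALT,
    mapq = suppressWarnings(as.numeric(mapq_raw)),
    depth = suppressWarnings(as.numeric(depth_raw)),
    base_qual = suppressWarnings(as.numeric(bq_raw)),
    vaf = parse_freq(vaf_raw)
  ) %>%
    mutate(alt = strsplit(.data$alt, ",", fixed = TRUE)) %>%
    tidyr::unnest("alt") %>%
    mutate(alt = ifelse(grepl("^[acgtn]+$", .data$alt),
                        toupper(.data$alt), .data$alt),
           vtype = classify_vtype(.data$ref, .data$alt),
           sample_id = sample_id) %>%
    filter(.data$ref != .data$alt) %>%
    select(all_of(names(variant_columns())))
  o <- order(rec$chrom, rec$pos1)
  if (!identical(o, seq_len(nrow(rec)))) {
    warn("VCF records not coordinate-sorted; sorting by (chrom, pos1)")
    rec <- rec[o, , drop = FALSE]
  }
  attr(rec, "n_malformed") <- n_malformed
  rec
}

#' Apply qualification thresholds to variant records
#'
#' A record is kept iff every available criterion passes inclusively
#' (`value >= threshold`); criteria whose field is missing (`NA`) are
#' skipped, not failed, and the skip is tallied in the report. The VAF
#' threshold is chosen by variant type (SNP vs INS/DEL). Records of type
#' OTHER are always rejected. A record failing several criteria is counted
#' once, under the first failing criterion in the order mapq, depth,
#' base_qual, vaf.
#'
#' @param records Variant tibble from [read_vcf()].
#' @param thresholds A [filter_thresholds()] object.
#' @return The kept records (same columns), with a `filter_report` attribute:
#'   list with `n_input`, `n_kept`, `n_rejected`, `rejected` (named counts
#'   per reason) and `skipped_criteria` (named counts of absent fields).
#'   Retrieve it with [filter_report()].
#' @export
filter_variants <- function(records, thresholds = filter_thresholds()) {
  t <- thresholds
  vaf_min <- ifelse(records$vtype == "SNP", t$min_vaf_snp,
                    ifelse(records$vtype %in% c("INS", "DEL"),
                           t$min_vaf_indel, NA_real_))
  fail_mapq <- !is.na(records$mapq) & records$mapq < t$min_mapq
  fail_depth <- !is.na(records$depth) & records$depth < t$min_depth
  fail_bq <- !is.na(records$base_qual) & records$base_qual < t$min_base_qual
  fail_vaf <- !is.na(records$vaf) & !is.na(vaf_min) & records$vaf < vaf_min
  unsupported <- records$vtype %not_in% c("SNP", "INS", "DEL")

  reason <- rep(NA_character_, nrow(records))
  reason[fail_vaf] <- "vaf"
  reason[fail_bq] <- "base_qual"
  reason[fail_depth] <- "depth"
  reason[fail_mapq] <- "mapq"
  reason[unsupported] <- "unsupported_type"

  keep <- is.na(reason)
  kept <- records[keep, , drop = FALSE]
  report <- list(
    n_input = nrow(records),
    n_kept = sum(keep),
    n_rejected = sum(!keep),
    rejected = table_counts(reason[!keep],
                            c("mapq", "depth", "base_qual", "vaf",
                              "unsupported_type")),
    skipped_criteria = c(
      mapq = sum(is.na(records$mapq) & !unsupported),
      depth = sum(is.na(records$depth) & !unsupported),
      base_qual = sum(is.na(records$base_qual) & !unsupported),
      vaf = sum(is.na(records$vaf) & !unsupported)
    ),
    thresholds = unclass(t)
  )
  attr(kept, "filter_report") <- report
  kept
}

table_counts <- function(x, levels) {
  out <- stats::setNames(integer(length(levels)), levels)
  tb <- table(x)
  out[names(tb)] <- as.integer(tb)
  out
}

#' Retrieve the filter report attached by [filter_variants()]
#' @param records A tibble returned by [filter_variants()].
#' @return The report list, or `NULL` when absent.
#' @export
filter_report <- function(records) attr(records, "filter_report")

#' Write variant records back to VCF
#'
#' Emits a minimal VCF 4.2 file with the records' quality annotations in
#' INFO (`DP`, `MQ`, `BQ`, `AF`). Used to persist the kept set after
#' filtering; the header notes the thresholds applied when a report is
#' attached.
#'
#' @param records Variant tibble.
#' @param path Output path.
#' @param genome Optional `genome_ref` used to write contig header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2", "##source=varscape")
  rep <- filter_report(records)
  if (!is.null(rep)) {
    th <- rep$thresholds
    hdr <- c(hdr, sprintf(
      "##FILTER=<ID=varscape_qualified,Description=\"mapq>=%s depth>=%s base_qual>=%s vaf_snp>=%s vaf_indel>=%s\">",
      th$min_mapq, th$min_depth, th$min_base_qual, th$min_vaf_snp,
      th$min_vaf_indel))
  }
  if (!is.null(genome)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          genome$chrom$chrom, genome$chrom$length))
  }
  hdr <- c(hdr,
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mean mapping quality\">",
    "##INFO=<ID=BQ,Number=1,Type=Float,Description=\"Average base quality\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- with(records, {
    parts <- cbind(
      ifelse(is.na(depth), NA, paste0("DP=", depth)),
      ifelse(is.na(mapq), NA, paste0("MQ=", mapq)),
      ifelse(is.na(base_qual), NA, paste0("BQ=", base_qual)),
      ifelse(is.na(vaf), NA, paste0("AF=", vaf))
    )
    apply(parts, 1, function(p) {
      p <- p[!is.na(p)]
      if (length(p) == 0) "." else paste(p, collapse = ";")
    })
  })
  if (nrow(records) == 0) info <- character()
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  records$chrom, records$pos1, records$ref, records$alt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}
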