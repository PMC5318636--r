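#' Classify a base change as transition or transversion
#'
#' Base changes are counted as unordered pairs, so G→A and A→G both fall in
#' class A/G. Transitions are the purine↔purine and pyrimidine↔pyrimidine
#' pairs A/G and C/T; the four remaining pairs (A/C, A/T, C/G, G/T) are
#' transversions.
#'
#' @param ref_base,alt_base Single bases; vectors are accepted.
#' @return Tibble with columns `pair` (e.g. `"A/G"`, NA for ambiguous bases)
#'   and `class` (`"transition"`, `"transversion"`, or `"unclassified"` when
#'   either base is not in A/C/G/T).
#' @export
classify_base_change <- function(ref_base, alt_base) {
  ok <- ref_base %in% c("A", "C", "G", "T") &
    alt_base %in% c("A", "C", "G", "T") & ref_base != alt_base
  lo <- pmin(ref_base, alt_base)
  hi <- pmax(ref_base, alt_base)
  pair <- ifelse(ok, paste0(lo, "/", hi), NA_character_)
  tibble(
    pair = pair,
    class = dplyr::case_when(
      !ok ~ "unclassified",
      pair %in% c("A/G", "C/T") ~ "transition",
      TRUE ~ "transversion"
    )
  )
}

spectrum_pairs <- c("A/G", "C/T", "A/C", "A/T", "C/G", "G/T")

#' Base-change spectrum and Ts/Tv ratio
#'
#' Tallies the six unordered base-change classes over filtered SNP records
#' and computes the transition/transversion ratio
#' `ts_tv = (n[A/G] + n[C/T]) / (n[A/C] + n[A/T] + n[C/G] + n[G/T])`.
#' A ratio well above 0.5 — the expectation under uniform substitution,
#' since transversions have twice as many classes — is the classic
#' transition bias; resequenced rice genomes sit around 2.2–2.4.
#'
#' @param records Filtered SNP tibble (one or more samples; tallied per
#'   sample). Non-SNP records are ignored.
#' @return A `spectrum_table` tibble, one row per sample: columns `sample_id`,
#'   the six pair counts (backticked names like `` `A/G` ``), `ts_total`,
#'   `tv_total`, `unclassified`, and `ts_tv` (NA when no transversions —
#'   undefined, never infinity).
#' @export
spectrum <- function(records) {
  snps <- records %>% filter(.data$vtype == "SNP")
  cls <- classify_base_change(snps$ref, snps$alt)
  tagged <- snps %>% mutate(pair = cls$pair)
  tb <- tagged %>%
    dplyr::distinct(.data$sample_id) %>%
    arrange(.data$sample_id)
  for (p in spectrum_pairs) {
    cnt <- tagged %>%
      filter(.data$pair == !!p) %>%
      dplyr::count(.data$sample_id)
    tb[[p]] <- dplyr::coalesce(
      cnt$n[match(tb$sample_id, cnt$sample_id)], 0L)
  }
  uncl <- tagged %>%
    filter(is.na(.data$pair)) %>%
    dplyr::count(.data$sample_id)
  tb$unclassified <- dplyr::coalesce(
    uncl$n[match(tb$sample_id, uncl$sample_id)], 0L)
  out <- tb %>%
    mutate(ts_total = .data$`A/G` + .data$`C/T`,
           tv_total = .data$`A/C` + .data$`A/T` + .data$`C/G` + .data$`G/T`,
           ts_tv = ifelse(.data$tv_total > 0,
                          .data$ts_total / .data$tv_total, NA_real_))
  class(out) <- c("spectrum_table", class(out))
  out
}

#' Export a spectrum table as TSV
#'
#' Ratios are rounded half-up to 3 decimals, the conventional table format.
#' @param spec A `spectrum_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  spec %>%
    as_tibble() %>%
    mutate(ts_tv = round_half_up(.data$ts_tv, 3)) %>%
    readr::write_tsv(path)
  invisible(path)
}

#' InDel length histogram
#'
#' Signed lengths: `+k` for a k-bp insertion, `-k` for a k-bp deletion,
#' computed as `nchar(alt) - nchar(ref)` on prefix-normalized records.
#'
#' @param records Filtered variant tibble; only INS/DEL rows are used.
#' @return Tibble per sample and signed `length` with `count`, plus
#'   attributes-free summary columns joined in: use [indel_length_summary()]
#'   for max insertion/deletion and mono-/dinucleotide fractions.
#' @export
indel_lengths <- function(records) {
  records %>%
    filter(.data$vtype %in% c("INS", "DEL")) %>%
    mutate(length = nchar(.data$alt) - nchar(.data$ref)) %>%
    dplyr::count(.data$sample_id, .data$length, name = "count") %>%
    arrange(.data$sample_id, .data$length)
}

#' Summary statistics of InDel lengths
#' @param records Filtered variant tibble.
#' @return One row per sample: `n_indel`, `max_insertion`, `max_deletion`
#'   (positive bp), `frac_mono`, `frac_di`.
#' @export
indel_length_summary <- function(records) {
  indel_lengths(records) %>%
    group_by(.data$sample_id) %>%
    summarise(
      n_indel = sum(.data$count),
      max_insertion = max(c(0L, .data$length[.data$length > 0])),
      max_deletion = max(c(0L, -.data$length[.data$length < 0])),
      frac_mono = sum(.data$count[abs(.data$length) == 1]) / sum(.data$count),
      frac_di = sum(.data$count[abs(.data$length) == 2]) / sum(.data$count),
      .groups = "drop")
}
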