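#' Bin variants into fixed non-overlapping windows
#'
#' Counts variants of one class per window of `window_size` bp on every
#' chromosome of the genome. A variant at 1-based position p falls in window
#' `floor((p - 1) / window_size)`; insertions and deletions are assigned by
#' their anchor position (the first REF base). The final window of each
#' chromosome may be partial and keeps its true width, so telomeric variants
#' are never dropped.
#'
#' @param records Filtered variant tibble (one sample).
#' @param genome A `genome_ref`; its chromosomes define the window grid.
#' @param window_size Window width in bp, `>= 1000`. Default 100 kb.
#' @param variant_class One of `"SNP"`, `"INS"`, `"DEL"`, `"INDEL"`
#'   (insertions plus deletions).
#' @return A `density_track` tibble: `sample_id, variant_class, chrom,
#'   window, start0, end0, width, count`, one row per window, every window
#'   of every chromosome present. Variants beyond the chromosome end are
#'   excluded with a warning; their count is in attribute `n_out_of_range`.
#' @export
bin_counts <- function(records, genome, window_size = 100000L,
                       variant_class = c("SNP", "INS", "DEL", "INDEL")) {
  variant_class <- match.arg(variant_class)
  stop_if_not(window_size >= 1000, "window_size must be >= 1000 bp")
  classes <- if (variant_class == "INDEL") c("INS", "DEL") else variant_class
  sample_id <- if (nrow(records)) records$sample_id[1] else NA_character_

  grid <- window_grid(genome, window_size)
  rec <- records %>% filter(.data$vtype %in% classes)
  lens <- chrom_lengths(genome)
  beyond <- is.na(lens[rec$chrom]) | rec$pos1 > lens[rec$chrom]
  if (any(beyond)) {
    warn(sprintf("%d variant(s) beyond chromosome end excluded", sum(beyond)))
    rec <- rec[!beyond, , drop = FALSE]
  }
  counts <- rec %>%
    mutate(window = (.data$pos1 - 1L) %/% as.integer(window_size)) %>%
    dplyr::count(.data$chrom, .data$window, name = "count")
  out <- grid %>%
    left_join(counts, by = c("chrom", "window")) %>%
    mutate(count = dplyr::coalesce(.data$count, 0L),
           sample_id = sample_id, variant_class = variant_class) %>%
    select("sample_id", "variant_class", "chrom", "window", "start0",
           "end0", "width", "count")
  attr(out, "window_size") <- as.integer(window_size)
  attr(out, "n_out_of_range") <- sum(beyond)
  class(out) <- c("density_track", class(out))
  out
}

window_grid <- function(genome, window_size) {
  purrr::map2(genome$chrom$chrom, genome$chrom$length, function(ch, len) {
    stop_if_not(len > 0, paste0("zero-length chromosome: ", ch))
    n <- ceiling(len / window_size)
    start0 <- as.integer((seq_len(n) - 1L) * window_size)
    tibble(chrom = ch, window = seq_len(n) - 1L, start0 = start0,
           end0 = as.integer(pmin(start0 + window_size, len)))
  }) %>%
    bind_rows() %>%
    mutate(width = .data$end0 - .data$start0)
}

#' Per-chromosome density summary of a track
#'
#' @param track A `density_track` from [bin_counts()].
#' @return Tibble with one row per chromosome: `total` count, `mean_per_window`
#'   (per full-window equivalent: total divided by chromosome length in
#'   window units, so the partial final window is weighted by its true
#'   width), and `per_kb` density (total / (chrom length / 1000)).
#' @export
density_summary <- function(track) {
  ws <- attr(track, "window_size")
  track %>%
    as_tibble() %>%
    group_by(sample_id = .data$sample_id,
             variant_class = .data$variant_class, chrom = .data$chrom) %>%
    summarise(chrom_length = sum(.data$width), total = sum(.data$count),
              .groups = "drop") %>%
    mutate(mean_per_window = .data$total / (.data$chrom_length / ws),
           per_kb = .data$total / (.data$chrom_length / 1000))
}

#' Export a density track as TSV or BEDGRAPH
#'
#' @param track A `density_track`.
#' @param path Output file.
#' @param format `"tsv"` (chrom, window_start0, window_end0, count) or
#'   `"bedgraph"`.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, format = c("tsv", "bedgraph")) {
  format <- match.arg(format)
  tb <- track %>%
    as_tibble() %>%
    select(chrom = "chrom", window_start0 = "start0", window_end0 = "end0",
           count = "count")
  if (format == "tsv") {
    readr::write_tsv(tb, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("track type=bedGraph name=\"%s_%s\"",
                       track$sample_id[1], track$variant_class[1]), con)
    writeLines(sprintf("%s\t%d\t%d\t%d", tb$chrom, tb$window_start0,
                       tb$window_end0, tb$count), con)
  }
  invisible(path)
}

#' @method autoplot density_track
#' @export
autoplot.density_track <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = (.data$start0 + .data$end0) / 2e6, y = .data$count)) +
    geom_col(width = diff(range(object$end0)) / 1e6 / nrow(object),
             fill = "grey30") +
    facet_wrap(~chrom, scales = "free_x") +
    labs(x = "position (Mb)",
         y = sprintf("%s per %d kb window", object$variant_class[1],
                     attr(object, "window_size") %/% 1000),
         title = object$sample_id[1]) +
    theme_minimal()
}
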