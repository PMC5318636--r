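#' Find SNP deserts in a density track
#'
#' A SNP desert is a maximal run of consecutive windows whose SNP density
#' falls strictly below `threshold_per_kb` (default 1 SNP/kb). A window of
#' width w bp qualifies iff `count < threshold_per_kb * w / 1000`; runs never
#' cross chromosome boundaries and single qualifying windows are reported,
#' so the minimum reportable desert is one window.
#'
#' @param track A SNP `density_track` from [bin_counts()]. Tracks of other
#'   variant classes are refused: deserts are defined on SNP density only.
#' @param threshold_per_kb Density threshold in SNPs per kb.
#' @return Tibble of `desert_interval` rows: `sample_id, chrom, start0, end0,
#'   size_bp, n_windows, genes_within` (NA until
#'   [annotate_desert_genes()] is applied).
#' @export
find_deserts <- function(track, threshold_per_kb = 1.0) {
  stop_if_not(identical(track$variant_class[1], "SNP") || nrow(track) == 0,
              "deserts are defined on SNP tracks only")
  tb <- as_tibble(track) %>%
    mutate(qual = .data$count < threshold_per_kb * .data$width / 1000)
  out <- tb %>%
    group_by(.data$chrom) %>%
    dplyr::group_modify(function(d, key) {
      r <- rle(d$qual)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      if (length(runs) == 0) {
        return(tibble(start0 = integer(), end0 = integer(),
                      n_windows = integer()))
      }
      tibble(start0 = d$start0[starts[runs]], end0 = d$end0[ends[runs]],
             n_windows = r$lengths[runs])
    }) %>%
    ungroup() %>%
    mutate(sample_id = track$sample_id[1], size_bp = .data$end0 - .data$start0,
           genes_within = NA_integer_, sub_window = FALSE) %>%
    select("sample_id", "chrom", "start0", "end0", "size_bp", "n_windows",
           "genes_within", "sub_window") %>%
    arrange(.data$chrom, .data$start0)
  attr(out, "window_size") <- attr(track, "window_size")
  attr(out, "threshold_per_kb") <- threshold_per_kb
  out
}

#' Intersect SNP deserts across samples
#'
#' Computes the bp-level set intersection of every sample's desert intervals
#' and reports the maximal shared intervals, tagged `sample_id = "shared"`.
#' Shared intervals shorter than one window are retained and flagged
#' `sub_window`.
#'
#' @param per_sample Named list (or bare list) of desert tibbles from
#'   [find_deserts()], one per sample; at least two.
#' @return Desert tibble with `sample_id = "shared"`; `n_windows` is NA for
#'   sub-window fragments.
#' @export
shared_deserts <- function(per_sample) {
  stop_if_not(length(per_sample) >= 2,
              "shared deserts require at least two samples")
  ws <- attr(per_sample[[1]], "window_size") %||% NA_integer_
  chroms <- unique(unlist(purrr::map(per_sample, ~ unique(.x$chrom))))
  out <- purrr::map(sort(chroms), function(ch) {
    acc <- per_sample[[1]] %>% filter(.data$chrom == ch)
    for (d in per_sample[-1]) {
      acc <- intersect_intervals(acc, d %>% filter(.data$chrom == ch))
      if (nrow(acc) == 0) break
    }
    if (nrow(acc) == 0) return(NULL)
    acc %>% mutate(chrom = ch)
  }) %>%
    bind_rows()
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), start0 = integer(), end0 = integer())
  }
  out <- out %>%
    mutate(sample_id = "shared", size_bp = .data$end0 - .data$start0,
           n_windows = if (is.na(ws)) NA_integer_ else
             ifelse(.data$size_bp %% ws == 0, .data$size_bp %/% ws,
                    NA_integer_),
           genes_within = NA_integer_,
           sub_window = !is.na(ws) & .data$size_bp < ws) %>%
    select("sample_id", "chrom", "start0", "end0", "size_bp", "n_windows",
           "genes_within", "sub_window") %>%
    arrange(.data$chrom, .data$start0)
  attr(out, "window_size") <- ws
  out
}

#' Count genes fully contained in each desert
#'
#' Fills `genes_within` with the number of gene spans lying entirely inside
#' the interval; genes straddling a desert boundary are not counted.
#'
#' @param deserts Desert tibble from [find_deserts()] or [shared_deserts()].
#' @param gene_spans `genes` tibble from [load_gene_models()].
#' @return The desert tibble with `genes_within` filled.
#' @export
annotate_desert_genes <- function(deserts, gene_spans) {
  deserts$genes_within <- purrr::pmap_int(
    list(deserts$chrom, deserts$start0, deserts$end0),
    function(ch, s, e) {
      sum(gene_spans$chrom == ch & gene_spans$start0 >= s &
            gene_spans$end0 <= e)
    })
  deserts
}

#' Write deserts as BED
#'
#' 0-based half-open BED intervals with the desert size as score.
#' @param deserts Desert tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_deserts_bed <- function(deserts, path) {
  lines <- sprintf("%s\t%d\t%d\t%s_desert\t%d", deserts$chrom,
                   deserts$start0, deserts$end0, deserts$sample_id,
                   deserts$size_bp)
  writeLines(lines, path)
  invisible(path)
}
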