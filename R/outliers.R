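#' Per-gene nonsynonymous SNP density
#'
#' Density is nonsynonymous SNPs per kb of the gene's CDS union (bases
#' shared between overlapping transcripts counted once). Genes with no CDS
#' are excluded; genes with zero nonsynonymous SNPs are retained at density
#' zero. An alternative denominator — the full gene span — is available for
#' sensitivity checks.
#'
#' @param effects Effect tibble from [annotate_variants()] (one sample).
#' @param gene_spans `genes` tibble from [load_gene_models()].
#' @param denominator `"cds_union"` (default) or `"span"`.
#' @return Tibble `gene_id, nssnp_count, denom_bp, density` (per kb).
#' @export
gene_ns_density <- function(effects, gene_spans,
                            denominator = c("cds_union", "span")) {
  denominator <- match.arg(denominator)
  counts <- effects %>%
    filter(.data$category == "cds_nonsynonymous") %>%
    dplyr::count(.data$gene_id, name = "nssnp_count")
  out <- gene_spans %>%
    mutate(denom_bp = if (denominator == "cds_union") .data$cds_union_length
           else .data$end0 - .data$start0) %>%
    filter(.data$denom_bp > 0) %>%
    left_join(counts, by = "gene_id") %>%
    mutate(nssnp_count = dplyr::coalesce(.data$nssnp_count, 0L),
           density = .data$nssnp_count / (.data$denom_bp / 1000)) %>%
    select("gene_id", "nssnp_count", "denom_bp", "density")
  class(out) <- c("gene_density", class(out))
  out
}

#' Tukey five-number summary with boxplot fences
#'
#' Hinges are computed by Tukey's rule: the median of the lower / upper half
#' of the sorted data, each half including the overall median when n is odd
#' (the convention behind the classic box-and-whisker plot). The upper fence
#' is `Q3 + 1.5 * IQR`.
#'
#' @param values Numeric vector, length >= 4, no NAs.
#' @return A `five_num` list: `min, q1, median, q3, max, iqr, upper_fence,
#'   lower_fence, n`.
#' @export
five_number_summary <- function(values) {
  stop_if_not(length(values) >= 4,
              "five_number_summary needs at least 4 values")
  stop_if_not(!anyNA(values), "values must not contain NA")
  s <- sort(values)
  n <- length(s)
  med <- stats::median(s)
  half <- if (n %% 2 == 0) n / 2 else (n + 1) / 2
  q1 <- stats::median(s[1:half])
  q3 <- stats::median(s[(n - half + 1):n])
  iqr <- q3 - q1
  structure(list(min = s[1], q1 = q1, median = med, q3 = q3, max = s[n],
                 iqr = iqr, upper_fence = q3 + 1.5 * iqr,
                 lower_fence = q1 - 1.5 * iqr, n = n),
            class = "five_num")
}

#' @export
print.five_num <- function(x, ...) {
  cat(sprintf(
    "<five_num> n=%d  min=%g  q1=%g  median=%g  q3=%g  max=%g  upper fence=%g\n",
    x$n, x$min, x$q1, x$median, x$q3, x$max, x$upper_fence))
  invisible(x)
}

#' @method tidy five_num
#' @export
tidy.five_num <- function(x, ...) {
  tibble(statistic = c("min", "q1", "median", "q3", "max", "iqr",
                       "upper_fence", "lower_fence"),
         value = unlist(x[c("min", "q1", "median", "q3", "max", "iqr",
                            "upper_fence", "lower_fence")],
                        use.names = FALSE))
}

#' Flag outlier genes above the boxplot upper fence
#'
#' A gene is an outlier when its density lies strictly above
#' `q3 + 1.5 * IQR` of the density distribution. The cutoff is one-sided:
#' low-density genes are never flagged.
#'
#' @param densities Tibble from [gene_ns_density()].
#' @param summary Optional [five_number_summary()] of `densities$density`;
#'   computed when omitted.
#' @return Outlier rows of `densities`, sorted by decreasing density, with
#'   the fence in attribute `upper_fence`.
#' @export
find_outlier_genes <- function(densities, summary = NULL) {
  if (is.null(summary)) summary <- five_number_summary(densities$density)
  out <- densities %>%
    filter(.data$density > summary$upper_fence) %>%
    arrange(desc(.data$density))
  attr(out, "upper_fence") <- summary$upper_fence
  attr(out, "five_num") <- summary
  out
}

#' Export an outlier-gene table as TSV
#' @param outliers Tibble from [find_outlier_genes()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_outlier_genes <- function(outliers, path) {
  outliers %>%
    as_tibble() %>%
    mutate(denom_kb = .data$denom_bp / 1000) %>%
    select("gene_id", "nssnp_count", "denom_kb", "density") %>%
    readr::write_tsv(path)
  invisible(path)
}

#' @method autoplot gene_density
#' @export
autoplot.gene_density <- function(object, ...) {
  fn <- five_number_summary(object$density)
  ggplot(as_tibble(object), aes(x = "", y = .data$density)) +
    geom_boxplot(coef = 1.5, outlier.colour = "firebrick",
                 outlier.size = 0.8) +
    geom_hline(yintercept = fn$upper_fence, linetype = "dashed") +
    labs(x = NULL, y = "nonsynonymous SNPs per kb CDS",
         subtitle = sprintf("upper fence = %.3g", fn$upper_fence)) +
    theme_minimal()
}
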