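#' Assemble windowed counts into a windows-by-samples matrix
#'
#' All tracks must share the same window grid (same genome and window size).
#' Rows follow genome chromosome order then window index; columns follow the
#' input sample order. Windows with zero counts in every sample are kept —
#' shared deserts are signal, not missingness.
#'
#' @param tracks Named list of SNP `density_track`s, one per sample.
#' @return A `density_matrix`: list with `counts` (numeric matrix, windows x
#'   samples), `windows` (tibble chrom/window/start0/end0) and `samples`.
#' @export
density_matrix <- function(tracks) {
  stop_if_not(length(tracks) >= 1, "no tracks supplied")
  if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
    names(tracks) <- purrr::map_chr(tracks, ~ .x$sample_id[1])
  }
  ref <- as_tibble(tracks[[1]]) %>% select("chrom", "window", "start0", "end0")
  cols <- purrr::imap(tracks, function(tr, nm) {
    tb <- as_tibble(tr)
    same <- identical(tb %>% select("chrom", "window", "start0", "end0"),
                      ref)
    stop_if_not(same, paste0("track '", nm,
                             "' is on a different window grid"))
    tb$count
  })
  m <- do.call(cbind, cols)
  colnames(m) <- names(tracks)
  structure(list(counts = m, windows = ref, samples = names(tracks)),
            class = "density_matrix")
}

#' Pearson correlation of windowed SNP densities between samples
#'
#' The sample-relatedness statistic of resequencing panels: Pearson's r
#' between the windowed SNP counts of every sample pair, genome-wide or per
#' chromosome. Same-subspecies samples correlate near one; divergent groups
#' near zero.
#'
#' @param m A `density_matrix`.
#' @param scope `"genome"` (one matrix over the concatenated windows,
#'   default) or `"per_chromosome"` (named list of matrices).
#' @param log1p Correlate `log1p(count)` instead of raw counts.
#' @return For `"genome"`, a `correlation_result`: list with `r` (symmetric
#'   samples x samples matrix, unit diagonal) and `n_windows`. For
#'   `"per_chromosome"`, a named list of `correlation_result`s.
#' @export
pearson_matrix <- function(m, scope = c("genome", "per_chromosome"),
                           log1p = FALSE) {
  scope <- match.arg(scope)
  one <- function(counts, label) {
    stop_if_not(nrow(counts) >= 2,
                paste0("need >= 2 windows to correlate (", label, ")"))
    x <- if (log1p) base::log1p(counts) else counts
    sds <- apply(x, 2, stats::sd)
    flat <- colnames(x)[sds == 0]
    if (length(flat) > 0) {
      abort(paste0("sample(s) with zero variance across windows: ",
                   paste(flat, collapse = ", ")))
    }
    structure(list(r = stats::cor(x, method = "pearson"),
                   n_windows = nrow(counts)),
              class = "correlation_result")
  }
  if (scope == "genome") {
    one(m$counts, "genome")
  } else {
    chroms <- unique(m$windows$chrom)
    stats::setNames(purrr::map(chroms, function(ch) {
      one(m$counts[m$windows$chrom == ch, , drop = FALSE], ch)
    }), chroms)
  }
}

#' Cluster samples on correlation distance
#'
#' Agglomerative clustering of samples with distance `d = 1 - r` and average
#' linkage (UPGMA) by default. Samples are ordered lexicographically before
#' linkage so exact ties resolve deterministically regardless of input
#' order.
#'
#' @param corr A `correlation_result` from [pearson_matrix()], or a bare
#'   symmetric correlation matrix.
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @return A `sample_clustering`: list with `hclust` (the tree), `phylo`
#'   (the [ape::phylo] version), `r`, and `linkage`.
#' @export
cluster_samples <- function(corr, linkage = c("average", "single",
                                              "complete")) {
  linkage <- match.arg(linkage)
  r <- if (inherits(corr, "correlation_result")) corr$r else corr
  stop_if_not(isTRUE(all.equal(r, t(r), tolerance = 1e-8)),
              "correlation matrix must be symmetric")
  ord <- order(colnames(r))
  r <- r[ord, ord, drop = FALSE]
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc, phylo = ape::as.phylo(hc), r = r,
                 linkage = linkage),
            class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("<sample_clustering> ", length(x$hclust$labels), " samples, ",
      x$linkage, " linkage on 1 - r\n", sep = "")
  print(x$phylo)
  invisible(x)
}

#' Groups from the first split of a sample clustering
#' @param clustering A `sample_clustering`.
#' @param k Number of groups (default 2).
#' @return Named integer vector of group memberships.
#' @export
cut_groups <- function(clustering, k = 2) {
  stats::cutree(clustering$hclust, k = k)
}

#' Write a sample clustering as Newick
#' @param clustering A `sample_clustering`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(clustering, path) {
  ape::write.tree(clustering$phylo, file = path)
  invisible(path)
}

#' Write a correlation matrix as TSV (with a leading sample column)
#' @param corr A `correlation_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_correlation <- function(corr, path) {
  tb <- as_tibble(corr$r, rownames = "sample_id")
  readr::write_tsv(tb, path)
  invisible(path)
}

#' @method tidy correlation_result
#' @export
tidy.correlation_result <- function(x, ...) {
  as_tibble(x$r, rownames = "sample_a") %>%
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b",
                        values_to = "r") %>%
    filter(.data$sample_a < .data$sample_b)
}

#' @method glance correlation_result
#' @export
glance.correlation_result <- function(x, ...) {
  off <- x$r[lower.tri(x$r)]
  tibble(n_samples = ncol(x$r), n_windows = x$n_windows,
         r_min = min(off), r_mean = mean(off), r_max = max(off))
}

#' @method tidy sample_clustering
#' @export
tidy.sample_clustering <- function(x, ...) {
  m <- x$hclust$merge
  tibble(step = seq_len(nrow(m)), height = x$hclust$height,
         left = m[, 1], right = m[, 2])
}

#' @method glance sample_clustering
#' @export
glance.sample_clustering <- function(x, ...) {
  tibble(n_samples = length(x$hclust$labels), linkage = x$linkage,
         max_height = max(x$hclust$height))
}

#' @method autoplot correlation_result
#' @export
autoplot.correlation_result <- function(object, ...) {
  tb <- as_tibble(object$r, rownames = "sample_a") %>%
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b",
                        values_to = "r")
  ggplot(tb, aes(.data$sample_a, .data$sample_b, fill = .data$r)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$r)), size = 3) +
    scale_fill_gradient2(low = "steelblue", mid = "white",
                         high = "firebrick", midpoint = 0.5,
                         limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "Pearson r") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' @method autoplot sample_clustering
#' @export
autoplot.sample_clustering <- function(object, ...) {
  dend <- object$hclust
  seg <- dendrogram_segments(dend)
  ggplot(seg) +
    geom_segment(aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend)) +
    scale_x_continuous(breaks = seq_along(dend$labels[dend$order]),
                       labels = dend$labels[dend$order]) +
    labs(x = NULL, y = "1 - r (height)") +
    theme_minimal()
}

# minimal hclust -> segment table for ggplot dendrograms
dendrogram_segments <- function(hc) {
  n <- length(hc$order)
  pos <- numeric(n)
  pos[hc$order] <- seq_len(n)
  xc <- numeric(nrow(hc$merge))
  segs <- list()
  leaf_x <- function(i) if (i < 0) pos[-i] else xc[i]
  leaf_h <- function(i) if (i < 0) 0 else hc$height[i]
  for (k in seq_len(nrow(hc$merge))) {
    a <- hc$merge[k, 1]; b <- hc$merge[k, 2]
    xa <- leaf_x(a); xb <- leaf_x(b)
    ha <- leaf_h(a); hb <- leaf_h(b)
    h <- hc$height[k]
    xc[k] <- (xa + xb) / 2
    segs[[k]] <- tibble(
      x = c(xa, xb, xa), y = c(ha, hb, h),
      xend = c(xa, xb, xb), yend = c(h, h, h))
  }
  bind_rows(segs)
}
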