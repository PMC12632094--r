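# Normalize a ranking argument: a named numeric/integer vector of ordinal
# rank positions (1 = most long-lived), or an outranking_result.
as_ranking <- function(rank) {
  if (inherits(rank, "outranking_result")) rank <- rank$rank
  if (inherits(rank, "ranked_dataset")) rank <- rank$ranks
  if (is.null(names(rank))) stop("ranking must be named by gene")
  names(rank) <- toupper(names(rank))
  rank
}

#' Cumulative distribution of a gene set along a ranking
#'
#' For each rank position, the fraction of the gene set found at that
#' position or better (closer to the long-lived top). Under a uniformly
#' spread set the curve follows the diagonal.
#'
#' @param rank Named ranking (1 = most long-lived) or an
#'   `outranking_result`.
#' @param genes Character vector; at least one must be in the ranking.
#' @return An object of class `rank_ecdf`: list with `position` (1..N),
#'   `cum_fraction`, `set_size` (genes in the ranking) and `n` (N).
#' @export
rank_ecdf <- function(rank, genes) {
  rank <- as_ranking(rank)
  genes <- toupper(genes)
  hit <- names(rank) %in% genes
  if (!any(hit)) stop("no set gene present in the ranking")
  N <- length(rank)
  counts <- tabulate(ceiling(rank[hit]), nbins = N)
  structure(list(position = seq_len(N),
                 cum_fraction = cumsum(counts) / sum(hit),
                 set_size = sum(hit), n = N),
            class = "rank_ecdf")
}

#' Wilcoxon rank-sum shift test of a gene set along a ranking
#'
#' Tests whether the set's rank positions differ from the complement's, i.e.
#' whether the set deviates from a uniform distribution along the ranking.
#' Uses the normal approximation with tie correction, or exact enumeration
#' when both groups have at most `exact_max` genes and no ties.
#'
#' @param rank Named ranking or `outranking_result`.
#' @param genes Gene set (character).
#' @param alternative `"two_sided"`, `"toward_top"` (set concentrated at the
#'   long-lived top, i.e. smaller rank positions) or `"toward_bottom"`.
#' @param exact_max Group-size ceiling for the exact test (default 8).
#' @return List with `statistic` (the rank-sum W of the set vs complement),
#'   `p_value`, `n_set`, `n_complement`, `alternative`.
#' @export
rank_shift_test <- function(rank, genes,
                            alternative = c("two_sided", "toward_top",
                                            "toward_bottom"),
                            exact_max = 8L) {
  alternative <- match.arg(alternative)
  rank <- as_ranking(rank)
  genes <- toupper(genes)
  inset <- names(rank) %in% genes
  if (!any(inset) || all(inset))
    stop("set and complement must each contain at least one ranked gene")
  x <- rank[inset]; y <- rank[!inset]
  alt <- switch(alternative, two_sided = "two.sided",
                toward_top = "less", toward_bottom = "greater")
  use_exact <- length(x) <= exact_max && length(y) <= exact_max &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alt, exact = use_exact,
                       correct = !use_exact)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_set = length(x), n_complement = length(y),
       alternative = alternative)
}

#' Hypergeometric tail enrichment of a gene set
#'
#' One-sided over-representation of a gene set within the top or bottom
#' `fraction` of the ranking: with tail size k = max(1, floor(fraction N)),
#' p = P(X >= overlap) for X ~ Hypergeometric(N, |set|, k).
#'
#' @param rank Named ranking or `outranking_result`.
#' @param genes Gene set.
#' @param tail `"top"` (long-lived end) or `"bottom"`.
#' @param fraction Tail fraction in (0, 1).
#' @return An object of class `tail_enrichment`: list with `tail`,
#'   `fraction`, `tail_size`, `set_size`, `overlap`, `expected` and
#'   `p_value`.
#' @export
tail_enrichment <- function(rank, genes, tail = c("top", "bottom"),
                            fraction) {
  tail <- match.arg(tail)
  stopifnot(fraction > 0, fraction < 1)
  rank <- as_ranking(rank)
  genes <- toupper(genes)
  N <- length(rank)
  k <- max(1L, floor(fraction * N))
  o <- order(rank)
  tail_genes <- if (tail == "top") names(rank)[o[seq_len(k)]]
                else names(rank)[o[seq.int(N - k + 1L, N)]]
  m <- sum(names(rank) %in% genes)     # set genes in the ranked universe
  q <- sum(tail_genes %in% genes)
  p <- stats::phyper(q - 1L, m, N - m, k, lower.tail = FALSE)
  structure(list(tail = tail, fraction = fraction, tail_size = k,
                 set_size = m, overlap = q, expected = k * m / N,
                 p_value = p),
            class = "tail_enrichment")
}

#' @export
print.tail_enrichment <- function(x, ...) {
  cat("tail_enrichment: ", x$overlap, "/", x$tail_size, " in ", x$tail,
      " ", format(100 * x$fraction), "% (expected ",
      format(x$expected, digits = 3), "), p = ",
      format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Tail over-representation across a gene-set collection
#'
#' Applies [tail_enrichment()] to every set of a collection and adjusts the
#' p-values with Benjamini-Hochberg across the sets (one analysis family).
#'
#' @param rank Named ranking or `outranking_result`.
#' @param sets A [gene_set_collection()] or named list of gene vectors.
#' @param tail,fraction As in [tail_enrichment()].
#' @return Data frame `term, tail_size, set_size, overlap, expected,
#'   p_value, fdr`, sorted by p-value.
#' @export
tail_enrichment_sets <- function(rank, sets, tail = c("top", "bottom"),
                                 fraction) {
  tail <- match.arg(tail)
  if (inherits(sets, "gene_set_collection")) sets <- sets$genes
  res <- lapply(names(sets), function(nm) {
    te <- tail_enrichment(rank, sets[[nm]], tail, fraction)
    data.frame(term = nm, tail_size = te$tail_size, set_size = te$set_size,
               overlap = te$overlap, expected = te$expected,
               p_value = te$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), , drop = FALSE]
}

#' Spearman correlation between rank and a per-gene covariate
#'
#' Tie-aware Spearman correlation (two-sided t-approximation p-value)
#' between the consensus rank positions and a per-gene phenotype such as
#' relative growth rate or measured relative lifespan, over the genes
#' common to both.
#'
#' @param rank Named ranking or `outranking_result`.
#' @param values Named numeric vector of per-gene values.
#' @return List with `rho`, `p_value`, `n`.
#' @export
rank_value_correlation <- function(rank, values) {
  rank <- as_ranking(rank)
  if (is.null(names(values))) stop("'values' must be named by gene")
  names(values) <- toupper(names(values))
  common <- intersect(names(rank), names(values))
  if (length(common) < 3L) stop("need at least 3 genes in common")
  st <- spearman_t(rank[common], values[common])
  list(rho = st$rho, p_value = st$p, n = st$n)
}

#' Binned trend of a covariate along the ranking
#'
#' Splits the ranking into `n_bins` contiguous bins (deciles by default) and
#' returns the per-bin mean of the covariate with a t confidence interval.
#'
#' @param rank Named ranking or `outranking_result`.
#' @param values Named numeric vector of per-gene values.
#' @param n_bins Number of contiguous rank bins (default 10).
#' @param ci_level Confidence level (default 0.95).
#' @return Data frame `bin, n, rank_mid, mean, lower, upper`.
#' @export
decile_trend <- function(rank, values, n_bins = 10L, ci_level = 0.95) {
  rank <- as_ranking(rank)
  if (is.null(names(values))) stop("'values' must be named by gene")
  names(values) <- toupper(names(values))
  common <- intersect(names(rank), names(values))
  if (!length(common)) stop("no genes in common")
  r <- rank[common]; v <- values[common]
  brk <- seq(min(r) - 0.5, max(r) + 0.5, length.out = n_bins + 1L)
  bin <- cut(r, breaks = brk, labels = FALSE, include.lowest = TRUE)
  out <- lapply(seq_len(n_bins), function(b) {
    vb <- v[bin == b]
    if (length(vb) == 0L) stop("empty rank bin ", b,
                               "; reduce 'n_bins' or supply more genes")
    if (length(vb) < 2L) stop("bin ", b, " has fewer than 2 genes; ",
                              "a confidence interval needs at least 2")
    mu <- mean(vb)
    se <- stats::sd(vb) / sqrt(length(vb))
    tq <- stats::qt(1 - (1 - ci_level) / 2, df = length(vb) - 1L)
    data.frame(bin = b, n = length(vb), rank_mid = mean(r[bin == b]),
               mean = mu, lower = mu - tq * se, upper = mu + tq * se)
  })
  do.call(rbind, out)
}
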