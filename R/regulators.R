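#' Construct a regulatory network
#'
#' @param edges Named list mapping transcription-factor id to a character
#'   vector of target genes (duplicates are removed).
#' @param evidence Optional data frame `tf, target, evidence` with evidence
#'   type (`binding`, `expression`, `both`).
#' @return An object of class `regulatory_network`.
#' @export
regulatory_network <- function(edges, evidence = NULL) {
  stopifnot(is.list(edges), !is.null(names(edges)))
  edges <- lapply(edges, function(t) unique(toupper(t)))
  structure(list(edges = edges, evidence = evidence),
            class = "regulatory_network")
}

#' Read a TF-target edge list from TSV
#'
#' @param path TSV with columns `tf`, `target` and optional `evidence`.
#' @return A [regulatory_network()].
#' @export
read_network_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("tf", "target") %in% names(tab)))
    stop("network table must have columns 'tf' and 'target'")
  regulatory_network(split(toupper(tab$target), tab$tf),
                     evidence = if ("evidence" %in% names(tab)) tab)
}

#' Associate transcription factors with functional-cluster leading edges
#'
#' For every (TF, cluster) pair, computes the fraction of the cluster's
#' leading-edge genes targeted by the TF and a one-sided hypergeometric
#' over-representation p-value of the overlap against the gene universe. A
#' TF is retained as relevant when p < `relevance_alpha` in at least one
#' cluster.
#'
#' @param leading_edges Named list: cluster label -> leading-edge gene set.
#' @param network A [regulatory_network()].
#' @param universe Character vector of background genes (must cover all
#'   leading-edge genes).
#' @param relevance_alpha Per-test relevance threshold (default 0.01).
#' @return An object of class `regulator_profiles`: list with `fractions`
#'   and `p_values` (TF x cluster matrices over retained TFs),
#'   `n_significant` (per retained TF), `relevance_alpha`, `clusters`, and
#'   `skipped` (TFs with no target in the universe).
#' @export
regulator_association <- function(leading_edges, network, universe,
                                  relevance_alpha = 0.01) {
  stopifnot(inherits(network, "regulatory_network"),
            length(leading_edges) >= 1L)
  universe <- unique(toupper(universe))
  leading_edges <- lapply(leading_edges, function(g)
    unique(toupper(g)))
  outside <- setdiff(unlist(leading_edges, use.names = FALSE), universe)
  if (length(outside))
    stop("leading-edge genes outside the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  if (any(lengths(leading_edges) == 0L)) stop("empty cluster leading edge")
  N <- length(universe)
  tfs <- names(network$edges)
  targets <- lapply(network$edges, function(t) intersect(t, universe))
  skipped <- tfs[lengths(targets) == 0L]
  if (length(skipped))
    warning("TF(s) with no target in the universe skipped: ",
            paste(utils::head(skipped, 5L), collapse = ", "))
  tfs <- setdiff(tfs, skipped)
  K <- length(leading_edges)
  cl <- names(leading_edges)
  frac <- pv <- matrix(NA_real_, length(tfs), K, dimnames = list(tfs, cl))
  for (tf in tfs) {
    tg <- targets[[tf]]
    for (c in cl) {
      le <- leading_edges[[c]]
      q <- length(intersect(tg, le))
      frac[tf, c] <- q / length(le)
      pv[tf, c] <- stats::phyper(q - 1L, length(tg), N - length(tg),
                                 length(le), lower.tail = FALSE)
    }
  }
  nsig <- rowSums(pv < relevance_alpha)
  retained <- tfs[nsig >= 1L]
  structure(list(fractions = frac[retained, , drop = FALSE],
                 p_values = pv[retained, , drop = FALSE],
                 n_significant = nsig[retained],
                 relevance_alpha = relevance_alpha,
                 clusters = cl, skipped = skipped),
            class = "regulator_profiles")
}

#' Classify regulator breadth
#'
#' Labels each retained TF as a `global` regulator (significant in at least
#' `global_min_clusters` clusters), `local` (significant in at most
#' `local_max_clusters`) or `meso` (in between). Defaults follow the
#' qualitative reading of broad vs narrow regulation: global = at least two
#' thirds of the clusters, local = at most 2.
#'
#' @param profiles A [regulator_association()] result.
#' @param global_min_clusters Minimum significant clusters for `global`
#'   (default `ceiling(2/3 * n_clusters)`).
#' @param local_max_clusters Maximum significant clusters for `local`
#'   (default 2).
#' @return `profiles` with an added `breadth` element (named character
#'   vector: `global`/`meso`/`local`) and `order` (hierarchical-clustering
#'   row order of the fraction matrix, for report display).
#' @export
classify_breadth <- function(profiles, global_min_clusters = NULL,
                             local_max_clusters = 2L) {
  stopifnot(inherits(profiles, "regulator_profiles"))
  K <- length(profiles$clusters)
  if (is.null(global_min_clusters))
    global_min_clusters <- ceiling(2 / 3 * K)
  if (global_min_clusters <= local_max_clusters)
    stop("'global_min_clusters' must exceed 'local_max_clusters'")
  ns <- profiles$n_significant
  breadth <- ifelse(ns >= global_min_clusters, "global",
                    ifelse(ns <= local_max_clusters, "local", "meso"))
  profiles$breadth <- stats::setNames(breadth, names(ns))
  fr <- profiles$fractions
  profiles$order <- if (nrow(fr) >= 3L) {
    stats::hclust(stats::dist(fr), method = "average")$order
  } else seq_len(nrow(fr))
  profiles
}

#' @export
print.regulator_profiles <- function(x, ...) {
  cat("regulator_profiles: ", nrow(x$fractions), " TF(s) relevant (p < ",
      x$relevance_alpha, ") across ", length(x$clusters),
      " cluster(s)\n", sep = "")
  if (!is.null(x$breadth)) print(table(x$breadth))
  invisible(x)
}
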