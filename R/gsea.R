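#' Construct a gene-set collection
#'
#' @param genes Named list of character vectors (term id -> genes).
#' @param names Optional named character vector of human-readable term names.
#' @param namespace Optional named character vector (e.g. `"BP"`/`"CC"`).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(genes, names = NULL, namespace = NULL) {
  stopifnot(is.list(genes), !is.null(base::names(genes)))
  if (anyDuplicated(base::names(genes))) stop("duplicate term ids")
  genes <- lapply(genes, function(g) unique(toupper(g)))
  structure(list(genes = genes, names = names, namespace = namespace),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x$genes)
  cat("gene_set_collection: ", length(x$genes), " sets (sizes ",
      min(sizes), "-", max(sizes), ")\n", sep = "")
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' One term per line: `term_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' When the description has the form `namespace|name` the two parts are
#' split into the collection's `namespace` and `names` fields.
#'
#' @param path GMT file path.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1L), 1L)
  desc <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "",
                 character(1L))
  genes <- lapply(parts, function(p) if (length(p) >= 3L) p[-(1:2)]
                  else character())
  names(genes) <- ids
  ns <- nm <- stats::setNames(rep(NA_character_, length(ids)), ids)
  has_ns <- grepl("|", desc, fixed = TRUE)
  ns[has_ns] <- sub("\\|.*$", "", desc[has_ns])
  nm[has_ns] <- sub("^[^|]*\\|", "", desc[has_ns])
  nm[!has_ns] <- desc[!has_ns]
  gene_set_collection(genes, names = nm, namespace = ns)
}

#' Write gene sets in GMT format
#'
#' @param sets A [gene_set_collection()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  ids <- names(sets$genes)
  desc <- vapply(ids, function(id) {
    ns <- if (!is.null(sets$namespace)) sets$namespace[[id]] else NA
    nm <- if (!is.null(sets$names)) sets$names[[id]] else NA
    if (!is.na(ns)) paste0(ns, "|", if (is.na(nm)) id else nm)
    else if (!is.na(nm)) nm else id
  }, character(1L))
  lines <- vapply(seq_along(ids), function(i) {
    paste(c(ids[[i]], desc[[i]], sets$genes[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

# Order a named statistic decreasingly with a deterministic name tie-break.
order_statistic <- function(stat) {
  if (is.null(names(stat))) stop("statistic must be named by gene")
  names(stat) <- toupper(names(stat))
  stat[order(-stat, names(stat))]
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list from the long-lived top: at each set gene ("hit")
#' the running sum rises by \eqn{|s|^{exponent}} normalized by the hit
#' total, at each miss it falls by 1/(N - |S|). The enrichment score is the
#' signed maximum deviation from zero; the leading edge is the set genes up
#' to the maximum (positive ES) or from the minimum onward (negative ES).
#'
#' @param stat Named numeric statistic (e.g. phi-scores); internally sorted
#'   decreasingly, ties broken by gene name.
#' @param term_genes Character vector of set genes (at least one present).
#' @param weight_exponent Exponent on `|stat|` for hit increments; 0 gives
#'   the unweighted Kolmogorov-Smirnov-like statistic, 1 (default) the
#'   standard weighted form.
#' @return List with `es`, `running` (named running sum along the ranked
#'   list), `leading_edge`, and `n_hits`.
#' @export
running_enrichment_score <- function(stat, term_genes, weight_exponent = 1) {
  stat <- order_statistic(stat)
  term_genes <- unique(toupper(term_genes))
  N <- length(stat)
  hit <- names(stat) %in% term_genes
  k <- sum(hit)
  if (k == 0L) stop("no term gene present in the ranked universe")
  if (length(unique(stat)) == 1L) {
    # fully tied statistic: the ranking is arbitrary, ES defined as 0
    return(list(es = 0, running = stats::setNames(rep(0, N), names(stat)),
                leading_edge = character(), n_hits = k))
  }
  w <- abs(stat)^weight_exponent
  wh <- w * hit
  sumw <- sum(wh)
  inc <- if (sumw > 0) wh / sumw else hit / k
  dec <- if (N > k) (!hit) / (N - k) else rep(0, N)
  running <- cumsum(inc - dec)
  i_max <- which.max(running); i_min <- which.min(running)
  es <- if (running[i_max] >= -running[i_min]) running[i_max]
        else running[i_min]
  leading <- if (es >= 0) names(stat)[seq_len(i_max)][hit[seq_len(i_max)]]
             else names(stat)[seq.int(i_min, N)][hit[seq.int(i_min, N)]]
  list(es = unname(es), running = stats::setNames(running, names(stat)),
       leading_edge = leading, n_hits = k)
}

#' Preranked gene-set enrichment analysis
#'
#' Runs the weighted running-sum statistic of [running_enrichment_score()]
#' for every set whose effective size (after intersecting the ranked
#' universe) lies within `[min_size, max_size]`, against a gene-label
#' permutation null: each permutation reassigns the set to uniformly drawn
#' positions of the ranked list. The permutation p-value is
#' (1 + #\{same-sign permuted |ES| >= |ES|\}) / (1 + #\{same-sign
#' permutations\}), the normalized score NES divides ES by the mean
#' same-sign permuted |ES|, and Benjamini-Hochberg FDR is applied across
#' the retained sets.
#'
#' @param stat Named numeric statistic (e.g. phi-scores).
#' @param sets A [gene_set_collection()] or named list of gene vectors.
#' @param min_size,max_size Effective set-size filter (defaults 10 and 100).
#' @param n_perm Number of permutations (default 10000, minimum 100).
#' @param seed Integer seed; required, so runs are reproducible.
#' @param weight_exponent Passed to [running_enrichment_score()].
#' @return An object of class `gsea_result`: a data frame with columns
#'   `term, namespace, size, es, nes, p_value, fdr, direction,
#'   leading_edge` (`direction` is `"long"` for positive ES, `"short"` for
#'   negative); leading edges are semicolon-separated. The full leading-edge
#'   lists are attached as the `leading_edges` attribute (named list).
#' @export
preranked_gsea <- function(stat, sets, min_size = 10L, max_size = 100L,
                           n_perm = 10000L, seed, weight_exponent = 1) {
  if (missing(seed) || is.null(seed)) stop("'seed' is required")
  if (n_perm < 100L) stop("'n_perm' must be at least 100")
  if (inherits(sets, "gene_set_collection")) {
    namespace <- sets$namespace
    sets <- sets$genes
  } else namespace <- NULL
  sets <- lapply(sets, function(g) unique(toupper(g)))
  stat <- order_statistic(stat)
  N <- length(stat)
  eff <- lapply(sets, function(g) intersect(g, names(stat)))
  keep <- lengths(eff) >= min_size & lengths(eff) <= max_size
  if (!any(keep)) {
    warning("no gene set passes the ", min_size, "-", max_size,
            " effective-size filter")
    return(structure(data.frame(term = character(), namespace = character(),
                                size = integer(), es = numeric(),
                                nes = numeric(), p_value = numeric(),
                                fdr = numeric(), direction = character(),
                                leading_edge = character(),
                                stringsAsFactors = FALSE),
                     leading_edges = list(), class = c("gsea_result",
                                                       "data.frame")))
  }
  eff <- eff[keep]
  degenerate <- length(unique(stat)) == 1L
  w <- abs(stat)^weight_exponent
  pos_of <- stats::setNames(seq_len(N), names(stat))
  set.seed(seed)
  # one shared permutation pool per distinct set size keeps cost O(sizes)
  sizes <- sort(unique(lengths(eff)))
  perm_pool <- lapply(sizes, function(k) {
    if (degenerate) numeric() else gsea_perm_es_cpp(unname(w), k, n_perm)
  })
  names(perm_pool) <- as.character(sizes)
  rows <- vector("list", length(eff))
  ledges <- vector("list", length(eff))
  names(ledges) <- names(eff)
  for (i in seq_along(eff)) {
    genes <- eff[[i]]
    k <- length(genes)
    if (degenerate) {
      es <- 0; nes <- 0; p <- 1; le <- character()
    } else {
      res <- running_enrichment_score(stat, genes, weight_exponent)
      es <- res$es
      le <- res$leading_edge
      perm <- perm_pool[[as.character(k)]]
      same <- if (es >= 0) perm[perm >= 0] else perm[perm < 0]
      if (length(same) == 0L) {
        p <- 1; nes <- NA_real_
      } else {
        p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
        nes <- es / mean(abs(same))
      }
    }
    ledges[[i]] <- le
    rows[[i]] <- data.frame(
      term = names(eff)[[i]],
      namespace = if (!is.null(namespace)) namespace[[names(eff)[[i]]]]
                  else NA_character_,
      size = k, es = es, nes = nes, p_value = p,
      direction = if (es > 0) "long" else if (es < 0) "short"
                  else NA_character_,
      leading_edge = paste(le, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[, c("term", "namespace", "size", "es", "nes", "p_value",
                 "fdr", "direction", "leading_edge")]
  out <- out[order(out$p_value, -abs(out$es)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, leading_edges = ledges,
            class = c("gsea_result", "data.frame"))
}

#' Jaccard overlap network of enriched terms
#'
#' Builds the term-overlap network of significant terms: nodes are terms,
#' edges connect terms whose gene-content Jaccard index strictly exceeds
#' `ji_threshold`, and average-linkage hierarchical clustering of the
#' distance 1 - Ji groups redundant terms into functional clusters. Each
#' cluster is named after its largest member term.
#'
#' @param results A `gsea_result` (typically filtered to `fdr < 0.05`).
#' @param sets The [gene_set_collection()] used for the enrichment.
#' @param ji_threshold Edges kept where Ji > this value (strict; default
#'   0.1).
#' @param cut_height Dendrogram cut height on 1 - Ji (default 0.75).
#' @param universe Optional character vector restricting term gene content
#'   (e.g. the ranked universe).
#' @return An object of class `term_network`: list with `nodes` (data frame
#'   `term, direction, size, cluster`), `edges` (data frame
#'   `term_a, term_b, ji`), `clusters` (named character vector term ->
#'   cluster label) and `ji` (the full Jaccard matrix).
#' @export
term_network <- function(results, sets, ji_threshold = 0.1,
                         cut_height = 0.75, universe = NULL) {
  stopifnot(inherits(results, "gsea_result"), nrow(results) >= 1L)
  if (inherits(sets, "gene_set_collection")) sets <- sets$genes
  sets <- lapply(sets, function(g) unique(toupper(g)))
  terms <- results$term
  content <- lapply(sets[terms], function(g) {
    if (!is.null(universe)) intersect(g, toupper(universe)) else g
  })
  Tn <- length(terms)
  ji <- diag(1, Tn)
  dimnames(ji) <- list(terms, terms)
  if (Tn >= 2L) {
    for (i in seq_len(Tn - 1L)) for (j in seq.int(i + 1L, Tn)) {
      inter <- length(intersect(content[[i]], content[[j]]))
      uni <- length(union(content[[i]], content[[j]]))
      ji[i, j] <- ji[j, i] <- if (uni > 0L) inter / uni else 0
    }
  }
  edges <- which(upper.tri(ji) & ji > ji_threshold, arr.ind = TRUE)
  edges_df <- data.frame(term_a = terms[edges[, 1L]],
                         term_b = terms[edges[, 2L]],
                         ji = ji[edges], stringsAsFactors = FALSE)
  if (Tn >= 2L) {
    hc <- stats::hclust(stats::as.dist(1 - ji), method = "average")
    cl <- stats::cutree(hc, h = cut_height)
  } else cl <- stats::setNames(1L, terms)
  # label each cluster by its largest member term
  labels <- vapply(split(terms, cl), function(members) {
    members[[which.max(lengths(content[members]))]]
  }, character(1L))
  clusters <- stats::setNames(labels[as.character(cl)], terms)
  nodes <- data.frame(term = terms, direction = results$direction,
                      size = lengths(content)[terms],
                      cluster = unname(clusters), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges_df, clusters = clusters,
                 ji = ji),
            class = "term_network")
}

#' @export
print.term_network <- function(x, ...) {
  cat("term_network: ", nrow(x$nodes), " terms, ", nrow(x$edges),
      " edges, ", length(unique(x$clusters)), " clusters\n", sep = "")
  invisible(x)
}

#' Pooled leading-edge genes per functional cluster
#'
#' @param results A `gsea_result`.
#' @param network A [term_network()] built from the same results.
#' @return Named list: cluster label -> union of member terms' leading-edge
#'   genes.
#' @export
cluster_leading_edges <- function(results, network) {
  ledges <- attr(results, "leading_edges")
  out <- lapply(split(names(network$clusters), unname(network$clusters)),
                function(members) {
                  sort(unique(unlist(ledges[members], use.names = FALSE)))
                })
  out[lengths(out) > 0L]
}
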