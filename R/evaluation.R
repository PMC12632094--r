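#' Read a curated phenotype catalog from TSV
#'
#' The catalog lists gene deletions with a validated long- or short-lived
#' phenotype from small-scale assays (CFU counts or live/dead staining),
#' together with the study identifiers supplying the evidence. Genes with
#' balanced conflicting evidence are expected to have been excluded upstream.
#'
#' @param path TSV with columns `gene`, `label` (one of `long`/`short`) and
#'   optional `sources` (semicolon-separated study identifiers).
#' @return An object of class `curated_catalog`: list with `labels` (named
#'   character vector) and `sources` (named list of character vectors).
#' @export
read_catalog <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("gene", "label") %in% names(tab)))
    stop("catalog must have columns 'gene' and 'label'")
  curated_catalog(stats::setNames(tab$label, toupper(tab$gene)),
                  sources = if ("sources" %in% names(tab))
                    stats::setNames(strsplit(tab$sources, ";", fixed = TRUE),
                                    toupper(tab$gene)))
}

#' Construct a curated phenotype catalog
#'
#' @param labels Named character vector, values `"long"` or `"short"`,
#'   names are gene identifiers.
#' @param sources Optional named list mapping gene to study identifiers.
#' @return An object of class `curated_catalog`.
#' @export
curated_catalog <- function(labels, sources = NULL) {
  if (is.null(names(labels))) stop("'labels' must be named by gene")
  names(labels) <- toupper(names(labels))
  bad <- setdiff(unique(labels), c("long", "short"))
  if (length(bad)) stop("labels must be 'long' or 'short'; got: ",
                        paste(bad, collapse = ", "))
  if (anyDuplicated(names(labels))) stop("duplicate genes in catalog")
  if (!is.null(sources)) names(sources) <- toupper(names(sources))
  structure(list(labels = labels, sources = sources),
            class = "curated_catalog")
}

#' Mann-Whitney AUC statistic
#'
#' The probability that a random positive scores above a random negative,
#' with ties counted as one half:
#' (#\{pos > neg\} + 0.5 #\{pos = neg\}) / (n_pos * n_neg).
#'
#' @param pos_scores,neg_scores Non-empty numeric vectors.
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(pos_scores, neg_scores) {
  stopifnot(length(pos_scores) >= 1L, length(neg_scores) >= 1L)
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  np <- length(pos_scores); nn <- length(neg_scores)
  # rank-sum identity: U = sum(rank(pos)) - np(np+1)/2 counts wins + ties/2
  u <- sum(r[seq_len(np)]) - np * (np + 1) / 2
  u / (np * nn)
}

#' ROC curve of a ranked screen against the curated catalog
#'
#' Evaluates how well one screen's ranking separates curated long-lived from
#' short-lived deletions. The classifier score of a gene is minus its rank
#' (better rank = higher score). Catalog genes not measured by the dataset
#' are skipped and reported; when the dataset itself contributed a gene's
#' curated phenotype, the gene can be excluded to avoid common-source bias.
#'
#' @param ds A `ranked_dataset` from [rank_genes()].
#' @param catalog A [curated_catalog()].
#' @param exclude_same_source If `TRUE`, drop catalog genes whose evidence
#'   sources include `dataset_source`.
#' @param dataset_source Study identifier of `ds` for same-source exclusion.
#' @param positive Which phenotype is the positive class (default `"long"`).
#' @return An object of class `roc_result`: list with `dataset`, `points`
#'   (data frame `fpr`, `tpr` from (0,0) to (1,1)), `auc`, `n_pos`, `n_neg`,
#'   `excluded` (same-source genes) and `skipped` (catalog genes not
#'   measured).
#' @export
roc_curve <- function(ds, catalog, exclude_same_source = FALSE,
                      dataset_source = NULL,
                      positive = c("long", "short")) {
  stopifnot(inherits(ds, "ranked_dataset"), inherits(catalog, "curated_catalog"))
  positive <- match.arg(positive)
  labels <- catalog$labels
  excluded <- character()
  if (exclude_same_source) {
    if (is.null(dataset_source))
      stop("'dataset_source' required when exclude_same_source = TRUE")
    if (!is.null(catalog$sources)) {
      has_src <- vapply(names(labels), function(g) {
        s <- catalog$sources[[g]]
        !is.null(s) && dataset_source %in% s
      }, logical(1L))
      excluded <- names(labels)[has_src]
      labels <- labels[!has_src]
    }
  }
  present <- names(labels) %in% names(ds$ranks)
  skipped <- names(labels)[!present]
  labels <- labels[present]
  is_pos <- labels == positive
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("need at least one positive and one negative catalog gene in '",
         ds$name, "' after exclusions")
  score <- -ds$ranks[names(labels)]
  # sweep thresholds over decreasing score; tied scores advance jointly,
  # which yields the diagonal (trapezoidal) segment for ties
  o <- order(score, decreasing = TRUE)
  s <- score[o]; y <- is_pos[o]
  grp <- cumsum(!duplicated(s))            # threshold group per tied block
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(dataset = ds$name,
                 points = data.frame(fpr = fpr, tpr = tpr),
                 auc = auc, n_pos = n_pos, n_neg = n_neg,
                 excluded = excluded, skipped = skipped),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("roc_result '", x$dataset, "': AUC = ", format(round(x$auc, 4L), nsmall = 4L),
      " (", x$n_pos, " long / ", x$n_neg, " short)\n", sep = "")
  invisible(x)
}

#' Build a dataset weight scheme for outranking
#'
#' @param datasets Character vector of dataset names.
#' @param scheme `"equal"` (1/D each), `"auc_proportional"` (AUC_i / sum AUC)
#'   or `"priority"` (supplied vector normalized to sum 1).
#' @param aucs Named numeric vector of AUCs (required for
#'   `"auc_proportional"`).
#' @param priority_vector Numeric vector matching `datasets` (required for
#'   `"priority"`).
#' @return An object of class `weight_scheme`: list with `weights` (named,
#'   summing to 1) and `scheme`.
#' @examples
#' make_weights(letters[1:5], "equal")$weights   # 0.2 each
#' @export
make_weights <- function(datasets,
                         scheme = c("equal", "auc_proportional", "priority"),
                         aucs = NULL, priority_vector = NULL) {
  scheme <- match.arg(scheme)
  D <- length(datasets)
  stopifnot(D >= 1L, !anyDuplicated(datasets))
  w <- switch(scheme,
    equal = rep(1 / D, D),
    auc_proportional = {
      if (is.null(aucs) || !all(datasets %in% names(aucs)))
        stop("'aucs' must cover all datasets for scheme 'auc_proportional'")
      as.numeric(aucs[datasets])
    },
    priority = {
      if (is.null(priority_vector) || length(priority_vector) != D)
        stop("'priority_vector' must match the number of datasets")
      as.numeric(priority_vector)
    })
  if (any(w < 0)) stop("weights must be non-negative")
  tot <- sum(w)
  if (tot <= 0) stop("total weight must be positive")
  structure(list(weights = stats::setNames(w / tot, datasets),
                 scheme = scheme),
            class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("weight_scheme (", x$scheme, "):\n", sep = "")
  print(round(x$weights, 4L))
  invisible(x)
}
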