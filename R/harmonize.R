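#' Construct a screen dataset
#'
#' A `screen_dataset` holds one genome-wide screen's representative lifespan
#' value per gene deletion, oriented so that larger values mean longer-lived,
#' together with the experimental profile of the assay (medium, ploidy,
#' auxotrophy, setup, ...).
#'
#' @param values Named numeric vector of lifespan scores; names are systematic
#'   ORF identifiers (matched case-insensitively, stored upper-case).
#' @param name Dataset name (e.g. the first author of the source screen).
#' @param profile Optional [experimental_profile()] describing the assay.
#' @param symbols Optional named character vector of display gene symbols.
#' @return An object of class `screen_dataset` with elements `name`, `values`,
#'   `profile`, `symbols`.
#' @examples
#' ds <- screen_dataset(c(YAL001C = 1.2, YBR001C = -0.3), "toy")
#' length(ds$values)
#' @export
screen_dataset <- function(values, name, profile = NULL, symbols = NULL) {
  if (!is.numeric(values) || length(values) < 1L)
    stop("'values' must be a non-empty numeric vector")
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("'values' must be named by gene identifiers")
  names(values) <- toupper(names(values))
  dup <- unique(names(values)[duplicated(names(values))])
  if (length(dup))
    stop("duplicate gene identifiers in dataset '", name, "': ",
         paste(utils::head(dup, 5L), collapse = ", "))
  if (any(!is.finite(values)))
    stop("all scores must be finite; drop non-finite rows before construction")
  structure(
    list(name = as.character(name), values = values,
         profile = profile, symbols = symbols),
    class = "screen_dataset"
  )
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat("screen_dataset '", x$name, "': ", length(x$values), " genes\n", sep = "")
  invisible(x)
}

#' Describe the experimental profile of a screen
#'
#' Records the categorical experimental variables of one screen so that
#' pairwise "shared condition" indicators can be formed downstream (see
#' [shared_variable_model()]). Any named categorical variable may be supplied;
#' typical variables are ploidy, auxotrophy, medium base, glucose percentage,
#' buffering, aeration, experimental setup, assay read-out, nutrient
#' limitation and dietary restriction.
#'
#' @param ... Named scalar values (character/logical/numeric); each is stored
#'   as a categorical level.
#' @return An object of class `experimental_profile` (a named character
#'   vector of levels).
#' @examples
#' experimental_profile(ploidy = "haploid", auxotrophy = "auxotroph",
#'                      buffered = FALSE, setup = "pooled")
#' @export
experimental_profile <- function(...) {
  vals <- list(...)
  if (length(vals) && (is.null(names(vals)) || any(!nzchar(names(vals)))))
    stop("all profile variables must be named")
  out <- vapply(vals, function(v) {
    if (length(v) != 1L) stop("profile variables must be scalar")
    as.character(v)
  }, character(1L))
  structure(out, class = "experimental_profile")
}

#' Load a screen table from TSV
#'
#' Reads a two-column (`gene`, `value`; optional `symbol`) tab-separated
#' table, orients scores so that larger = longer-lived, and drops rows with
#' missing or non-finite values (reported via a message).
#'
#' @param path Path to a TSV file with header columns `gene` and `value`.
#' @param name Dataset name.
#' @param profile Optional [experimental_profile()].
#' @param orientation `"higher_is_longer"` (values kept as-is) or
#'   `"lower_is_longer"` (values negated so larger = longer-lived).
#' @return A [screen_dataset()].
#' @export
load_screen_table <- function(path, name,
                              profile = NULL,
                              orientation = c("higher_is_longer",
                                              "lower_is_longer")) {
  orientation <- match.arg(orientation)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("gene", "value") %in% names(tab)))
    stop("screen table must have columns 'gene' and 'value': ", path)
  if (nrow(tab) == 0L) stop("empty screen table: ", path)
  gene <- toupper(as.character(tab$gene))
  dup <- unique(gene[duplicated(gene)])
  if (length(dup))
    stop("duplicate gene rows in '", name, "': ",
         paste(utils::head(dup, 5L), collapse = ", "))
  val <- suppressWarnings(as.numeric(tab$value))
  keep <- is.finite(val)
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    message("load_screen_table('", name, "'): dropped ", n_drop,
            " row(s) with missing/non-finite values")
  if (!any(keep)) stop("no finite values in screen table: ", path)
  val <- val[keep]
  gene <- gene[keep]
  if (orientation == "lower_is_longer") val <- -val
  symbols <- NULL
  if ("symbol" %in% names(tab)) {
    symbols <- as.character(tab$symbol)[keep]
    names(symbols) <- gene
  }
  screen_dataset(stats::setNames(val, gene), name,
                 profile = profile, symbols = symbols)
}

#' Rank genes of a screen from most to least long-lived
#'
#' Rank 1 is the largest (most long-lived) score; ties receive the average of
#' the spanned ranks, so the rank sum is always N(N+1)/2.
#'
#' @param ds A [screen_dataset()].
#' @return An object of class `ranked_dataset` with elements `name` and
#'   `ranks` (named numeric vector, 1 = most long-lived).
#' @examples
#' rank_genes(screen_dataset(c(a = 3, b = 2, c = 2), "toy"))$ranks
#' @export
rank_genes <- function(ds) {
  stopifnot(inherits(ds, "screen_dataset"))
  r <- rank(-ds$values, ties.method = "average")
  structure(list(name = ds$name, ranks = r), class = "ranked_dataset")
}

#' @export
print.ranked_dataset <- function(x, ...) {
  cat("ranked_dataset '", x$name, "': ", length(x$ranks), " genes\n", sep = "")
  invisible(x)
}

#' Genes shared across all datasets
#'
#' @param datasets List of [screen_dataset()] objects.
#' @return Sorted character vector: the intersection of the gene universes.
#' @export
shared_genes <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  universes <- lapply(datasets, function(d) names(d$values))
  sort(Reduce(intersect, universes))
}

#' Pooled gene universe across datasets
#'
#' @param datasets List of [screen_dataset()] objects.
#' @return Sorted character vector: the union of the gene universes.
#' @export
pooled_gene_universe <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  universes <- lapply(datasets, function(d) names(d$values))
  sort(Reduce(union, universes))
}

#' Write a ranked dataset to TSV
#'
#' @param ds A [screen_dataset()].
#' @param path Output path; columns `gene`, `score`, `rank`.
#' @return Invisibly, the written data frame.
#' @export
write_ranked_tsv <- function(ds, path) {
  rk <- rank_genes(ds)
  out <- data.frame(gene = names(ds$values),
                    score = unname(ds$values),
                    rank = unname(rk$ranks),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
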