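#' Run the full meta-analysis from a configuration
#'
#' Orchestrates harmonization, concordance, dataset evaluation, outranking,
#' rank-distribution statistics, gene-set enrichment and regulator
#' association from a single declarative configuration, writing per-stage
#' TSV outputs, a machine-readable JSON summary and a log of seeds and
#' dropped records. The competitive-aging fit runs independently on plate
#' inputs via [subtract_background()] and [fit_survival_model()].
#'
#' Configuration fields (YAML file or named list):
#' \describe{
#'   \item{datasets}{List of entries `path`, `name`, `orientation`
#'     (default `higher_is_longer`), optional `profile` (variable -> level).}
#'   \item{catalog}{Path to the curated-catalog TSV (optional).}
#'   \item{criteria}{Dataset names used as outranking criteria (default:
#'     all).}
#'   \item{weight_scheme}{`equal` (default), `auc_proportional` (requires
#'     `catalog`) or `priority` (requires `priority_vector`).}
#'   \item{missing_policy}{`renormalize` (default) or `zero_preference`.}
#'   \item{gene_sets}{Path to a GMT file (optional).}
#'   \item{gsea}{List: `n_perm` (default 10000), `seed` (required when
#'     `gene_sets` given), `min_size` (10), `max_size` (100),
#'     `fdr_threshold` (0.05), `ji_threshold` (0.1).}
#'   \item{network}{Path to a TF-target TSV (optional; needs `gene_sets`).}
#'   \item{relevance_alpha}{TF relevance threshold (default 0.01).}
#'   \item{tail_fraction}{Tail fraction for enrichment (default 0.05).}
#'   \item{variables}{Profile variables for the shared-variable model
#'     (default: all variables present in every profile).}
#'   \item{out_dir}{Output directory (required).}
#' }
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @return Invisibly, a list with the per-stage results (`datasets`,
#'   `concordance`, `shared_model`, `rocs`, `weights`, `outranking`,
#'   `tails`, `gsea`, `network`, `regulators`, `summary`).
#' @export
run_meta_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir),
            !is.null(config$datasets))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(paste0("clsmeta run: ", format(Sys.time())))
  logmsg <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  ## harmonize -------------------------------------------------------------
  datasets <- stage("harmonize", {
    lapply(config$datasets, function(d) {
      profile <- if (!is.null(d$profile))
        do.call(experimental_profile, as.list(d$profile))
      ds <- load_screen_table(d$path, d$name, profile = profile,
                              orientation = d$orientation %||%
                                "higher_is_longer")
      logmsg("dataset '", d$name, "': ", length(ds$values), " genes")
      ds
    })
  })
  names(datasets) <- vapply(datasets, function(d) d$name, character(1L))
  shared <- shared_genes(datasets)
  universe <- pooled_gene_universe(datasets)
  logmsg("shared genes: ", length(shared), "; pooled universe: ",
         length(universe))

  ## concordance -----------------------------------------------------------
  conc <- shared_model <- NULL
  if (length(datasets) >= 2L && length(shared) >= 3L) {
    conc <- stage("concordance", spearman_matrix(datasets, shared))
    utils::write.table(conc$pairs, file.path(out_dir, "concordance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    profiles <- lapply(datasets, function(d) d$profile)
    if (!any(vapply(profiles, is.null, logical(1L)))) {
      variables <- config$variables %||%
        Reduce(intersect, lapply(profiles, names))
      if (length(variables) >= 1L &&
          nrow(conc$pairs) >= length(variables) + 2L) {
        shared_model <- stage("shared_variable_model", suppressWarnings(
          shared_variable_model(conc$pairs, profiles, variables)))
        utils::write.table(
          data.frame(variable = names(shared_model$coefficients),
                     coefficient = unname(shared_model$coefficients),
                     p_value = unname(shared_model$p_values)),
          file.path(out_dir, "shared_variable_model.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }

  ## evaluation ------------------------------------------------------------
  catalog <- rocs <- NULL
  criteria <- config$criteria %||% names(datasets)
  if (!all(criteria %in% names(datasets)))
    stop("unknown criteria: ",
         paste(setdiff(criteria, names(datasets)), collapse = ", "))
  if (!is.null(config$catalog)) {
    catalog <- stage("catalog", read_catalog(config$catalog))
    rocs <- stage("roc", lapply(datasets[criteria], function(d) {
      roc_curve(rank_genes(d), catalog)
    }))
    roc_df <- data.frame(dataset = criteria,
                         auc = vapply(rocs, function(r) r$auc, numeric(1L)),
                         n_pos = vapply(rocs, function(r) r$n_pos,
                                        integer(1L)),
                         n_neg = vapply(rocs, function(r) r$n_neg,
                                        integer(1L)))
    utils::write.table(roc_df, file.path(out_dir, "roc_auc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  scheme <- config$weight_scheme %||% "equal"
  weights <- stage("weights", switch(scheme,
    equal = make_weights(criteria, "equal"),
    auc_proportional = {
      if (is.null(rocs)) stop("'auc_proportional' needs a catalog")
      make_weights(criteria, "auc_proportional",
                   aucs = vapply(rocs, function(r) r$auc, numeric(1L)))
    },
    priority = make_weights(criteria, "priority",
                            priority_vector = unlist(config$priority_vector)),
    stop("unknown weight_scheme: ", scheme)))
  logmsg("weights (", scheme, "): ",
         paste(sprintf("%s=%.4f", names(weights$weights), weights$weights),
               collapse = ", "))

  ## outranking ------------------------------------------------------------
  missing_policy <- config$missing_policy %||% "renormalize"
  cm <- criteria_matrix(datasets[criteria], weights)
  outr <- stage("outranking",
                suppressMessages(net_flows(cm, missing_policy)))
  write_outranking_tsv(outr, file.path(out_dir, "outranking.tsv"))
  logmsg("outranking: ", length(outr$phi), " alternatives, policy ",
         missing_policy)

  ## rank distribution ------------------------------------------------------
  tail_fraction <- config$tail_fraction %||% 0.05
  tails <- NULL
  if (!is.null(catalog)) {
    tails <- stage("tails", {
      long_set <- names(catalog$labels)[catalog$labels == "long"]
      short_set <- names(catalog$labels)[catalog$labels == "short"]
      rbind(
        data.frame(set = "curated_long", tail = "top",
                   p_value = tail_enrichment(outr, long_set, "top",
                                             tail_fraction)$p_value),
        data.frame(set = "curated_short", tail = "bottom",
                   p_value = tail_enrichment(outr, short_set, "bottom",
                                             tail_fraction)$p_value))
    })
    utils::write.table(tails, file.path(out_dir, "tail_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## gsea + regulators ------------------------------------------------------
  gsea_res <- network <- regulators <- NULL
  if (!is.null(config$gene_sets)) {
    gcfg <- config$gsea %||% list()
    if (is.null(gcfg$seed)) stop("gsea.seed is required with gene_sets")
    sets <- read_gmt(config$gene_sets)
    gsea_res <- stage("gsea", preranked_gsea(
      outr$phi, sets,
      min_size = gcfg$min_size %||% 10L,
      max_size = gcfg$max_size %||% 100L,
      n_perm = gcfg$n_perm %||% 10000L,
      seed = gcfg$seed))
    utils::write.table(as.data.frame(gsea_res),
                       file.path(out_dir, "gsea.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    signif <- gsea_res[gsea_res$fdr < (gcfg$fdr_threshold %||% 0.05), ,
                       drop = FALSE]
    if (nrow(signif) >= 1L) {
      network <- stage("term_network", term_network(
        signif, sets, ji_threshold = gcfg$ji_threshold %||% 0.1,
        universe = names(outr$phi)))
      utils::write.table(network$edges,
                         file.path(out_dir, "term_edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(network$nodes,
                         file.path(out_dir, "term_clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(config$network)) {
        net <- read_network_tsv(config$network)
        ledges <- cluster_leading_edges(signif, network)
        regulators <- stage("regulators", {
          pr <- suppressWarnings(regulator_association(
            ledges, net, universe = names(outr$phi),
            relevance_alpha = config$relevance_alpha %||% 0.01))
          if (nrow(pr$fractions) >= 1L) classify_breadth(pr) else pr
        })
        if (nrow(regulators$fractions) >= 1L) {
          frac_df <- data.frame(tf = rownames(regulators$fractions),
                                breadth = regulators$breadth %||% NA,
                                regulators$fractions, check.names = FALSE)
          utils::write.table(frac_df,
                             file.path(out_dir, "regulators.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
    } else logmsg("gsea: no term at FDR < ",
                  gcfg$fdr_threshold %||% 0.05)
  }

  summary <- list(
    n_datasets = length(datasets),
    n_shared_genes = length(shared),
    n_pooled_genes = length(universe),
    criteria = criteria,
    weight_scheme = scheme,
    weights = as.list(round(weights$weights, 4L)),
    missing_policy = missing_policy,
    max_pairwise_rho = if (!is.null(conc) && nrow(conc$pairs))
      max(conc$pairs$rho) else NULL,
    shared_model_r2_adjusted = if (!is.null(shared_model))
      shared_model$r2_adjusted else NULL,
    aucs = if (!is.null(rocs))
      as.list(round(vapply(rocs, function(r) r$auc, numeric(1L)), 4L))
      else NULL,
    n_gsea_significant = if (!is.null(gsea_res))
      sum(gsea_res$fdr < 0.05) else NULL,
    n_relevant_tfs = if (!is.null(regulators))
      nrow(regulators$fractions) else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(datasets = datasets, concordance = conc,
                 shared_model = shared_model, rocs = rocs,
                 weights = weights, outranking = outr, tails = tails,
                 gsea = gsea_res, network = network,
                 regulators = regulators, summary = summary))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
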