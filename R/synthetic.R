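#' Simulate correlated genome-wide screens
#'
#' Draws a latent per-gene longevity effect \eqn{\lambda \sim N(0,1)} and,
#' for each screen d, scores \eqn{score_{g,d} = \beta_d \lambda_g +
#' \epsilon_{g,d}} with \eqn{\epsilon \sim N(0, \sigma_d^2)}, an optional
#' monotone per-dataset distortion, and a uniform coverage mask (each screen
#' observes `floor(coverage * n_genes)` genes drawn without replacement).
#' Screens therefore agree only through the shared latent effect, emulating
#' the modest rank correlation seen between real lifespan screens.
#'
#' @param n_genes Number of genes in the pooled universe.
#' @param datasets Data frame with columns `name`, `beta`, `sigma`,
#'   `coverage` (one row per screen). Default: five screens with
#'   `beta = 1`, `sigma = 0.5`, full coverage.
#' @param seed Integer seed (required; all draws are reproducible).
#' @param distortion `"identity"`, `"rank"` (scores replaced by their rank /
#'   N) or `"logistic"` (plogis), applied per dataset after the linear
#'   draw; all three are monotone so rank-based analyses are unaffected.
#' @param profiles Optional named list of [experimental_profile()] objects;
#'   by default random profiles over six standard variables are generated
#'   and recorded in the truth object.
#' @return List with `datasets` (list of [screen_dataset()]) and `truth`
#'   (a `synthetic_truth` object recording `latent`, `dataset_params`,
#'   `profiles` and `seed`).
#' @export
simulate_screens <- function(n_genes,
                             datasets = data.frame(
                               name = paste0("screen", 1:5),
                               beta = 1, sigma = 0.5, coverage = 1),
                             seed,
                             distortion = c("identity", "rank", "logistic"),
                             profiles = NULL) {
  if (missing(seed)) stop("'seed' is required")
  distortion <- match.arg(distortion)
  stopifnot(n_genes >= 2L, all(datasets$beta >= 0), all(datasets$sigma >= 0),
            all(datasets$coverage > 0), all(datasets$coverage <= 1))
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  lambda <- stats::setNames(stats::rnorm(n_genes), genes)
  if (is.null(profiles)) {
    vars <- list(ploidy = c("haploid", "diploid"),
                 auxotrophy = c("auxotroph", "prototroph"),
                 medium_base = c("SC", "water"),
                 buffered = c("TRUE", "FALSE"),
                 aerated = c("TRUE", "FALSE"),
                 setup = c("monoculture", "two_strain", "pooled"))
    profiles <- lapply(seq_len(nrow(datasets)), function(i) {
      do.call(experimental_profile,
              lapply(vars, function(v) sample(v, 1L)))
    })
    names(profiles) <- datasets$name
  }
  out <- vector("list", nrow(datasets))
  for (i in seq_len(nrow(datasets))) {
    score <- datasets$beta[[i]] * lambda +
      stats::rnorm(n_genes, sd = datasets$sigma[[i]])
    score <- switch(distortion,
                    identity = score,
                    rank = rank(score, ties.method = "average") / n_genes,
                    logistic = stats::plogis(score))
    n_obs <- floor(datasets$coverage[[i]] * n_genes)
    obs <- sort(sample.int(n_genes, n_obs))
    out[[i]] <- screen_dataset(score[obs], datasets$name[[i]],
                               profile = profiles[[datasets$name[[i]]]])
  }
  truth <- structure(list(latent = lambda, dataset_params = datasets,
                          profiles = profiles, distortion = distortion,
                          seed = seed),
                     class = "synthetic_truth")
  list(datasets = out, truth = truth)
}

#' Simulate a curated catalog and gene sets with planted shifts
#'
#' Long labels are drawn from the genes with the highest latent effect,
#' short labels from the lowest, after which a `label_noise` fraction of
#' labels is flipped. Half of the gene sets are planted: their genes are
#' sampled by exponential tilting of the latent effect (weight
#' \eqn{e^{\pm shift \cdot \lambda}}), which for a standard-normal latent
#' is equivalent to sampling from a population with \eqn{\lambda} shifted
#' by \eqn{\pm shift}; the other half are uniform null sets.
#'
#' @param truth A `synthetic_truth` from [simulate_screens()].
#' @param n_long,n_short Number of long / short curated labels.
#' @param label_noise Fraction of labels flipped (0 = clean).
#' @param n_sets Total number of gene sets (half planted, half null).
#' @param set_size_range Integer range of set sizes (default `c(10, 100)`,
#'   inside the enrichment size filter).
#' @param shift Latent shift of planted sets (alternating sign).
#' @param seed Integer seed.
#' @param n_sources Number of synthetic evidence-source labels assigned to
#'   catalog genes (for same-source exclusion tests).
#' @return List with `catalog` (a [curated_catalog()]), `sets`
#'   (a [gene_set_collection()]) and `truth` (the input truth extended with
#'   `catalog_truth` and `planted_sets`, a named vector of planted shifts,
#'   0 for null sets).
#' @export
simulate_catalog_and_sets <- function(truth, n_long = 80L, n_short = 80L,
                                      label_noise = 0.05, n_sets = 40L,
                                      set_size_range = c(10L, 100L),
                                      shift = 1, seed, n_sources = 2L) {
  if (missing(seed)) stop("'seed' is required")
  stopifnot(inherits(truth, "synthetic_truth"))
  lambda <- truth$latent
  n <- length(lambda)
  stopifnot(n_long + n_short <= n)
  set.seed(seed)
  o <- order(-lambda)
  long_genes <- names(lambda)[o[seq_len(n_long)]]
  short_genes <- names(lambda)[o[seq.int(n - n_short + 1L, n)]]
  labels <- c(stats::setNames(rep("long", n_long), long_genes),
              stats::setNames(rep("short", n_short), short_genes))
  n_flip <- round(label_noise * length(labels))
  if (n_flip > 0L) {
    flip <- sample(seq_along(labels), n_flip)
    labels[flip] <- ifelse(labels[flip] == "long", "short", "long")
  }
  sources <- lapply(seq_along(labels), function(i)
    paste0("study", sample.int(n_sources, 1L)))
  names(sources) <- names(labels)
  catalog <- curated_catalog(labels, sources = sources)

  sizes <- sample(seq.int(set_size_range[[1L]], set_size_range[[2L]]),
                  n_sets, replace = TRUE)
  n_planted <- n_sets %/% 2L
  planted <- stats::setNames(rep(0, n_sets),
                             sprintf("SET%03d", seq_len(n_sets)))
  sets <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    if (i <= n_planted) {
      s <- if (i %% 2L == 1L) shift else -shift
      planted[[i]] <- s
      w <- exp(s * lambda)
      sets[[i]] <- sample(names(lambda), sizes[[i]], prob = w / sum(w))
    } else {
      sets[[i]] <- sample(names(lambda), sizes[[i]])
    }
  }
  names(sets) <- names(planted)
  truth$catalog_truth <- labels
  truth$planted_sets <- planted
  list(catalog = catalog,
       sets = gene_set_collection(
         sets,
         names = stats::setNames(names(planted), names(planted)),
         namespace = stats::setNames(rep("BP", n_sets), names(planted))),
       truth = truth)
}

#' Simulate a TF-target network with planted regulator breadth
#'
#' Global TFs target a fixed fraction of the genes of every cluster, local
#' TFs the same fraction of exactly one cluster, and background TFs target
#' uniformly random universe genes; `edge_noise` adds that fraction of
#' random extra targets to every planted TF.
#'
#' @param clusters Named list of gene sets (e.g. cluster leading edges).
#' @param n_global,n_local Numbers of planted global / local TFs.
#' @param background_tfs Number of unplanted background TFs.
#' @param edge_noise Fraction of random extra targets per planted TF.
#' @param seed Integer seed.
#' @param universe Background gene universe (default: union of clusters).
#' @param target_frac Fraction of cluster genes targeted by a planted TF
#'   (default 0.7).
#' @return List with `network` (a [regulatory_network()]) and
#'   `planted_tfs` (named character vector: `global` / `local` /
#'   `background`).
#' @export
simulate_regulatory_network <- function(clusters, n_global = 2L,
                                        n_local = 3L, background_tfs = 5L,
                                        edge_noise = 0.05, seed,
                                        universe = NULL,
                                        target_frac = 0.7) {
  if (missing(seed)) stop("'seed' is required")
  stopifnot(length(clusters) >= 1L, all(lengths(clusters) >= 1L))
  clusters <- lapply(clusters, toupper)
  if (is.null(universe)) universe <- unique(unlist(clusters))
  universe <- unique(toupper(universe))
  set.seed(seed)
  take <- function(g) sample(g, max(1L, round(target_frac * length(g))))
  edges <- list()
  breadth <- character()
  for (i in seq_len(n_global)) {
    tf <- sprintf("TFG%02d", i)
    edges[[tf]] <- unique(unlist(lapply(clusters, take)))
    breadth[[tf]] <- "global"
  }
  for (i in seq_len(n_local)) {
    tf <- sprintf("TFL%02d", i)
    cl <- 1L + (i - 1L) %% length(clusters)
    edges[[tf]] <- take(clusters[[cl]])
    breadth[[tf]] <- "local"
  }
  if (edge_noise > 0) {
    for (tf in names(edges)) {
      extra <- round(edge_noise * length(edges[[tf]]))
      if (extra > 0L)
        edges[[tf]] <- unique(c(edges[[tf]], sample(universe, extra)))
    }
  }
  mean_size <- max(1L, round(mean(lengths(clusters))))
  for (i in seq_len(background_tfs)) {
    tf <- sprintf("TFB%02d", i)
    edges[[tf]] <- sample(universe, min(mean_size, length(universe)))
    breadth[[tf]] <- "background"
  }
  list(network = regulatory_network(edges), planted_tfs = breadth)
}

#' Simulate a competitive-aging plate
#'
#' Forward model of the survival regression: for every competition or WT/WT
#' well and sampling point, the log ratio
#' \eqn{y = A_w + S_w T_i + G_w t_j + C_{T_i,t_j} + N(0, noise\_sd^2)} is
#' generated and exponentiated into an RFP/CFP pair (CFP held at
#' `cfp_level`, RFP = CFP * exp(y)); the configured channel `background` is
#' then added to every reading, and single-color reference wells carry only
#' their own signal plus background. WT/WT wells are generated with
#' S = G = 0. OD rises linearly with outgrowth time between `od_range`.
#'
#' @param design A [competition_design()] (single- or multi-plate).
#' @param truth Data frame `well, A, S, G` for competition wells (plate
#'   column optional when the design has one plate); WT/WT wells are forced
#'   to S = G = 0 and default A = 0 unless listed.
#' @param plate_effects Named numeric vector of C values keyed
#'   `"<day>d:<hour>h"` (recycled across plates), or `NULL` for C = 0.
#'   Values summing to zero make A and C exactly identifiable.
#' @param noise_sd Gaussian noise sd on the log ratio.
#' @param days,times Aging days and outgrowth hours sampled.
#' @param seed Integer seed.
#' @param cfp_level Reference CFP signal (default 5000).
#' @param background Added channel background (default 100).
#' @param od_range OD at first and last outgrowth time (default
#'   `c(0.1, 0.9)`).
#' @return List with `measurements` (long-format data frame matching
#'   [read_plate_tsv()]) and `truth` (per-well A, S, G with WT/WT rows
#'   included, plus the C values used).
#' @export
simulate_competition_plate <- function(design, truth, plate_effects = NULL,
                                       noise_sd = 0.1,
                                       days = c(4, 6, 8, 10),
                                       times = c(4, 8, 12, 16),
                                       seed, cfp_level = 5000,
                                       background = 100,
                                       od_range = c(0.1, 0.9)) {
  if (missing(seed)) stop("'seed' is required")
  stopifnot(inherits(design, "competition_design"), noise_sd >= 0,
            length(days) >= 2L, length(times) >= 2L)
  set.seed(seed)
  dw <- design$wells
  if (!"plate" %in% names(truth)) truth$plate <- dw$plate[[1L]]
  combos <- expand.grid(aging_day = days, outgrowth_hour = times,
                        KEEP.OUT.ATTRS = FALSE)
  ckey <- paste0(combos$aging_day, "d:", combos$outgrowth_hour, "h")
  cval <- if (is.null(plate_effects)) stats::setNames(rep(0, nrow(combos)),
                                                      ckey)
          else plate_effects[ckey]
  if (anyNA(cval)) stop("plate_effects must cover every (day, hour) combo")
  od <- od_range[[1L]] + (combos$outgrowth_hour - min(times)) /
    (max(times) - min(times)) * diff(od_range)
  rows <- list()
  truth_rows <- list()
  for (i in seq_len(nrow(dw))) {
    p <- dw$plate[[i]]; w <- dw$well[[i]]; role <- dw$role[[i]]
    if (role %in% c("competition", "wt_wt")) {
      if (role == "wt_wt") {
        tr <- truth[truth$plate == p & truth$well == w, , drop = FALSE]
        A <- if (nrow(tr)) tr$A[[1L]] else 0
        S <- 0; G <- 0
      } else {
        tr <- truth[truth$plate == p & truth$well == w, , drop = FALSE]
        if (!nrow(tr)) stop("no truth row for competition well '", w, "'")
        A <- tr$A[[1L]]; S <- tr$S[[1L]]; G <- tr$G[[1L]]
      }
      y <- A + S * combos$aging_day + G * combos$outgrowth_hour +
        unname(cval) + stats::rnorm(nrow(combos), sd = noise_sd)
      rfp <- cfp_level * exp(y) + background
      cfp <- cfp_level + background
      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(plate = p, well = w, A = A, S = S, G = G,
                   stringsAsFactors = FALSE)
    } else if (role == "ref_rfp") {
      rfp <- cfp_level + background
      cfp <- background
    } else {
      rfp <- background
      cfp <- cfp_level + background
    }
    rows[[length(rows) + 1L]] <- data.frame(
      plate = p, well = w, strain = dw$strain[[i]],
      is_wt_wt = role == "wt_wt",
      aging_day = combos$aging_day, outgrowth_hour = combos$outgrowth_hour,
      od = od, rfp = rfp, cfp = cfp, stringsAsFactors = FALSE)
  }
  list(measurements = do.call(rbind, rows),
       truth = list(wells = do.call(rbind, truth_rows), C = cval,
                    noise_sd = noise_sd, seed = seed))
}

#' Write a complete synthetic input bundle
#'
#' Generates screens, catalog, gene sets, TF network and a competition
#' plate with one call and writes them under `dir` as plain-text files
#' (screens `<name>.tsv`, `catalog.tsv`, `sets.gmt`, `network.tsv`,
#' `plate.tsv`, `profiles.yaml`, `truth.json`), ready for
#' [run_meta_analysis()].
#'
#' @param dir Output directory (created if needed).
#' @param n_genes Number of genes (default 2000).
#' @param seed Integer seed driving every stage.
#' @param ... Passed to [simulate_screens()].
#' @return Invisibly, a list with the generated objects and `truth`.
#' @export
simulate_bundle <- function(dir, n_genes = 2000L, seed, ...) {
  if (missing(seed)) stop("'seed' is required")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scr <- simulate_screens(n_genes, seed = seed, ...)
  cs <- simulate_catalog_and_sets(scr$truth, seed = seed + 1L)
  for (d in scr$datasets) {
    utils::write.table(
      data.frame(gene = names(d$values), value = unname(d$values)),
      file.path(dir, paste0(d$name, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cat_df <- data.frame(gene = names(cs$catalog$labels),
                       label = unname(cs$catalog$labels),
                       sources = vapply(cs$catalog$sources, paste,
                                        character(1L), collapse = ";"))
  utils::write.table(cat_df, file.path(dir, "catalog.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(cs$sets, file.path(dir, "sets.gmt"))
  # regulator network planted on the strongest planted sets
  planted <- names(cs$truth$planted_sets)[cs$truth$planted_sets != 0]
  clusters <- cs$sets$genes[utils::head(planted, 4L)]
  net <- simulate_regulatory_network(clusters, seed = seed + 2L,
                                     universe = names(scr$truth$latent))
  edge_df <- do.call(rbind, lapply(names(net$network$edges), function(tf) {
    data.frame(tf = tf, target = net$network$edges[[tf]],
               evidence = "binding", stringsAsFactors = FALSE)
  }))
  utils::write.table(edge_df, file.path(dir, "network.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  design <- competition_design(data.frame(
    plate = "P1",
    well = sprintf("W%02d", 1:12),
    strain = c(sprintf("mut%02d", 1:8), "WT_WT", "WT_WT",
               "WT_RFP", "WT_CFP"),
    role = c(rep("competition", 8L), "wt_wt", "wt_wt",
             "ref_rfp", "ref_cfp"), stringsAsFactors = FALSE))
  set.seed(seed + 3L)
  w_truth <- data.frame(well = sprintf("W%02d", 1:8),
                        A = stats::rnorm(8L, 0.7, 0.2),
                        S = stats::rnorm(8L, 0, 0.15),
                        G = stats::rnorm(8L, 0, 0.02))
  plate <- simulate_competition_plate(design, w_truth, seed = seed + 4L)
  utils::write.table(plate$measurements, file.path(dir, "plate.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(lapply(scr$truth$profiles, as.list),
                   file.path(dir, "profiles.yaml"))
  truth_json <- list(
    seed = seed,
    latent = as.list(scr$truth$latent),
    dataset_params = scr$truth$dataset_params,
    catalog_truth = as.list(cs$truth$catalog_truth),
    planted_sets = as.list(cs$truth$planted_sets),
    planted_tfs = as.list(net$planted_tfs),
    network_clusters = names(clusters),
    plate_truth = plate$truth$wells)
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(screens = scr$datasets, catalog = cs$catalog,
                 sets = cs$sets, network = net$network,
                 plate = plate$measurements, design = design,
                 truth = list(screens = scr$truth, sets = cs$truth,
                              tfs = net$planted_tfs,
                              network_clusters = names(clusters),
                              plate = plate$truth)))
}
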