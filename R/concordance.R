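# Tie-aware Spearman correlation with a two-sided t-approximation p-value.
# cor() on average ranks handles ties; p from t = rho*sqrt((n-2)/(1-rho^2)).
spearman_t <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3L)
  rho <- stats::cor(rank(x, ties.method = "average"),
                    rank(y, ties.method = "average"))
  if (is.na(rho)) return(list(rho = NA_real_, p = NA_real_, n = n))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Pairwise Spearman correlation between screens
#'
#' Computes the tie-aware Spearman rank correlation between every pair of
#' screens over a common gene list (typically [shared_genes()]), with
#' two-sided p-values from the t approximation.
#'
#' @param datasets List of [screen_dataset()] objects.
#' @param genes Character vector of genes present in every dataset (>= 3).
#' @return An object of class `concordance_matrix`: list with `rho` and `p`
#'   (named square matrices), `n_genes`, and `pairs`, a data frame with one
#'   row per unordered pair (`dataset_a`, `dataset_b`, `n_shared`, `rho`,
#'   `p_value`).
#' @export
spearman_matrix <- function(datasets, genes) {
  stopifnot(length(datasets) >= 1L, length(genes) >= 3L)
  genes <- toupper(genes)
  nm <- vapply(datasets, function(d) d$name, character(1L))
  if (anyDuplicated(nm)) stop("dataset names must be unique")
  for (d in datasets) {
    miss <- setdiff(genes, names(d$values))
    if (length(miss))
      stop("gene '", miss[[1L]], "' missing from dataset '", d$name, "'")
  }
  vals <- vapply(datasets, function(d) d$values[genes],
                 numeric(length(genes)))
  colnames(vals) <- nm
  D <- length(nm)
  rho <- diag(1, D); p <- matrix(0, D, D)
  dimnames(rho) <- dimnames(p) <- list(nm, nm)
  pairs <- list()
  k <- 0L
  if (D >= 2L) {
    for (i in seq_len(D - 1L)) for (j in seq.int(i + 1L, D)) {
      st <- spearman_t(vals[, i], vals[, j])
      rho[i, j] <- rho[j, i] <- st$rho
      p[i, j] <- p[j, i] <- st$p
      k <- k + 1L
      pairs[[k]] <- data.frame(dataset_a = nm[i], dataset_b = nm[j],
                               n_shared = st$n, rho = st$rho,
                               p_value = st$p, stringsAsFactors = FALSE)
    }
  }
  pairs <- if (k) do.call(rbind, pairs) else
    data.frame(dataset_a = character(), dataset_b = character(),
               n_shared = integer(), rho = numeric(), p_value = numeric())
  structure(list(rho = rho, p = p, n_genes = length(genes), pairs = pairs),
            class = "concordance_matrix")
}

#' Jaccard overlap of ranking tails between two screens
#'
#' Takes each dataset's top (`long`) or bottom (`short`) `cutoff_fraction` of
#' the genes shared by the two rankings and returns the Jaccard index of the
#' two tail sets. Tail size is `floor(cutoff_fraction * N)` with a minimum
#' of 1, computed after re-ranking within the shared gene universe.
#'
#' @param a,b [rank_genes()] results (`ranked_dataset` objects).
#' @param tail `"long"` (best ranks) or `"short"` (worst ranks).
#' @param cutoff_fraction Tail fraction in (0, 1).
#' @return Jaccard index in \[0, 1\].
#' @export
tail_jaccard <- function(a, b, tail = c("long", "short"), cutoff_fraction) {
  tail <- match.arg(tail)
  stopifnot(inherits(a, "ranked_dataset"), inherits(b, "ranked_dataset"),
            cutoff_fraction > 0, cutoff_fraction < 1)
  common <- intersect(names(a$ranks), names(b$ranks))
  if (!length(common)) stop("no shared genes between '", a$name, "' and '",
                            b$name, "'")
  k <- max(1L, floor(cutoff_fraction * length(common)))
  pick_tail <- function(r) {
    r <- r[common]
    # re-rank within the shared universe; 'long' = smallest ranks
    o <- if (tail == "long") order(r) else order(-r)
    common[o[seq_len(k)]]
  }
  ta <- pick_tail(a$ranks)
  tb <- pick_tail(b$ranks)
  length(intersect(ta, tb)) / length(union(ta, tb))
}

#' Model pairwise correlation from shared experimental variables
#'
#' Ordinary least squares of the pairwise Spearman correlation on binary
#' indicators, one per experimental variable: the indicator is 1 when both
#' datasets of the pair have the same level of that variable. Constant
#' (non-estimable) indicators are dropped with a warning.
#'
#' @param pairs Data frame of pairwise correlations as produced in the
#'   `pairs` element of [spearman_matrix()].
#' @param profiles Named list of [experimental_profile()] objects, one per
#'   dataset name appearing in `pairs`.
#' @param variables Character vector of profile variables to use.
#' @return An object of class `shared_variable_model`: list with
#'   `coefficients`, `p_values` (named by variable), `intercept`,
#'   `r2_adjusted`, `n_pairs`, `dropped` (non-estimable variables), and the
#'   underlying `fit` (an `lm` object).
#' @export
shared_variable_model <- function(pairs, profiles, variables) {
  stopifnot(is.data.frame(pairs), length(variables) >= 1L)
  need <- union(pairs$dataset_a, pairs$dataset_b)
  miss <- setdiff(need, names(profiles))
  if (length(miss)) stop("missing profiles for: ", paste(miss, collapse = ", "))
  if (nrow(pairs) < length(variables) + 2L)
    stop("need at least |variables| + 2 pairs for the model")
  ind <- sapply(variables, function(v) {
    la <- vapply(pairs$dataset_a, function(d) {
      p <- profiles[[d]]; if (v %in% names(p)) p[[v]] else NA_character_
    }, character(1L))
    lb <- vapply(pairs$dataset_b, function(d) {
      p <- profiles[[d]]; if (v %in% names(p)) p[[v]] else NA_character_
    }, character(1L))
    as.numeric(!is.na(la) & !is.na(lb) & la == lb)
  })
  ind <- matrix(ind, nrow = nrow(pairs),
                dimnames = list(NULL, variables))
  const <- apply(ind, 2L, function(x) length(unique(x)) == 1L)
  if (any(const)) {
    warning("non-estimable (constant) shared-variable indicator(s) dropped: ",
            paste(variables[const], collapse = ", "))
  }
  keep <- variables[!const]
  dat <- data.frame(rho = pairs$rho, ind[, keep, drop = FALSE],
                    check.names = FALSE)
  fit <- stats::lm(rho ~ ., data = dat)
  sm <- summary(fit)
  co <- stats::coef(sm)
  coefs <- stats::setNames(rep(NA_real_, length(keep)), keep)
  pv <- coefs
  # lm backticks non-syntactic names; strip them before matching
  rn <- gsub("^`|`$", "", rownames(co))
  for (v in keep) {
    i <- match(v, rn)
    if (!is.na(i)) {
      coefs[[v]] <- co[i, 1L]
      pv[[v]] <- co[i, 4L]
    }
  }
  structure(list(coefficients = coefs, p_values = pv,
                 intercept = unname(co["(Intercept)", 1L]),
                 r2_adjusted = sm$adj.r.squared,
                 n_pairs = nrow(pairs),
                 dropped = variables[const],
                 fit = fit),
            class = "shared_variable_model")
}

#' @export
print.shared_variable_model <- function(x, ...) {
  cat("shared_variable_model on", x$n_pairs, "pairs; adj. R^2 =",
      format(x$r2_adjusted, digits = 3), "\n")
  print(data.frame(coefficient = x$coefficients, p_value = x$p_values))
  invisible(x)
}
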