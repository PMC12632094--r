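#' Usual preference function
#'
#' The binary ("usual") preference function for a maximized criterion: a
#' strictly positive score difference yields full preference (1), a tie or a
#' deficit yields none (0).
#'
#' @param d Numeric vector of score differences (a minus b).
#' @return Numeric vector of 0/1 preference degrees.
#' @examples
#' usual_preference(c(-0.3, 0, 0.3))
#' @export
usual_preference <- function(d) {
  stopifnot(all(is.finite(d)))
  as.numeric(d > 0)
}

#' Assemble a criteria matrix for outranking
#'
#' Rows are alternatives (genes in the pooled universe of the chosen
#' screens), columns are criteria (one per screen); entries are the oriented
#' lifespan scores, `NA` where a gene was not measured by a screen.
#'
#' @param datasets List of [screen_dataset()] objects (the criteria).
#' @param weights A [make_weights()] scheme covering exactly these datasets;
#'   default equal weights.
#' @return An object of class `criteria_matrix`: list with `values` (numeric
#'   matrix, genes x criteria) and `weights` (named, summing to 1).
#' @export
criteria_matrix <- function(datasets, weights = NULL) {
  stopifnot(length(datasets) >= 1L)
  nm <- vapply(datasets, function(d) d$name, character(1L))
  if (anyDuplicated(nm)) stop("dataset names must be unique")
  genes <- pooled_gene_universe(datasets)
  values <- matrix(NA_real_, length(genes), length(nm),
                   dimnames = list(genes, nm))
  for (d in datasets) values[names(d$values), d$name] <- d$values
  if (is.null(weights)) weights <- make_weights(nm, "equal")
  stopifnot(inherits(weights, "weight_scheme"))
  if (!setequal(names(weights$weights), nm))
    stop("weights must cover exactly the criteria: ",
         paste(nm, collapse = ", "))
  structure(list(values = values, weights = weights$weights[nm]),
            class = "criteria_matrix")
}

# Validate a plain values matrix + weights into canonical form.
as_criteria <- function(m, weights = NULL) {
  if (inherits(m, "criteria_matrix")) return(m)
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  if (is.null(weights)) {
    weights <- rep(1 / ncol(m), ncol(m))
    names(weights) <- colnames(m)
  } else if (inherits(weights, "weight_scheme")) {
    weights <- weights$weights
  }
  stopifnot(length(weights) == ncol(m))
  if (is.null(names(weights))) names(weights) <- colnames(m)
  structure(list(values = m, weights = weights[colnames(m)]),
            class = "criteria_matrix")
}

#' PROMETHEE II net flows
#'
#' Computes positive, negative and net preference flows (phi-scores) over
#' all alternatives using the usual preference function on every criterion
#' (all criteria maximized). For an ordered pair (a, b) the aggregated
#' preference is \eqn{\pi(a,b) = \sum_j w_j P_j(a,b)} over the criteria
#' observed for both; under `missing_policy = "renormalize"` the weights are
#' rescaled to sum to one over those mutually observed criteria, under
#' `"zero_preference"` unobserved criteria simply contribute zero. Net flow
#' is \eqn{\phi(a) = \frac{1}{n-1}\sum_{b \ne a} [\pi(a,b) - \pi(b,a)]} with
#' n the total number of alternatives.
#'
#' The default method groups alternatives by their missingness pattern and
#' counts, per criterion, how many members of the partner group score
#' strictly lower or higher; it is exactly equivalent to the O(n^2) pairwise
#' sweep available as `method = "brute"`.
#'
#' @param m A [criteria_matrix()], or a numeric matrix (genes x criteria,
#'   `NA` = not measured) combined with `weights`.
#' @param missing_policy `"renormalize"` (default) or `"zero_preference"`.
#' @param weights Optional weights when `m` is a plain matrix.
#' @param method `"fast"` (pattern-grouped counting) or `"brute"` (explicit
#'   pairwise loop; reference implementation).
#' @return An object of class `outranking_result`: list with named numeric
#'   vectors `phi`, `phi_plus`, `phi_minus`, integer `rank` (1 = highest
#'   phi, phi ties broken lexicographically by gene), `n_no_overlap_pairs`
#'   (pairs with no mutually observed criterion, contributing zero), and
#'   `table` (a data frame sorted by rank).
#' @examples
#' m <- cbind(c1 = c(3, 2, 1), c2 = c(1, 2, 3))
#' rownames(m) <- c("g1", "g2", "g3")
#' net_flows(m, weights = c(c1 = 0.7, c2 = 0.3))$phi
#' @export
net_flows <- function(m, missing_policy = c("renormalize", "zero_preference"),
                      weights = NULL, method = c("fast", "brute")) {
  missing_policy <- match.arg(missing_policy)
  method <- match.arg(method)
  cm <- as_criteria(m, weights)
  X <- cm$values
  w <- cm$weights
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 alternatives")
  obs <- is.finite(X)
  if (any(rowSums(obs) == 0L))
    stop("every alternative must be observed on at least one criterion: ",
         paste(utils::head(rownames(X)[rowSums(obs) == 0L], 5L),
               collapse = ", "))
  res <- if (method == "fast") {
    net_flows_fast(X, w, obs, missing_policy)
  } else {
    net_flows_brute(X, w, obs, missing_policy)
  }
  phi <- (res$plus - res$minus) / (n - 1)
  phi_plus <- res$plus / (n - 1)
  phi_minus <- res$minus / (n - 1)
  genes <- rownames(X)
  names(phi) <- names(phi_plus) <- names(phi_minus) <- genes
  out <- structure(list(phi = phi, phi_plus = phi_plus,
                        phi_minus = phi_minus,
                        rank = NULL,
                        n_no_overlap_pairs = res$n_no_overlap,
                        missing_policy = missing_policy),
                   class = "outranking_result")
  out$rank <- rank_by_phi(out)
  out$table <- data.frame(gene = genes, phi = unname(phi),
                          phi_plus = unname(phi_plus),
                          phi_minus = unname(phi_minus),
                          rank = unname(out$rank),
                          stringsAsFactors = FALSE)
  out$table <- out$table[order(out$table$rank), , drop = FALSE]
  rownames(out$table) <- NULL
  if (res$n_no_overlap > 0L)
    message("net_flows: ", res$n_no_overlap,
            " pair(s) share no observed criterion (zero preference)")
  out
}

# Pattern-grouped counting path. For the usual function, the summed
# preference of 'a' over a group on criterion j is the count of group
# members scoring strictly below 'a'.
net_flows_fast <- function(X, w, obs, missing_policy) {
  n <- nrow(X)
  pat_key <- apply(obs, 1L, function(z) paste(as.integer(z), collapse = ""))
  groups <- split(seq_len(n), pat_key)
  pats <- lapply(groups, function(idx) which(obs[idx[[1L]], ]))
  G <- length(groups)
  plus <- numeric(n)
  minus <- numeric(n)
  n_no_overlap <- 0L
  for (gi in seq_len(G)) {
    for (gj in gi:G) {
      P <- groups[[gi]]; Q <- groups[[gj]]
      S <- intersect(pats[[gi]], pats[[gj]])
      if (!length(S) || sum(w[S]) == 0) {   # zero-weight overlap = no overlap
        if (!length(S)) n_no_overlap <- n_no_overlap + length(P) * length(Q)
        next
      }
      wS <- w[S]
      if (missing_policy == "renormalize") wS <- wS / sum(wS)
      for (k in seq_along(S)) {
        j <- S[[k]]
        xP <- X[P, j]; xQ <- X[Q, j]
        sQ <- sort(xQ)
        winP <- findInterval(xP, sQ, left.open = TRUE)       # #{Q < a}
        lossP <- length(xQ) - findInterval(xP, sQ)           # #{Q > a}
        plus[P] <- plus[P] + wS[[k]] * winP
        minus[P] <- minus[P] + wS[[k]] * lossP
        if (gi != gj) {
          sP <- sort(xP)
          winQ <- findInterval(xQ, sP, left.open = TRUE)
          lossQ <- length(xP) - findInterval(xQ, sP)
          plus[Q] <- plus[Q] + wS[[k]] * winQ
          minus[Q] <- minus[Q] + wS[[k]] * lossQ
        }
      }
    }
  }
  list(plus = plus, minus = minus, n_no_overlap = n_no_overlap)
}

# Reference O(n^2) pairwise sweep.
net_flows_brute <- function(X, w, obs, missing_policy) {
  n <- nrow(X)
  plus <- numeric(n)
  minus <- numeric(n)
  n_no_overlap <- 0L
  for (a in seq_len(n - 1L)) {
    for (b in seq.int(a + 1L, n)) {
      S <- which(obs[a, ] & obs[b, ])
      if (!length(S) || sum(w[S]) == 0) {
        if (!length(S)) n_no_overlap <- n_no_overlap + 1L
        next
      }
      wS <- w[S]
      if (missing_policy == "renormalize") wS <- wS / sum(wS)
      d <- X[a, S] - X[b, S]
      pab <- sum(wS * usual_preference(d))
      pba <- sum(wS * usual_preference(-d))
      plus[a] <- plus[a] + pab; minus[b] <- minus[b] + pab
      plus[b] <- plus[b] + pba; minus[a] <- minus[a] + pba
    }
  }
  list(plus = plus, minus = minus, n_no_overlap = n_no_overlap)
}

#' Ordinal ranking from net flows
#'
#' Rank 1 is the largest phi; exact phi ties are broken lexicographically by
#' gene identifier so the ranking is deterministic.
#'
#' @param r An `outranking_result` from [net_flows()].
#' @return Named integer vector of ranks (same order as `r$phi`).
#' @export
rank_by_phi <- function(r) {
  stopifnot(inherits(r, "outranking_result"))
  genes <- names(r$phi)
  o <- order(-r$phi, genes)
  rk <- integer(length(o))
  rk[o] <- seq_along(o)
  stats::setNames(rk, genes)
}

#' @export
print.outranking_result <- function(x, ...) {
  cat("outranking_result: ", length(x$phi), " alternatives (policy: ",
      x$missing_policy, ")\n", sep = "")
  print(utils::head(x$table))
  invisible(x)
}

#' Write an outranking result to TSV
#'
#' @param r An `outranking_result`.
#' @param path Output path; columns `gene, phi, phi_plus, phi_minus, rank`.
#' @return Invisibly, the written data frame.
#' @export
write_outranking_tsv <- function(r, path) {
  utils::write.table(r$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(r$table)
}
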