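named_stat <- function(n, seed = 1) {
  set.seed(seed)
  stats::setNames(rnorm(n), sprintf("G%04d", seq_len(n)))
}

test_that("a single-gene set at the top gives ES = 1", {
  stat <- stats::setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  res <- running_enrichment_score(stat, "g1", weight_exponent = 0)
  expect_equal(res$es, 1)
  expect_equal(res$leading_edge, "G1")
})

test_that("running score matches the step-by-step oracle to 1e-12", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(10:100, 1L)
    stat <- named_stat(n, seed = i)
    genes <- sample(names(stat), sample(2:min(30L, n - 1L), 1L))
    for (expo in c(0, 1)) {
      res <- running_enrichment_score(stat, genes, weight_exponent = expo)
      expect_equal(res$es, oracle_running_es(stat, genes, expo),
                   tolerance = 1e-12)
      # running sum returns to zero at the end
      expect_lt(abs(res$running[[n]]), 1e-12)
    }
  }
})

test_that("ES agrees with fgsea on the same weighted statistic", {
  skip_if_not_installed("fgsea")
  stat <- named_stat(300, seed = 9)
  set.seed(10)
  sets <- lapply(1:5, function(i) sample(names(stat), sample(10:40, 1L)))
  names(sets) <- paste0("s", 1:5)
  fg <- suppressWarnings(fgsea::fgsea(sets, stat, minSize = 1,
                                      maxSize = 500, nPermSimple = 101))
  for (s in names(sets)) {
    own <- running_enrichment_score(stat, sets[[s]])$es
    expect_equal(own, fg$ES[fg$pathway == s], tolerance = 1e-10)
  }
})

test_that("a balanced interleaved set keeps |ES| within 1/|S|", {
  n <- 100L
  stat <- stats::setNames(as.numeric(n:1), sprintf("G%04d", 1:n))
  for (k in c(4L, 5L, 10L, 20L)) {
    # hits at the exact centers of k equal blocks
    step <- n / k
    genes <- names(sort(stat, decreasing = TRUE))[round((seq_len(k) - 0.5) *
                                                          step)]
    res <- running_enrichment_score(stat, genes, weight_exponent = 0)
    expect_lte(abs(res$es), 1 / k + 1e-12)
  }
})

test_that("the 10-100 effective size filter is applied", {
  stat <- named_stat(500, seed = 2)
  sets <- list(too_small = sample(names(stat), 9L),
               kept = sample(names(stat), 10L),
               capped = sample(names(stat), 100L),
               too_big = sample(names(stat), 101L),
               shrunk = c(sample(names(stat), 9L), "NOT_IN_UNIVERSE"))
  res <- preranked_gsea(stat, sets, n_perm = 100L, seed = 4L)
  expect_setequal(res$term, c("kept", "capped"))
})

test_that("a planted shifted set is detected with the right direction", {
  set.seed(33)
  stat <- named_stat(2000, seed = 33)
  planted <- sample(names(stat), 50L)
  stat[planted] <- stat[planted] + 2
  down <- sample(setdiff(names(stat), planted), 50L)
  stat[down] <- stat[down] - 2
  sets <- c(list(up_set = planted, down_set = down),
            stats::setNames(lapply(1:20, function(i)
              sample(names(stat), 50L)), paste0("null", 1:20)))
  res <- preranked_gsea(stat, sets, n_perm = 1000L, seed = 7L)
  expect_lt(res$fdr[res$term == "up_set"], 0.05)
  expect_equal(res$direction[res$term == "up_set"], "long")
  expect_lt(res$fdr[res$term == "down_set"], 0.05)
  expect_equal(res$direction[res$term == "down_set"], "short")
})

test_that("a fully tied statistic yields ES 0 and p 1", {
  stat <- stats::setNames(rep(1, 50L), sprintf("G%04d", 1:50))
  res <- running_enrichment_score(stat, names(stat)[1:10])
  expect_equal(res$es, 0)
  g <- preranked_gsea(stat, list(s = names(stat)[1:12]),
                      n_perm = 100L, seed = 1L)
  expect_equal(g$es, 0)
  expect_equal(g$p_value, 1)
})

test_that("negating the statistic flips every ES and direction", {
  stat <- named_stat(400, seed = 12)
  set.seed(13)
  sets <- stats::setNames(lapply(1:6, function(i)
    sample(names(stat), 20L)), paste0("s", 1:6))
  a <- preranked_gsea(stat, sets, n_perm = 200L, seed = 3L)
  b <- preranked_gsea(-stat, sets, n_perm = 200L, seed = 3L)
  a <- a[order(a$term), ]; b <- b[order(b$term), ]
  expect_equal(a$es, -b$es, tolerance = 1e-12)
  expect_equal(a$direction,
               ifelse(b$direction == "long", "short", "long"))
})

test_that("permutation p-values are reproducible and BH-consistent", {
  stat <- named_stat(300, seed = 5)
  set.seed(77)
  sets <- stats::setNames(lapply(1:8, function(i)
    sample(names(stat), 15L)), paste0("s", 1:8))
  r1 <- preranked_gsea(stat, sets, n_perm = 200L, seed = 11L)
  r2 <- preranked_gsea(stat, sets, n_perm = 200L, seed = 11L)
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(r1$fdr, stats::p.adjust(r1$p_value, "BH"),
               tolerance = 1e-12)
  expect_true(all(r1$fdr >= r1$p_value - 1e-15))
  # BH is monotone in the raw p-values
  o <- order(r1$p_value)
  expect_true(all(diff(r1$fdr[o]) >= -1e-15))
})

test_that("term_network keeps strict Jaccard edges and clusters duplicates", {
  stat <- named_stat(100, seed = 8)
  g1 <- names(stat)[1:10]
  sets <- gene_set_collection(list(
    t_dup1 = g1, t_dup2 = g1,
    t_abc = c("A", "B", "C"), t_cde = c("C", "D", "E"),
    t_exact = c(paste0("X", 1:9), "Y1"),
    t_exact2 = c(paste0("X", 1:9), paste0("Z", 1:9), "Y1")))
  res <- structure(
    data.frame(term = names(sets$genes),
               namespace = "BP", size = lengths(sets$genes),
               es = 0.5, nes = 1, p_value = 0.01, fdr = 0.01,
               direction = "long",
               leading_edge = "", stringsAsFactors = FALSE),
    leading_edges = sets$genes, class = c("gsea_result", "data.frame"))
  net <- term_network(res, sets, ji_threshold = 0.1, cut_height = 0.4)
  ji <- net$ji
  expect_equal(ji["t_dup1", "t_dup2"], 1)
  expect_equal(net$clusters[["t_dup1"]], net$clusters[["t_dup2"]])
  expect_equal(ji["t_abc", "t_cde"], 0.2)
  expect_true(any(net$edges$term_a == "t_abc" & net$edges$term_b == "t_cde"))
  # Ji exactly 0.1 (1 shared of 10 total... construct 10/19-overlap pair)
  ji_exact <- ji["t_exact", "t_exact2"]
  expect_equal(ji_exact, 10 / 19)
  # strict threshold: an edge at exactly the threshold is dropped
  net_strict <- term_network(res, sets, ji_threshold = 0.2)
  expect_false(any((net_strict$edges$term_a == "t_abc" &
                      net_strict$edges$term_b == "t_cde") |
                     (net_strict$edges$term_a == "t_cde" &
                        net_strict$edges$term_b == "t_abc")))
})

test_that("gmt round-trip preserves sets, names and namespaces", {
  sets <- gene_set_collection(
    list(T1 = c("A", "B"), T2 = c("C", "D", "E")),
    names = c(T1 = "first term", T2 = "second term"),
    namespace = c(T1 = "BP", T2 = "CC"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back$genes, sets$genes)
  expect_equal(back$namespace[["T2"]], "CC")
  expect_equal(back$names[["T1"]], "first term")
})
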