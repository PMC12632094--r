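test_that("noise-free full-coverage screens correlate perfectly", {
  sim <- simulate_screens(
    100L, datasets = data.frame(name = c("a", "b", "c"), beta = 1,
                                sigma = 0, coverage = 1), seed = 1L)
  cm <- spearman_matrix(sim$datasets, shared_genes(sim$datasets))
  expect_true(all(abs(cm$rho - 1) < 1e-12))
})

test_that("a zero-loading screen is uncorrelated with the others", {
  sim <- simulate_screens(
    1000L, datasets = data.frame(name = c("sig", "null"),
                                 beta = c(1, 0), sigma = c(0.2, 1),
                                 coverage = 1), seed = 2L)
  cm <- spearman_matrix(sim$datasets, shared_genes(sim$datasets))
  expect_lt(abs(cm$rho["sig", "null"]), 2 / sqrt(1000))
})

test_that("coverage masks draw the exact number of genes", {
  sim <- simulate_screens(
    1000L, datasets = data.frame(name = "d", beta = 1, sigma = 0.5,
                                 coverage = 0.8), seed = 3L)
  expect_length(sim$datasets[[1L]]$values, 800L)
})

test_that("monotone distortions preserve every ranking", {
  for (d in c("rank", "logistic")) {
    plain <- simulate_screens(200L, seed = 4L, distortion = "identity")
    warped <- simulate_screens(200L, seed = 4L, distortion = d)
    for (i in seq_along(plain$datasets)) {
      expect_equal(rank_genes(plain$datasets[[i]])$ranks,
                   rank_genes(warped$datasets[[i]])$ranks)
    }
  }
})

test_that("generators are bit-reproducible for a fixed seed", {
  a <- simulate_screens(300L, seed = 5L)
  b <- simulate_screens(300L, seed = 5L)
  expect_identical(a$truth$latent, b$truth$latent)
  expect_identical(lapply(a$datasets, `[[`, "values"),
                   lapply(b$datasets, `[[`, "values"))
  ca <- simulate_catalog_and_sets(a$truth, seed = 6L)
  cb <- simulate_catalog_and_sets(b$truth, seed = 6L)
  expect_identical(ca$catalog$labels, cb$catalog$labels)
  expect_identical(ca$sets$genes, cb$sets$genes)
})

test_that("a clean catalog separates the latent tails exactly", {
  sim <- simulate_screens(500L, seed = 7L)
  cs <- simulate_catalog_and_sets(sim$truth, n_long = 40L, n_short = 40L,
                                  label_noise = 0, seed = 8L)
  lam <- sim$truth$latent
  longs <- names(cs$catalog$labels)[cs$catalog$labels == "long"]
  shorts <- names(cs$catalog$labels)[cs$catalog$labels == "short"]
  expect_gt(min(lam[longs]), max(lam[shorts]))
  # label noise flips the requested fraction
  noisy <- simulate_catalog_and_sets(sim$truth, n_long = 40L,
                                     n_short = 40L, label_noise = 0.1,
                                     seed = 9L)
  expect_equal(sum(noisy$catalog$labels != cs$catalog$labels), 8L)
})

test_that("generated set sizes respect the enrichment filter window", {
  sim <- simulate_screens(2000L, seed = 10L)
  cs <- simulate_catalog_and_sets(sim$truth, n_sets = 30L,
                                  set_size_range = c(10L, 100L),
                                  seed = 11L)
  sizes <- lengths(cs$sets$genes)
  expect_true(all(sizes >= 10L & sizes <= 100L))
  expect_equal(sum(cs$truth$planted_sets != 0), 15L)
})

test_that("planted sets shift the latent mean by about the tilt", {
  sim <- simulate_screens(5000L, seed = 12L)
  cs <- simulate_catalog_and_sets(sim$truth, n_sets = 20L, shift = 1,
                                  set_size_range = c(80L, 100L),
                                  seed = 13L)
  lam <- sim$truth$latent
  planted_up <- names(cs$truth$planted_sets)[cs$truth$planted_sets > 0]
  mus <- vapply(cs$sets$genes[planted_up], function(g) mean(lam[g]),
                numeric(1L))
  # exponential tilt of a standard normal moves the mean to the shift
  expect_lt(abs(mean(mus) - 1), 0.25)
  null_sets <- names(cs$truth$planted_sets)[cs$truth$planted_sets == 0]
  mus0 <- vapply(cs$sets$genes[null_sets], function(g) mean(lam[g]),
                 numeric(1L))
  expect_lt(abs(mean(mus0)), 0.15)
})

test_that("noiseless regulator networks are block-structured", {
  universe <- sprintf("g%04d", 1:500)
  clusters <- split(universe[1:90], rep(1:3, each = 30L))
  names(clusters) <- paste0("cl", 1:3)
  sim <- simulate_regulatory_network(clusters, n_global = 1L, n_local = 3L,
                                     background_tfs = 0L, edge_noise = 0,
                                     seed = 14L, universe = universe)
  for (tf in names(sim$planted_tfs)) {
    tg <- sim$network$edges[[tf]]
    per_cluster <- vapply(clusters, function(cl)
      length(intersect(tg, toupper(cl))), integer(1L))
    if (sim$planted_tfs[[tf]] == "global") {
      expect_true(all(per_cluster > 0L))
    } else {
      expect_equal(sum(per_cluster > 0L), 1L)
    }
  }
})

test_that("plate simulation is seed-stable and matches its noise level", {
  design <- competition_design(data.frame(
    plate = "P1", well = sprintf("W%02d", 1:8),
    strain = c(sprintf("m%d", 1:5), "WT_WT", "WT_RFP", "WT_CFP"),
    role = c(rep("competition", 5L), "wt_wt", "ref_rfp", "ref_cfp")))
  tr <- data.frame(well = sprintf("W%02d", 1:5),
                   A = seq(-0.4, 0.4, length.out = 5L),
                   S = c(0.1, -0.1, 0, 0.2, -0.2),
                   G = c(0.01, 0, -0.01, 0.02, 0))
  s1 <- simulate_competition_plate(design, tr, noise_sd = 0.1, seed = 15L)
  s2 <- simulate_competition_plate(design, tr, noise_sd = 0.1, seed = 15L)
  expect_identical(s1$measurements, s2$measurements)
  # residual sd after refitting approximates the generating noise
  days <- c(2, 4, 6, 8, 10, 12); times <- c(2, 4, 6, 8, 10, 12)
  s3 <- simulate_competition_plate(design, tr, noise_sd = 0.1,
                                   days = days, times = times, seed = 16L)
  corr <- subtract_background(s3$measurements, design)
  fit <- fit_survival_model(corr, design)
  resid_sd <- {
    pred <- merge(corr, as.data.frame(fit)[, c("well", "A", "S", "G")],
                  by = "well")
    ce <- attr(fit, "plate_effects")$P1
    key <- paste0(pred$aging_day, "d:", pred$outgrowth_hour, "h")
    r <- pred$y - (pred$A + pred$S * pred$aging_day +
                     pred$G * pred$outgrowth_hour + ce[key])
    n_par <- 6L + 2L * 5L + (length(ce) - 1L)   # A's, S/G's, free C's
    sqrt(sum(r^2) / (length(r) - n_par))
  }
  expect_gt(nrow(corr), 200L)
  expect_lt(abs(resid_sd - 0.1) / 0.1, 0.1)
})

test_that("simulate_bundle writes a complete loadable input set", {
  dir <- withr::local_tempdir()
  b <- simulate_bundle(file.path(dir, "bundle"), n_genes = 300L, seed = 17L)
  files <- list.files(file.path(dir, "bundle"))
  expect_true(all(c("catalog.tsv", "sets.gmt", "network.tsv", "plate.tsv",
                    "profiles.yaml", "truth.json") %in% files))
  ds <- load_screen_table(file.path(dir, "bundle", "screen1.tsv"),
                          "screen1")
  # round-trip through text loses only the printed precision
  expect_equal(ds$values, b$screens[[1L]]$values, tolerance = 1e-10)
  truth <- jsonlite::read_json(file.path(dir, "bundle", "truth.json"))
  expect_equal(truth$seed, 17L)
  expect_length(truth$latent, 300L)
})
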