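toy_design <- function(n_mut = 3L, plate = "P1") {
  wells <- sprintf("W%02d", seq_len(n_mut + 3L))
  competition_design(data.frame(
    plate = plate, well = wells,
    strain = c(sprintf("mut%02d", seq_len(n_mut)), "WT_WT", "WT_RFP",
               "WT_CFP"),
    role = c(rep("competition", n_mut), "wt_wt", "ref_rfp", "ref_cfp"),
    stringsAsFactors = FALSE))
}

centered_effects <- function(days, times, sd = 0.2, seed = 1) {
  set.seed(seed)
  combos <- expand.grid(d = days, t = times)
  ce <- rnorm(nrow(combos), sd = sd)
  ce <- ce - mean(ce)
  stats::setNames(ce, paste0(combos$d, "d:", combos$t, "h"))
}

test_that("background subtraction removes a constant reference signal", {
  design <- toy_design(1L)
  tr <- data.frame(well = "W01", A = 0.3, S = 0.05, G = 0.01)
  sim <- simulate_competition_plate(design, tr, noise_sd = 0, seed = 2,
                                    background = 0)
  corr0 <- subtract_background(sim$measurements, design)
  # zero background: measurements pass through unchanged
  expect_equal(corr0$rfp_corr, corr0$rfp[seq_len(nrow(corr0))],
               tolerance = 1e-12)
  sim_bg <- simulate_competition_plate(design, tr, noise_sd = 0, seed = 2,
                                       background = 100)
  corr <- subtract_background(sim_bg$measurements, design)
  expect_equal(corr$y, corr0$y, tolerance = 1e-12)
  # direct arithmetic: reference at 100, well reading 350 -> 250
  m <- sim_bg$measurements[1L, ]
  expect_equal(subtract_background(
    transform(sim_bg$measurements, rfp = ifelse(
      well == "W01", 350, rfp)), design)$rfp_corr[1L], 250)
})

test_that("corrected values at or below zero are floored and flagged", {
  design <- toy_design(1L)
  tr <- data.frame(well = "W01", A = 0, S = 0, G = 0)
  sim <- simulate_competition_plate(design, tr, noise_sd = 0, seed = 3,
                                    background = 100)
  m <- sim$measurements
  m$rfp[m$well == "W01"] <- 50      # below the 100-unit background
  corr <- subtract_background(m, design)
  expect_true(all(corr$clipped[corr$well == "W01"]))
  expect_equal(corr$rfp_corr[corr$well == "W01"],
               rep(1, sum(corr$well == "W01")))
})

test_that("missing reference timepoints fall back to the nearest one", {
  design <- toy_design(1L)
  tr <- data.frame(well = "W01", A = 0.2, S = 0.1, G = 0)
  sim <- simulate_competition_plate(design, tr, noise_sd = 0, seed = 4)
  m <- sim$measurements
  drop <- m$well %in% c("W03", "W04") & m$aging_day == max(m$aging_day)
  m <- m[!drop, , drop = FALSE]
  w <- testthat::capture_warnings(corr <- subtract_background(m, design))
  expect_true(any(grepl("nearest", w)))
  expect_false(anyNA(corr$y))
})

test_that("noise-free plates recover A, S, G and C to 1e-9", {
  design <- toy_design(4L)
  tr <- data.frame(well = sprintf("W%02d", 1:4),
                   A = c(0.5, -0.2, 0.8, 0), S = c(0.12, -0.3, 0, 0.05),
                   G = c(0.01, -0.02, 0.015, 0))
  ce <- centered_effects(c(4, 6, 8, 10), c(4, 8, 12, 16), seed = 11)
  sim <- simulate_competition_plate(design, tr, plate_effects = ce,
                                    noise_sd = 0, seed = 12)
  fit <- suppressWarnings(fit_survival_model(
    subtract_background(sim$measurements, design), design))
  mut <- fit[!fit$is_wt_wt, ]
  expect_equal(mut$A, tr$A, tolerance = 1e-9)
  expect_equal(mut$S, tr$S, tolerance = 1e-9)
  expect_equal(mut$G, tr$G, tolerance = 1e-9)
  pe <- attr(fit, "plate_effects")$P1
  expect_equal(unname(pe[names(ce)]), unname(ce), tolerance = 1e-9)
  # WT/WT wells are constrained, not estimated
  expect_equal(fit$S[fit$is_wt_wt], 0)
  expect_equal(fit$G[fit$is_wt_wt], 0)
  expect_equal(fit$L, 1 + fit$S)
})

test_that("tiny two-well design matches hand-built normal equations", {
  design <- competition_design(data.frame(
    plate = "P1", well = c("W1", "W2", "W3", "W4"),
    strain = c("mut", "WT_WT", "WT_RFP", "WT_CFP"),
    role = c("competition", "wt_wt", "ref_rfp", "ref_cfp")))
  days <- c(2, 4); times <- c(3, 6)
  tr <- data.frame(well = "W1", A = 0.4, S = -0.1, G = 0.02)
  sim <- simulate_competition_plate(design, tr, noise_sd = 0.05,
                                    days = days, times = times, seed = 21)
  corr <- subtract_background(sim$measurements, design)
  fit <- suppressWarnings(fit_survival_model(corr, design))
  # oracle: explicit design matrix, sum-to-zero C over the 4 combos
  mw <- corr[order(corr$well, corr$aging_day, corr$outgrowth_hour), ]
  is1 <- as.numeric(mw$well == "W1")
  is2 <- as.numeric(mw$well == "W2")
  combo <- factor(paste0(mw$aging_day, "d:", mw$outgrowth_hour, "h"))
  Cz <- stats::model.matrix(~combo,
                            contrasts.arg = list(combo = "contr.sum"))[, -1L]
  X <- cbind(A1 = is1, A2 = is2, S1 = is1 * mw$aging_day,
             G1 = is1 * mw$outgrowth_hour, Cz)
  beta <- oracle_ols(X, mw$y)
  w1 <- fit[fit$well == "W1", ]
  expect_equal(w1$A, unname(beta["A1", 1L]), tolerance = 1e-12)
  expect_equal(w1$S, unname(beta["S1", 1L]), tolerance = 1e-12)
  expect_equal(w1$G, unname(beta["G1", 1L]), tolerance = 1e-12)
})

test_that("estimates ignore a common multiplicative signal change", {
  design <- toy_design(2L)
  tr <- data.frame(well = c("W01", "W02"), A = c(0.3, -0.1),
                   S = c(0.08, -0.15), G = c(0.01, 0))
  sim <- simulate_competition_plate(design, tr, noise_sd = 0.05, seed = 31,
                                    background = 0)
  m2 <- sim$measurements
  m2$rfp <- m2$rfp * 3          # common gain change on both channels
  m2$cfp <- m2$cfp * 3
  f1 <- suppressWarnings(fit_survival_model(
    subtract_background(sim$measurements, design), design))
  f2 <- suppressWarnings(fit_survival_model(
    subtract_background(m2, design), design))
  expect_equal(f1$S, f2$S, tolerance = 1e-9)
  expect_equal(f1$G, f2$G, tolerance = 1e-9)
})

test_that("omitting the C term biases S when plate effects exist", {
  design <- toy_design(3L)
  tr <- data.frame(well = sprintf("W%02d", 1:3), A = c(0.2, 0.5, -0.3),
                   S = c(0.1, -0.1, 0.05), G = c(0.01, 0, -0.01))
  # a day-correlated plate effect confounds S if unmodeled
  days <- c(4, 6, 8, 10); times <- c(4, 8, 12, 16)
  combos <- expand.grid(d = days, t = times)
  ce <- 0.15 * (combos$d - mean(days))
  ce <- ce - mean(ce)
  names(ce) <- paste0(combos$d, "d:", combos$t, "h")
  sim <- simulate_competition_plate(design, tr, plate_effects = ce,
                                    noise_sd = 0.02, seed = 41)
  corr <- subtract_background(sim$measurements, design)
  full <- suppressWarnings(fit_survival_model(corr, design))
  # naive per-well regression without C
  naive_s <- vapply(sprintf("W%02d", 1:3), function(w) {
    d <- corr[corr$well == w, ]
    stats::coef(stats::lm(y ~ aging_day + outgrowth_hour, d))[["aging_day"]]
  }, numeric(1L))
  full_err <- max(abs(full$S[match(tr$well, full$well)] - tr$S))
  naive_err <- max(abs(naive_s - tr$S))
  expect_lt(full_err, 0.02)
  expect_gt(naive_err, full_err)
})

test_that("degenerate designs are rejected with a clear message", {
  design <- toy_design(1L)
  tr <- data.frame(well = "W01", A = 0, S = 0, G = 0)
  sim <- simulate_competition_plate(design, tr, noise_sd = 0, seed = 51)
  corr <- subtract_background(sim$measurements, design)
  one_day <- corr[corr$aging_day == corr$aging_day[1L], ]
  expect_error(fit_survival_model(one_day, design), "aging days")
  expect_error(fit_survival_model(sim$measurements, design),
               "subtract_background")
})

test_that("relative_lifespan is the 1 + S transform", {
  expect_equal(relative_lifespan(0), 1)
  expect_equal(relative_lifespan(0.2), 1.2)
  expect_equal(relative_lifespan(-0.5), 0.5)
  expect_error(relative_lifespan(NA_real_))
})

test_that("plate TSV round-trip rebuilds the design from strain labels", {
  design <- toy_design(2L)
  tr <- data.frame(well = c("W01", "W02"), A = c(0.1, 0.2), S = c(0, 0.1),
                   G = c(0, 0))
  sim <- simulate_competition_plate(design, tr, noise_sd = 0, seed = 61)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(sim$measurements, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  back <- read_plate_tsv(path)
  expect_setequal(back$design$wells$role, design$wells$role)
  expect_equal(nrow(back$measurements), nrow(sim$measurements))
})
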