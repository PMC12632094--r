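#' Define a competitive-aging plate design
#'
#' Each well of a plate carries either a mutant (RFP) competing against the
#' wild-type reference (CFP), a neutral WT/WT competition used to constrain
#' the model, or a single-color reference well used for background
#' fluorescence.
#'
#' @param wells Data frame with columns `plate`, `well`, `strain` and `role`
#'   (one of `"competition"`, `"wt_wt"`, `"ref_rfp"`, `"ref_cfp"`).
#' @return An object of class `competition_design`.
#' @export
competition_design <- function(wells) {
  need <- c("plate", "well", "strain", "role")
  if (!all(need %in% names(wells)))
    stop("design needs columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(wells$role),
                 c("competition", "wt_wt", "ref_rfp", "ref_cfp"))
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(paste(wells$plate, wells$well)))
    stop("duplicate (plate, well) entries in design")
  for (p in unique(wells$plate)) {
    r <- wells$role[wells$plate == p]
    if (!any(r == "wt_wt"))
      stop("plate '", p, "' needs at least one WT/WT well")
    if (!any(r == "ref_rfp") || !any(r == "ref_cfp"))
      stop("plate '", p, "' needs single-color reference wells of both colors")
  }
  structure(list(wells = wells), class = "competition_design")
}

#' Read competitive-aging measurements from TSV
#'
#' @param path Long-format TSV with columns `plate, well, strain, is_wt_wt,
#'   aging_day, outgrowth_hour, od, rfp, cfp`. Single-color reference wells
#'   are recognized by strain names `WT_RFP` / `WT_CFP`.
#' @return List with `measurements` (the data frame) and `design`
#'   (a [competition_design()] inferred from strain labels).
#' @export
read_plate_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("plate", "well", "strain", "is_wt_wt", "aging_day",
            "outgrowth_hour", "od", "rfp", "cfp")
  if (!all(need %in% names(tab)))
    stop("plate table needs columns: ", paste(need, collapse = ", "))
  wells <- unique(tab[, c("plate", "well", "strain", "is_wt_wt")])
  wells$role <- ifelse(wells$strain == "WT_RFP", "ref_rfp",
                ifelse(wells$strain == "WT_CFP", "ref_cfp",
                ifelse(as.logical(wells$is_wt_wt), "wt_wt", "competition")))
  list(measurements = tab,
       design = competition_design(wells[, c("plate", "well", "strain",
                                             "role")]))
}

#' Subtract background fluorescence
#'
#' For each plate, color and sampling point (aging day, outgrowth hour), the
#' background is the mean signal of the opposite-color single-strain
#' reference wells (wells carrying no strain of that color). The background
#' is subtracted and the result floored at `floor` fluorescence units so the
#' log-ratio stays defined; when a sampling point has no reference reading,
#' the nearest sampling point (in hours, days counted as 24 h) is used with
#' a warning.
#'
#' @param measurements Data frame as in [read_plate_tsv()].
#' @param design A [competition_design()].
#' @param floor Minimum corrected fluorescence (default 1).
#' @return The measurements of competition and WT/WT wells with added
#'   columns `rfp_corr`, `cfp_corr`, `clipped` (logical) and
#'   `y = log(rfp_corr / cfp_corr)`.
#' @export
subtract_background <- function(measurements, design, floor = 1) {
  stopifnot(inherits(design, "competition_design"), floor > 0)
  dw <- design$wells
  out <- list()
  for (p in unique(dw$plate)) {
    mp <- measurements[measurements$plate == p, , drop = FALSE]
    ref_rfp_wells <- dw$well[dw$plate == p & dw$role == "ref_rfp"]
    ref_cfp_wells <- dw$well[dw$plate == p & dw$role == "ref_cfp"]
    # background per (T, t): RFP channel from CFP-only wells and vice versa
    key <- paste(mp$aging_day, mp$outgrowth_hour)
    bg <- function(channel, ref_wells) {
      sel <- mp$well %in% ref_wells
      tapply(mp[[channel]][sel], key[sel], mean)
    }
    bg_rfp <- bg("rfp", ref_cfp_wells)
    bg_cfp <- bg("cfp", ref_rfp_wells)
    keep <- mp$well %in% dw$well[dw$plate == p &
                                   dw$role %in% c("competition", "wt_wt")]
    mp <- mp[keep, , drop = FALSE]
    key <- paste(mp$aging_day, mp$outgrowth_hour)
    lookup <- function(bgtab, keys, days, hours) {
      v <- bgtab[keys]
      if (anyNA(v)) {
        warning("missing reference reading at ", sum(is.na(v)),
                " sampling point(s); using nearest-timepoint background")
        have <- do.call(rbind, strsplit(names(bgtab), " ", fixed = TRUE))
        hd <- as.numeric(have[, 1L]); hh <- as.numeric(have[, 2L])
        for (i in which(is.na(v))) {
          d <- abs(hd - days[i]) * 24 + abs(hh - hours[i])
          v[i] <- bgtab[[which.min(d)]]
        }
      }
      as.numeric(v)
    }
    rfp_corr <- mp$rfp - lookup(bg_rfp, key, mp$aging_day, mp$outgrowth_hour)
    cfp_corr <- mp$cfp - lookup(bg_cfp, key, mp$aging_day, mp$outgrowth_hour)
    clipped <- rfp_corr < floor | cfp_corr < floor
    mp$rfp_corr <- pmax(rfp_corr, floor)
    mp$cfp_corr <- pmax(cfp_corr, floor)
    mp$clipped <- clipped
    mp$y <- log(mp$rfp_corr / mp$cfp_corr)
    out[[length(out) + 1L]] <- mp
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit the competitive-aging survival model
#'
#' Fits, separately per plate, the joint linear model
#' \deqn{y_{w,T_i,t_j} = A_w + S_w T_i + G_w t_j + C_{T_i,t_j}}
#' where y is the background-corrected log fluorescence ratio
#' ln(RFP/CFP), A_w the initial log viable-cell ratio of well w, S_w the
#' relative survival slope per aging day, G_w the growth-rate difference per
#' outgrowth hour, and C a plate-level systematic offset shared by all wells
#' at each sampling point, constrained to sum to zero for identifiability.
#' WT/WT competition wells have their S and G columns omitted, enforcing
#' S = G = 0 by construction (these wells anchor the C term). Relative
#' lifespan is L = 1 + S.
#'
#' @param observations Background-corrected measurements from
#'   [subtract_background()].
#' @param design A [competition_design()].
#' @param od_min,od_max Outgrowth window: only timepoints with
#'   `od_min <= od <= od_max` enter the fit (defaults 0.02 and 1.0; plate
#'   readers saturate near OD 1).
#' @return An object of class `survival_fit`: data frame with one row per
#'   well (`plate, well, strain, is_wt_wt, A, se_A, S, se_S, G, se_G, L`;
#'   constrained WT/WT slopes have `NA` standard errors) and attribute
#'   `plate_effects` (named list of per-plate C estimates by sampling
#'   point).
#' @export
fit_survival_model <- function(observations, design,
                               od_min = 0.02, od_max = 1.0) {
  stopifnot(inherits(design, "competition_design"))
  if (!"y" %in% names(observations))
    stop("run subtract_background() first (no 'y' column)")
  dw <- design$wells
  obs <- observations[observations$od >= od_min & observations$od <= od_max,
                      , drop = FALSE]
  results <- list()
  plate_effects <- list()
  for (p in unique(obs$plate)) {
    mp <- obs[obs$plate == p, , drop = FALSE]
    if (length(unique(mp$aging_day)) < 2L ||
        length(unique(mp$outgrowth_hour)) < 2L)
      stop("plate '", p, "' needs >= 2 aging days and >= 2 outgrowth times ",
           "inside the OD window")
    wl <- sort(unique(mp$well))
    wt_wells <- dw$well[dw$plate == p & dw$role == "wt_wt"]
    fw <- factor(mp$well, levels = wl)
    A <- stats::model.matrix(~ 0 + fw)
    colnames(A) <- paste0("A.", wl)
    mut <- setdiff(wl, wt_wells)
    Smat <- vapply(mut, function(w) (mp$well == w) * mp$aging_day,
                   numeric(nrow(mp)))
    Gmat <- vapply(mut, function(w) (mp$well == w) * mp$outgrowth_hour,
                   numeric(nrow(mp)))
    Smat <- matrix(Smat, nrow = nrow(mp),
                   dimnames = list(NULL, paste0("S.", mut)))
    Gmat <- matrix(Gmat, nrow = nrow(mp),
                   dimnames = list(NULL, paste0("G.", mut)))
    combo <- factor(paste0(mp$aging_day, "d:", mp$outgrowth_hour, "h"))
    Cmat <- NULL
    if (nlevels(combo) >= 2L) {
      Cmat <- stats::model.matrix(~ combo,
                                  contrasts.arg = list(combo = "contr.sum"))
      Cmat <- Cmat[, -1L, drop = FALSE]     # drop intercept column
      colnames(Cmat) <- paste0("C.", seq_len(ncol(Cmat)))
    }
    X <- cbind(A, Smat, Gmat, Cmat)
    fit <- stats::lm(mp$y ~ 0 + X)
    cf <- stats::coef(fit)
    names(cf) <- sub("^X", "", names(cf))
    if (anyNA(cf))
      stop("rank-deficient design on plate '", p, "'; unidentifiable: ",
           paste(names(cf)[is.na(cf)], collapse = ", "))
    se <- stats::setNames(summary(fit)$coefficients[, 2L], names(cf))
    grab <- function(prefix, w) {
      nmv <- paste0(prefix, ".", w)
      if (nmv %in% names(cf)) c(cf[[nmv]], se[[nmv]]) else c(0, NA_real_)
    }
    rows <- lapply(wl, function(w) {
      a <- grab("A", w); s <- grab("S", w); g <- grab("G", w)
      data.frame(plate = p, well = w,
                 strain = dw$strain[dw$plate == p & dw$well == w][1L],
                 is_wt_wt = w %in% wt_wells,
                 A = a[1L], se_A = a[2L], S = s[1L], se_S = s[2L],
                 G = g[1L], se_G = g[2L], L = relative_lifespan(s[1L]),
                 stringsAsFactors = FALSE)
    })
    results[[length(results) + 1L]] <- do.call(rbind, rows)
    if (!is.null(Cmat)) {
      cvals <- cf[grep("^C\\.", names(cf))]
      call_levels <- c(cvals, -sum(cvals))
      names(call_levels) <- levels(combo)
      plate_effects[[as.character(p)]] <- call_levels
    }
  }
  out <- do.call(rbind, results)
  rownames(out) <- NULL
  structure(out, plate_effects = plate_effects,
            class = c("survival_fit", "data.frame"))
}

#' Relative lifespan from a survival slope
#'
#' A neutral competition (S = 0) has relative lifespan 1; each unit of
#' survival slope shifts it one-for-one: L = 1 + S.
#'
#' @param s Survival slope(s) per aging day.
#' @return Relative lifespan value(s).
#' @examples
#' relative_lifespan(c(0, 0.2, -0.5))
#' @export
relative_lifespan <- function(s) {
  stopifnot(all(is.finite(s)))
  1 + s
}
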