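# Differential splicing / expression statistics: per-replicate deltas are
# divided by a coverage-local standard deviation (sliding window over
# features sorted by supporting-read totals, loess-smoothed) to give Z
# values; replicates are combined by direction-specific rank products whose
# significance comes from permuted rank lists.

#' Differential-analysis configuration
#'
#' @param window_fraction sliding-window size as a fraction of the feature
#'   count (default 0.01, i.e. a 1 percent window).
#' @param min_window minimum window size in features (default 25).
#' @param loess_span loess smoothing span over coverage rank (default 0.3).
#' @param n_permutations permutations for the rank-product FDR (default 200).
#' @param fdr_cut FDR threshold for calls (default 0.05).
#' @param delta_cut minimum |mean delta| for PSI/PIR calls (default 0.10);
#'   expression calls use `log2(fold_cut)` instead.
#' @param fold_cut minimum fold change for expression calls (default 1.5).
#' @param min_coverage minimum junction-informative coverage per sample for a
#'   feature to enter testing (default 10).
#' @param pseudocount added to RPKM before the log2 ratio (default 0.1).
#' @param seed integer seed for the permutation generator.
#' @return An object of class `diff_config`.
#' @export
differential_config <- function(window_fraction = 0.01, min_window = 25L,
                                loess_span = 0.3, n_permutations = 200L,
                                fdr_cut = 0.05, delta_cut = 0.10,
                                fold_cut = 1.5, min_coverage = 10L,
                                pseudocount = 0.1, seed = 1L) {
  stopifnot(window_fraction > 0, window_fraction <= 1, n_permutations >= 1L,
            min_window >= 2L)
  structure(as.list(environment()), class = "diff_config")
}

#' Per-replicate change in a splicing or expression metric
#'
#' PSI/PIR changes are plain differences (case minus control); expression
#' changes are `log2((case + c) / (control + c))` with pseudocount `c`.
#'
#' @param case_value,control_value numeric vectors; NA propagates (callers
#'   exclude such records with a reason).
#' @param metric "psi", "pir" or "expression".
#' @param pseudocount pseudocount for the expression ratio.
#' @return Numeric delta vector.
#' @export
delta_metric <- function(case_value, control_value,
                         metric = c("psi", "pir", "expression"),
                         pseudocount = 0.1) {
  metric <- match.arg(metric)
  if (metric == "expression") {
    log2((case_value + pseudocount) / (control_value + pseudocount))
  } else {
    case_value - control_value
  }
}

#' Coverage-local standard deviation
#'
#' Features are sorted by their supporting-read totals; each feature's raw
#' local SD is the SD of the deltas inside a centred window of
#' `max(min_window, round(window_fraction * n))` features (windows are
#' shifted inward at the list edges, never shrunk). Raw SDs are then
#' loess-smoothed against coverage rank and floored at a small positive
#' epsilon. With fewer than `min_window` features a single global SD is used
#' with a warning.
#'
#' @param deltas numeric vector of per-feature changes.
#' @param coverages aligned numeric vector of supporting-read totals (the
#'   sorting key).
#' @param config a [differential_config()].
#' @param eps positive floor for the smoothed SD.
#' @return Numeric vector of local SDs in the original feature order.
#' @export
local_sd <- function(deltas, coverages, config = differential_config(),
                     eps = 1e-6) {
  n <- length(deltas)
  stopifnot(length(coverages) == n)
  if (n < config$min_window) {
    warning("fewer than min_window features; using a single global SD")
    g <- stats::sd(deltas)
    if (!is.finite(g)) g <- eps
    return(rep(max(g, eps), n))
  }
  ord <- order(coverages)
  w <- max(config$min_window, round(config$window_fraction * n))
  raw <- running_sd(deltas[ord], w)
  rk <- seq_len(n)
  sm <- tryCatch(
    stats::predict(stats::loess(raw ~ rk, span = config$loess_span,
                                degree = 2, family = "gaussian")),
    error = function(e) raw
  )
  sm <- pmax(sm, eps)
  out <- numeric(n)
  out[ord] <- sm
  out
}

#' Z-value transformation
#'
#' @param delta numeric change.
#' @param local_sd positive local standard deviation.
#' @return `delta / local_sd`.
#' @export
z_transform <- function(delta, local_sd) {
  if (any(local_sd <= 0)) stop("local SD must be positive")
  delta / local_sd
}

#' Direction-specific rank product across replicates
#'
#' Within each replicate features are ranked by Z, rank 1 being the most
#' extreme in the requested direction (largest Z for "up", smallest for
#' "down"); tied Z values receive average ranks. Per-feature ranks are
#' multiplied across replicates.
#'
#' @param z matrix (features x replicates) of Z values, no missing entries.
#' @param direction "up" or "down".
#' @return List with `ranks` (matrix) and `rp` (numeric vector).
#' @export
rank_product <- function(z, direction = c("up", "down")) {
  direction <- match.arg(direction)
  z <- as.matrix(z)
  if (ncol(z) < 1L) stop("at least one replicate required")
  if (anyNA(z)) stop("Z matrix must be complete (exclude missing features first)")
  r <- apply(z, 2L, function(col) {
    if (direction == "up") rank(-col, ties.method = "average")
    else rank(col, ties.method = "average")
  })
  r <- matrix(r, nrow = nrow(z))
  list(ranks = r, rp = apply(r, 1L, prod))
}

#' Permutation FDR for rank products
#'
#' For each permutation every replicate's rank list is shuffled
#' independently and null rank products are recomputed. The FDR of a feature
#' is the expected number of null rank products at or below its observed one
#' (averaged over permutations), divided by the observed number of features
#' at or below it, made monotone non-decreasing in the rank product and
#' capped at 1.
#'
#' @param rp observed rank products.
#' @param n_features number of features ranked (usually `length(rp)`).
#' @param n_replicates number of replicates multiplied into the products.
#' @param config a [differential_config()] (permutation count and seed).
#' @return Numeric FDR vector aligned with `rp`.
#' @export
rank_product_fdr <- function(rp, n_features = length(rp),
                             n_replicates, config = differential_config()) {
  B <- config$n_permutations
  if (B < 1L) stop("n_permutations must be >= 1")
  set.seed(config$seed)
  null_rp <- numeric(n_features * B)
  for (b in seq_len(B)) {
    p <- rep(1, n_features)
    for (j in seq_len(n_replicates)) p <- p * sample.int(n_features)
    null_rp[((b - 1L) * n_features + 1L):(b * n_features)] <- p
  }
  null_sorted <- sort(null_rp)
  exp_null <- findInterval(rp, null_sorted) / B
  obs_le <- findInterval(rp, sort(rp))
  fdr <- exp_null / obs_le
  # monotone non-decreasing in RP, lowering only (step-up), cap at 1
  o <- order(rp)
  f <- fdr[o]
  f <- rev(cummin(rev(f)))
  fdr[o] <- f
  pmin(fdr, 1)
}

#' Apply significance and effect-size cutoffs
#'
#' A feature is called "down" if its down-direction FDR is below `fdr_cut`
#' and its mean delta is at most `-delta_cut`; "up" analogously; otherwise
#' "none". For the expression metric the effect cutoff is
#' `log2(fold_cut)`.
#'
#' @param records data.frame with `delta_mean`, `fdr_up`, `fdr_down`.
#' @param config a [differential_config()].
#' @param metric metric the records carry.
#' @return `records` with a `call` column added.
#' @export
call_differential <- function(records, config = differential_config(),
                              metric = c("psi", "pir", "expression")) {
  metric <- match.arg(metric)
  cut <- if (metric == "expression") log2(config$fold_cut) else config$delta_cut
  up <- records$fdr_up < config$fdr_cut & records$delta_mean >= cut
  dn <- records$fdr_down < config$fdr_cut & records$delta_mean <= -cut
  records$call <- ifelse(dn, "down", ifelse(up, "up", "none"))
  records
}

#' Differential test over paired case/control replicate count tables
#'
#' The full replicate-combining procedure for one metric: per replicate pair
#' the metric is computed in case and control (features below the coverage
#' floor or with undefined values anywhere are excluded and reported), the
#' delta is Z-transformed with the coverage-local SD of that replicate, and
#' replicates are combined by up- and down-direction rank products with
#' permutation FDRs. Mean delta across replicates is the reported effect
#' size.
#'
#' @param case,control lists (one element per replicate) of data.frames. For
#'   "psi": columns `exon_id`, `e_in`, `e_out`; for "pir": `intron_id`,
#'   `i_in`, `i_out`; for "expression": `gene_id`, `reads`, `exon_kb`.
#' @param metric "psi", "pir" or "expression".
#' @param config a [differential_config()].
#' @return data.frame with `feature_id`, per-replicate `delta.*` and `z.*`
#'   columns, `coverage`, `delta_mean`, `rp_up`, `fdr_up`, `rp_down`,
#'   `fdr_down`, `call`; excluded feature ids and reasons in attribute
#'   `excluded`.
#' @export
differential_test <- function(case, control,
                              metric = c("psi", "pir", "expression"),
                              config = differential_config()) {
  metric <- match.arg(metric)
  stopifnot(length(case) == length(control), length(case) >= 1L)
  k <- length(case)

  extract <- function(tb) {
    if (metric == "psi") {
      data.frame(feature_id = tb$exon_id, value = psi(tb$e_in, tb$e_out),
                 coverage = tb$e_in + tb$e_out, stringsAsFactors = FALSE)
    } else if (metric == "pir") {
      data.frame(feature_id = tb$intron_id, value = pir(tb$i_in, tb$i_out),
                 coverage = tb$i_in + tb$i_out, stringsAsFactors = FALSE)
    } else {
      total_m <- sum(tb$reads) / 1e6
      data.frame(feature_id = tb$gene_id,
                 value = rpkm(tb$reads, tb$exon_kb, total_m),
                 coverage = tb$reads, stringsAsFactors = FALSE)
    }
  }

  ids <- NULL
  per_rep <- vector("list", k)
  for (r in seq_len(k)) {
    ca <- extract(case[[r]])
    co <- extract(control[[r]])
    m <- match(ca$feature_id, co$feature_id)
    tb <- data.frame(
      feature_id = ca$feature_id,
      v_case = ca$value, v_ctrl = co$value[m],
      cov = ca$coverage + ifelse(is.na(m), 0L, co$coverage[m]),
      cov_case = ca$coverage, cov_ctrl = co$coverage[m],
      stringsAsFactors = FALSE
    )
    per_rep[[r]] <- tb
    ids <- if (is.null(ids)) tb$feature_id else intersect(ids, tb$feature_id)
  }

  # feature universe: defined values and coverage floor in every sample
  floor_cov <- if (metric == "expression") 0L else config$min_coverage
  excluded <- character(0)
  ok <- rep(TRUE, length(ids))
  reason <- rep(NA_character_, length(ids))
  for (r in seq_len(k)) {
    tb <- per_rep[[r]][match(ids, per_rep[[r]]$feature_id), ]
    bad_na <- is.na(tb$v_case) | is.na(tb$v_ctrl)
    bad_cov <- !bad_na & (tb$cov_case < floor_cov | tb$cov_ctrl < floor_cov)
    reason[ok & bad_na] <- "undefined_value"
    reason[ok & bad_cov] <- "low_coverage"
    ok <- ok & !(bad_na | bad_cov)
  }
  excluded <- data.frame(feature_id = ids[!ok], reason = reason[!ok],
                         stringsAsFactors = FALSE)
  ids <- ids[ok]
  if (length(ids) < 2L) stop("fewer than 2 testable features")

  delta <- matrix(NA_real_, length(ids), k)
  zmat <- matrix(NA_real_, length(ids), k)
  covmat <- matrix(NA_real_, length(ids), k)
  for (r in seq_len(k)) {
    tb <- per_rep[[r]][match(ids, per_rep[[r]]$feature_id), ]
    d <- delta_metric(tb$v_case, tb$v_ctrl, metric, config$pseudocount)
    s <- local_sd(d, tb$cov, config)
    delta[, r] <- d
    zmat[, r] <- z_transform(d, s)
    covmat[, r] <- tb$cov
  }

  rp_up <- rank_product(zmat, "up")
  rp_dn <- rank_product(zmat, "down")
  # one derived seed for both directions: mirrored Z then yields exactly
  # mirrored up/down lists when case and control labels are swapped
  cfg_rp <- config
  cfg_rp$seed <- stage_seed(config$seed, "rank_product_null")
  fdr_up <- rank_product_fdr(rp_up$rp, length(ids), k, cfg_rp)
  fdr_dn <- rank_product_fdr(rp_dn$rp, length(ids), k, cfg_rp)

  out <- data.frame(feature_id = ids, stringsAsFactors = FALSE)
  for (r in seq_len(k)) out[[paste0("delta.", r)]] <- delta[, r]
  for (r in seq_len(k)) out[[paste0("z.", r)]] <- zmat[, r]
  out$coverage <- rowMeans(covmat)
  out$delta_mean <- rowMeans(delta)
  out$z_mean <- rowMeans(zmat)
  out$rp_up <- rp_up$rp
  out$fdr_up <- fdr_up
  out$rp_down <- rp_dn$rp
  out$fdr_down <- fdr_dn
  out <- call_differential(out, config, metric)
  attr(out, "excluded") <- excluded
  out
}
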