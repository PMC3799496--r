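# Delta metrics, local SD, Z, rank products, permutation FDR, calls.

test_that("delta_metric computes differences and pseudocounted log ratios", {
  expect_equal(delta_metric(0.4, 0.7, "psi"), -0.3)
  expect_equal(delta_metric(20, 10, "expression", 0.1),
               log2(20.1 / 10.1))
  expect_true(is.na(delta_metric(NA_real_, 0.5, "psi")))
})

test_that("local_sd handles the zero-variance limit and matches a window oracle", {
  cfg <- differential_config()
  # all deltas equal -> everything floored at epsilon
  s0 <- local_sd(rep(0.2, 100), seq_len(100), cfg, eps = 1e-6)
  expect_true(all(s0 == 1e-6))
  # n = 200 with 1% window -> effective window = min_window = 25;
  # raw windowed SDs must equal a brute-force computation
  set.seed(8)
  d <- rnorm(200, 0, 0.3)
  cov <- sample.int(10000L, 200L)
  ord <- order(cov)
  ds <- d[ord]
  brute <- vapply(seq_len(200), function(i) {
    lo <- max(1L, i - 12L); hi <- min(200L, lo + 24L); lo <- max(1L, hi - 24L)
    sd(ds[lo:hi])
  }, numeric(1))
  raw <- clipsplice:::running_sd(ds, 25L)
  expect_equal(raw, brute)
  # fewer than min_window features -> global SD with a warning
  expect_warning(sg <- local_sd(d[1:10], cov[1:10], cfg), "global")
  expect_equal(sg, rep(sd(d[1:10]), 10))
})

test_that("local_sd recovers a known homoscedastic sigma", {
  set.seed(13)
  n <- 5000L
  d <- rnorm(n, 0, 0.2)
  cov <- sample.int(100000L, n)
  s <- local_sd(d, cov, differential_config())
  expect_true(all(abs(s - 0.2) < 0.02))
  z <- z_transform(d, s)
  expect_lt(abs(mean(z)), 0.1)
  expect_true(sd(z) > 0.9 && sd(z) < 1.1)
})

test_that("z_transform is the exact quotient with a positivity guard", {
  expect_equal(z_transform(0.2, 0.1), 2)
  expect_equal(z_transform(0, 5), 0)
  expect_equal(z_transform(-0.3, 0.1), -3)
  expect_error(z_transform(1, 0), "positive")
})

test_that("rank products multiply direction-specific average ranks", {
  z <- cbind(c(3, 2, 1), c(1, 3, 2))
  rp <- rank_product(z, "up")
  expect_equal(rp$ranks[, 1], c(1, 2, 3))
  expect_equal(rp$rp, c(3, 2, 6))
  # most extreme everywhere -> RP = 1
  z2 <- cbind(c(5, 1, 0), c(9, 2, 1), c(4, 0, -1))
  expect_equal(rank_product(z2, "up")$rp[1], 1)
  # ties share average ranks
  z3 <- cbind(c(2, 2, 1), c(3, 1, 2))
  expect_equal(rank_product(z3, "up")$ranks[, 1], c(1.5, 1.5, 3))
  # down direction reverses the ranking
  expect_equal(rank_product(z, "down")$ranks[, 1], c(3, 2, 1))
})

test_that("permutation FDR matches exhaustive enumeration at n = 5, k = 2", {
  # exhaustive oracle over all (5!)^2 = 14400 rank-list permutation pairs
  all_perm <- function() {
    # enumerate permutations of 1:5 without external packages
    rec <- function(v) {
      if (length(v) == 1L) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (rest in rec(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
      }
      out
    }
    rec(1:5)
  }
  P <- all_perm()
  null_counts <- function(r_obs) {
    tot <- numeric(length(r_obs))
    for (p1 in P) for (p2 in P) {
      rp_null <- p1 * p2
      for (t in seq_along(r_obs)) tot[t] <- tot[t] + sum(rp_null <= r_obs[t])
    }
    tot / length(P)^2
  }
  z <- cbind(c(2.5, 1.2, 0.1, -0.8, -2.0), c(2.0, 0.3, 0.9, -1.1, -1.5))
  rp <- rank_product(z, "up")$rp
  exact_E <- null_counts(rp)
  obs_le <- vapply(rp, function(r) sum(rp <= r), numeric(1))
  exact_fdr <- pmin(exact_E / obs_le, 1)
  o <- order(rp)
  f <- exact_fdr[o]; f <- rev(cummin(rev(f))); exact_fdr[o] <- f

  cfg <- differential_config(n_permutations = 10000L, seed = 99L)
  est <- rank_product_fdr(rp, 5L, 2L, cfg)
  # Monte-Carlo standard error of E (counts in 0..5 per draw) is bounded by
  # sqrt(var) / sqrt(B); allow 3 SE through the fdr ratio
  se_E <- sqrt(5) / sqrt(10000)
  tol <- 3 * se_E / obs_le
  expect_true(all(abs(est - exact_fdr) <= pmax(tol, 1e-3)))
})

test_that("pure ties saturate the null: nothing is called", {
  z <- matrix(0, nrow = 50, ncol = 2)  # identical deltas everywhere
  rp <- rank_product(z, "down")$rp
  fdr <- rank_product_fdr(rp, 50L, 2L, differential_config(seed = 3L))
  expect_true(all(fdr > 0.5))
})

test_that("FDR estimates converge as permutations double", {
  set.seed(4)
  z <- matrix(rnorm(200 * 2), ncol = 2)
  rp <- rank_product(z, "up")$rp
  f1 <- rank_product_fdr(rp, 200L, 2L,
                         differential_config(n_permutations = 400L, seed = 5L))
  f2 <- rank_product_fdr(rp, 200L, 2L,
                         differential_config(n_permutations = 800L, seed = 6L))
  # binomial-scale Monte-Carlo error on the expected-null counts
  expect_lt(median(abs(f1 - f2)), 0.05)
  expect_gt(cor(f1, f2), 0.98)
})

test_that("calls require both the FDR and the effect-size cutoff", {
  rec <- data.frame(delta_mean = c(-0.25, -0.05, -0.30, 0.2),
                    fdr_up = c(1, 1, 1, 0.01),
                    fdr_down = c(0.01, 0.01, 0.20, 1))
  out <- call_differential(rec, differential_config())
  expect_equal(out$call, c("down", "none", "none", "up"))
})

test_that("swapping case and control mirrors the calls", {
  cfg <- sim_config(seed = 71, n_genes = 150, cassette_fraction = 1,
                    planted_fraction = 0.1, true_delta_psi = -0.35,
                    depth_per_exon = 150, with_sequence = FALSE)
  sim <- simulate_genome(cfg)
  cnt <- simulate_splicing_counts(sim, n_replicates = 4)  # the KD design
  dcfg <- differential_config(seed = 17L)
  fwd <- differential_test(cnt$exons$case, cnt$exons$control, "psi", dcfg)
  rev <- differential_test(cnt$exons$control, cnt$exons$case, "psi", dcfg)
  expect_gt(sum(fwd$call == "down"), 0)
  expect_equal(fwd$feature_id[fwd$call == "down"],
               rev$feature_id[rev$call == "up"])
  expect_equal(fwd$delta_mean, -rev$delta_mean)
  # planted effects are concentrated in the down list
  tru <- sim$truth$exons
  called <- fwd$feature_id[fwd$call == "down"]
  expect_gt(mean(tru$planted[match(called, tru$exon_id)]), 0.5)
  expect_equal(sum(fwd$call == "up"), 0)
})
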