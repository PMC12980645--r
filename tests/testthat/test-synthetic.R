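test_that("generators are bit-reproducible given a seed", {
  expect_identical(gen_melt(tm = 330, dh = 45, noise_sd = 0.3, seed = 5),
                   gen_melt(tm = 330, dh = 45, noise_sd = 0.3, seed = 5))
  a <- gen_unfolded_ensemble(n_frames = 3, seed = 6)
  b <- gen_unfolded_ensemble(n_frames = 3, seed = 6)
  expect_identical(a$x, b$x)
  c1 <- gen_folded_ensemble(n_frames = 3, jitter_sd = 0.2, seed = 7)
  c2 <- gen_folded_ensemble(n_frames = 3, jitter_sd = 0.2, seed = 7)
  expect_identical(c1$z, c2$z)
  expect_false(identical(
    gen_melt(tm = 330, dh = 45, noise_sd = 0.3, seed = 5)$signal,
    gen_melt(tm = 330, dh = 45, noise_sd = 0.3, seed = 6)$signal))
})

test_that("the tuned folded geometry hits the class spacing targets", {
  ens <- gen_folded_ensemble(n_frames = 2, jitter_sd = 0, seed = 1)
  means <- attr(ens, "geometry")$class_means
  expect_lt(abs(means[["sb_eg"]] - 9.9), 0.5)
  expect_lt(abs(means[["nsb_eg"]] - 10.9), 0.5)
  expect_lt(abs(means[["fb"]] - 16.1), 0.5)
  # f/b' sites generated this way are out of reach of a ~14 A staple
  expect_equal(classify_compatibility(means[["fb"]], "x4x"), "incompatible")
  # jitter-free frames have zero spacing variance
  s <- cb_distance_series(ens, data.frame(chain_a = "A", index_a = 6,
                                          chain_b = "B", index_b = 8))
  expect_equal(sd(s$distance), 0)
  expect_error(gen_folded_ensemble(targets = c(sb_eg = 3, nsb_eg = 30, fb = 4),
                                   n_frames = 2),
               "unreachable spacing targets")
})

test_that("jittered folded ensembles average to the configured spacing", {
  ens <- gen_folded_ensemble(n_frames = 300, jitter_sd = 0.2, seed = 8)
  s <- cb_distance_series(ens, data.frame(chain_a = "A", index_a = 20,
                                          chain_b = "B", index_b = 15))
  sm <- summarize_series(s, t_start = 0)
  expect_lt(abs(sm$mean - 9.9), max(3 * sm$sem, 0.05))
})

test_that("unfolded anchor separation grows monotonically with loop length", {
  u <- gen_unfolded_ensemble(n_frames = 120, seed = 9)
  nsb <- data.frame(chain_a = "A", index_a = c(27, 20, 13, 6),
                    chain_b = "B", index_b = c(29, 22, 15, 8))
  means <- vapply(seq_len(4), function(i) {
    summarize_series(cb_distance_series(u, nsb[i, ]), t_start = 0)$mean
  }, numeric(1))
  ll <- loop_length("A", nsb$index_a, "B", nsb$index_b)
  expect_equal(cor(ll, means, method = "spearman"), 1)
})

test_that("a staple cap saturates the capped pair at its span", {
  span <- 14
  uc <- gen_unfolded_ensemble(n_frames = 40, seed = 10,
                              staple_cap = list(index_a = 6, index_b = 8,
                                                span = span))
  s <- cb_distance_series(uc, data.frame(chain_a = "A", index_a = 6,
                                         chain_b = "B", index_b = 8))
  expect_true(all(s$distance <= span))
  expect_gt(mean(s$distance), span / 2)  # pulled taut, not collapsed
  expect_error(
    gen_unfolded_ensemble(n_frames = 2,
                          staple_cap = list(index_a = 6, index_b = 8,
                                            span = 5)),
    "infeasible")
})

test_that("stapling constrains distal pairs more than proximal ones", {
  free <- gen_unfolded_ensemble(n_frames = 80, seed = 12)
  pair_of <- function(i, j) data.frame(chain_a = "A", index_a = i,
                                       chain_b = "B", index_b = j)
  dcb_for <- function(i, j) {
    capped <- gen_unfolded_ensemble(
      n_frames = 80, seed = 12 + i,
      staple_cap = list(index_a = i, index_b = j, span = 14))
    delta_cb(summarize_series(cb_distance_series(capped, pair_of(i, j)),
                              t_start = 0),
             summarize_series(cb_distance_series(free, pair_of(i, j)),
                              t_start = 0))$delta
  }
  distal <- dcb_for(6, 8)
  proximal <- dcb_for(27, 29)
  expect_lt(distal, proximal)
  expect_lt(distal, 0)
})

test_that("design datasets follow their generating line exactly at zero noise", {
  recs <- gen_design_dataset(true_slope = 0.04,
                             true_intercepts = c(sb_eg = -0.9, nsb_eg = 0.1),
                             noise_sd = 0, n_per_class = 5, seed = 13)
  fit <- ddg_vs_dcb(recs, "by_class", "sim")
  expect_equal(fit$slope, rep(0.04, 2), tolerance = 1e-10)
  expect_equal(sort(fit$intercept), c(-0.9, 0.1), tolerance = 1e-10)
  expect_equal(attr(fit, "intercept_contrast"), -1.0, tolerance = 1e-10)
})

test_that("noisy design datasets recover the slope within two standard errors", {
  recs <- gen_design_dataset(true_slope = 0.04,
                             true_intercepts = c(sb_eg = -0.5),
                             noise_sd = 0.1, n_per_class = 20, seed = 14)
  fit <- ddg_vs_dcb(recs, "pooled", "sim")
  expect_lt(abs(fit$slope - 0.04), 2 * fit$se_slope)
  # an injected intercept gap of 1 kcal/mol is detected by the class fits
  gap <- gen_design_dataset(true_slope = 0.04,
                            true_intercepts = c(sb_eg = -1.2, nsb_eg = -0.2),
                            noise_sd = 0.05, n_per_class = 10, seed = 15)
  byc <- ddg_vs_dcb(gap, "by_class", "sim")
  expect_equal(attr(byc, "intercept_contrast"), -1.0, tolerance = 0.2)
})

test_that("an end-to-end synthetic pipeline recovers the generating site ranking", {
  # build folded + unfolded summaries for three e/g'-like candidates with
  # increasingly distal anchors, then rank them against a model fitted on
  # synthetic records
  free <- gen_unfolded_ensemble(n_frames = 60, seed = 16)
  folded <- gen_folded_ensemble(n_frames = 30, jitter_sd = 0.2, seed = 16)
  sites <- data.frame(chain_a = "A", index_a = c(6, 20, 27),
                      chain_b = "B", index_b = c(8, 22, 29))
  cands <- purrr::map_dfr(seq_len(3), function(i) {
    tibble::tibble(
      index_a = sites$index_a[i], index_b = sites$index_b[i],
      pair_class = "nsb_eg",
      folded_mean = summarize_series(
        cb_distance_series(folded, sites[i, ]), t_start = 0)$mean,
      unfolded_mean = summarize_series(
        cb_distance_series(free, sites[i, ]), t_start = 0)$mean
    )
  })
  recs <- gen_design_dataset(true_slope = 0.045,
                             true_intercepts = c(nsb_eg = -0.1),
                             noise_sd = 0, n_per_class = 5, seed = 17)
  model <- fit_linear(recs$dcb, recs$ddg_sim)
  rec <- recommend_sites(cands, "x4x", model)
  # the generating law ranks the most distal (widest unfolded) site first
  expect_equal(rec$index_a[order(rec$rank)], c(6, 20, 27))
})
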