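test_that("staple span constants are ordered relaxed <= effective <= extended", {
  specs <- dplyr::filter(staple_specs(), !is.na(span_effective))
  expect_true(all(specs$span_relaxed <= specs$span_effective))
  expect_true(all(specs$span_effective <= specs$span_extended))
})

test_that("folded-state compatibility uses the effective span with a marginal band", {
  expect_equal(classify_compatibility(9.86, "x4x"), "compatible")
  expect_equal(classify_compatibility(16.2, "x4x"), "incompatible")
  # boundary: exactly the span is still compatible
  span <- staple_specs()$span_effective[staple_specs()$name == "x4x"]
  expect_equal(classify_compatibility(span, "x4x"), "compatible")
  expect_equal(classify_compatibility(span * 1.05, "x4x"), "marginal")
  expect_equal(classify_compatibility(span * 1.11, "x4x"), "incompatible")
  # the native f/b' range sits beyond x4x's reach
  expect_equal(classify_compatibility(c(16.03, 16.34), "x4x"),
               rep("incompatible", 2))
  expect_error(classify_compatibility(10, "z2x"), "no effective span")
  expect_error(classify_compatibility(10, "q9q"), "unknown staple")
})

test_that("the line fit matches the closed-form normal equations", {
  f <- fit_linear(1:6, 2 * (1:6) + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)

  # independent oracle: normal equations written out
  withr::with_seed(31, {
    x <- rnorm(40); y <- 3 - 0.7 * x + rnorm(40, sd = 0.5)
  })
  f2 <- fit_linear(x, y)
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ic <- mean(y) - sl * mean(x)
  r2 <- 1 - sum((y - ic - sl * x)^2) / sum((y - mean(y))^2)
  expect_equal(f2$slope, sl, tolerance = 1e-10)
  expect_equal(f2$intercept, ic, tolerance = 1e-10)
  expect_equal(f2$r_squared, r2, tolerance = 1e-10)

  # permuted responses carry no signal
  yp <- withr::with_seed(32, sample(y))
  expect_lt(fit_linear(x, yp)$r_squared, 0.15)

  expect_error(fit_linear(1:2, 1:2), "at least 3")
  expect_error(fit_linear(rep(1, 5), 1:5), "zero variance")
  expect_error(fit_linear(c(1, 2, NA), 1:3), "finite")
})

test_that("pooled stabilization models reproduce the reference fits", {
  st <- table1_stapled()
  sim <- ddg_vs_dcb(st, "pooled", "sim")
  obs <- ddg_vs_dcb(st, "pooled", "obs")
  expect_equal(sim$n, 11)  # e/g' sites only; f/b' never enter
  expect_equal(sim$r_squared, 0.89, tolerance = 0.01 / 0.89)
  expect_equal(obs$r_squared, 0.53, tolerance = 0.01 / 0.53)
  # more unfolded-state constraint (more negative dcb), more stabilization
  expect_gt(sim$slope, 0)
  expect_gt(obs$slope, 0)
})

test_that("class-specific intercepts separate on observed but not simulated data", {
  st <- table1_stapled()
  sim <- ddg_vs_dcb(st, "by_class", "sim")
  obs <- ddg_vs_dcb(st, "by_class", "obs")
  expect_setequal(sim$pair_class, c("sb_eg", "nsb_eg"))
  sim_gap <- abs(attr(sim, "intercept_contrast"))
  obs_gap <- abs(attr(obs, "intercept_contrast"))
  sim_pooled_sd <- ddg_vs_dcb(st, "pooled", "sim")$sigma
  obs_pooled_sd <- ddg_vs_dcb(st, "pooled", "obs")$sigma
  expect_lt(sim_gap, sim_pooled_sd)   # one line fits both classes
  expect_gt(obs_gap, obs_pooled_sd)   # markedly different intercepts
})

test_that("stabilization grows with sequence separation", {
  st <- table1_stapled()
  eg <- dplyr::filter(st, pair_class != "fb")
  eg$loop_length <- loop_length("A", eg$index_a, "B", eg$index_b)
  f <- ddg_vs_separation(eg, "obs")
  expect_lt(f$slope, 0)
  const <- eg; const$loop_length <- 11
  expect_error(ddg_vs_separation(const, "obs"), "zero variance")
})

test_that("separation fits recover a known linear law from synthetic records", {
  recs <- gen_design_dataset(true_slope = 0.05,
                             true_intercepts = c(sb_eg = -0.5),
                             noise_sd = 0.1, n_per_class = 20, seed = 41)
  recs$loop_length <- -recs$dcb  # separation proxy proportional to constraint
  f <- ddg_vs_separation(recs, "sim")
  expect_lt(abs(f$slope - (-0.05)), 2 * f$se_slope)
})

test_that("matched-pair contrasts reproduce the reference values", {
  st <- table1_stapled()
  obs <- staple_contrast(st, "x4x_vs_z4x", "obs")
  expect_equal(obs$n_pairs, 2)  # the two dual-staple 27e sites
  expect_equal(obs$mean_diff, -0.25, tolerance = 0.005 / 0.25)
  sim <- staple_contrast(st, "x4x_vs_z4x", "sim")
  expect_equal(sim$mean_diff, -0.07, tolerance = 1e-9)
  sbnsb <- staple_contrast(st, "sb_vs_nsb", "sim")
  expect_equal(sbnsb$n_pairs, 5)  # heptads 6, 13, 20 + both 27e staples
  expect_equal(sbnsb$mean_diff, -0.28, tolerance = 0.005 / 0.28)
  # identical records difference to zero
  dup <- st[st$variant_id == "s27e/29g'-z4x", ]
  dup2 <- dup; dup2$staple <- "x4x"
  expect_equal(staple_contrast(rbind(dup, dup2), "x4x_vs_z4x",
                               "obs")$mean_diff, 0)
})

test_that("site recommendation filters by compatibility and ranks by predicted ddG", {
  tab <- load_table1()
  ns <- dplyr::filter(tab, !stapled)
  # deduplicate sites measured with both staple precursors
  cands <- ns |>
    dplyr::group_by(index_a, index_b, pair_class) |>
    dplyr::summarise(folded_mean = mean(cb310), unfolded_mean = mean(cb450),
                     .groups = "drop")
  model <- ddg_vs_dcb(table1_stapled(), "pooled", "sim")
  rec <- recommend_sites(cands, "x4x", model)
  expect_true(all(rec$verdict[rec$pair_class == "fb"] == "incompatible"))
  expect_true(all(rec$note[rec$pair_class == "fb"] == "predicted destabilizing"))
  ranked <- dplyr::filter(rec, !is.na(rank)) |> dplyr::arrange(rank)
  top2 <- paste(ranked$index_a[1:2], ranked$index_b[1:2])
  expect_setequal(top2, c("6 1", "6 8"))
  prox <- paste(ranked$index_a, ranked$index_b)
  expect_true(which(prox == "6 8") < which(prox == "27 29"))
  expect_true(which(prox == "6 8") < which(prox == "34 29"))
  # never rank an incompatible site above a compatible one
  expect_true(all(is.na(rec$rank[rec$verdict == "incompatible"])))
})

test_that("recommendation recovers the generating order and handles edge cases", {
  recs <- gen_design_dataset(true_slope = 0.045,
                             true_intercepts = c(nsb_eg = -0.1),
                             noise_sd = 0, n_per_class = 6, seed = 51)
  span <- staple_specs()$span_effective[staple_specs()$name == "x4x"]
  cands <- tibble::tibble(
    pair_class = recs$pair_class,
    folded_mean = 10,
    unfolded_mean = span - recs$dcb
  )
  model <- fit_linear(recs$dcb, recs$ddg_sim)
  rec <- recommend_sites(cands, "x4x", model)
  expect_equal(rec$dcb_pred[order(rec$rank)],
               sort(recs$dcb))  # most negative constraint ranks first
  # single compatible candidate ranks first
  one <- recommend_sites(tibble::tibble(folded_mean = 10, unfolded_mean = 30),
                         "x4x", model)
  expect_equal(one$rank, 1L)
  # no compatible site: empty ranking plus diagnostic
  expect_warning(
    none <- recommend_sites(tibble::tibble(folded_mean = 17,
                                           unfolded_mean = 30), "x4x", model),
    "no candidate is compatible"
  )
  expect_true(all(is.na(none$rank)))
})
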