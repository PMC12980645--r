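# Seeded generators with known ground truth: two-state melt curves, an
# idealized folded coiled-coil ensemble, a tethered random-coil unfolded
# ensemble, and linear-law design datasets.  These emulate the statistical
# structure of the real measurements (sigmoidal melts with linear baselines;
# heptad-correct folded anchor spacings; unfolded anchor separations that
# grow with loop length and saturate at a staple's span) -- they make no
# claim of physical realism beyond that.

#' Generate a synthetic two-state melt curve
#'
#' Signal from the two-state model of [fit_two_state()] plus i.i.d. Gaussian
#' noise; bit-reproducible given `seed`.
#'
#' @param tm Midpoint, K.
#' @param dh van't Hoff enthalpy at `tm`, kcal/mol.
#' @param dcp Heat capacity increment, kcal/mol/K.
#' @param t_grid Temperature grid, K.
#' @param bf,bu Folded/unfolded baseline `c(intercept, slope)` in signal
#'   units; defaults give a CD-like transition amplitude of ~20 units.
#' @param noise_sd Noise standard deviation, signal units.
#' @param seed Seed.
#' @param variant_id Label attached to the curve.
#' @return Tibble `temperature` (K), `signal`, with the generator parameters
#'   in attribute `"params"`.
#' @export
gen_melt <- function(tm, dh, dcp = 0, t_grid = seq(280, 380, by = 1),
                     bf = c(-28, 0.02), bu = c(-12, 0.02),
                     noise_sd = 0, seed = 1, variant_id = "synthetic") {
  stopifnot(noise_sd >= 0, tm >= min(t_grid), tm <= max(t_grid))
  y <- two_state_signal(t_grid, tm, dh, dcp, bf[1], bf[2], bu[1], bu[2])
  if (noise_sd > 0) {
    y <- y + withr::with_seed(seed, rnorm(length(t_grid), sd = noise_sd))
  }
  out <- tibble(temperature = t_grid, signal = y)
  attr(out, "variant_id") <- variant_id
  attr(out, "params") <- list(tm = tm, dh = dh, dcp = dcp, bf = bf, bu = bu,
                              noise_sd = noise_sd, seed = seed)
  out
}

# ---- idealized folded coiled coil ------------------------------------------

# CA/CB coordinates of an idealized parallel two-helix dimer.  Both helices
# run along z with 1.5 A rise per residue and exactly 3.5 residues per turn
# (so the register repeats every 7 residues), helix radius `r`.  CB sits
# 1.53 A radially outward of CA.  Free parameters: axis separation `d`, the
# two helical phases, and an axial offset of chain B.
cc_geometry <- function(n_res, d, phi_a, phi_b, z_off, r = 2.26,
                        rise = 1.5, cb_len = 1.53) {
  dphi <- 2 * pi * 2 / 7  # 102.857 deg per residue
  one_chain <- function(x0, phi0, z0, sgn) {
    i <- seq_len(n_res)
    th <- phi0 + (i - 1) * dphi * sgn
    ca <- cbind(x0 + r * cos(th), r * sin(th), z0 + (i - 1) * rise)
    cb <- cbind(x0 + (r + cb_len) * cos(th), (r + cb_len) * sin(th),
                z0 + (i - 1) * rise)
    list(ca = ca, cb = cb)
  }
  a <- one_chain(-d / 2, phi_a, 0, 1)
  b <- one_chain(d / 2, phi_b, z_off, 1)
  list(A = a, B = b)
}

class_pairs_for <- function(register_a, register_b) {
  pairs <- enumerate_anchor_pairs(register_a, register_b,
                                  crosslinks = tibble(
                                    chain_1 = character(), index_1 = integer(),
                                    chain_2 = character(), index_2 = integer(),
                                    kind = character())[0, ])
  pairs
}

geometry_class_means <- function(geom, pairs) {
  d <- sqrt(rowSums((geom$A$cb[pairs$index_a, , drop = FALSE] -
                       geom$B$cb[pairs$index_b, , drop = FALSE])^2))
  tapply(d, pairs$pair_class, mean)
}

tune_cc_geometry <- function(n_res, register_a, register_b, targets,
                             tol = 0.5) {
  pairs <- enumerate_anchor_pairs(
    register_a, register_b,
    crosslinks = tibble(chain_1 = "A", index_1 = n_res - 1L,
                        chain_2 = "B", index_2 = n_res - 1L,
                        kind = "disulfide")
  )
  pairs <- filter(pairs, .data$pair_class %in% names(targets))
  objective <- function(p) {
    geom <- cc_geometry(n_res, p[1], p[2], p[3], p[4])
    m <- geometry_class_means(geom, pairs)
    sum((m[names(targets)] - targets)^2)
  }
  starts <- tidyr::expand_grid(d = c(8, 9.5, 11),
                               phi_a = seq(0, 2 * pi, length.out = 5)[-5],
                               phi_b = seq(0, 2 * pi, length.out = 5)[-5])
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- optim(c(starts$d[k], starts$phi_a[k], starts$phi_b[k], 0),
                 objective, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$value < 1e-8) break
  }
  geom <- cc_geometry(n_res, best$par[1], best$par[2], best$par[3],
                      best$par[4])
  means <- geometry_class_means(geom, pairs)
  err <- abs(means[names(targets)] - targets)
  if (any(err > tol)) {
    abort(paste0(
      "unreachable spacing targets: best idealized geometry gives ",
      paste(sprintf("%s = %.2f (target %.2f)", names(targets),
                    means[names(targets)], targets), collapse = ", ")))
  }
  list(par = best$par, geom = geom, means = means, pairs = pairs)
}

#' Generate a synthetic folded coiled-coil ensemble
#'
#' Builds an idealized parallel in-register two-helix dimer (1.5 Angstrom
#' rise per residue, exactly 3.5 residues per turn so the heptad repeats
#' geometrically, CB atoms 1.53 Angstrom radially outward of CA) whose axis
#' separation, helical phases and axial offset are tuned numerically so the
#' class-mean e/g' and f/b' anchor spacings hit the configured targets; it
#' errors if any class mean cannot be brought within `target_tol` of its
#' target.  Frames add isotropic per-coordinate Gaussian jitter of sd
#' `jitter_sd` (so a jitter-free ensemble has zero spacing variance, and the
#' per-atom RMSF of a jittered one is `jitter_sd * sqrt(3)` up to sampling
#' error).
#'
#' Default spacing targets are the folded-temperature class means of the
#' A/B reference table: salt-bridged e/g' 9.9, non-salt-bridged e/g' 10.9,
#' f/b' 16.1 Angstrom.
#'
#' @param n_res Residues per chain.
#' @param first_register Register letter of residue 1 (both chains).
#' @param targets Named class targets (Angstrom) for any of `sb_eg`,
#'   `nsb_eg`, `fb`.
#' @param jitter_sd Per-coordinate Gaussian jitter, Angstrom.
#' @param n_frames Number of frames.
#' @param seed Seed.
#' @param temperature_label,variant_id Ensemble provenance tags.
#' @param target_tol Maximum allowed class-mean miss, Angstrom.
#' @return A [ensemble()] with CA and CB atoms on chains A and B.
#' @export
gen_folded_ensemble <- function(n_res = 34, first_register = "g",
                                targets = c(sb_eg = 9.9, nsb_eg = 10.9,
                                            fb = 16.1),
                                jitter_sd = 0.2, n_frames = 100, seed = 1,
                                temperature_label = 310,
                                variant_id = "synthetic-folded",
                                target_tol = 0.5) {
  stopifnot(n_frames >= 1, jitter_sd >= 0)
  reg_a <- assign_register(n_res, first_register, "A")
  reg_b <- assign_register(n_res, first_register, "B")
  tuned <- tune_cc_geometry(n_res, reg_a, reg_b, targets, tol = target_tol)
  base <- bind_rows(
    tibble(chain = "A", resid = seq_len(n_res), atom = "CA",
           x = tuned$geom$A$ca[, 1], y = tuned$geom$A$ca[, 2],
           z = tuned$geom$A$ca[, 3]),
    tibble(chain = "A", resid = seq_len(n_res), atom = "CB",
           x = tuned$geom$A$cb[, 1], y = tuned$geom$A$cb[, 2],
           z = tuned$geom$A$cb[, 3]),
    tibble(chain = "B", resid = seq_len(n_res), atom = "CA",
           x = tuned$geom$B$ca[, 1], y = tuned$geom$B$ca[, 2],
           z = tuned$geom$B$ca[, 3]),
    tibble(chain = "B", resid = seq_len(n_res), atom = "CB",
           x = tuned$geom$B$cb[, 1], y = tuned$geom$B$cb[, 2],
           z = tuned$geom$B$cb[, 3])
  )
  coords <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_frames), function(f) {
      d <- base
      if (jitter_sd > 0) {
        d$x <- d$x + rnorm(nrow(d), sd = jitter_sd)
        d$y <- d$y + rnorm(nrow(d), sd = jitter_sd)
        d$z <- d$z + rnorm(nrow(d), sd = jitter_sd)
      }
      d$frame <- f
      d
    })
  })
  out <- ensemble(coords, temperature_label = temperature_label,
                  variant_id = variant_id)
  attr(out, "geometry") <- list(par = tuned$par, class_means = tuned$means)
  out
}

# ---- tethered random-coil unfolded ensemble --------------------------------

random_unit <- function(n) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# CB direction at each CA: difference of the incoming and outgoing backbone
# unit vectors (an arbitrary perpendicular-ish local frame); chain ends use
# a vector perpendicular to their single bond.
place_cb <- function(ca, cb_len = 1.53) {
  n <- nrow(ca)
  dirs <- matrix(0, n, 3)
  bonds <- diff(ca)
  bonds <- bonds / sqrt(rowSums(bonds^2))
  perp <- function(u) {
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ref - sum(ref * u) * u
    v / sqrt(sum(v^2))
  }
  for (i in seq_len(n)) {
    if (i == 1) {
      dirs[i, ] <- perp(bonds[1, ])
    } else if (i == n) {
      dirs[i, ] <- perp(bonds[n - 1, ])
    } else {
      v <- bonds[i - 1, ] - bonds[i, ]
      if (sqrt(sum(v^2)) < 1e-8) v <- perp(bonds[i, ])
      dirs[i, ] <- v / sqrt(sum(v^2))
    }
  }
  ca + cb_len * dirs
}

# Grow a freely-jointed chain outward from its anchor residue, resampling
# each step's direction until the new CA clears `min_sep` from every CA
# placed so far (this chain and `obstacles`).  Returns NULL on a dead end so
# the caller can restart the chain.
grow_chain <- function(n_res, anchor_index, anchor_pos, step, min_sep,
                       obstacles = NULL, max_step_tries = 200) {
  pos <- matrix(NA_real_, n_res, 3)
  pos[anchor_index, ] <- anchor_pos
  placed <- rbind(obstacles, anchor_pos)
  order_up <- if (anchor_index < n_res) (anchor_index + 1):n_res else integer(0)
  order_dn <- if (anchor_index > 1) (anchor_index - 1):1 else integer(0)
  for (i in c(order_up, order_dn)) {
    prev <- pos[if (i > anchor_index) i - 1 else i + 1, ]
    ok <- FALSE
    for (try in seq_len(max_step_tries)) {
      cand <- prev + step * as.vector(random_unit(1))
      d2 <- (placed[, 1] - cand[1])^2 + (placed[, 2] - cand[2])^2 +
        (placed[, 3] - cand[3])^2
      # the bonded neighbour sits at exactly `step` >= min_sep, so no
      # exclusion is needed
      if (min(d2) >= min_sep^2) {
        ok <- TRUE
        break
      }
    }
    if (!ok) return(NULL)
    pos[i, ] <- cand
    placed <- rbind(placed, cand)
  }
  pos
}

#' Generate a synthetic unfolded-temperature ensemble
#'
#' Each chain is a freely-jointed random walk with a fixed 3.8 Angstrom
#' CA--CA step, grown outward from the tether residue; the two tether
#' residues are joined by one covalent step, emulating the C-terminal
#' disulfide that keeps the chains associated when unfolded.  Excluded
#' volume is enforced during growth: each step's direction is resampled
#' until the new CA clears `min_sep` from every CA already placed
#' (chain-growth Monte Carlo; a dead-ended chain is restarted).  When a
#' `staple_cap` is supplied, frames where the capped pair's CB--CB distance
#' exceeds the staple span are regenerated whole -- the covalent cap is
#' enforced exactly, by rejection.  CB atoms sit
#' 1.53 Angstrom off each CA along a local frame.  Anchor separations grow
#' with loop length (the random-walk sqrt-of-length law) exactly as the
#' unfolded-state constraint analysis requires; the model makes no other
#' physical claim.
#'
#' @param n_res Residues per chain.
#' @param tether `c(index_A, index_B)` of the covalent tether (default
#'   33--33').
#' @param staple_cap Optional `list(index_a=, index_b=, span=)`: cap the
#'   CB--CB distance of that cross-chain pair at `span` Angstrom.
#' @param n_frames Number of frames.
#' @param step CA--CA step length, Angstrom.
#' @param min_sep Excluded-volume cutoff for non-bonded CA pairs, Angstrom.
#' @param seed Seed.
#' @param temperature_label,variant_id Provenance tags.
#' @param max_tries Attempt cap per frame before giving up.
#' @return A [ensemble()] with CA and CB atoms on chains A and B.
#' @export
gen_unfolded_ensemble <- function(n_res = 34, tether = c(33, 33),
                                  staple_cap = NULL, n_frames = 100,
                                  step = 3.8, min_sep = 3.0, seed = 1,
                                  temperature_label = 450,
                                  variant_id = "synthetic-unfolded",
                                  max_tries = 50000) {
  stopifnot(n_frames >= 1, all(tether >= 1), all(tether <= n_res))
  if (!is.null(staple_cap)) {
    stopifnot(all(c("index_a", "index_b", "span") %in% names(staple_cap)))
    if (staple_cap$span < 2 * step) {
      abort("staple cap infeasible: span shorter than two chain steps")
    }
  }
  gen_frame <- function() {
    repeat {
      ca_a <- grow_chain(n_res, tether[1], c(0, 0, 0), step, min_sep)
      if (is.null(ca_a)) next
      anchor_b <- step * as.vector(random_unit(1))
      d2 <- (ca_a[, 1] - anchor_b[1])^2 + (ca_a[, 2] - anchor_b[2])^2 +
        (ca_a[, 3] - anchor_b[3])^2
      d2[tether[1]] <- Inf  # the tether link itself is a bond
      if (min(d2) < min_sep^2) next
      ca_b <- grow_chain(n_res, tether[2], anchor_b, step, min_sep,
                         obstacles = ca_a)
      if (is.null(ca_b)) next
      cb_a <- place_cb(ca_a)
      cb_b <- place_cb(ca_b)
      if (!is.null(staple_cap)) {
        d <- sqrt(sum((cb_a[staple_cap$index_a, ] -
                         cb_b[staple_cap$index_b, ])^2))
        if (d > staple_cap$span) next
      }
      return(list(ca_a = ca_a, cb_a = cb_a, ca_b = ca_b, cb_b = cb_b))
    }
  }
  coords <- withr::with_seed(seed, {
    frames <- vector("list", n_frames)
    tries <- 0L
    f <- 1L
    while (f <= n_frames) {
      tries <- tries + 1L
      if (tries > max_tries) {
        abort("frame rejection rate too high; relax the cap or excluded volume")
      }
      frames[[f]] <- gen_frame()
      f <- f + 1L
    }
    purrr::imap_dfr(frames, function(fr, i) {
      bind_rows(
        tibble(chain = "A", resid = seq_len(n_res), atom = "CA",
               x = fr$ca_a[, 1], y = fr$ca_a[, 2], z = fr$ca_a[, 3]),
        tibble(chain = "A", resid = seq_len(n_res), atom = "CB",
               x = fr$cb_a[, 1], y = fr$cb_a[, 2], z = fr$cb_a[, 3]),
        tibble(chain = "B", resid = seq_len(n_res), atom = "CA",
               x = fr$ca_b[, 1], y = fr$ca_b[, 2], z = fr$ca_b[, 3]),
        tibble(chain = "B", resid = seq_len(n_res), atom = "CB",
               x = fr$cb_b[, 1], y = fr$cb_b[, 2], z = fr$cb_b[, 3])
      ) |> mutate(frame = i)
    })
  })
  ensemble(coords, temperature_label = temperature_label,
           variant_id = variant_id)
}

#' Generate site records from a known linear stabilization law
#'
#' `ddG = intercept[class] + slope * dcb + noise`, for regression- and
#' ranking-recovery tests with exact ground truth.  The same generated value
#' is placed in both `ddg_obs` and `ddg_sim` (the generator does not model a
#' measurement-modality difference).
#'
#' @param true_slope Slope, kcal/mol per Angstrom.
#' @param true_intercepts Named intercepts per class, kcal/mol, e.g.
#'   `c(sb_eg = -0.8, nsb_eg = -0.2)`.
#' @param noise_sd Gaussian noise sd, kcal/mol.
#' @param sites Tibble with `pair_class` and `dcb` columns (optionally
#'   `loop_length`); if `NULL`, `n_per_class` sites per class with `dcb`
#'   drawn uniformly on (-50, -3).
#' @param n_per_class Used when `sites` is `NULL`.
#' @param seed Seed.
#' @return Site-record tibble: `pair_class`, `dcb`, `ddg_obs`, `ddg_sim`,
#'   `ddg_true`, plus any extra `sites` columns.
#' @export
gen_design_dataset <- function(true_slope, true_intercepts, noise_sd = 0,
                               sites = NULL, n_per_class = 5, seed = 1) {
  withr::with_seed(seed, {
    if (is.null(sites)) {
      sites <- tidyr::expand_grid(pair_class = names(true_intercepts),
                                  i = seq_len(n_per_class)) |>
        mutate(dcb = runif(n(), -50, -3)) |>
        select(-"i")
    }
    stopifnot(all(sites$pair_class %in% names(true_intercepts)))
    ddg_true <- true_intercepts[sites$pair_class] + true_slope * sites$dcb
    noise <- if (noise_sd > 0) rnorm(nrow(sites), sd = noise_sd) else 0
    mutate(as_tibble(sites),
           ddg_true = unname(ddg_true),
           ddg_obs = .data$ddg_true + noise,
           ddg_sim = .data$ddg_obs)
  })
}
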