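# Conformational ensembles are long coordinate tibbles: one row per atom per
# frame, columns frame / chain / resid / atom / x / y / z (Angstrom), with
# the temperature label, variant id and frame timing carried as attributes.

#' Build a conformational ensemble
#'
#' Validates a long coordinate table (one row per atom per frame) and tags it
#' with its provenance.  Every frame must share one atom table and all
#' coordinates must be finite.  Frame times may be supplied explicitly; if
#' absent they default to uniform spacing over `total_time_ns` (so the usual
#' 40 ns equilibration cutoff removes the first 2% of a default 2000 ns
#' trajectory, applied by frame fraction).
#'
#' @param coords Data frame with columns `frame`, `chain`, `resid`, `atom`,
#'   `x`, `y`, `z`.
#' @param temperature_label Temperature of the ensemble, K (e.g. 310 for the
#'   folded-temperature ensemble, 450 for the unfolded one).
#' @param variant_id Variant label.
#' @param frame_times Optional numeric vector of frame times (ns), one per
#'   frame.
#' @param total_time_ns Trajectory span used when `frame_times` is absent.
#' @return The validated tibble, classed `cc_ensemble`.
#' @export
ensemble <- function(coords, temperature_label = NA_real_,
                     variant_id = NA_character_, frame_times = NULL,
                     total_time_ns = 2000) {
  need <- c("frame", "chain", "resid", "atom", "x", "y", "z")
  stopifnot(all(need %in% names(coords)))
  coords <- as_tibble(coords)
  if (!all(is.finite(coords$x) & is.finite(coords$y) & is.finite(coords$z))) {
    abort("ensemble coordinates must be finite")
  }
  frames <- sort(unique(coords$frame))
  key <- function(f) {
    d <- coords[coords$frame == f, c("chain", "resid", "atom")]
    paste(d$chain, d$resid, d$atom, collapse = ";")
  }
  k1 <- key(frames[1])
  same <- vapply(frames[-1], function(f) identical(key(f), k1), logical(1))
  if (!all(same)) abort("all frames must share one atom table")
  if (!is.null(frame_times) && length(frame_times) != length(frames)) {
    abort("`frame_times` must have one entry per frame")
  }
  structure(
    arrange(coords, .data$frame),
    class = c("cc_ensemble", class(coords)),
    temperature_label = temperature_label,
    variant_id = variant_id,
    frame_times = frame_times,
    total_time_ns = total_time_ns
  )
}

n_frames <- function(ens) length(unique(ens$frame))

frame_times <- function(ens) {
  ft <- attr(ens, "frame_times")
  nf <- n_frames(ens)
  if (!is.null(ft)) return(ft)
  total <- attr(ens, "total_time_ns") %||% 2000
  if (nf == 1) return(0)
  seq(0, total, length.out = nf)
}

#' Per-frame Cbeta--Cbeta distance of an anchor pair
#'
#' The side-chain beta-carbon distance of the two anchor residues is the
#' working measure of anchor spacing: in a folded-temperature ensemble it is
#' the folded-state spacing a staple must reach across, in an
#' unfolded-temperature ensemble of a stapled variant it approaches the
#' staple's accessible span.  A residue without a CB atom (glycine) is a hard
#' error naming the residue -- the descriptor is defined on CB and no silent
#' CA fallback is attempted.
#'
#' @param ens A [ensemble()].
#' @param pair One-row data frame with `chain_a`, `index_a`, `chain_b`,
#'   `index_b` (e.g. a row of [enumerate_anchor_pairs()]).
#' @return Tibble with one row per frame: `frame`, `time_ns`, `distance`
#'   (Angstrom), carrying the pair and the ensemble's temperature label as
#'   attributes.
#' @export
cb_distance_series <- function(ens, pair) {
  stopifnot(inherits(ens, "cc_ensemble"),
            all(c("chain_a", "index_a", "chain_b", "index_b") %in% names(pair)))
  pick <- function(chain, resid) {
    d <- ens[ens$chain == chain & ens$resid == resid & ens$atom == "CB", ]
    if (nrow(d) != n_frames(ens)) {
      abort(sprintf("residue %s%d has no CB atom in every frame", chain, resid))
    }
    arrange(d, .data$frame)
  }
  a <- pick(pair$chain_a[1], pair$index_a[1])
  b <- pick(pair$chain_b[1], pair$index_b[1])
  out <- tibble(
    frame = a$frame,
    time_ns = frame_times(ens),
    distance = sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  )
  attr(out, "pair") <- as_tibble(pair)[1, ]
  attr(out, "temperature_label") <- attr(ens, "temperature_label")
  attr(out, "variant_id") <- attr(ens, "variant_id")
  attr(out, "atom_kind") <- "CB"
  out
}

#' Equilibrated summary of a distance series
#'
#' Mean, standard deviation and standard error of the anchor spacing over the
#' frames inside `[t_start, t_end]`.  The default 40 ns start discards the
#' equilibration leg of a trajectory.
#'
#' @param series A [cb_distance_series()] result.
#' @param t_start,t_end Averaging window, ns.
#' @return One-row tibble: pair columns (when known), `temperature_label`,
#'   `variant_id`, `mean`, `sd`, `sem`, `n_frames_used`,
#'   `equilibration_cutoff`.
#' @export
summarize_series <- function(series, t_start = 40, t_end = Inf) {
  stopifnot(all(c("time_ns", "distance") %in% names(series)))
  used <- series$distance[series$time_ns >= t_start & series$time_ns <= t_end]
  if (length(used) < 2) abort("averaging window contains fewer than 2 frames")
  pair <- attr(series, "pair")
  base <- if (!is.null(pair)) {
    pair[, intersect(c("chain_a", "index_a", "chain_b", "index_b", "pair_class"),
                     names(pair))]
  } else {
    tibble(.rows = 1)
  }
  bind_cols(base, tibble(
    temperature_label = attr(series, "temperature_label") %||% NA_real_,
    variant_id = attr(series, "variant_id") %||% NA_character_,
    mean = mean(used),
    sd = sd(used),
    sem = sd(used) / sqrt(length(used)),
    n_frames_used = length(used),
    equilibration_cutoff = t_start
  ))
}

#' Centered moving-window mean
#'
#' Smooths a distance series with a centered moving average; the default
#' window of 50 points is widened to 51 so the window is symmetric about each
#' point, and windows are truncated at the edges.
#'
#' @param series Numeric vector, or a [cb_distance_series()] tibble (its
#'   `distance` column is used).
#' @param window Window size in frames; even values are increased by one.
#' @return Numeric vector the same length as the input.
#' @export
moving_window_mean <- function(series, window = 50) {
  x <- if (is.data.frame(series)) series$distance else series
  stopifnot(is.numeric(x))
  if (window < 1) abort("`window` must be >= 1")
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (window > length(x)) abort("`window` exceeds the series length")
  as.numeric(zoo::rollapply(x, width = window, FUN = mean,
                            align = "center", partial = TRUE))
}

#' Unfolded-state constraint of a staple
#'
#' The stapled-minus-non-stapled difference in mean anchor spacing at the
#' unfolded temperature.  Stapling collapses the wide unfolded-state spacing
#' of a distal pair down to the staple's span, so more negative values mean
#' more unfolded-ensemble freedom removed, hence (for a compatible staple)
#' more stabilization.
#'
#' @param stapled,nonstapled One-row summaries from [summarize_series()] for
#'   the same anchor pair at the same temperature.
#' @return One-row tibble: `delta` (Angstrom) and its propagated `se`.
#' @export
delta_cb <- function(stapled, nonstapled) {
  for (col in c("index_a", "index_b", "temperature_label")) {
    if (col %in% names(stapled) && col %in% names(nonstapled) &&
        !isTRUE(all.equal(stapled[[col]][1], nonstapled[[col]][1]))) {
      abort(sprintf("summaries disagree on `%s`; compare like with like", col))
    }
  }
  tibble(delta = stapled$mean[1] - nonstapled$mean[1],
         se = sqrt(stapled$sem[1]^2 + nonstapled$sem[1]^2))
}

#' Effective staple span from unfolded-temperature ensembles
#'
#' In the unfolded-temperature ensemble of a stapled variant the chain pulls
#' the staple taut from both ends, so the mean anchor spacing of the stapled
#' pair estimates the staple's maximum realistic reach.  Averaging those
#' means over variants sharing a staple chemistry gives its effective span.
#'
#' @param summaries Tibble of [summarize_series()] rows (one or more) for
#'   stapled variants of one staple chemistry at the unfolded temperature.
#' @return One-row tibble: `span_effective`, `span_min`, `span_max`, `n`.
#' @export
staple_span_estimate <- function(summaries) {
  if (is.null(summaries) || nrow(summaries) == 0) {
    abort("need at least one unfolded-temperature summary")
  }
  tibble(span_effective = mean(summaries$mean),
         span_min = min(summaries$mean),
         span_max = max(summaries$mean),
         n = nrow(summaries))
}

# ---- multi-model PDB I/O (bio3d) -------------------------------------------

#' Read an ensemble from a multi-model PDB file
#'
#' Standard MODEL/ENDMDL records become frames (1-based).
#'
#' @param path PDB file.
#' @inheritParams ensemble
#' @return A [ensemble()].
#' @export
read_ensemble_pdb <- function(path, temperature_label = NA_real_,
                              variant_id = NA_character_,
                              frame_times = NULL, total_time_ns = 2000) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nfr <- nrow(xyz)
  nat <- nrow(pdb$atom)
  coords <- tibble(
    frame = rep(seq_len(nfr), each = nat),
    chain = rep(pdb$atom$chain, nfr),
    resid = rep(as.integer(pdb$atom$resno), nfr),
    atom = rep(pdb$atom$elety, nfr),
    x = as.vector(t(xyz[, seq(1, 3 * nat, by = 3), drop = FALSE])),
    y = as.vector(t(xyz[, seq(2, 3 * nat, by = 3), drop = FALSE])),
    z = as.vector(t(xyz[, seq(3, 3 * nat, by = 3), drop = FALSE]))
  )
  ensemble(coords, temperature_label = temperature_label,
           variant_id = variant_id, frame_times = frame_times,
           total_time_ns = total_time_ns)
}

#' Write an ensemble to a multi-model PDB file
#'
#' @param ens A [ensemble()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ens, path) {
  stopifnot(inherits(ens, "cc_ensemble"))
  frames <- sort(unique(ens$frame))
  first <- ens[ens$frame == frames[1], ]
  xyz <- t(vapply(frames, function(f) {
    d <- ens[ens$frame == f, ]
    as.vector(rbind(d$x, d$y, d$z))
  }, numeric(3 * nrow(first))))
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    type = rep("ATOM", nrow(first)),
    resno = first$resid,
    chain = first$chain,
    resid = rep("ALA", nrow(first)),
    elety = first$atom
  )
  invisible(path)
}

#' Cbeta--Cbeta distance of a residue pair in a PDB structure
#'
#' Convenience for measuring native anchor spacing in a crystal structure
#' (e.g. the 7f/10b' spacing in the A/B entry 1kd9).  Uses the first model
#' and the first altloc of each CB atom.
#'
#' @param path PDB file.
#' @param chain_a,resid_a,chain_b,resid_b The two residues.
#' @return Distance in Angstrom.
#' @export
cb_distance_pdb <- function(path, chain_a, resid_a, chain_b, resid_b) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  pick <- function(chain, resid) {
    d <- at[at$chain == chain & at$resno == resid & at$elety == "CB", ,
            drop = FALSE]
    if (nrow(d) == 0) {
      abort(sprintf("residue %s%d has no CB atom", chain, resid))
    }
    unlist(d[1, c("x", "y", "z")])
  }
  a <- pick(chain_a, resid_a)
  b <- pick(chain_b, resid_b)
  sqrt(sum((a - b)^2))
}

#' Fig-2 style view of a distance series
#'
#' Raw per-frame distances, the centered moving-window mean, and the
#' equilibrated trajectory mean with a +/- 1 sd band.
#'
#' @param series A [cb_distance_series()] result.
#' @param window Moving-window size (frames).
#' @param t_start Equilibration cutoff (ns) for the trajectory mean.
#' @return A ggplot.
#' @export
plot_distance_series <- function(series, window = 50, t_start = 40) {
  sm <- summarize_series(series, t_start = t_start)
  series$smooth <- moving_window_mean(series, window)
  ggplot2::ggplot(series, ggplot2::aes(x = .data$time_ns)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$distance), colour = "grey60",
                       linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smooth), colour = "#e69f00") +
    ggplot2::geom_hline(yintercept = sm$mean, colour = "#0072b2") +
    ggplot2::geom_hline(yintercept = sm$mean + c(-1, 1) * sm$sd,
                        colour = "#0072b2", linetype = 3) +
    ggplot2::labs(x = "time (ns)", y = "CB-CB distance (Å)")
}
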