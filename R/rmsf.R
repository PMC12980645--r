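# Per-atom fluctuation maps: iterated least-squares superposition onto the
# ensemble mean structure, then RMSF about the mean position.

# Least-squares (Kabsch) superposition of n x 3 matrix `mobile` onto `ref`
# using the rows indexed by `on`; returns the transformed full matrix.
kabsch_fit <- function(mobile, ref, on = seq_len(nrow(mobile))) {
  if (length(on) < 3) abort("alignment selection needs at least 3 atoms")
  cm <- colMeans(mobile[on, , drop = FALSE])
  cr <- colMeans(ref[on, , drop = FALSE])
  p <- sweep(mobile[on, , drop = FALSE], 2, cm)
  q <- sweep(ref[on, , drop = FALSE], 2, cr)
  s <- svd(crossprod(p, q))
  if (min(s$d) < 1e-10 && s$d[2] < 1e-8) {
    abort("degenerate alignment selection (collinear atoms)")
  }
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(sweep(mobile, 2, cm) %*% rot, 2, cr, `+`)
}

#' Per-atom root-mean-square fluctuation of an ensemble
#'
#' Each frame after the equilibration cutoff is superposed onto the ensemble
#' mean structure by optimal rigid-body rotation/translation over the
#' alignment selection, iterating align -> mean -> realign until the mean
#' structure moves by less than `tol`.  The RMSF of an atom is the root mean
#' squared deviation of its position from its mean position.  Staple/linker
#' atoms, present only in stapled variants, should be excluded from the
#' alignment selection (the default backbone selection does this
#' automatically when linker atoms carry non-backbone names).
#'
#' @param ens A [ensemble()].
#' @param align_on Atom names used for the superposition; defaults to the
#'   backbone names among `N`, `CA`, `C`, `O` present in the ensemble.
#' @param t_start Equilibration cutoff, ns.
#' @param tol Convergence tolerance on the mean structure, Angstrom.
#' @param max_iter Iteration cap.
#' @return Tibble with one row per atom: `chain`, `resid`, `atom`, `rmsf`
#'   (Angstrom).
#' @export
rmsf <- function(ens, align_on = NULL, t_start = 40, tol = 1e-6,
                 max_iter = 100) {
  stopifnot(inherits(ens, "cc_ensemble"))
  frames <- sort(unique(ens$frame))
  keep <- frames[frame_times(ens) >= t_start]
  if (length(keep) < 2) abort("need at least 2 frames after the cutoff")
  atoms <- ens[ens$frame == keep[1], c("chain", "resid", "atom")]
  if (is.null(align_on)) {
    align_on <- intersect(c("N", "CA", "C", "O"), unique(atoms$atom))
    if (length(align_on) == 0) {
      abort("no backbone atoms found; supply `align_on`")
    }
  }
  sel <- which(atoms$atom %in% align_on)
  if (length(sel) < 3) abort("alignment selection has fewer than 3 atoms")

  mats <- lapply(keep, function(f) {
    d <- ens[ens$frame == f, ]
    cbind(d$x, d$y, d$z)
  })
  ref <- mats[[1]]
  for (iter in seq_len(max_iter)) {
    mats <- lapply(mats, kabsch_fit, ref = ref, on = sel)
    m <- Reduce(`+`, mats) / length(mats)
    if (max(abs(m - ref)) < tol) {
      ref <- m
      break
    }
    ref <- m
  }
  sq <- Reduce(`+`, lapply(mats, function(x) (x - ref)^2)) / length(mats)
  tibble(chain = atoms$chain, resid = atoms$resid, atom = atoms$atom,
         rmsf = sqrt(rowSums(sq)))
}

#' Stapled-minus-non-stapled fluctuation difference map
#'
#' Joins two RMSF maps atom-by-atom and classifies each difference on the
#' +/- `threshold` scale used for distortion maps: `increased` at or above
#' `+threshold`, `decreased` at or below `-threshold`, `unchanged` between.
#' Atoms present in only one variant (e.g. the bis-azido linker of an x4x
#' staple, absent from the non-stapled variant) are flagged `uncomparable`.
#'
#' @param stapled,nonstapled RMSF maps from [rmsf()].
#' @param mapping Optional explicit atom correspondence: a data frame with
#'   columns `chain_s`, `resid_s`, `atom_s`, `chain_n`, `resid_n`, `atom_n`.
#'   By default atoms are matched by identical (`chain`, `resid`, `atom`).
#' @param threshold Classification threshold, Angstrom (default 5).
#' @return Tibble: atom keys, `rmsf_stapled`, `rmsf_nonstapled`,
#'   `delta_rmsf`, `class`.
#' @export
delta_rmsf <- function(stapled, nonstapled, mapping = NULL, threshold = 5) {
  if (!is.null(mapping) && nrow(mapping) == 0) abort("empty atom mapping")
  if (is.null(mapping)) {
    joined <- full_join(
      rename(stapled, rmsf_stapled = "rmsf"),
      rename(nonstapled, rmsf_nonstapled = "rmsf"),
      by = c("chain", "resid", "atom")
    )
  } else {
    s <- rename(stapled, chain_s = "chain", resid_s = "resid",
                atom_s = "atom", rmsf_stapled = "rmsf")
    n <- rename(nonstapled, chain_n = "chain", resid_n = "resid",
                atom_n = "atom", rmsf_nonstapled = "rmsf")
    joined <- full_join(
      left_join(s, mapping, by = c("chain_s", "resid_s", "atom_s")),
      n,
      by = c("chain_n", "resid_n", "atom_n")
    )
    joined <- rename(joined, chain = "chain_s", resid = "resid_s",
                     atom = "atom_s")
  }
  joined <- mutate(
    joined,
    delta_rmsf = .data$rmsf_stapled - .data$rmsf_nonstapled,
    class = case_when(
      is.na(.data$delta_rmsf) ~ "uncomparable",
      .data$delta_rmsf >= .env$threshold ~ "increased",
      .data$delta_rmsf <= -.env$threshold ~ "decreased",
      TRUE ~ "unchanged"
    )
  )
  joined
}

#' Plot a fluctuation-difference map along the sequence
#'
#' @param dmap A [delta_rmsf()] result.
#' @param threshold Classification threshold shown as guide lines.
#' @return A ggplot.
#' @export
plot_delta_rmsf <- function(dmap, threshold = 5) {
  d <- filter(dmap, .data$class != "uncomparable")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$resid, y = .data$delta_rmsf,
                                  colour = .data$class)) +
    ggplot2::geom_hline(yintercept = c(-threshold, 0, threshold),
                        linetype = c(3, 1, 3), colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chain)) +
    ggplot2::scale_colour_manual(values = c(increased = "#d55e00",
                                            unchanged = "#009e73",
                                            decreased = "#0072b2")) +
    ggplot2::labs(x = "residue", y = "ΔRMSF (Å)")
}

#' Write an RMSF map as a B-factor-annotated PDB
#'
#' Writes the mean-like first frame of an ensemble with each atom's RMSF in
#' the B-factor column, for coloring in a molecular viewer.
#'
#' @param ens The ensemble the map was computed from.
#' @param map An [rmsf()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rmsf_pdb <- function(ens, map, path) {
  stopifnot(inherits(ens, "cc_ensemble"))
  first <- ens[ens$frame == min(ens$frame), ]
  first <- left_join(first, map, by = c("chain", "resid", "atom"))
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(rbind(first$x, first$y, first$z)),
    type = rep("ATOM", nrow(first)),
    resno = first$resid,
    chain = first$chain,
    resid = rep("ALA", nrow(first)),
    elety = first$atom,
    b = ifelse(is.na(first$rmsf), 0, first$rmsf)
  )
  invisible(path)
}
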