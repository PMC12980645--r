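# Shared fixtures, all built in code.

# a tiny hand-placed ensemble: explicit coordinates, no generators
manual_ensemble <- function(frames) {
  # frames: list of data.frames with chain, resid, atom, x, y, z
  coords <- purrr::imap_dfr(frames, function(d, i) dplyr::mutate(d, frame = i))
  ensemble(coords)
}

two_atom_frame <- function(xa, xb, chain = c("A", "B"), resid = c(1, 1)) {
  data.frame(chain = chain, resid = resid, atom = "CB",
             x = c(xa[1], xb[1]), y = c(xa[2], xb[2]), z = c(xa[3], xb[3]))
}

# random rigid-body transform applied to every frame of an ensemble
apply_rigid <- function(ens, angles, shift) {
  rx <- matrix(c(1, 0, 0,
                 0, cos(angles[1]), -sin(angles[1]),
                 0, sin(angles[1]), cos(angles[1])), 3, byrow = TRUE)
  rz <- matrix(c(cos(angles[2]), -sin(angles[2]), 0,
                 sin(angles[2]), cos(angles[2]), 0,
                 0, 0, 1), 3, byrow = TRUE)
  m <- as.matrix(ens[, c("x", "y", "z")]) %*% (rx %*% rz)
  ens$x <- m[, 1] + shift[1]
  ens$y <- m[, 2] + shift[2]
  ens$z <- m[, 3] + shift[3]
  ens
}

table1_stapled <- function() dplyr::filter(load_table1(), stapled)
table1_nonstapled <- function() dplyr::filter(load_table1(), !stapled)
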