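#' Assign a heptad register to a chain
#'
#' Coiled-coil sequences repeat with a seven-residue period whose positions
#' are conventionally labelled `a`--`g`; `a`/`d` form the hydrophobic core,
#' `e`/`g` flank it, and `b`/`c`/`f` face solvent.  Given the register letter
#' of the first residue, this labels every residue of a chain.  The register
#' is supplied, not predicted: register prediction from sequence is a
#' separate problem and out of scope here.
#'
#' For the A/B heterodimer both 34-residue chains start at `g`, which places
#' residues 6, 13, 20, 27 and 34 at `e` and 7, 14, 21 and 28 at `f`.
#'
#' @param sequence_length Number of residues (>= 7).
#' @param first_register Register letter (`"a"`--`"g"`) of residue 1.
#' @param chain Chain label, e.g. `"A"`.
#' @return A tibble with columns `chain`, `index` (1-based) and `register`.
#' @examples
#' assign_register(34, "g", "A")
#' @export
assign_register <- function(sequence_length, first_register = "g", chain = "A") {
  stopifnot(is.numeric(sequence_length), length(sequence_length) == 1)
  if (sequence_length < 7) {
    abort("`sequence_length` must be at least one heptad (7 residues)")
  }
  if (!is.character(first_register) || length(first_register) != 1 ||
      !first_register %in% letters[1:7]) {
    abort("`first_register` must be one of 'a'..'g'")
  }
  offset <- match(first_register, letters[1:7]) - 1L
  idx <- seq_len(sequence_length)
  tibble(
    chain = chain,
    index = idx,
    register = letters[1:7][((idx - 1L + offset) %% 7L) + 1L]
  )
}

#' Classify a cross-chain anchor pair
#'
#' Interhelical staple sites in a parallel in-register dimer fall into three
#' geometric classes defined by the register letters and the index offset of
#' the two anchors: salt-bridged e/g' pairs (`sb_eg`, the g' partner comes
#' from the preceding heptad, e index minus g index = 5), non-salt-bridged
#' e/g' pairs (`nsb_eg`, offset e minus g = -2), and outward-facing f/b'
#' pairs (`fb`, b index minus f index = 3).  Anything else is `other`.
#'
#' Anchors must sit on different chains: intrachain staples are out of scope
#' and raise an error, as do antiparallel topologies (this model only treats
#' the parallel A/B dimer).
#'
#' @param chain_a,index_a,register_a First anchor (chain label, 1-based
#'   residue index, register letter).
#' @param chain_b,index_b,register_b Second anchor.
#' @return Character vector of classes (`"sb_eg"`, `"nsb_eg"`, `"fb"`,
#'   `"other"`).  Vectorized over anchors.
#' @examples
#' classify_pair("A", 27, "e", "B", 22, "g") # sb_eg
#' classify_pair("A", 27, "e", "B", 29, "g") # nsb_eg
#' classify_pair("A", 7, "f", "B", 10, "b")  # fb
#' @export
classify_pair <- function(chain_a, index_a, register_a,
                          chain_b, index_b, register_b) {
  n <- max(length(index_a), length(index_b))
  args <- lapply(
    list(chain_a, index_a, register_a, chain_b, index_b, register_b),
    rep_len, n
  )
  names(args) <- c("ca", "ia", "ra", "cb", "ib", "rb")
  if (any(args$ca == args$cb)) {
    abort("anchors lie on the same chain; intrachain staples are out of scope")
  }
  bad <- !(args$ra %in% letters[1:7]) | !(args$rb %in% letters[1:7])
  if (any(bad)) abort("register letters must be one of 'a'..'g'")
  purrr::pmap_chr(args, function(ca, ia, ra, cb, ib, rb) {
    regs <- c(ra, rb)
    if (setequal(regs, c("e", "g"))) {
      i_e <- if (ra == "e") ia else ib
      i_g <- if (ra == "g") ia else ib
      if (i_e - i_g == 5L) return("sb_eg")
      if (i_e - i_g == -2L) return("nsb_eg")
      return("other")
    }
    if (setequal(regs, c("f", "b"))) {
      i_f <- if (ra == "f") ia else ib
      i_b <- if (ra == "b") ia else ib
      if (i_b - i_f == 3L) return("fb")
      return("other")
    }
    "other"
  })
}

#' The C-terminal disulfide tether of the A/B dimer
#'
#' A/B carries a Cys33--Cys33' interchain disulfide that fixes the
#' oligomeric state even when unfolded; it is the default pre-existing
#' crosslink through which loop lengths are computed.
#'
#' @return A one-row crosslink tibble (`chain_1`, `index_1`, `chain_2`,
#'   `index_2`, `kind`).
#' @export
ab_disulfide <- function() {
  tibble(chain_1 = "A", index_1 = 33L, chain_2 = "B", index_2 = 33L,
         kind = "disulfide")
}

#' Through-bond loop length closed by stapling an anchor pair
#'
#' The loop length of a candidate staple is the minimal through-bond residue
#' count of the cycle the staple would close, walking along chain backbones
#' and through any existing crosslinks (each crosslink counts as one covalent
#' link).  For a same-chain pair this reduces to `|i - j|`; for the A/B dimer
#' the path runs through the Cys33--Cys33' disulfide, giving
#' `(33 - i_A) + (33 - i_B) + 1`.  Longer loops mean more unfolded-state
#' conformational freedom removed by the staple, hence (for a compatible
#' staple) more stabilization.
#'
#' Computed as a shortest path on the residue graph, so arbitrary crosslink
#' sets are supported.
#'
#' @param chain_a,index_a,chain_b,index_b The two anchors.
#' @param crosslinks Tibble of existing crosslinks as in [ab_disulfide()]
#'   (may have zero rows for a monomeric scaffold).
#' @param n_res Named integer vector of chain lengths, e.g.
#'   `c(A = 34, B = 34)`.
#' @return Integer loop length (vectorized over anchors).
#' @examples
#' loop_length("A", 27, "B", 29) # 11
#' loop_length("A", 6, "B", 8)   # 53
#' @export
loop_length <- function(chain_a, index_a, chain_b, index_b,
                        crosslinks = ab_disulfide(),
                        n_res = c(A = 34L, B = 34L)) {
  chains <- names(n_res)
  stopifnot(!is.null(chains))
  vid <- function(chain, index) paste0(chain, index)
  verts <- unlist(lapply(chains, function(ch) vid(ch, seq_len(n_res[[ch]]))))
  backbone <- do.call(rbind, lapply(chains, function(ch) {
    i <- seq_len(n_res[[ch]] - 1L)
    cbind(vid(ch, i), vid(ch, i + 1L))
  }))
  edges <- backbone
  if (nrow(crosslinks) > 0) {
    edges <- rbind(edges, cbind(vid(crosslinks$chain_1, crosslinks$index_1),
                                vid(crosslinks$chain_2, crosslinks$index_2)))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  missing <- setdiff(verts, igraph::V(g)$name)
  if (length(missing)) g <- igraph::add_vertices(g, length(missing), name = missing)
  n <- max(length(index_a), length(index_b))
  from <- rep_len(vid(chain_a, index_a), n)
  to <- rep_len(vid(chain_b, index_b), n)
  if (!all(c(from, to) %in% igraph::V(g)$name)) {
    abort("anchor residue outside the defined chains")
  }
  d <- purrr::map2_dbl(from, to, function(f, t) {
    igraph::distances(g, v = f, to = t)[1, 1]
  })
  if (any(!is.finite(d))) {
    abort("no covalent path connects the two anchors")
  }
  as.integer(d)
}

#' Enumerate candidate staple sites on a parallel dimer
#'
#' Lists every cross-chain e/g' and f/b' anchor pair implied by the two
#' chains' registers, together with its class and loop length through the
#' supplied crosslinks.  This is the candidate set that
#' [recommend_sites()] evaluates.
#'
#' @param register_a,register_b Register tibbles from [assign_register()].
#' @param crosslinks Existing crosslinks (default the A/B disulfide).
#' @return Tibble with columns `chain_a`, `index_a`, `register_a`, `chain_b`,
#'   `index_b`, `register_b`, `pair_class`, `loop_length`.
#' @export
enumerate_anchor_pairs <- function(register_a, register_b,
                                   crosslinks = ab_disulfide()) {
  stopifnot(all(c("chain", "index", "register") %in% names(register_a)))
  grid <- tidyr::expand_grid(
    a = seq_len(nrow(register_a)),
    b = seq_len(nrow(register_b))
  )
  out <- tibble(
    chain_a = register_a$chain[grid$a],
    index_a = register_a$index[grid$a],
    register_a = register_a$register[grid$a],
    chain_b = register_b$chain[grid$b],
    index_b = register_b$index[grid$b],
    register_b = register_b$register[grid$b]
  )
  out <- filter(out, (.data$register_a == "e" & .data$register_b == "g") |
                  (.data$register_a == "f" & .data$register_b == "b"))
  out$pair_class <- classify_pair(out$chain_a, out$index_a, out$register_a,
                                  out$chain_b, out$index_b, out$register_b)
  out <- filter(out, .data$pair_class != "other")
  n_res <- setNames(
    c(nrow(register_a), nrow(register_b)),
    c(register_a$chain[1], register_b$chain[1])
  )
  out$loop_length <- loop_length(out$chain_a, out$index_a,
                                 out$chain_b, out$index_b,
                                 crosslinks = crosslinks, n_res = n_res)
  out
}
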