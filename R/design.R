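# Staple chemistry constants and the stabilization models built on top of
# the ensemble metrics.

#' Staple chemistries and their span estimates
#'
#' Three independent estimates of how far a triazole/PEG staple can reach,
#' as Cbeta--Cbeta distance between its anchors:
#' * `span_extended`: fully extended conformation of the isolated staple
#'   model (an overestimate -- such conformations are unlikely once the
#'   staple is anchored in a fold);
#' * `span_relaxed`: mean span of the unconstrained staple model in
#'   solution-like simulations;
#' * `span_effective`: mean anchor spacing in unfolded-temperature ensembles
#'   of stapled variants, where the chain pulls the staple taut from both
#'   ends -- the most realistic estimate of maximum accessible span, and the
#'   one the compatibility classifier uses.
#'
#' `z4x` joins an Asn-linked four-unit PEG azide to a propargylglycine;
#' `x4x` bridges two propargylglycines with a bis-azido four-unit PEG; both
#' reach ~14 Angstrom effectively.  `z2x` is the shorter two-unit analog; no
#' span estimates are bundled for it.
#'
#' @return Tibble with columns `name`, `span_extended`, `span_relaxed`,
#'   `span_effective` (Angstrom).
#' @export
staple_specs <- function() {
  tibble(
    name = c("z4x", "x4x", "z2x"),
    span_extended = c(19.3, 20.4, NA),
    span_relaxed = c(10.96, 10.66, NA),
    span_effective = c(13.83, 14.20, NA)
  )
}

resolve_staple <- function(staple) {
  if (is.character(staple)) {
    hit <- filter(staple_specs(), .data$name == staple)
    if (nrow(hit) == 0) abort(sprintf("unknown staple chemistry '%s'", staple))
    return(hit)
  }
  stopifnot(is.data.frame(staple), nrow(staple) == 1)
  as_tibble(staple)
}

#' Folded-state compatibility of a staple with a site
#'
#' Stabilization requires the staple's maximum accessible span to cover the
#' intrinsic folded-state anchor spacing; a staple that falls short forces
#' the fold into a compressed non-native geometry and destabilizes.  Sites
#' are `compatible` when the native spacing is at most the effective span,
#' `marginal` within `marginal_frac` (default +10%) beyond it, and
#' `incompatible` farther out.  The band acknowledges borderline cases: a
#' native spacing only ~1.4 Angstrom past the span has been seen to remain
#' weakly stabilizing.
#'
#' @param native_spacing Folded-state Cbeta--Cbeta spacing(s), Angstrom.
#' @param staple Staple name (see [staple_specs()]) or a one-row spec with a
#'   `span_effective` column.
#' @param marginal_frac Width of the marginal band as a fraction of the
#'   effective span.
#' @return Character vector: `"compatible"`, `"marginal"` or
#'   `"incompatible"`.
#' @examples
#' classify_compatibility(9.86, "x4x")  # compatible
#' classify_compatibility(16.2, "x4x")  # incompatible
#' @export
classify_compatibility <- function(native_spacing, staple,
                                   marginal_frac = 0.10) {
  spec <- resolve_staple(staple)
  span <- spec$span_effective[1]
  if (is.na(span)) {
    abort(sprintf("staple '%s' has no effective span estimate", spec$name[1]))
  }
  stopifnot(all(native_spacing > 0))
  case_when(
    native_spacing <= span ~ "compatible",
    native_spacing <= span * (1 + marginal_frac) ~ "marginal",
    TRUE ~ "incompatible"
  )
}

#' Ordinary least-squares line fit
#'
#' Unweighted (or optionally weighted) straight-line fit, the form used for
#' all the stabilization models here.
#'
#' @param x,y Numeric vectors (n >= 3, finite, `x` not constant).
#' @param weights Optional observation weights.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `n`,
#'   `se_slope`, `se_intercept`, `sigma`, and the residuals as a
#'   list-column.
#' @export
fit_linear <- function(x, y, weights = NULL) {
  if (length(x) != length(y)) abort("`x` and `y` lengths differ")
  if (length(x) < 3) abort("need at least 3 points")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("values must be finite")
  if (var(x) == 0) abort("`x` has zero variance")
  fit <- if (is.null(weights)) lm(y ~ x) else lm(y ~ x, weights = weights)
  # exact synthetic data is a designed use; the perfect-fit warning is noise
  s <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = s$r.squared,
    n = length(x),
    se_slope = s$coefficients[2, 2],
    se_intercept = s$coefficients[1, 2],
    sigma = s$sigma,
    residuals = list(unname(stats::residuals(fit)))
  )
}

pick_ddg <- function(records, source = c("obs", "sim")) {
  source <- match.arg(source)
  col <- paste0("ddg_", source)
  if (!col %in% names(records)) abort(sprintf("column `%s` not found", col))
  records[[col]]
}

#' Stabilization vs unfolded-state constraint
#'
#' Regresses the staple stabilization `ddG` on the unfolded-state constraint
#' `dcb` (stapled-minus-non-stapled unfolded anchor spacing) across e/g'
#' sites, pooled or per class.  If unfolded-state constraint were the sole
#' determinant of stabilization, one line should fit the pooled data; a
#' markedly different intercept between the salt-bridged and
#' non-salt-bridged fits signals class-specific stabilization that the
#' constraint alone does not explain.
#'
#' @param records Site records with columns `pair_class`, `dcb` and
#'   `ddg_obs`/`ddg_sim` (e.g. the stapled rows of [load_table1()]).
#' @param grouping `"pooled"` or `"by_class"`.
#' @param source `"obs"` or `"sim"`.
#' @return For `"pooled"`, a one-row [fit_linear()] tibble.  For
#'   `"by_class"`, one row per class with a `pair_class` column, and the
#'   sb-minus-nsb intercept difference in attribute
#'   `"intercept_contrast"`.
#' @export
ddg_vs_dcb <- function(records, grouping = c("pooled", "by_class"),
                       source = c("obs", "sim")) {
  grouping <- match.arg(grouping)
  source <- match.arg(source)
  records <- mutate(records, .ddg = pick_ddg(records, source))
  records <- filter(records, .data$pair_class %in% c("sb_eg", "nsb_eg"),
                    !is.na(.data$.ddg), !is.na(.data$dcb))
  if (grouping == "pooled") {
    return(fit_linear(records$dcb, records$.ddg))
  }
  fits <- records |>
    group_by(.data$pair_class) |>
    group_modify(function(d, key) {
      if (nrow(d) < 3) {
        abort(sprintf("class %s has fewer than 3 records", key$pair_class))
      }
      fit_linear(d$dcb, d$.ddg)
    }) |>
    ungroup()
  contrast <- fits$intercept[fits$pair_class == "sb_eg"] -
    fits$intercept[fits$pair_class == "nsb_eg"]
  attr(fits, "intercept_contrast") <- contrast
  fits
}

#' Stabilization vs sequence separation
#'
#' Regresses `ddG` on the through-bond loop length of each site: the
#' simulation-free surrogate for unfolded-state constraint.  Residues farther
#' apart along the covalent path can separate farther in the unfolded
#' ensemble, so longer loops give more negative `ddG` (negative slope), as
#' long as the staple is geometrically compatible with the site.
#'
#' @param records Site records with `loop_length` and `ddg_obs`/`ddg_sim`
#'   columns; rows with either missing are dropped.
#' @inheritParams ddg_vs_dcb
#' @return A one-row [fit_linear()] tibble.
#' @export
ddg_vs_separation <- function(records, source = c("obs", "sim")) {
  source <- match.arg(source)
  if (!"loop_length" %in% names(records)) {
    abort("records need a `loop_length` column (see `loop_length()`)")
  }
  records <- mutate(records, .ddg = pick_ddg(records, source))
  records <- filter(records, !is.na(.data$.ddg), !is.na(.data$loop_length))
  fit_linear(records$loop_length, records$.ddg)
}

#' Matched-pair stabilization contrasts
#'
#' Mean `ddG` difference over explicitly matched variant pairs:
#' * `x4x_vs_z4x`: sites carrying both staples, x4x minus z4x -- how
#'   interchangeable the two chemistries are;
#' * `sb_vs_nsb`: salt-bridged minus non-salt-bridged e/g' sites whose
#'   e-anchor sits in the same heptad (matched additionally by staple where
#'   a site carries both chemistries).
#'
#' The standard error propagates the member ses through the pair
#' differences.
#'
#' @param records Stapled site records with `pair_class`, `staple`,
#'   `index_a`, `ddg_*` and `ddg_*_se` columns (e.g. the stapled rows of
#'   [load_table1()]).
#' @param contrast `"x4x_vs_z4x"` or `"sb_vs_nsb"`.
#' @inheritParams ddg_vs_dcb
#' @return One-row tibble: `contrast`, `mean_diff`, `se`, `n_pairs`, plus
#'   the per-pair table as a list-column.
#' @export
staple_contrast <- function(records, contrast = c("x4x_vs_z4x", "sb_vs_nsb"),
                            source = c("obs", "sim")) {
  contrast <- match.arg(contrast)
  source <- match.arg(source)
  se_col <- paste0("ddg_", source, "_se")
  records <- mutate(records,
                    .ddg = pick_ddg(records, source),
                    .se = if (se_col %in% names(records)) .data[[se_col]] else NA_real_)
  records <- filter(records, !is.na(.data$.ddg))

  if (contrast == "x4x_vs_z4x") {
    eg <- filter(records, .data$pair_class %in% c("sb_eg", "nsb_eg"))
    pairs <- inner_join(
      filter(eg, .data$staple == "x4x"),
      filter(eg, .data$staple == "z4x"),
      by = c("pair_class", "index_a", "index_b"),
      suffix = c("_x4x", "_z4x")
    )
    if (nrow(pairs) == 0) abort("no site carries both x4x and z4x records")
    diffs <- pairs$.ddg_x4x - pairs$.ddg_z4x
    ses <- sqrt(pairs$.se_x4x^2 + pairs$.se_z4x^2)
  } else {
    sb <- filter(records, .data$pair_class == "sb_eg")
    nsb <- filter(records, .data$pair_class == "nsb_eg")
    pairs <- inner_join(sb, nsb, by = "index_a", suffix = c("_sb", "_nsb"),
                        relationship = "many-to-many")
    if (nrow(pairs) == 0) abort("no matched sb/nsb site pairs")
    # where a heptad offers same-staple pairings, keep only those
    pairs <- pairs |>
      group_by(.data$index_a) |>
      group_modify(function(d, key) {
        same <- d[d$staple_sb == d$staple_nsb, , drop = FALSE]
        if (nrow(same) > 0) same else d
      }) |>
      ungroup()
    diffs <- pairs$.ddg_sb - pairs$.ddg_nsb
    ses <- sqrt(pairs$.se_sb^2 + pairs$.se_nsb^2)
  }
  tibble(
    contrast = contrast,
    source = source,
    mean_diff = mean(diffs),
    se = if (all(is.finite(ses))) sqrt(sum(ses^2)) / length(ses) else NA_real_,
    n_pairs = length(diffs),
    pairs = list(pairs)
  )
}

#' Rank candidate staple sites
#'
#' The prospective design workflow: from folded- and unfolded-temperature
#' summaries of the non-stapled scaffold, (1) keep sites whose folded-state
#' spacing the staple can reach (compatibility filter), (2) predict each
#' kept site's stabilization from a fitted `ddG` vs `dcb` model, using
#' `span_effective - unfolded mean` as the constraint the staple would
#' impose, and (3) rank by predicted `ddG` (most stabilizing first).
#' Incompatible sites are returned unranked and flagged
#' `predicted destabilizing`; sites in the marginal band are ranked after
#' all fully compatible sites.
#'
#' @param candidates Tibble with one row per candidate pair: site columns
#'   (`index_a`, `index_b`, optionally `pair_class`, registers), plus
#'   `folded_mean` (native spacing, Angstrom) and `unfolded_mean`
#'   (non-stapled unfolded-temperature spacing, Angstrom).
#' @param staple Staple chemistry (name or spec row).
#' @param model A pooled [fit_linear()]/[ddg_vs_dcb()] result, or a
#'   by-class result (then a candidate's class-specific intercept is used
#'   when its `pair_class` is present in the model).
#' @param marginal_frac Passed to [classify_compatibility()].
#' @return `candidates` with `native_spacing`, `span_effective`, `verdict`,
#'   `dcb_pred`, `predicted_ddg`, `rank` (NA for incompatible sites) and
#'   `note`, sorted ranked-first.
#' @export
recommend_sites <- function(candidates, staple, model,
                            marginal_frac = 0.10) {
  stopifnot(all(c("folded_mean", "unfolded_mean") %in% names(candidates)))
  spec <- resolve_staple(staple)
  span <- spec$span_effective[1]
  out <- mutate(
    candidates,
    native_spacing = .data$folded_mean,
    span_effective = span,
    staple = spec$name[1],
    verdict = classify_compatibility(.data$folded_mean, spec, marginal_frac),
    dcb_pred = span - .data$unfolded_mean
  )
  by_class <- "pair_class" %in% names(model)
  predict_one <- function(class, dcb) {
    row <- if (by_class && !is.na(class) && class %in% model$pair_class) {
      model[model$pair_class == class, ]
    } else if (by_class) {
      abort("by-class model lacks this candidate's class; fit pooled instead")
    } else {
      model
    }
    row$intercept[1] + row$slope[1] * dcb
  }
  cls <- if ("pair_class" %in% names(out)) out$pair_class else rep(NA, nrow(out))
  out$predicted_ddg <- purrr::map2_dbl(cls, out$dcb_pred, predict_one)
  out <- arrange(out,
                 factor(.data$verdict,
                        levels = c("compatible", "marginal", "incompatible")),
                 .data$predicted_ddg)
  ranked <- out$verdict != "incompatible"
  out$rank <- NA_integer_
  out$rank[ranked] <- seq_len(sum(ranked))
  out$note <- ifelse(ranked, "", "predicted destabilizing")
  if (!any(ranked)) {
    warn(sprintf(
      "no candidate is compatible with staple %s (span %.1f Å); all native spacings exceed its reach",
      spec$name[1], span))
  }
  out
}
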