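#' Specific leaf area
#'
#' SLA is leaf area per unit dry mass, the canonical leaf-economics
#' production trait.
#'
#' @param leaf_area Leaf area in cm^2, strictly positive.
#' @param dry_mass Leaf dry mass in g, strictly positive.
#' @return SLA in cm^2 g^-1. Vectorized.
#' @export
#' @examples
#' compute_sla(30, 0.1) # 300
compute_sla <- function(leaf_area, dry_mass) {
  check_positive(leaf_area, "leaf_area")
  check_positive(dry_mass, "dry_mass")
  leaf_area / dry_mass
}

#' Leaf dry matter content
#'
#' LDMC is dry mass per unit water-saturated fresh mass, reported in
#' mg g^-1 (the mass ratio times 1000).
#'
#' @param dry_mass Dry mass in g, strictly positive, at most `fresh_mass`.
#' @param fresh_mass Saturated fresh mass in g, strictly positive.
#' @return LDMC in mg g^-1. Vectorized.
#' @export
#' @examples
#' compute_ldmc(0.2, 1.0) # 200
compute_ldmc <- function(dry_mass, fresh_mass) {
  check_positive(dry_mass, "dry_mass")
  check_positive(fresh_mass, "fresh_mass")
  if (any(dry_mass > fresh_mass)) {
    abort("`dry_mass` cannot exceed `fresh_mass`.",
          class = "leafspectra_domain_error")
  }
  1000 * dry_mass / fresh_mass
}

#' Paired-plot relative change
#'
#' The invader-community interaction metric for a variable measured in an
#' invaded plot (`vi`) and its paired uninvaded plot (`vu`):
#' `(vi - vu) / (vi + vu)`. It is antisymmetric in its arguments and
#' bounded in \[-1, 1\] for nonnegative inputs.
#'
#' @param vi,vu Nonnegative paired values; `vi + vu` must be positive.
#' @return Relative change in \[-1, 1\]. Vectorized.
#' @export
#' @examples
#' relative_change(3, 1) # 0.5
relative_change <- function(vi, vu) {
  if (any(!is.finite(vi)) || any(!is.finite(vu)) || any(vi < 0) || any(vu < 0)) {
    abort("`vi` and `vu` must be finite and nonnegative.",
          class = "leafspectra_domain_error")
  }
  if (any(vi + vu == 0)) {
    abort("relative change is undefined when vi + vu = 0.",
          class = "leafspectra_domain_error")
  }
  (vi - vu) / (vi + vu)
}

#' Phenotypic variation index
#'
#' Min-max-normalized trait score: `(max(T) - T) / (max(T) - min(T))`,
#' equal to 0 at the sample maximum and 1 at the sample minimum. The
#' extremes are taken over `reference` (by default the scored values
#' themselves), so scores for plot-level units can be normalized against
#' population-level extremes if desired.
#'
#' @param x Trait values to score (>= 2 values when `reference` is `x`).
#' @param reference Values supplying the extremes; defaults to `x`.
#' @return PVI scores in \[0, 1\].
#' @export
#' @examples
#' compute_pvi(c(2, 4, 6, 10)) # 1.0 0.75 0.5 0.0
compute_pvi <- function(x, reference = x) {
  if (any(!is.finite(x)) || any(!is.finite(reference))) {
    abort("trait values must be finite.", class = "leafspectra_domain_error")
  }
  if (length(reference) < 2) {
    abort("need at least two reference values.",
          class = "leafspectra_domain_error")
  }
  hi <- max(reference)
  lo <- min(reference)
  if (hi == lo) {
    abort("degenerate trait range: max equals min.",
          class = "leafspectra_degenerate_error")
  }
  (hi - x) / (hi - lo)
}

#' Production and tolerance trait categories
#'
#' The seven leaf traits split into four production traits (leaf area,
#' SLA, chlorophyll, leaf N) and three stress-tolerance traits (LDMC,
#' leaf C, leaf C:N).
#'
#' @return A list with character vectors `production` and `tolerance`.
#' @export
trait_categories <- function() {
  list(production = c("leaf_area", "sla", "chlorophyll", "leaf_n"),
       tolerance = c("ldmc", "leaf_c", "leaf_cn"))
}

max_normalised_sum <- function(traits, cols, what) {
  missing_cols <- setdiff(cols, names(traits))
  if (length(missing_cols) > 0) {
    abort(paste0("missing ", what, " trait column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "leafspectra_schema_error")
  }
  m <- as.matrix(traits[, cols])
  check_positive(m, what)
  colmax <- apply(m, 2, max)
  rowSums(sweep(m, 2, colmax, `/`))
}

#' Leaf production index
#'
#' Per-unit sum, over the four production traits, of the trait value
#' divided by its cross-unit maximum; lies in (0, 4], reaching 4 only for
#' a unit maximal in all four traits.
#'
#' @param traits Data frame with the production trait columns.
#' @param categories Trait category map, see [trait_categories()].
#' @return Numeric vector of LPI values.
#' @export
compute_lpi <- function(traits, categories = trait_categories()) {
  max_normalised_sum(traits, categories$production, "production")
}

#' Leaf stress-tolerance index
#'
#' Per-unit sum, over LDMC, leaf C and leaf C:N, of the trait value
#' divided by its cross-unit maximum; lies in (0, 3].
#'
#' @inheritParams compute_lpi
#' @return Numeric vector of LTI values.
#' @export
compute_lti <- function(traits, categories = trait_categories()) {
  max_normalised_sum(traits, categories$tolerance, "tolerance")
}

#' Trait spectrum ratio
#'
#' The per-unit ratio of the stress-tolerance index to the production
#' index, used as the scalar summary of where a unit sits on the leaf
#' production/stress-tolerance spectrum.
#'
#' @param lti,lpi Positive index values.
#' @return `lti / lpi`. Vectorized.
#' @export
spectrum_ratio <- function(lti, lpi) {
  check_positive(lti, "lti")
  check_positive(lpi, "lpi")
  lti / lpi
}

# Validate a trait table and reconcile the leaf C:N column with leaf C and
# leaf N. A supplied C:N column wins over the recomputed ratio, with a
# warning when they disagree beyond 1e-6 relative.
validate_traits <- function(traits) {
  need <- setdiff(trait_names(), "leaf_cn")
  missing_cols <- setdiff(need, names(traits))
  if (length(missing_cols) > 0) {
    abort(paste0("trait table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "leafspectra_schema_error")
  }
  if (!"unit_id" %in% names(traits)) {
    traits$unit_id <- sprintf("U%04d", seq_len(nrow(traits)))
  }
  for (tr in need) check_positive(traits[[tr]], tr)
  ratio <- traits$leaf_c / traits$leaf_n
  if (!"leaf_cn" %in% names(traits)) {
    traits$leaf_cn <- ratio
  } else {
    check_positive(traits$leaf_cn, "leaf_cn")
    rel <- abs(traits$leaf_cn - ratio) / ratio
    if (any(rel > 1e-6)) {
      warn(sprintf("leaf_cn disagrees with leaf_c/leaf_n for %d unit(s); keeping the supplied column.",
                   sum(rel > 1e-6)))
    }
  }
  as_tibble(traits)
}

#' Per-unit trait index table
#'
#' Computes, for every unit of a trait table, the seven per-trait
#' phenotypic variation indices, the production and tolerance indices and
#' the LTI/LPI spectrum ratio.
#'
#' @param traits Data frame with `unit_id` (optional) and the seven trait
#'   columns (`leaf_cn` is recomputed from `leaf_c`/`leaf_n` when absent).
#' @param reference Optional second trait table supplying the PVI/max
#'   extremes (e.g. population-aggregated values); defaults to `traits`.
#' @param categories Trait category map.
#' @return A tibble: `unit_id`, `pvi_<trait>` for the seven traits, `lpi`,
#'   `lti`, `spectrum_ratio`.
#' @export
#' @examples
#' sv <- simulate_survey(seed = 1)
#' head(trait_indices(sv$traits))
trait_indices <- function(traits, reference = NULL,
                          categories = trait_categories()) {
  traits <- validate_traits(traits)
  reference <- if (is.null(reference)) traits else validate_traits(reference)
  out <- tibble(unit_id = traits$unit_id)
  for (tr in trait_names()) {
    out[[paste0("pvi_", tr)]] <- compute_pvi(traits[[tr]], reference[[tr]])
  }
  # max-normalisation shares the reference scope with the PVI extremes
  scale_by_ref <- function(cols) {
    m <- as.matrix(traits[, cols])
    colmax <- apply(as.matrix(reference[, cols]), 2, max)
    rowSums(sweep(m, 2, colmax, `/`))
  }
  out$lpi <- scale_by_ref(categories$production)
  out$lti <- scale_by_ref(categories$tolerance)
  out$spectrum_ratio <- spectrum_ratio(out$lti, out$lpi)
  out
}

#' Long-format PVI table
#'
#' Reshapes a [trait_indices()] table to one row per unit x trait, the
#' shape [pvi_anova()] expects.
#'
#' @param indices Output of [trait_indices()].
#' @return A tibble with `unit_id`, `trait`, `pvi`.
#' @export
pvi_long <- function(indices) {
  indices |>
    select("unit_id", dplyr::starts_with("pvi_")) |>
    pivot_longer(-"unit_id", names_to = "trait", values_to = "pvi",
                 names_prefix = "pvi_")
}

#' Benchmark statistics of a raw leaf-trait table
#'
#' Computes the two published summaries a raw per-population leaf-trait
#' table supports: the mean (and SE) phenotypic variation index of each
#' trait, and the standardized-major-axis fit of the production index
#' against the tolerance index. Intended for replication against the
#' survey's deposited raw trait data when a copy is available.
#'
#' @param traits A trait table (data frame or path to a CSV with the seven
#'   trait columns).
#' @return A list with `pvi_summary` (tibble: trait, mean_pvi, se, n,
#'   sorted by mean) and `spectrum_fit` (an `sma_fit` of LPI vs LTI).
#' @export
replicate_benchmarks <- function(traits) {
  if (is.character(traits)) {
    traits <- readr::read_csv(traits, show_col_types = FALSE, progress = FALSE)
  }
  idx <- trait_indices(traits)
  pvi_summary <- pvi_long(idx) |>
    group_by(.data$trait) |>
    summarise(mean_pvi = mean(.data$pvi),
              se = sd(.data$pvi) / sqrt(dplyr::n()),
              n = dplyr::n(), .groups = "drop") |>
    arrange(desc(.data$mean_pvi))
  list(pvi_summary = pvi_summary,
       spectrum_fit = sma_fit(idx$lti, idx$lpi))
}
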