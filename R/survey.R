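#' Survey design for a paired invaded/uninvaded plot survey
#'
#' Describes the geometry of a stratified paired-plot field survey:
#' locations, sites nested in locations, and invaded/uninvaded plot pairs
#' nested in sites. Two strata are supported, a "major" stratum of sites
#' carrying `pairs_per_site_major` pairs and a "minor" stratum carrying
#' `pairs_per_site_minor`. The default reproduces a 22-location x 3-site
#' survey with five pairs at 51 sites and three pairs at 15 sites, i.e.
#' 300 plot pairs across 66 populations.
#'
#' @param n_locations Number of sampling locations.
#' @param sites_per_location Sites nested within each location.
#' @param n_five_pair_sites Number of sites in the major (five-pair) stratum.
#' @param n_three_pair_sites Number of sites in the minor (three-pair) stratum.
#' @param pairs_per_site_major Plot pairs at each major-stratum site.
#' @param pairs_per_site_minor Plot pairs at each minor-stratum site.
#'
#' @return An object of class `survey_design`.
#' @export
#' @examples
#' d <- survey_design()
#' nrow(generate_design(d)) # 300
survey_design <- function(n_locations = 22L,
                          sites_per_location = 3L,
                          n_five_pair_sites = 51L,
                          n_three_pair_sites = 15L,
                          pairs_per_site_major = 5L,
                          pairs_per_site_minor = 3L) {
  counts <- c(n_locations, sites_per_location, n_five_pair_sites,
              n_three_pair_sites, pairs_per_site_major, pairs_per_site_minor)
  if (any(!is.finite(counts)) || any(counts != round(counts)) ||
      any(counts[c(1, 2, 5, 6)] <= 0) || any(counts[c(3, 4)] < 0)) {
    abort("survey_design counts must be positive integers.",
          class = "leafspectra_design_error")
  }
  if (n_locations * sites_per_location != n_five_pair_sites + n_three_pair_sites) {
    abort(paste0("inconsistent design: locations x sites (",
                 n_locations * sites_per_location,
                 ") must equal the number of stratified sites (",
                 n_five_pair_sites + n_three_pair_sites, ")."),
          class = "leafspectra_design_error")
  }
  structure(
    list(n_locations = as.integer(n_locations),
         sites_per_location = as.integer(sites_per_location),
         n_five_pair_sites = as.integer(n_five_pair_sites),
         n_three_pair_sites = as.integer(n_three_pair_sites),
         pairs_per_site_major = as.integer(pairs_per_site_major),
         pairs_per_site_minor = as.integer(pairs_per_site_minor)),
    class = "survey_design"
  )
}

#' @export
print.survey_design <- function(x, ...) {
  idx <- generate_design(x)
  cat("<survey_design> ", x$n_locations, " locations x ",
      x$sites_per_location, " sites; ",
      x$n_five_pair_sites, " sites x ", x$pairs_per_site_major, " pairs + ",
      x$n_three_pair_sites, " sites x ", x$pairs_per_site_minor, " pairs = ",
      nrow(idx), " plot pairs\n", sep = "")
  invisible(x)
}

#' Expand a survey design into its plot-pair index
#'
#' Produces one record per invaded/uninvaded plot pair, labelled by
#' location, site and pair. Sites are assigned to the major stratum in
#' site order (the first `n_five_pair_sites` sites), which keeps the
#' expansion deterministic.
#'
#' @param design A [survey_design()].
#' @return A tibble with columns `unit_id`, `location`, `site`, `pair`.
#' @export
generate_design <- function(design = survey_design()) {
  if (!inherits(design, "survey_design")) {
    abort("`design` must be a survey_design object.",
          class = "leafspectra_design_error")
  }
  n_sites <- design$n_locations * design$sites_per_location
  site_seq <- seq_len(n_sites)
  location <- rep(seq_len(design$n_locations), each = design$sites_per_location)
  pairs_at <- ifelse(site_seq <= design$n_five_pair_sites,
                     design$pairs_per_site_major,
                     design$pairs_per_site_minor)
  site_lab <- sprintf("L%02dS%d", location,
                      rep(seq_len(design$sites_per_location), design$n_locations))
  tibble(
    location = rep(sprintf("L%02d", location), pairs_at),
    site = rep(site_lab, pairs_at),
    pair = unlist(lapply(pairs_at, seq_len), use.names = FALSE)
  ) |>
    mutate(unit_id = sprintf("%s_P%d", .data$site, .data$pair)) |>
    select("unit_id", "location", "site", "pair")
}

# Canonical driver and trait naming used throughout the package.
driver_names <- function() {
  c("mat", "map", "richness", "evenness", "ph", "texture", "nutrients",
    "bacteria", "fungi", "fb_ratio", "d_richness", "d_ph", "d_nutrients",
    "d_bacteria", "d_fungi", "d_fb_ratio")
}

base_driver_names <- function() {
  c("mat", "map", "richness", "evenness", "ph", "texture", "nutrients",
    "bacteria", "fungi")
}

paired_variable_names <- function() {
  c("richness", "ph", "nutrients", "bacteria", "fungi")
}

trait_names <- function() {
  c("leaf_area", "sla", "ldmc", "chlorophyll", "leaf_c", "leaf_n", "leaf_cn")
}

default_effect_matrix <- function() {
  b <- matrix(0, nrow = 16, ncol = 7,
              dimnames = list(driver_names(), trait_names()))
  # A production/tolerance trade-off structure: resource drivers (MAP,
  # nutrients, soil microbes) push production traits up and tolerance
  # traits down; temperature pushes tolerance traits up. Units are trait
  # units per SD of the driver.
  b["map", ] <- c(6, 10, -12, 1.5, -0.6, 0.12, -2.5)
  b["mat", ] <- c(-2, -4, 10, 0.8, 0.8, -0.05, 2.0)
  b["nutrients", ] <- c(5, 12, -10, 2.0, -0.5, 0.20, -3.5)
  b["evenness", ] <- c(-3, -5, 6, -1.0, 0.3, -0.08, 1.5)
  b["richness", ] <- c(2, 3, -4, 0.5, -0.2, 0.05, -0.8)
  b["ph", ] <- c(0, 4, 0, -1.2, 0, 0.06, -1.0)
  b["texture", ] <- c(-1.5, -3, 4, 0, 0.2, -0.04, 0.8)
  b["bacteria", ] <- c(1.5, 3, -3, 0.6, -0.15, 0.05, -0.9)
  b["fungi", ] <- c(-1, -2, 3, -0.4, 0.15, -0.03, 0.6)
  b["fb_ratio", ] <- c(-0.8, -1.5, 2, -0.3, 0.1, -0.02, 0.4)
  b["d_nutrients", ] <- c(2.5, 5, -5, 1.0, -0.25, 0.10, -1.8)
  b["d_richness", ] <- c(-1, -2, 2, -0.3, 0.1, -0.03, 0.5)
  b["d_ph", ] <- c(0, 1.5, 0, -0.4, 0, 0.02, -0.4)
  b["d_bacteria", ] <- c(1, 2, -2, 0.4, -0.1, 0.04, -0.7)
  b["d_fungi", ] <- c(-0.7, -1.5, 1.5, -0.25, 0.08, -0.02, 0.4)
  b["d_fb_ratio", ] <- c(-0.5, -1, 1.2, -0.2, 0.06, -0.015, 0.3)
  b
}

#' Ground-truth effect model for the synthetic survey generator
#'
#' Bundles everything the generator needs to build a survey with a known
#' linear trait-environment structure: a 16 x 7 matrix of per-trait slopes
#' on standardized drivers, per-trait baselines and residual SDs, the
#' sampling distribution of the nine directly drawn base drivers (means,
#' SDs and a 9 x 9 correlation matrix), the invasion-induced mean shift on
#' the five paired variables, and the pair-level noise SD. F/B ratio and
#' the six relative-change variables are derived, not drawn, so they carry
#' no sampling distribution of their own.
#'
#' @param effect_matrix 16 x 7 numeric matrix (drivers x traits), slopes in
#'   trait units per standardized-driver SD.
#' @param trait_baselines Named length-7 vector of positive trait intercepts.
#' @param noise_sd Named length-7 vector of positive residual SDs.
#' @param driver_means,driver_sds Named length-9 vectors for the base drivers.
#' @param driver_correlation 9 x 9 positive-definite correlation matrix for
#'   the base drivers.
#' @param invasion_shift Named length-5 vector: mean invaded-minus-uninvaded
#'   shift for richness, pH, nutrients, bacteria, fungi.
#' @param pair_noise_frac Pair-level noise SD as a fraction of each paired
#'   variable's site-level SD.
#' @param cn_mode `"derived"` (default) computes leaf C:N as leaf C / leaf N;
#'   `"direct"` generates it from the 7th effect column like any other trait.
#'
#' @return An object of class `effect_model`.
#' @export
effect_model <- function(effect_matrix = default_effect_matrix(),
                         trait_baselines = c(leaf_area = 60, sla = 180,
                                             ldmc = 250, chlorophyll = 35,
                                             leaf_c = 42, leaf_n = 2.1,
                                             leaf_cn = 20),
                         noise_sd = c(leaf_area = 8, sla = 18, ldmc = 20,
                                      chlorophyll = 3, leaf_c = 1.2,
                                      leaf_n = 0.22, leaf_cn = 2.5),
                         driver_means = c(mat = 16, map = 1400, richness = 12,
                                          evenness = 0.65, ph = 6.5,
                                          texture = 40, nutrients = 60,
                                          bacteria = 50, fungi = 12),
                         driver_sds = c(mat = 2, map = 300, richness = 4,
                                        evenness = 0.12, ph = 0.7,
                                        texture = 12, nutrients = 18,
                                        bacteria = 12, fungi = 2.5),
                         driver_correlation = diag(9),
                         invasion_shift = c(richness = -3, ph = -0.2,
                                            nutrients = 8, bacteria = 5,
                                            fungi = 2),
                         pair_noise_frac = 0.15,
                         cn_mode = c("derived", "direct")) {
  cn_mode <- match.arg(cn_mode)
  effect_matrix <- as.matrix(effect_matrix)
  if (!all(dim(effect_matrix) == c(16, 7)) || any(!is.finite(effect_matrix))) {
    abort("`effect_matrix` must be a finite 16 x 7 matrix.",
          class = "leafspectra_model_error")
  }
  dimnames(effect_matrix) <- list(driver_names(), trait_names())
  trait_baselines <- trait_baselines[trait_names()]
  noise_sd <- noise_sd[trait_names()]
  check_positive(trait_baselines, "trait_baselines")
  if (any(!is.finite(noise_sd)) || any(noise_sd < 0)) {
    abort("`noise_sd` must be nonnegative and finite.",
          class = "leafspectra_model_error")
  }
  driver_means <- driver_means[base_driver_names()]
  driver_sds <- driver_sds[base_driver_names()]
  check_positive(driver_sds, "driver_sds")
  driver_correlation <- as.matrix(driver_correlation)
  if (!all(dim(driver_correlation) == c(9, 9)) ||
      !isTRUE(all.equal(driver_correlation, t(driver_correlation))) ||
      any(abs(diag(driver_correlation) - 1) > 1e-12)) {
    abort("`driver_correlation` must be a symmetric 9 x 9 matrix with unit diagonal.",
          class = "leafspectra_model_error")
  }
  invasion_shift <- invasion_shift[paired_variable_names()]
  if (any(!is.finite(invasion_shift))) {
    abort("`invasion_shift` must be finite for all five paired variables.",
          class = "leafspectra_model_error")
  }
  structure(
    list(effect_matrix = effect_matrix,
         trait_baselines = trait_baselines,
         noise_sd = noise_sd,
         driver_means = driver_means,
         driver_sds = driver_sds,
         driver_correlation = driver_correlation,
         invasion_shift = invasion_shift,
         pair_noise_frac = pair_noise_frac,
         cn_mode = cn_mode),
    class = "effect_model"
  )
}

# Relative change with the both-zero clamp artifact mapped to 0 (a pair
# whose variable is zero in both plots has not changed). The exported
# relative_change() keeps the strict domain guard.
safe_relative_change <- function(vi, vu) {
  tot <- vi + vu
  ifelse(tot == 0, 0, (vi - vu) / ifelse(tot == 0, 1, tot))
}

# Multivariate normal draw via Cholesky; errors if the correlation matrix
# is not positive definite.
draw_base_drivers <- function(n, model) {
  L <- tryCatch(chol(model$driver_correlation), error = function(e) {
    abort("`driver_correlation` is not positive definite.",
          class = "leafspectra_model_error")
  })
  z <- matrix(rnorm(n * 9), nrow = n) %*% L
  x <- sweep(sweep(z, 2, model$driver_sds, `*`), 2, model$driver_means, `+`)
  colnames(x) <- base_driver_names()
  x <- clamp_drivers(x)
  x
}

clamp_drivers <- function(x) {
  nonneg <- intersect(colnames(x), c("richness", "nutrients", "bacteria",
                                     "fungi", "ph"))
  x[, nonneg] <- pmax(x[, nonneg, drop = FALSE], 0)
  if ("evenness" %in% colnames(x)) {
    x[, "evenness"] <- pmin(pmax(x[, "evenness"], 0), 1)
  }
  if ("texture" %in% colnames(x)) {
    x[, "texture"] <- pmin(pmax(x[, "texture"], 0), 100)
  }
  x
}

#' Generate the environment and paired-plot tables of a synthetic survey
#'
#' Site-level base drivers are drawn from the effect model's multivariate
#' Gaussian (MAT and MAP held constant within a location); uninvaded-plot
#' values of the paired variables add pair-level noise around the site
#' value; invaded-plot values add the invasion shift plus pair-level noise.
#' F/B ratio is fungi/bacteria, and the six interaction variables are the
#' paired relative changes of richness, pH, nutrients, bacteria, fungi and
#' F/B ratio (see [relative_change()]).
#'
#' @param design A [survey_design()].
#' @param model An [effect_model()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A list with `environment` (one row per plot pair, 16 driver
#'   columns) and `pairs` (long table of uninvaded/invaded values and
#'   relative changes for the six paired variables).
#' @export
generate_environment <- function(design = survey_design(),
                                 model = effect_model(),
                                 seed = 1L) {
  idx <- generate_design(design)
  sites <- unique(idx$site)
  site_loc <- sub("S\\d+$", "", sites)

  with_seed(stage_seed(seed, "environment"), {
    site_draw <- draw_base_drivers(length(sites), model)
    rownames(site_draw) <- sites
    # climate varies between, not within, locations
    for (cl in c("mat", "map")) {
      first <- !duplicated(site_loc)
      loc_val <- setNames(site_draw[first, cl], site_loc[first])
      site_draw[, cl] <- loc_val[site_loc]
    }

    pv <- paired_variable_names()
    pair_sd <- model$pair_noise_frac * model$driver_sds[pv]
    n_pair <- nrow(idx)
    site_of <- match(idx$site, sites)

    vu <- site_draw[site_of, pv, drop = FALSE] +
      matrix(rnorm(n_pair * length(pv)), n_pair) %*% diag(pair_sd)
    vi <- vu +
      matrix(model$invasion_shift[pv], n_pair, length(pv), byrow = TRUE) +
      matrix(rnorm(n_pair * length(pv)), n_pair) %*% diag(pair_sd)
    colnames(vu) <- colnames(vi) <- pv
    vu <- clamp_drivers(vu)
    vi <- clamp_drivers(vi)

    vu_full <- cbind(vu, fb_ratio = vu[, "fungi"] / pmax(vu[, "bacteria"], 1e-8))
    vi_full <- cbind(vi, fb_ratio = vi[, "fungi"] / pmax(vi[, "bacteria"], 1e-8))

    env <- idx
    for (cl in c("mat", "map", "evenness", "texture")) {
      env[[cl]] <- unname(site_draw[site_of, cl])
    }
    for (v in colnames(vu_full)) {
      env[[v]] <- unname(vu_full[, v])
      env[[paste0("d_", v)]] <- unname(safe_relative_change(vi_full[, v],
                                                            vu_full[, v]))
    }
    env <- env[, c("unit_id", "location", "site", "pair", driver_names())]

    pairs <- tibble(
      unit_id = rep(idx$unit_id, times = ncol(vu_full)),
      variable = rep(colnames(vu_full), each = nrow(idx)),
      uninvaded = as.vector(vu_full),
      invaded = as.vector(vi_full)
    ) |>
      mutate(delta = safe_relative_change(.data$invaded, .data$uninvaded)) |>
      arrange(.data$unit_id, .data$variable)

    list(environment = as_tibble(env), pairs = pairs)
  })
}

#' Generate leaf traits from an environment table and a known effect model
#'
#' Each trait is `baseline + Z b + e`, where `Z` is the within-sample
#' z-scored 16-driver matrix, `b` the trait's effect column and `e`
#' Gaussian noise. Draws that would make a trait nonpositive are resampled
#' (at most 100 attempts per cell) so all traits stay strictly positive.
#' With `cn_mode = "derived"` (default), leaf C:N is computed as
#' leaf C / leaf N so the trait table is internally consistent.
#'
#' @param env Environment table from [generate_environment()].
#' @param model An [effect_model()].
#' @param seed Integer seed.
#' @return A tibble with `unit_id` and the seven trait columns.
#' @export
generate_traits <- function(env, model = effect_model(), seed = 1L) {
  missing_drv <- setdiff(driver_names(), names(env))
  if (length(missing_drv) > 0) {
    abort(paste0("environment table lacks driver columns: ",
                 paste(missing_drv, collapse = ", ")),
          class = "leafspectra_schema_error")
  }
  X <- as.matrix(env[, driver_names()])
  Z <- scale(X)
  Z[is.nan(Z)] <- 0 # constant driver column: no contribution

  with_seed(stage_seed(seed, "traits"), {
    mu <- sweep(Z %*% model$effect_matrix, 2, model$trait_baselines, `+`)
    out <- mu
    gen_traits <- if (model$cn_mode == "derived") {
      setdiff(trait_names(), "leaf_cn")
    } else {
      trait_names()
    }
    for (tr in gen_traits) {
      s <- model$noise_sd[[tr]]
      val <- mu[, tr] + rnorm(nrow(mu), 0, s)
      bad <- which(val <= 0)
      attempt <- 0
      while (length(bad) > 0 && attempt < 100) {
        val[bad] <- mu[bad, tr] + rnorm(length(bad), 0, s)
        bad <- which(val <= 0)
        attempt <- attempt + 1
      }
      if (length(bad) > 0) {
        abort(sprintf("could not draw strictly positive values for trait '%s' (baseline too close to zero).", tr),
              class = "leafspectra_model_error")
      }
      out[, tr] <- val
    }
    if (model$cn_mode == "derived") {
      out[, "leaf_cn"] <- out[, "leaf_c"] / out[, "leaf_n"]
    }
    bind_cols_traits <- as_tibble(as.data.frame(out))
    tibble(unit_id = env$unit_id) |>
      dplyr::bind_cols(bind_cols_traits)
  })
}

#' Simulate a complete paired-plot trait survey
#'
#' Runs [generate_design()], [generate_environment()] and
#' [generate_traits()] under one hierarchically split seed and bundles the
#' results together with the ground-truth effect model.
#'
#' @inheritParams generate_environment
#' @return An object of class `survey_bundle`: a list with `traits`,
#'   `environment`, `pairs`, `ground_truth`, `design` and `seed`.
#' @export
#' @examples
#' sv <- simulate_survey(seed = 7)
#' nrow(sv$traits)
simulate_survey <- function(design = survey_design(),
                            model = effect_model(),
                            seed = 1L) {
  envp <- generate_environment(design, model, seed)
  traits <- generate_traits(envp$environment, model, seed)
  structure(
    list(traits = traits,
         environment = envp$environment,
         pairs = envp$pairs,
         ground_truth = model,
         design = design,
         seed = as.integer(seed)),
    class = "survey_bundle"
  )
}

#' @export
print.survey_bundle <- function(x, ...) {
  cat("<survey_bundle> ", nrow(x$traits), " plot pairs, ",
      length(unique(x$environment$site)), " populations, seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Write or read a survey bundle as plain-text interchange files
#'
#' Writes `traits.csv`, `environment.csv`, `pairs.csv` and
#' `ground_truth.yaml` (effect matrix, baselines, noise SDs, seed) to a
#' directory; `read_survey()` reads the three CSVs back.
#'
#' @param bundle A `survey_bundle`.
#' @param dir Output directory (created if needed).
#' @return `write_survey()` returns `dir` invisibly; `read_survey()` a list
#'   of tibbles.
#' @export
write_survey <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_stable(bundle$traits, file.path(dir, "traits.csv"))
  write_csv_stable(bundle$environment, file.path(dir, "environment.csv"))
  write_csv_stable(bundle$pairs, file.path(dir, "pairs.csv"))
  gt <- bundle$ground_truth
  yaml::write_yaml(
    list(seed = bundle$seed,
         cn_mode = gt$cn_mode,
         trait_baselines = as.list(gt$trait_baselines),
         noise_sd = as.list(gt$noise_sd),
         invasion_shift = as.list(gt$invasion_shift),
         effect_matrix = apply(gt$effect_matrix, 1, as.list, simplify = FALSE)),
    file.path(dir, "ground_truth.yaml")
  )
  invisible(dir)
}

#' @rdname write_survey
#' @export
read_survey <- function(dir) {
  read1 <- function(f) readr::read_csv(file.path(dir, f),
                                       show_col_types = FALSE, progress = FALSE)
  list(traits = read1("traits.csv"),
       environment = read1("environment.csv"),
       pairs = read1("pairs.csv"))
}

#' Aggregate a plot-pair survey to population (site) level
#'
#' Averages all numeric columns within each site, yielding one row per
#' population (66 under the default design).
#'
#' @param df A tibble with a `site` column (traits or environment table
#'   joined with the design index).
#' @return A tibble with one row per site; `unit_id` is the site label.
#' @export
aggregate_to_populations <- function(df) {
  if (!"site" %in% names(df)) {
    abort("`df` must carry a `site` column to aggregate by population.",
          class = "leafspectra_schema_error")
  }
  numcols <- setdiff(names(df)[vapply(df, is.numeric, logical(1))], "pair")
  df |>
    group_by(.data$site) |>
    summarise(across(dplyr::all_of(numcols), mean), .groups = "drop") |>
    rename(unit_id = "site")
}
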