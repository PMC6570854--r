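test_that("design expansion reproduces the stratified pair arithmetic", {
  # default geometry: 22 x 3 sites, 5 x 51 + 3 x 15 pairs
  idx <- generate_design(survey_design())
  expect_equal(nrow(idx), 300)
  expect_equal(length(unique(idx$site)), 66)
  expect_equal(length(unique(idx$location)), 22)

  # single five-pair site
  one <- generate_design(survey_design(1, 1, 1, 0))
  expect_equal(nrow(one), 5)

  # 2 locations x 2 sites, 3 five-pair + 1 three-pair = 18
  small <- generate_design(survey_design(2, 2, 3, 1))
  expect_equal(nrow(small), 18)

  # arbitrary valid configurations follow the arithmetic exactly
  for (cfg in list(c(4, 2, 5, 3), c(3, 3, 0, 9), c(6, 1, 6, 0))) {
    d <- survey_design(cfg[1], cfg[2], cfg[3], cfg[4])
    expect_equal(nrow(generate_design(d)), 5 * cfg[3] + 3 * cfg[4])
  }
})

test_that("inconsistent designs are rejected", {
  expect_error(survey_design(2, 2, 3, 2), class = "leafspectra_design_error")
  expect_error(survey_design(0, 3, 51, 15), class = "leafspectra_design_error")
  expect_error(generate_design(list()), class = "leafspectra_design_error")
})

test_that("identical seeds give identical survey bundles", {
  a <- simulate_survey(seed = 11)
  b <- simulate_survey(seed = 11)
  expect_identical(a$traits, b$traits)
  expect_identical(a$environment, b$environment)
  expect_identical(a$pairs, b$pairs)
  c <- simulate_survey(seed = 12)
  expect_false(identical(a$traits, c$traits))
})

test_that("zero invasion shift and zero pair noise force all deltas to zero", {
  m <- effect_model(invasion_shift = c(richness = 0, ph = 0, nutrients = 0,
                                       bacteria = 0, fungi = 0),
                    pair_noise_frac = 0)
  envp <- generate_environment(survey_design(2, 2, 3, 1), m, seed = 3)
  dcols <- paste0("d_", c(paired_vars <- c("richness", "ph", "nutrients",
                                           "bacteria", "fungi"), "fb_ratio"))
  for (cl in dcols) expect_equal(envp$environment[[cl]], rep(0, 18))
})

test_that("a positive nutrient shift with zero pair noise gives positive delta everywhere", {
  m <- effect_model(invasion_shift = c(richness = 0, ph = 0, nutrients = 8,
                                       bacteria = 0, fungi = 0),
                    pair_noise_frac = 0)
  envp <- generate_environment(model = m, seed = 5)
  expect_true(all(envp$environment$d_nutrients > 0))
  expect_equal(envp$environment$d_richness, rep(0, 300))
})

test_that("zero-noise traits equal the linear predictor to round-off", {
  m <- effect_model(noise_sd = setNames(rep(0, 7), names(effect_model()$noise_sd)))
  envp <- generate_environment(model = m, seed = 9)
  traits <- generate_traits(envp$environment, m, seed = 9)
  Z <- scale(as.matrix(envp$environment[, leafspectra:::driver_names()]))
  mu <- sweep(Z %*% m$effect_matrix, 2, m$trait_baselines, `+`)
  for (tr in setdiff(names(m$trait_baselines), "leaf_cn")) {
    expect_lt(max(abs(traits[[tr]] - mu[, tr]) / mu[, tr]), 1e-10)
  }
  expect_lt(max(abs(traits$leaf_cn - traits$leaf_c / traits$leaf_n)), 1e-12)
})

test_that("a null effect matrix with zero noise yields constant baselines", {
  m <- effect_model(effect_matrix = matrix(0, 16, 7),
                    noise_sd = setNames(rep(0, 7), names(effect_model()$noise_sd)))
  envp <- generate_environment(model = m, seed = 2)
  traits <- generate_traits(envp$environment, m, seed = 2)
  expect_equal(unique(traits$sla), unname(m$trait_baselines[["sla"]]))
  expect_equal(unique(traits$ldmc), unname(m$trait_baselines[["ldmc"]]))
})

test_that("a single nonzero slope with zero noise gives perfect driver-trait correlation", {
  B <- matrix(0, 16, 7)
  rownames(B) <- leafspectra:::driver_names()
  colnames(B) <- leafspectra:::trait_names()
  B["nutrients", "sla"] <- 12
  m <- effect_model(effect_matrix = B,
                    noise_sd = setNames(rep(0, 7), leafspectra:::trait_names()))
  envp <- generate_environment(model = m, seed = 4)
  traits <- generate_traits(envp$environment, m, seed = 4)
  expect_equal(abs(cor(traits$sla, envp$environment$nutrients)), 1,
               tolerance = 1e-10)
})

test_that("all generated traits are strictly positive", {
  sv <- simulate_survey(seed = 21)
  for (tr in leafspectra:::trait_names()) expect_true(all(sv$traits[[tr]] > 0))
})

test_that("empirical base-driver correlations converge to the target matrix", {
  R <- diag(9)
  R[1, 2] <- R[2, 1] <- 0.5   # MAT-MAP
  R[7, 5] <- R[5, 7] <- -0.3  # nutrients-pH
  m <- effect_model(driver_correlation = R)
  x <- leafspectra:::with_seed(99, leafspectra:::draw_base_drivers(6000, m))
  emp <- cor(x)
  expect_lt(max(abs(emp - R)), 0.05)
})

test_that("a non-positive-definite driver correlation is rejected", {
  R <- diag(9)
  R[1, 2] <- R[2, 1] <- 1.2
  expect_error(generate_environment(model = effect_model(driver_correlation = R)),
               class = "leafspectra_model_error")
  expect_error(effect_model(driver_correlation = matrix(0.5, 9, 9)),
               class = "leafspectra_model_error")
})

test_that("survey bundles round-trip through CSV within float formatting", {
  sv <- simulate_survey(survey_design(2, 2, 3, 1), seed = 13)
  dir <- withr::local_tempdir()
  write_survey(sv, dir)
  expect_setequal(list.files(dir), c("traits.csv", "environment.csv",
                                     "pairs.csv", "ground_truth.yaml"))
  back <- read_survey(dir)
  expect_equal(as.data.frame(back$traits), as.data.frame(sv$traits),
               tolerance = 1e-9)
  expect_equal(as.data.frame(back$environment), as.data.frame(sv$environment),
               tolerance = 1e-9)
})

test_that("population aggregation averages pairs within sites", {
  sv <- simulate_survey(seed = 6)
  env_pop <- aggregate_to_populations(sv$environment)
  expect_equal(nrow(env_pop), 66)
  s1 <- sv$environment[sv$environment$site == "L01S1", ]
  expect_equal(env_pop$nutrients[env_pop$unit_id == "L01S1"],
               mean(s1$nutrients))
})
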