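#' Predictor schema for the 16-driver attribution analysis
#'
#' Names the 16 environmental drivers, their category (climate, diversity,
#' soil, interactions) and a biotic flag. Defaults: climate = MAT, MAP;
#' diversity = richness, evenness; soil = pH, texture, nutrients,
#' bacteria, fungi, F/B ratio; interactions = the six paired relative
#' changes. The biotic flag marks richness, evenness, bacteria, fungi,
#' F/B ratio and all six interaction variables as biotic (11 of 16).
#'
#' @param terms Character vector of predictor names.
#' @param category Per-predictor category labels.
#' @param biotic Per-predictor logical flags.
#' @return A tibble with columns `term`, `category`, `biotic`.
#' @export
predictor_schema <- function(terms = driver_names(),
                             category = NULL,
                             biotic = NULL) {
  if (is.null(category)) {
    category <- c(mat = "climate", map = "climate",
                  richness = "diversity", evenness = "diversity",
                  ph = "soil", texture = "soil", nutrients = "soil",
                  bacteria = "soil", fungi = "soil", fb_ratio = "soil",
                  d_richness = "interactions", d_ph = "interactions",
                  d_nutrients = "interactions", d_bacteria = "interactions",
                  d_fungi = "interactions", d_fb_ratio = "interactions")[terms]
    category[is.na(category)] <- "other"
  }
  if (is.null(biotic)) {
    abiotic_default <- c("mat", "map", "ph", "texture", "nutrients")
    biotic <- !(terms %in% abiotic_default)
  }
  if (anyDuplicated(terms)) {
    abort("predictor names must be unique.", class = "leafspectra_schema_error")
  }
  tibble(term = terms, category = unname(category), biotic = biotic)
}

#' Standardize predictor columns
#'
#' Centers each predictor to mean zero and scales it to unit SD so
#' model-averaged coefficients are comparable across drivers. The centers
#' and scales are retained as attributes for back-transformation.
#'
#' @param data Data frame holding the predictors.
#' @param terms Predictor column names; defaults to all 16 drivers.
#' @return A tibble of standardized predictors with attributes `center`
#'   and `scale`.
#' @export
standardize_predictors <- function(data, terms = intersect(driver_names(), names(data))) {
  missing_cols <- setdiff(terms, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing predictor column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "leafspectra_schema_error")
  }
  X <- as.matrix(data[, terms])
  if (any(!is.finite(X))) {
    abort("predictors must be finite.", class = "leafspectra_domain_error")
  }
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance predictor column(s): ",
                 paste(terms[sds == 0], collapse = ", ")),
          class = "leafspectra_degenerate_error")
  }
  Z <- scale(X)
  out <- as_tibble(as.data.frame(Z))
  attr(out, "center") <- attr(Z, "scaled:center")
  attr(out, "scale") <- attr(Z, "scaled:scale")
  out
}

#' Second-order Akaike information criterion for least squares
#'
#' `AICc = n log(RSS/n) + 2k + 2k(k+1)/(n - k - 1)`, the Gaussian
#' maximum-likelihood form with the small-sample correction; `k` counts
#' the estimated parameters (regression coefficients including the
#' intercept, plus the residual variance).
#'
#' @param n Sample size.
#' @param k Number of estimated parameters.
#' @param rss Residual sum of squares, strictly positive.
#' @return The AICc value. Vectorized over `k` and `rss`.
#' @export
#' @examples
#' aicc(20, 3, 20) # 7.5
aicc <- function(n, k, rss) {
  if (any(n - k - 1 <= 0)) {
    abort("AICc requires n - k - 1 > 0.",
          class = "leafspectra_small_sample_error")
  }
  if (any(rss <= 0)) {
    abort("AICc is degenerate for rss <= 0.",
          class = "leafspectra_degenerate_error")
  }
  n * base::log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Least-squares fit of one predictor subset
#'
#' Ordinary least squares (with intercept) of `y` on the columns of `X`
#' selected by `mask`. The empty subset gives the intercept-only model,
#' whose RSS is the total sum of squares about the mean.
#'
#' @param X Numeric predictor matrix (or data frame).
#' @param y Response vector.
#' @param mask Logical vector over columns of `X`, or integer column
#'   indices.
#' @return A list with `coefficients` (named, intercept first) and `rss`.
#' @export
fit_subset <- function(X, y, mask) {
  X <- as.matrix(X)
  if (is.logical(mask)) mask <- which(mask)
  n <- length(y)
  if (n <= length(mask) + 2) {
    abort("need n > subset size + 2.",
          class = "leafspectra_small_sample_error")
  }
  M <- cbind(`(Intercept)` = 1, X[, mask, drop = FALSE])
  qr_m <- qr(M)
  if (qr_m$rank < ncol(M)) {
    abort("rank-deficient predictor subset.",
          class = "leafspectra_singular_error")
  }
  beta <- qr.coef(qr_m, y)
  res <- y - M %*% beta
  list(coefficients = setNames(as.vector(beta), colnames(M)),
       rss = sum(res^2))
}

#' Exhaustively fit all predictor subsets and rank them by AICc
#'
#' Fits every one of the `2^p` candidate OLS models (each including an
#' intercept) and ranks them by the small-sample AICc; ties are broken by
#' the subset bitmask so the ordering is deterministic. Akaike weights are
#' attached with [akaike_weights()]. Subsets too large for the AICc
#' denominator (`n - k - 1 <= 0`) are skipped with a warning. The heavy
#' lifting runs in compiled code from precomputed Gram matrices.
#'
#' @param X Standardized predictor matrix or data frame (see
#'   [standardize_predictors()]).
#' @param y Response vector with positive variance.
#' @return An object of class `model_set`: tibble `models` (mask, terms,
#'   k, rss, aicc, delta_aicc, weight, sorted by AICc), coefficient and SE
#'   matrices aligned with `models`, `n`, `p`, `terms`.
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
#' ms <- enumerate_models(X, rnorm(40))
#' nrow(ms$models) # 4
enumerate_models <- function(X, y) {
  X <- as.matrix(X)
  p <- ncol(X)
  n <- length(y)
  if (nrow(X) != n) {
    abort("X and y sizes disagree.", class = "leafspectra_schema_error")
  }
  if (var(y) == 0) {
    abort("response has zero variance.",
          class = "leafspectra_degenerate_error")
  }
  terms <- colnames(X) %||% paste0("x", seq_len(p))
  colnames(X) <- terms

  M <- cbind(1, X)
  G <- crossprod(M)
  v <- crossprod(M, y)
  fits <- all_subsets_ols(G, as.vector(v), sum(y^2))

  masks <- 0:(2^p - 1)
  ksub <- integer(length(masks))
  tstr <- character(length(masks))
  for (j in seq_len(p)) {
    has <- bitwAnd(masks, bitwShiftL(1L, j - 1L)) != 0
    ksub[has] <- ksub[has] + 1L
    tstr[has] <- ifelse(tstr[has] == "", terms[j],
                        paste0(tstr[has], "+", terms[j]))
  }
  k <- ksub + 2L
  rss <- as.vector(fits$rss)

  ok <- rep(TRUE, length(masks))
  if (any(n - k - 1 <= 0)) {
    warn(sprintf("skipping %d subset(s) with n - k - 1 <= 0.",
                 sum(n - k - 1 <= 0)))
    ok <- ok & (n - k - 1 > 0)
  }
  if (anyNA(rss)) {
    warn(sprintf("skipping %d rank-deficient subset(s).", sum(is.na(rss))))
    ok <- ok & !is.na(rss)
  }
  if (any(rss[ok] <= 0)) {
    warn(sprintf("skipping %d perfect-fit subset(s) (rss = 0).",
                 sum(rss[ok] <= 0)))
    ok[ok] <- rss[ok] > 0
  }

  aicc_val <- rep(NA_real_, length(masks))
  aicc_val[ok] <- aicc(n, k[ok], rss[ok])
  ord <- order(aicc_val, masks, na.last = NA)

  # classical per-model coefficient SEs: sigma2 = rss / (n - n_coef)
  sigma2 <- rss / (n - (ksub + 1L))
  se <- sqrt(pmax(fits$dinv * sigma2, 0))

  models <- tibble(
    mask = masks[ord],
    terms = tstr[ord],
    k = k[ord],
    rss = rss[ord],
    aicc = aicc_val[ord]
  )

  ms <- structure(
    list(models = models,
         coef = fits$coef[ord, , drop = FALSE],
         se = se[ord, , drop = FALSE],
         n = n, p = p, terms = terms),
    class = "model_set"
  )
  akaike_weights(ms)
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("<model_set> %d candidate models over %d predictors (n = %d)\n",
              nrow(x$models), x$p, x$n))
  print(head(x$models, 5))
  invisible(x)
}

#' Akaike weights of a candidate model set
#'
#' Adds `delta_aicc` (AICc above the best model) and the normalized
#' Akaike weights `exp(-delta/2) / sum(exp(-delta/2))`.
#'
#' @param ms A `model_set` from [enumerate_models()].
#' @return The `model_set` with `delta_aicc` and `weight` columns.
#' @export
akaike_weights <- function(ms) {
  d <- ms$models$aicc - min(ms$models$aicc)
  w <- exp(-d / 2)
  ms$models$delta_aicc <- d
  ms$models$weight <- w / sum(w)
  ms
}

#' 95% cumulative-weight confidence set of models
#'
#' The smallest AICc-ordered prefix of the candidate set whose cumulative
#' Akaike weight reaches `level` (the crossing model is included). This
#' prefix is the pool over which coefficients are averaged.
#'
#' @param ms A `model_set` with weights.
#' @param level Cumulative weight level in (0, 1].
#' @return A `model_set` restricted to the confidence set, with attribute
#'   `cumulative_weight`.
#' @export
confidence_set <- function(ms, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level > 1) {
    abort("`level` must lie in (0, 1].", class = "leafspectra_parameter_error")
  }
  cw <- cumsum(ms$models$weight)
  m <- which(cw >= level - 1e-12)[1]
  if (is.na(m)) m <- nrow(ms$models)
  keep <- seq_len(m)
  out <- ms
  out$models <- ms$models[keep, ]
  out$coef <- ms$coef[keep, , drop = FALSE]
  out$se <- ms$se[keep, , drop = FALSE]
  attr(out, "cumulative_weight") <- cw[m]
  attr(out, "level") <- level
  out
}

#' Model-averaged coefficients over a confidence set
#'
#' Full (zero-substituted) model averaging: each predictor's estimate is
#' the renormalized-weight sum of its coefficient over all models of the
#' set, counting 0 where the predictor is absent. The unconditional SE
#' combines within-model variance and between-model spread,
#' `sqrt(sum w (se^2 + (b - bbar)^2))`; z = estimate/SE with a two-sided
#' normal p-value. `conditional = TRUE` averages only over the models
#' containing each predictor.
#'
#' @param cs A confidence-set `model_set` (see [confidence_set()]).
#' @param conditional Average only over models containing the term.
#' @return A tibble: `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`, `sign`; attributes `confidence_set_size` and
#'   `cumulative_weight`.
#' @export
average_coefficients <- function(cs, conditional = FALSE) {
  if (nrow(cs$models) == 0) {
    abort("empty confidence set.", class = "leafspectra_internal_error")
  }
  w <- cs$models$weight
  w <- w / sum(w)
  B <- cs$coef[, -1, drop = FALSE] # drop intercept column
  S <- cs$se[, -1, drop = FALSE]
  present <- outer(cs$models$mask, seq_len(cs$p),
                   function(m, j) bitwAnd(m, bitwShiftL(1L, j - 1L)) != 0)

  est <- se <- numeric(cs$p)
  for (j in seq_len(cs$p)) {
    if (conditional) {
      inj <- present[, j]
      if (!any(inj)) {
        est[j] <- 0
        se[j] <- 0
        next
      }
      wj <- w[inj] / sum(w[inj])
      bj <- B[inj, j]
      sj <- S[inj, j]
    } else {
      wj <- w
      bj <- B[, j]
      sj <- S[, j]
    }
    est[j] <- sum(wj * bj)
    se[j] <- sqrt(sum(wj * (sj^2 + (bj - est[j])^2)))
  }
  z <- ifelse(se > 0, est / se, 0)
  pval <- ifelse(se > 0, 2 * pnorm(-abs(z)), 1)
  out <- tibble(
    term = cs$terms,
    estimate = est,
    std_error = se,
    statistic = z,
    p_value = pval,
    sign = dplyr::case_when(est > 0 ~ "+", est < 0 ~ "-", TRUE ~ "0")
  )
  attr(out, "confidence_set_size") <- nrow(cs$models)
  attr(out, "cumulative_weight") <- attr(cs, "cumulative_weight") %||% sum(cs$models$weight)
  out
}

#' Summed-Akaike-weight variable importance
#'
#' The importance of a predictor is the sum of the Akaike weights of all
#' candidate models that contain it, computed over the full model set.
#'
#' @param ms A `model_set` with weights.
#' @return A tibble `term`, `importance` (each in \[0, 1\]).
#' @export
variable_importance <- function(ms) {
  w <- ms$models$weight
  imp <- vapply(seq_len(ms$p), function(j) {
    sum(w[bitwAnd(ms$models$mask, bitwShiftL(1L, j - 1L)) != 0])
  }, 0)
  tibble(term = ms$terms, importance = imp)
}

significance_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Relative, per-category and per-capita contributions
#'
#' Converts summed-weight importances into the contribution decomposition:
#' each predictor's relative contribution is its importance divided by the
#' total importance of all predictors (in percent, summing to 100); each
#' category's total is the sum over its members and its per-capita
#' contribution the total divided by the member count; biotic and abiotic
#' totals follow the schema's biotic flag. Signs and significance stars
#' are attached from the averaged coefficients when supplied.
#'
#' @param importance Tibble `term`, `importance` from
#'   [variable_importance()].
#' @param schema Predictor schema, see [predictor_schema()].
#' @param coefficients Optional averaged-coefficient tibble from
#'   [average_coefficients()].
#' @return An object of class `contribution_table`: `predictors` (term,
#'   category, biotic, importance, contribution, sign, stars, estimate,
#'   p_value), `categories` (category, total, n_members, per_capita),
#'   `biotic_total`, `abiotic_total`.
#' @export
relative_contributions <- function(importance, schema = predictor_schema(),
                                   coefficients = NULL) {
  tab <- importance |> left_join(schema, by = "term")
  if (anyNA(tab$category)) {
    abort("schema does not cover all predictors.",
          class = "leafspectra_schema_error")
  }
  total <- sum(tab$importance)
  if (total <= 0) {
    abort("all importances are zero.",
          class = "leafspectra_degenerate_error")
  }
  tab$contribution <- 100 * tab$importance / total
  if (!is.null(coefficients)) {
    tab <- tab |>
      left_join(select(coefficients, "term", "estimate", "p_value", "sign"),
                by = "term") |>
      mutate(stars = significance_stars(.data$p_value))
  } else {
    tab$estimate <- NA_real_
    tab$p_value <- NA_real_
    tab$sign <- NA_character_
    tab$stars <- NA_character_
  }
  cats <- tab |>
    group_by(.data$category) |>
    summarise(total = sum(.data$contribution), n_members = dplyr::n(),
              .groups = "drop") |>
    mutate(per_capita = .data$total / .data$n_members) |>
    arrange(desc(.data$per_capita))
  structure(
    list(predictors = select(tab, "term", "category", "biotic", "importance",
                             "contribution", "sign", "stars", "estimate",
                             "p_value"),
         categories = cats,
         biotic_total = sum(tab$contribution[tab$biotic]),
         abiotic_total = sum(tab$contribution[!tab$biotic])),
    class = "contribution_table"
  )
}

#' @export
print.contribution_table <- function(x, ...) {
  cat("<contribution_table>\n")
  print(x$categories)
  cat(sprintf("biotic %.1f%% vs abiotic %.1f%%\n",
              x$biotic_total, x$abiotic_total))
  invisible(x)
}

#' @rdname relative_contributions
#' @param x A `contribution_table`.
#' @param ... Unused.
#' @export
tidy.contribution_table <- function(x, ...) {
  x$predictors
}

#' Multimodel inference of trait-environment drivers
#'
#' The full attribution chain for one response: standardize the
#' predictors, exhaustively fit all `2^p` candidate OLS models, rank them
#' by AICc, form the cumulative-weight confidence set, average
#' coefficients over it (zero-substituted), compute summed-weight variable
#' importances over the full set, and decompose them into relative,
#' category and per-capita contributions.
#'
#' @param data Data frame holding the response and predictor columns.
#' @param response Response column name (string), or a numeric vector.
#' @param schema Predictor schema; its `term` column names the predictors.
#' @param level Cumulative-weight level of the averaging set.
#' @param conditional Use conditional instead of full averaging.
#' @return An object of class `mmi_fit` with elements `model_set`,
#'   `confidence_set`, `coefficients`, `importance`, `contributions`,
#'   `response`, `schema`, `level`.
#' @export
#' @examples
#' sv <- simulate_survey(seed = 1)
#' dat <- dplyr::bind_cols(sv$environment,
#'                         trait_indices(sv$traits)["spectrum_ratio"])
#' fit <- mmi(dat, "spectrum_ratio",
#'            schema = predictor_schema(c("mat", "map", "nutrients", "ph")))
#' tidy(fit)
mmi <- function(data, response, schema = predictor_schema(), level = 0.95,
                conditional = FALSE) {
  if (is.character(response)) {
    if (!response %in% names(data)) {
      abort(sprintf("response column '%s' not found.", response),
            class = "leafspectra_schema_error")
    }
    y <- data[[response]]
    resp_name <- response
  } else {
    y <- response
    resp_name <- "response"
  }
  Z <- standardize_predictors(data, schema$term)
  ms <- enumerate_models(as.matrix(Z), y)
  cs <- confidence_set(ms, level)
  coefs <- average_coefficients(cs, conditional = conditional)
  imp <- variable_importance(ms)
  contrib <- relative_contributions(imp, schema, coefs)
  structure(
    list(model_set = ms, confidence_set = cs, coefficients = coefs,
         importance = imp, contributions = contrib, response = resp_name,
         schema = schema, level = level),
    class = "mmi_fit"
  )
}

#' @export
print.mmi_fit <- function(x, ...) {
  cat(sprintf("<mmi_fit> response '%s': %d models over %d predictors (n = %d)\n",
              x$response, nrow(x$model_set$models), x$model_set$p,
              x$model_set$n))
  cat(sprintf("confidence set: %d models (cumulative weight %.3f)\n",
              nrow(x$confidence_set$models),
              attr(x$confidence_set, "cumulative_weight")))
  print(x$contributions)
  invisible(x)
}

#' @rdname mmi
#' @param x,object An `mmi_fit`.
#' @param ... Unused.
#' @export
tidy.mmi_fit <- function(x, ...) {
  x$coefficients |>
    left_join(x$importance, by = "term") |>
    left_join(select(x$contributions$predictors, "term", "category",
                     "contribution", "stars"),
              by = "term")
}

#' @rdname mmi
#' @export
glance.mmi_fit <- function(x, ...) {
  tibble(
    response = x$response,
    n = x$model_set$n,
    p = x$model_set$p,
    n_models = nrow(x$model_set$models),
    best_aicc = x$model_set$models$aicc[1],
    confidence_set_size = nrow(x$confidence_set$models),
    cumulative_weight = attr(x$confidence_set, "cumulative_weight"),
    biotic_total = x$contributions$biotic_total,
    abiotic_total = x$contributions$abiotic_total
  )
}

#' @rdname mmi
#' @export
autoplot.mmi_fit <- function(object, ...) {
  d <- tidy(object) |>
    mutate(signed = ifelse(.data$sign == "-", -1, 1) * .data$contribution,
           term = factor(.data$term, levels = rev(object$schema$term)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$signed, y = .data$term,
                                  fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), hjust = -0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "signed relative contribution (%)", y = NULL,
                  title = object$response) +
    ggplot2::theme_minimal()
}
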