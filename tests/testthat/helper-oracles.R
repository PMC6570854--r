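# Independent brute-force implementations used as oracles. Everything here
# is written directly against the published formulas and base R (lm, qr),
# never against the package's own fitting path.

oracle_aicc <- function(n, k, rss) {
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# All-subsets OLS via lm(), one refit per subset.
oracle_enumerate <- function(X, y) {
  X <- as.matrix(X)
  p <- ncol(X)
  n <- length(y)
  terms <- colnames(X)
  masks <- 0:(2^p - 1)
  rows <- lapply(masks, function(m) {
    sel <- which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) != 0)
    df <- data.frame(y = y, X[, sel, drop = FALSE])
    fit <- lm(y ~ ., data = df)
    sm <- summary(fit)
    k <- length(sel) + 2
    co <- stats::coef(sm)
    est <- se <- setNames(numeric(p), terms)
    if (length(sel) > 0) {
      est[terms[sel]] <- co[-1, "Estimate"]
      se[terms[sel]] <- co[-1, "Std. Error"]
    }
    list(mask = m, k = k, rss = sum(stats::residuals(fit)^2),
         est = est, se = se)
  })
  aicc_v <- vapply(rows, function(r) oracle_aicc(n, r$k, r$rss), 0)
  ord <- order(aicc_v, masks)
  rows <- rows[ord]
  aicc_v <- aicc_v[ord]
  d <- aicc_v - min(aicc_v)
  w <- exp(-d / 2)
  w <- w / sum(w)
  list(rows = rows, aicc = aicc_v, delta = d, weight = w, terms = terms,
       n = n, p = p)
}

# Cumulative-weight prefix, renormalized zero-substituted averaging,
# importance sums and contribution normalization, all by direct summation.
oracle_chain <- function(X, y, level = 0.95) {
  or <- oracle_enumerate(X, y)
  m <- which(cumsum(or$weight) >= level - 1e-12)[1]
  wset <- or$weight[1:m] / sum(or$weight[1:m])
  est <- se <- setNames(numeric(or$p), or$terms)
  for (j in seq_len(or$p)) {
    bj <- vapply(or$rows[1:m], function(r) r$est[j], 0)
    sj <- vapply(or$rows[1:m], function(r) r$se[j], 0)
    est[j] <- sum(wset * bj)
    se[j] <- sqrt(sum(wset * (sj^2 + (bj - est[j])^2)))
  }
  imp <- setNames(numeric(or$p), or$terms)
  for (j in seq_len(or$p)) {
    has <- vapply(or$rows, function(r) bitwAnd(r$mask, bitwShiftL(1L, j - 1L)) != 0,
                  logical(1))
    imp[j] <- sum(or$weight[has])
  }
  list(enumeration = or, set_size = m, estimate = est, se = se,
       importance = imp, contribution = 100 * imp / sum(imp))
}

# Validity check of a compact letter display against a pairwise
# "not significantly different" matrix: groups share a letter iff nsd.
cld_valid <- function(letters_vec, nsd) {
  k <- length(letters_vec)
  sets <- strsplit(letters_vec, "")
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      share <- length(intersect(sets[[i]], sets[[j]])) > 0
      if (share != nsd[i, j]) return(FALSE)
    }
  }
  all(nchar(letters_vec) > 0)
}

# Small random design helper for oracle comparisons.
random_instance <- function(n, p, seed, signal = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  X <- scale(X)
  y <- if (is.null(signal)) rnorm(n) else as.vector(X %*% signal) + rnorm(n)
  list(X = X, y = y)
}

# Seven-trait toy table with strictly positive values.
toy_traits <- function(n = 20, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    unit_id = sprintf("U%02d", 1:n),
    leaf_area = runif(n, 20, 80),
    sla = runif(n, 100, 250),
    ldmc = runif(n, 150, 350),
    chlorophyll = runif(n, 20, 50),
    leaf_c = runif(n, 38, 48),
    leaf_n = runif(n, 1.2, 3.2)
  ) |>
    dplyr::mutate(leaf_cn = leaf_c / leaf_n)
}
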