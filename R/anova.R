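#' One-way ANOVA with Tukey HSD compact letter display
#'
#' Compares the phenotypic variation index across traits (or any grouped
#' values) with a one-way ANOVA, runs Tukey HSD all-pairs comparisons at
#' `alpha`, and summarises the pairwise significance pattern as a compact
#' letter display: groups sharing a letter are not significantly
#' different.
#'
#' @param data Long-format data frame.
#' @param value,group Column names (strings) of the response and the
#'   grouping factor; defaults fit the output of [pvi_long()].
#' @param alpha Significance level for the pairwise comparisons.
#' @return An object of class `pvi_anova`: `summary` (tibble: group, mean,
#'   se, n, letter, ordered by decreasing mean), `f_statistic`, `p_value`,
#'   `tukey` (pairwise tibble), `alpha`.
#' @export
#' @examples
#' sv <- simulate_survey(seed = 1)
#' fit <- pvi_anova(pvi_long(trait_indices(sv$traits)))
#' fit$summary
pvi_anova <- function(data, value = "pvi", group = "trait", alpha = 0.05) {
  if (!all(c(value, group) %in% names(data))) {
    abort("`data` must contain the value and group columns.",
          class = "leafspectra_schema_error")
  }
  df <- tibble(y = data[[value]], g = factor(data[[group]]))
  df <- df[is.finite(df$y), ]
  sizes <- table(df$g)
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort("need >= 2 groups with >= 2 observations each.",
          class = "leafspectra_sample_size_error")
  }
  fit <- aov(y ~ g, data = df)
  ftab <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
  tukey <- tibble(
    group1 = vapply(cmp, `[`, "", 1),
    group2 = vapply(cmp, `[`, "", 2),
    diff = tk[, "diff"],
    p_adj = tk[, "p adj"]
  )

  groups <- levels(df$g)
  k <- length(groups)
  # pairwise "not significantly different" adjacency
  nsd <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(tukey))) {
    sig <- tukey$p_adj[i] < alpha
    nsd[tukey$group1[i], tukey$group2[i]] <- !sig
    nsd[tukey$group2[i], tukey$group1[i]] <- !sig
  }

  means <- df |>
    group_by(.data$g) |>
    summarise(mean = mean(.data$y), se = sd(.data$y) / sqrt(dplyr::n()),
              n = dplyr::n(), .groups = "drop") |>
    arrange(desc(.data$mean))
  ord <- as.character(means$g)
  letters_vec <- compact_letters(nsd[ord, ord, drop = FALSE])

  structure(
    list(summary = tibble(group = ord, mean = means$mean, se = means$se,
                          n = means$n, letter = letters_vec),
         f_statistic = ftab[["F value"]][1],
         p_value = ftab[["Pr(>F)"]][1],
         tukey = tukey,
         alpha = alpha),
    class = "pvi_anova"
  )
}

# Compact letter display as a minimal clique edge cover of the
# "not significantly different" graph. Exact for up to 12 groups
# (exhaustive cover over maximal cliques), which comfortably covers the
# seven-trait case; beyond that a greedy cover is used. Groups must be
# supplied ordered (typically by decreasing mean); letters are assigned in
# that order.
compact_letters <- function(nsd) {
  k <- nrow(nsd)
  if (k == 1) return("a")
  cliques <- maximal_cliques(nsd)
  edges <- which(nsd & upper.tri(nsd), arr.ind = TRUE)
  cover <- if (k <= 12) {
    minimal_clique_cover(cliques, edges, k)
  } else {
    greedy_clique_cover(cliques, edges, k)
  }
  # order cliques by their first member so letters read top-down
  cover <- cover[order(vapply(cover, min, 1L))]
  out <- character(k)
  for (ci in seq_along(cover)) {
    lab <- letters[(ci - 1) %% 26 + 1]
    if (ci > 26) lab <- paste0(lab, (ci - 1) %/% 26)
    for (v in cover[[ci]]) out[v] <- paste0(out[v], lab)
  }
  out
}

# Bron-Kerbosch (no pivot; fine at these sizes) over the logical adjacency
# matrix, self-loops ignored.
maximal_cliques <- function(adj) {
  k <- nrow(adj)
  diag(adj) <- FALSE
  res <- list()
  bk <- function(R, P, X) {
    if (length(P) == 0 && length(X) == 0) {
      res[[length(res) + 1]] <<- sort(R)
      return(invisible())
    }
    for (v in P) {
      nv <- which(adj[v, ])
      bk(c(R, v), intersect(P, nv), intersect(X, nv))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(k), integer(0))
  res
}

cover_valid <- function(chosen, cliques, edges, k) {
  covered_v <- unique(unlist(cliques[chosen]))
  if (length(setdiff(seq_len(k), covered_v)) > 0) return(FALSE)
  if (nrow(edges) == 0) return(TRUE)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]
    j <- edges[e, 2]
    hit <- any(vapply(cliques[chosen],
                      function(cl) i %in% cl && j %in% cl, logical(1)))
    if (!hit) return(FALSE)
  }
  TRUE
}

minimal_clique_cover <- function(cliques, edges, k) {
  m <- length(cliques)
  for (size in seq_len(m)) {
    combos <- utils::combn(m, size, simplify = FALSE)
    for (chosen in combos) {
      if (cover_valid(chosen, cliques, edges, k)) return(cliques[chosen])
    }
  }
  cliques
}

greedy_clique_cover <- function(cliques, edges, k) {
  chosen <- integer(0)
  repeat {
    if (cover_valid(chosen, cliques, edges, k)) break
    remaining <- setdiff(seq_along(cliques), chosen)
    gain <- vapply(remaining, function(ci) {
      cover_gain(c(chosen, ci), chosen, cliques, edges, k)
    }, numeric(1))
    chosen <- c(chosen, remaining[which.max(gain)])
  }
  cliques[chosen]
}

cover_gain <- function(new, old, cliques, edges, k) {
  count <- function(sel) {
    cv <- length(unique(unlist(cliques[sel])))
    ce <- if (nrow(edges) == 0) 0 else sum(vapply(seq_len(nrow(edges)), function(e) {
      any(vapply(cliques[sel], function(cl)
        edges[e, 1] %in% cl && edges[e, 2] %in% cl, logical(1)))
    }, logical(1)))
    cv + ce
  }
  count(new) - count(old)
}

#' @export
print.pvi_anova <- function(x, ...) {
  cat(sprintf("<pvi_anova> F = %.3f, p = %.3g (alpha = %g)\n",
              x$f_statistic, x$p_value, x$alpha))
  print(x$summary)
  invisible(x)
}

#' @rdname pvi_anova
#' @param x,object A `pvi_anova` object.
#' @param ... Unused.
#' @export
tidy.pvi_anova <- function(x, ...) {
  x$summary
}

#' @rdname pvi_anova
#' @export
glance.pvi_anova <- function(x, ...) {
  tibble(f.statistic = x$f_statistic, p.value = x$p_value,
         n.groups = nrow(x$summary), alpha = x$alpha)
}

#' @rdname pvi_anova
#' @param data_long The long-format data used for the fit (for the boxes);
#'   when `NULL` only means and letters are drawn.
#' @export
autoplot.pvi_anova <- function(object, data_long = NULL, ...) {
  s <- object$summary |>
    mutate(group = factor(.data$group, levels = .data$group))
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$group, y = .data$mean))
  p +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$letter,
                                    y = .data$mean + 3 * .data$se),
                       vjust = 0) +
    ggplot2::labs(x = NULL, y = "mean value") +
    ggplot2::theme_minimal()
}
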