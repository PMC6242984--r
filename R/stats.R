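# By-items inferential statistics: one-way and split-plot ANOVAs with partial
# eta squared, single-step Bonferroni pairwise contrasts, and compact letter
# displays mirroring superscript-letter table notation.

#' One-way between-groups ANOVA with partial eta squared
#'
#' Standard between/within sum-of-squares decomposition via [stats::lm()].
#' Partial eta squared is SS_effect / (SS_effect + SS_error). When every
#' group has zero variance and equal means, F is defined as 0.
#'
#' @param values Numeric response vector.
#' @param groups Grouping labels, same length.
#' @return List of class `anova_result`: `F`, `df_num`, `df_den`, `p`,
#'   `partial_eta_sq`, plus `ms_error`, `df_error`, `means` and `n` for
#'   downstream contrasts.
#' @export
oneway_anova <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  if (length(unique(groups)) < 2) {
    stop("need at least two groups", call. = FALSE)
  }
  if (any(table(groups) < 2)) {
    stop("need at least two values per group", call. = FALSE)
  }
  fit <- suppressWarnings(stats::anova(stats::lm(values ~ factor(groups))))
  ss_b <- fit$`Sum Sq`[1]; ss_e <- fit$`Sum Sq`[2]
  df_b <- fit$Df[1]; df_e <- fit$Df[2]
  eps <- 1e-12 * max(1, sum(values^2))
  if (ss_e <= eps && ss_b <= eps) {
    F <- 0; p <- 1; pes <- 0
  } else {
    F <- unname(fit$`F value`[1])
    p <- unname(fit$`Pr(>F)`[1])
    pes <- ss_b / (ss_b + ss_e)
  }
  means <- tapply(values, groups, mean)
  structure(list(effect = "group", F = F, df_num = df_b, df_den = df_e,
                 p = p, partial_eta_sq = pes,
                 ms_error = ss_e / df_e, df_error = df_e,
                 means = as.list(means),
                 n = as.list(table(groups))),
            class = "anova_result")
}

#' Split-plot (mixed) by-items ANOVA
#'
#' Between-items factor (expression) crossed with a within-items factor
#' (face region): the between-items sum of squares splits into the
#' expression effect and its item-level error; the within-items sum of
#' squares into the region effect, the region x expression interaction and
#' the within error. Each effect's partial eta squared uses its own error
#' term. Fitted with [stats::aov()] and an `Error(item)` stratum; the design
#' must be complete (every item measured at every within level).
#'
#' @param data data.frame in long format.
#' @param value,item,between,within Column names.
#' @return data.frame with one row per effect (`between`, `within`,
#'   `interaction`): F, df, p, partial_eta_sq.
#' @export
mixed_anova <- function(data, value = "value", item = "item",
                        between = "expression", within = "region") {
  d <- data.frame(y = data[[value]],
                  item = factor(data[[item]]),
                  b = factor(data[[between]]),
                  w = factor(data[[within]]))
  if (anyNA(d)) stop("mixed_anova data contain missing values", call. = FALSE)
  tab <- table(d$item, d$w)
  if (any(tab != 1)) {
    bad <- rownames(tab)[rowSums(tab != 1) > 0]
    stop("incomplete within-factor data for item(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (nlevels(d$w) < 2) {
    # degenerate design: the between effect reduces to a one-way ANOVA
    ow <- oneway_anova(d$y, as.character(d$b))
    return(rbind(
      data.frame(effect = "between", F = ow$F, df_num = ow$df_num,
                 df_den = ow$df_den, p = ow$p,
                 partial_eta_sq = ow$partial_eta_sq),
      data.frame(effect = c("within", "interaction"), F = 0, df_num = 0,
                 df_den = 0, p = 1, partial_eta_sq = 0)))
  }
  fit <- suppressWarnings(stats::aov(y ~ b * w + Error(item), data = d))
  s <- suppressWarnings(summary(fit))
  eps <- 1e-12 * max(1, sum(d$y^2))
  btab <- s[["Error: item"]][[1]]
  wtab <- s[["Error: Within"]][[1]]
  row_of <- function(tab, name) {
    k <- which(trimws(rownames(tab)) == name)
    as.numeric(tab[k, c("Df", "Sum Sq")])
  }
  eff_b <- row_of(btab, "b"); err_b <- row_of(btab, "Residuals")
  eff_w <- row_of(wtab, "w"); eff_i <- row_of(wtab, "b:w")
  err_w <- row_of(wtab, "Residuals")
  mk <- function(label, eff, err) {
    ss_e <- eff[2]; ss_r <- err[2]
    if (ss_r <= eps && ss_e <= eps) {
      F <- 0; p <- 1; pes <- 0
    } else {
      F <- (ss_e / eff[1]) / (ss_r / err[1])
      p <- stats::pf(F, eff[1], err[1], lower.tail = FALSE)
      pes <- ss_e / (ss_e + ss_r)
    }
    data.frame(effect = label, F = F, df_num = eff[1], df_den = err[1],
               p = p, partial_eta_sq = pes, stringsAsFactors = FALSE)
  }
  rbind(mk("between", eff_b, err_b),
        mk("within", eff_w, err_w),
        mk("interaction", eff_i, err_w))
}

#' Single-step Bonferroni pairwise contrasts
#'
#' Pairwise t statistics using the pooled ANOVA mean-square error and its
#' degrees of freedom; every raw p value receives the same adjustment,
#' multiplication by the number of pairs, capped at 1.
#'
#' @param values Numeric response vector.
#' @param groups Grouping labels.
#' @param ms_error,df_error Pooled error term; when `NULL`, computed from a
#'   one-way ANOVA of `values` on `groups`.
#' @param alpha Significance level for the flags.
#' @return List of class `pairwise_contrasts`: symmetric matrices `raw_p`,
#'   `adj_p`, logical `significant`, plus `means`, `m` (number of pairs) and
#'   `alpha`.
#' @export
bonferroni_pairwise <- function(values, groups, ms_error = NULL,
                                df_error = NULL, alpha = 0.05) {
  groups <- as.character(groups)
  labs <- unique(groups)
  g <- length(labs)
  if (g < 2) stop("need at least two groups", call. = FALSE)
  if (is.null(ms_error) || is.null(df_error)) {
    a <- oneway_anova(values, groups)
    ms_error <- a$ms_error
    df_error <- a$df_error
  }
  means <- tapply(values, groups, mean)[labs]
  ns <- table(groups)[labs]
  raw <- matrix(NA_real_, g, g, dimnames = list(labs, labs))
  m <- g * (g - 1) / 2
  for (i in seq_len(g - 1)) {
    for (j in (i + 1):g) {
      se <- sqrt(ms_error * (1 / ns[[i]] + 1 / ns[[j]]))
      tstat <- if (se > 0) (means[[i]] - means[[j]]) / se else
        if (means[[i]] == means[[j]]) 0 else Inf
      p <- 2 * stats::pt(-abs(tstat), df_error)
      raw[i, j] <- raw[j, i] <- p
    }
  }
  adj <- raw * m
  adj[!is.na(adj) & adj > 1] <- 1
  diag(raw) <- diag(adj) <- NA_real_
  structure(list(raw_p = raw, adj_p = adj,
                 significant = !is.na(adj) & adj < alpha,
                 means = as.list(means), m = m, alpha = alpha),
            class = "pairwise_contrasts")
}

#' Compact letter display
#'
#' Insert-and-absorb letter assignment: two groups share at least one letter
#' iff their pairwise contrast is non-significant. Letters are ordered so
#' that `"a"` attaches to the group with the highest mean.
#'
#' @param contrasts A `pairwise_contrasts` object, or a symmetric logical
#'   matrix of "significantly different" flags with dimnames.
#' @param means Named means for letter ordering; taken from `contrasts` when
#'   available.
#' @return Named character vector of letter strings, in decreasing-mean
#'   order.
#' @export
compact_letter_display <- function(contrasts, means = NULL) {
  if (inherits(contrasts, "pairwise_contrasts")) {
    sig <- contrasts$significant
    if (is.null(means)) means <- unlist(contrasts$means)
  } else {
    sig <- contrasts
  }
  labs <- rownames(sig)
  if (is.null(means)) stop("means required for letter ordering", call. = FALSE)
  means <- means[labs]
  ord <- labs[order(-means)]
  sig <- sig[ord, ord, drop = FALSE]
  g <- length(ord)
  sets <- list(seq_len(g))
  for (i in seq_len(g - 1)) {
    for (j in (i + 1):g) {
      if (!isTRUE(sig[i, j])) next
      k <- 1L
      while (k <= length(sets)) {
        s <- sets[[k]]
        if (i %in% s && j %in% s) {
          sets[[k]] <- setdiff(s, i)
          sets[[length(sets) + 1L]] <- setdiff(s, j)
          # absorb: drop sets that are subsets of another
          keep <- rep(TRUE, length(sets))
          for (a in seq_along(sets)) {
            for (b in seq_along(sets)) {
              if (a != b && keep[b] &&
                  all(sets[[a]] %in% sets[[b]]) &&
                  (length(sets[[a]]) < length(sets[[b]]) ||
                     (length(sets[[a]]) == length(sets[[b]]) && a > b))) {
                keep[a] <- FALSE
              }
            }
          }
          sets <- sets[keep]
          k <- 0L
        }
        k <- k + 1L
      }
    }
  }
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  letters_out <- stats::setNames(rep("", g), ord)
  for (k in seq_along(sets)) {
    for (idx in sets[[k]]) {
      letters_out[idx] <- paste0(letters_out[idx], letters[k])
    }
  }
  letters_out
}
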