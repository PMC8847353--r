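## The statistical battery: linear regression of cross-modality
## composition, Shapiro-Wilk-gated transforms, one-way ANOVA with Tukey
## HSD, and Kruskal-Wallis with Dunn post-hoc tests (Dunn's z tests are
## computed here directly from the tie-corrected rank statistics).

#' Linear regression between two composition vectors
#'
#' Ordinary least squares of y on x, e.g. PAT-derived versus
#' light-sheet-derived lipid percent composition across analysis regions.
#'
#' @param x,y paired numeric vectors (>= 3 finite pairs).
#' @return List: slope, intercept, r2 (squared Pearson correlation),
#'   p (slope test), n.
#' @export
regressionR2 <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  .assert(length(x) >= 3L, "need at least 3 paired observations")
  .assert(sd(x) > 0, "zero variance in x: regression undefined")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = sm$r.squared, p = unname(sm$coefficients[2, 4]), n = length(x))
}

#' Normality-gated transform selection
#'
#' Shapiro-Wilk on every group at alpha = 0.05; when any group fails, the
#' log then the reciprocal transform are tried in that order, selecting the
#' first under which all groups pass. If neither rescues normality the
#' data are flagged for the rank-based route. Transforms needing positive
#' values are skipped (with a note) when the data contain non-positive
#' values.
#'
#' @param groups list of numeric vectors (each of length >= 3).
#' @param alpha Shapiro-Wilk significance level.
#' @return List: transform ("none", "log", "reciprocal" or "rank_based"),
#'   pValues per transform tried, notes.
#' @export
normalityGate <- function(groups, alpha = 0.05) {
  .assert(is.list(groups) && all(lengths(groups) >= 3L),
          "each group needs >= 3 observations")
  notes <- character(0)
  sw <- function(g) vapply(g, function(v) shapiro.test(v)$p.value,
                           numeric(1))
  tried <- list()
  p0 <- sw(groups)
  tried$none <- p0
  if (all(p0 > alpha))
    return(list(transform = "none", pValues = tried, notes = notes))
  for (tr in c("log", "reciprocal")) {
    if (any(unlist(groups) <= 0)) {
      notes <- c(notes, sprintf(
        "%s transform skipped: data contain non-positive values", tr))
      next
    }
    g2 <- lapply(groups, if (tr == "log") log else function(v) 1 / v)
    p <- sw(g2)
    tried[[tr]] <- p
    if (all(p > alpha))
      return(list(transform = tr, pValues = tried, notes = notes))
  }
  notes <- c(notes, "no transform restored normality; use the rank-based route")
  list(transform = "rank_based", pValues = tried, notes = notes)
}

.stack_groups <- function(groups) {
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  data.frame(value = unlist(groups, use.names = FALSE),
             group = factor(rep(names(groups), lengths(groups)),
                            levels = names(groups)))
}

#' One-way ANOVA with Tukey HSD post-hoc test
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   observations).
#' @return List: test, statistic (F), df, p, and \code{posthoc}, the Tukey
#'   HSD pairwise table with family-wise adjusted p-values.
#' @export
anovaTukey <- function(groups) {
  .assert(length(groups) >= 2L, "need at least 2 groups")
  .assert(all(lengths(groups) >= 2L), "each group needs >= 2 observations")
  df <- .stack_groups(groups)
  fit <- aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  posthoc <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                        lwr = tk[, "lwr"], upr = tk[, "upr"],
                        pAdj = tk[, "p adj"], row.names = NULL)
  list(test = "one-way ANOVA", statistic = tab[1, "F value"],
       df = c(tab[1, "Df"], tab[2, "Df"]), p = tab[1, "Pr(>F)"],
       posthoc = posthoc)
}

#' Kruskal-Wallis test with Dunn's multiple comparisons
#'
#' Tie-corrected Kruskal-Wallis H with Dunn's pairwise z tests,
#' \eqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(\frac{N(N+1)}{12} -
#' \frac{\sum (t^3 - t)}{12 (N-1)}) (1/n_i + 1/n_j)}}, adjusted for
#' multiplicity (Holm by default; Bonferroni or none configurable).
#'
#' @param groups named list of numeric vectors (>= 2 groups).
#' @param adjust p-value adjustment for the Dunn table.
#' @return List: test, statistic (H), df, p, posthoc (comparison, z,
#'   p, pAdj), adjust.
#' @export
kruskalDunn <- function(groups, adjust = c("holm", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  .assert(length(groups) >= 2L, "need at least 2 groups")
  all_v <- unlist(groups, use.names = FALSE)
  .assert(length(unique(all_v)) > 1L,
          "all observations identical: H is undefined")
  df <- .stack_groups(groups)
  kw <- kruskal.test(value ~ group, data = df)

  N <- nrow(df)
  r <- rank(df$value)
  rbar <- tapply(r, df$group, mean)
  n <- tapply(r, df$group, length)
  ties <- table(df$value)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  gn <- names(groups) %||% levels(df$group)
  combos <- utils::combn(levels(df$group), 2)
  z <- apply(combos, 2, function(pair) {
    (rbar[pair[1]] - rbar[pair[2]]) /
      sqrt(s2 * (1 / n[pair[1]] + 1 / n[pair[2]]))
  })
  p <- 2 * pnorm(-abs(z))
  posthoc <- data.frame(
    comparison = apply(combos, 2, paste, collapse = "-"),
    z = as.numeric(z), p = as.numeric(p),
    pAdj = p.adjust(p, method = adjust), row.names = NULL)
  list(test = "Kruskal-Wallis", statistic = unname(kw$statistic),
       df = unname(kw$parameter), p = kw$p.value, posthoc = posthoc,
       adjust = adjust)
}
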