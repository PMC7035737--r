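#' Mid-parent and high-parent heterosis
#'
#' MPH = (F1 - MP) / MP * 100 and HPH = (F1 - HP) / HP * 100, where MP is
#' the parent average and HP the better parent under the trait direction
#' (the larger mean by default). Vectorized. A zero MP or HP makes the
#' corresponding index undefined (`NA` with a reason).
#'
#' @param f1_mean,p1_mean,p2_mean Group means.
#' @param direction `"larger"` (default) or `"smaller"`: which parent is the
#'   better one.
#' @return `data.frame`: `mp`, `hp`, `mph`, `hph`, `reason` (empty unless an
#'   index is undefined).
#' @export
mph_hph <- function(f1_mean, p1_mean, p2_mean,
                    direction = c("larger", "smaller")) {
  direction <- match.arg(direction)
  mp <- (p1_mean + p2_mean) / 2
  hp <- if (direction == "larger") pmax(p1_mean, p2_mean)
        else pmin(p1_mean, p2_mean)
  mph <- ifelse(mp != 0, (f1_mean - mp) / mp * 100, NA_real_)
  hph <- ifelse(hp != 0, (f1_mean - hp) / hp * 100, NA_real_)
  reason <- ifelse(mp == 0, "mid-parent mean is zero",
                   ifelse(hp == 0, "high-parent mean is zero", ""))
  data.frame(mp = mp, hp = hp, mph = mph, hph = hph, reason = reason,
             stringsAsFactors = FALSE)
}

# Welch's t-test from summary statistics
welch_t_stats <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop_fmt("insufficient replication for Welch t-test")
  se2 <- s1^2 / n1 + s2^2 / n2
  if (se2 == 0)
    return(list(t = if (m1 == m2) 0 else Inf * sign(m1 - m2),
                df = n1 + n2 - 2, p = if (m1 == m2) 1 else 0))
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# one-way fixed-effects ANOVA from summary statistics
anova_oneway_stats <- function(means, sds, ns) {
  if (any(ns < 2)) stop_fmt("insufficient replication for ANOVA")
  k <- length(means)
  n <- sum(ns)
  gm <- sum(ns * means) / n
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- k - 1
  df2 <- n - k
  if (ssw == 0)
    return(list(f = if (ssb == 0) 0 else Inf, df1 = df1, df2 = df2,
                p = if (ssb == 0) 1 else 0))
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, df1 = df1, df2 = df2, p = stats::pf(f, df1, df2,
                                                  lower.tail = FALSE))
}

# reduce long per-plant observations to (mean, sd, n) per cross/line/trait
summarize_trait_obs <- function(obs) {
  need <- c("cross", "line", "trait", "value")
  if (!all(need %in% names(obs)))
    stop_fmt("per-plant table must have columns: %s",
             paste(need, collapse = ", "))
  agg <- do.call(rbind, lapply(
    split(obs, list(obs$cross, obs$line, obs$trait), drop = TRUE),
    function(d) data.frame(cross = d$cross[1], line = d$line[1],
                           trait = d$trait[1], mean = mean(d$value),
                           sd = stats::sd(d$value), n = nrow(d),
                           stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  agg
}

#' Heterosis estimates with significance tests
#'
#' Per (cross, trait): MPH and HPH from the group means; a one-way ANOVA
#' across P1, P2 and F1; Welch's t of F1 against the high parent (HPH
#' significance) and of F1 against a mid-parent construct with mean
#' (m1 + m2) / 2, variance (s1^2 + s2^2) / 4 and n = min(n1, n2) (MPH
#' significance). All tests run on summary statistics, so per-plant and
#' (mean, SD, n) input give identical results.
#'
#' @param pheno Either a long per-plant table (`cross`, `line` in P1/P2/F1,
#'   `trait`, `value`) or a summary table (`cross`, `line`, `trait`, `mean`,
#'   `sd`, `n`).
#' @param direction_map Optional named vector trait -> `"larger"` or
#'   `"smaller"`; traits default to `"larger"` (bigger is better).
#' @return `data.frame` per (cross, trait): group means, `mph`, `hph`,
#'   `anova_p`, `mph_p`, `hph_p` and significance flags (`"*"` at 0.05,
#'   `"**"` at 0.01).
#' @export
heterosis_table <- function(pheno, direction_map = NULL) {
  summ <- if (all(c("mean", "sd", "n") %in% names(pheno))) pheno
          else summarize_trait_obs(pheno)
  if (any(summ$n < 2))
    stop_fmt("insufficient replication: n < 2 for %s",
             paste(unique(summ$trait[summ$n < 2]), collapse = ", "))
  flag <- function(p) ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
  rows <- lapply(split(summ, list(summ$cross, summ$trait), drop = TRUE),
                 function(d) {
    g <- lapply(c(P1 = "P1", P2 = "P2", F1 = "F1"), function(ln) {
      r <- d[d$line == ln, ]
      if (nrow(r) != 1)
        stop_fmt("cross %s trait %s: expected one %s row",
                 d$cross[1], d$trait[1], ln)
      r
    })
    dir <- (direction_map %||% character())[d$trait[1]]
    dir <- if (is.na(dir) || !length(dir)) "larger" else dir
    h <- mph_hph(g$F1$mean, g$P1$mean, g$P2$mean, dir)
    hp_is_p1 <- if (dir == "larger") g$P1$mean >= g$P2$mean
                else g$P1$mean <= g$P2$mean
    hp <- if (hp_is_p1) g$P1 else g$P2
    aov_p <- anova_oneway_stats(c(g$P1$mean, g$P2$mean, g$F1$mean),
                                c(g$P1$sd, g$P2$sd, g$F1$sd),
                                c(g$P1$n, g$P2$n, g$F1$n))$p
    hph_p <- welch_t_stats(g$F1$mean, g$F1$sd, g$F1$n,
                           hp$mean, hp$sd, hp$n)$p
    mph_p <- welch_t_stats(g$F1$mean, g$F1$sd, g$F1$n,
                           (g$P1$mean + g$P2$mean) / 2,
                           sqrt(g$P1$sd^2 + g$P2$sd^2) / 2,
                           min(g$P1$n, g$P2$n))$p
    data.frame(cross = d$cross[1], trait = d$trait[1],
               p1_mean = g$P1$mean, p2_mean = g$P2$mean,
               f1_mean = g$F1$mean, mp = h$mp, hp = h$hp,
               mph = h$mph, hph = h$hph,
               anova_p = aov_p, mph_p = mph_p, hph_p = hph_p,
               mph_sig = flag(mph_p), hph_sig = flag(hph_p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
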