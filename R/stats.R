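#' Single-pass mean +/- 2 SD outlier removal
#'
#' Drops values outside `[mean - 2*SD, mean + 2*SD]`, with mean and sample
#' SD (n-1 denominator) computed once on the full input; the rule is not
#' iterated. With fewer than 3 values the input is passed through with a
#' warning.
#'
#' @param values numeric vector.
#' @param k SD multiplier (default 2).
#' @return list with `values` (kept) and `removed` (indices into the input).
#' @export
remove_outliers <- function(values, k = 2) {
  if (length(values) < 3L) {
    warning("fewer than 3 values; outlier rule not applied")
    return(list(values = values, removed = integer()))
  }
  m <- mean(values, na.rm = TRUE)
  s <- sd(values, na.rm = TRUE)
  bad <- which(!is.na(values) & abs(values - m) > k * s)
  list(values = if (length(bad)) values[-bad] else values, removed = bad)
}

#' Choose the parametric or non-parametric comparison route
#'
#' Parametric analysis requires every group to pass Shapiro-Wilk normality
#' and the groups jointly to pass Levene's variance-homogeneity test (mean
#' centering, classic Levene) at the given alpha; otherwise the
#' non-parametric route (Kruskal-Wallis with Dunn's post hoc) is taken. A
#' degenerate zero-variance group forces the non-parametric route with a
#' warning.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @param alpha assumption-test significance threshold (default 0.05).
#' @return list with `route` (`"parametric"`/`"nonparametric"`),
#'   `shapiro_p` (named per group), `levene_p`.
#' @export
route_test <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  split_v <- split(values, groups)
  if (any(lengths(split_v) < 3L))
    stop("route_test needs at least 3 observations per group")
  degenerate <- vapply(split_v, function(v) sd(v) == 0, logical(1))
  if (any(degenerate)) {
    warning("zero-variance group(s): ",
            paste(names(split_v)[degenerate], collapse = ", "),
            "; forcing non-parametric route")
    return(list(route = "nonparametric",
                shapiro_p = setNames(rep(NA_real_, nlevels(groups)),
                                     levels(groups)),
                levene_p = NA_real_))
  }
  shap <- vapply(split_v, function(v) shapiro.test(v)$p.value, numeric(1))
  lev <- car::leveneTest(values ~ groups, center = mean)[["Pr(>F)"]][1]
  route <- if (any(shap < alpha) || lev < alpha) "nonparametric"
  else "parametric"
  list(route = route, shapiro_p = shap, levene_p = lev)
}

#' Mixed (split-plot) analysis of variance
#'
#' Fits `value ~ group * session + Error(subject/session)` via [stats::aov()]
#' for a between-subject group factor and a within-subject session factor,
#' returning F and p for the group, session and interaction effects.
#' Subjects missing a session are dropped with a message. With only two
#' within-subject levels sphericity holds trivially (Mauchly's test is
#' degenerate), which is reported as such.
#'
#' @param table long-format data frame.
#' @param value,group,session,subject column names.
#' @return list with `effects` (data frame: effect, df1, df2, F, p),
#'   `sphericity` (note string), `n_subjects`.
#' @export
mixed_anova <- function(table, value = "value", group = "group",
                        session = "session", subject = "subject_id") {
  d <- data.frame(value = table[[value]],
                  group = factor(table[[group]]),
                  session = factor(table[[session]]),
                  subject = factor(table[[subject]]))
  d <- d[complete.cases(d), ]
  nses <- nlevels(d$session)
  per_subj <- table(d$subject)
  keep <- names(per_subj)[per_subj == nses]
  if (length(keep) < length(per_subj))
    message(length(per_subj) - length(keep),
            " subject(s) dropped for missing sessions")
  d <- d[d$subject %in% keep, ]
  d$subject <- droplevels(d$subject)
  if (nlevels(d$group) < 2L) stop("mixed_anova needs at least 2 groups")
  fit <- aov(value ~ group * session + Error(subject / session), data = d)
  s <- summary(fit)
  btw <- s[["Error: subject"]][[1]]
  wth <- s[["Error: subject:session"]][[1]]
  pick <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    j <- match("Residuals", trimws(rownames(tab)))
    data.frame(effect = term, df1 = tab$Df[i], df2 = tab$Df[j],
               F = tab$`F value`[i], p = tab$`Pr(>F)`[i])
  }
  effects <- rbind(pick(btw, "group"),
                   pick(wth, "session"),
                   pick(wth, "group:session"))
  sphericity <- if (nses <= 2L)
    "two within-subject levels: sphericity holds trivially (Mauchly degenerate)"
  else "not assessed"
  list(effects = effects, sphericity = sphericity,
       n_subjects = nlevels(d$subject))
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition via [stats::aov()]. Identical group
#' means give F = 0; zero within-group variance with distinct means is
#' flagged (F is infinite).
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @return list with `F`, `p`, `df1`, `df2`, logical `zero_within_variance`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(split(values, groups)) < 2L))
    stop("each group needs at least 2 observations")
  tab <- summary(aov(values ~ groups))[[1]]
  sw <- tab$`Sum Sq`[2]
  zero_within <- sw <= .Machine$double.eps * sum(tab$`Sum Sq`)
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       df1 = tab$Df[1], df2 = tab$Df[2],
       zero_within_variance = zero_within)
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean_a - mean_b) / s_pool` with
#' `s_pool = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))`.
#' The magnitude label follows the conventional ascending thresholds
#' 0.2 / 0.5 / 0.8 on `|d|`. An externally supplied pooled SD (e.g. a
#' design-wide error term from a factorial model) can replace the two-group
#' pooled SD via `sd_pool`.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param sd_pool optional externally supplied pooled SD.
#' @return list with `d`, `magnitude`
#'   (`"negligible"/"small"/"medium"/"large"`), `flagged` (zero pooled SD).
#' @export
cohen_d <- function(a, b, sd_pool = NULL) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("cohen_d needs at least 2 values per sample")
  sp <- sd_pool %||%
    sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  if (!is.finite(sp) || sp == 0)
    return(list(d = NA_real_, magnitude = NA_character_, flagged = TRUE))
  d <- (mean(a) - mean(b)) / sp
  mag <- if (abs(d) >= 0.8) "large" else if (abs(d) >= 0.5) "medium"
  else if (abs(d) >= 0.2) "small" else "negligible"
  list(d = d, magnitude = mag, flagged = FALSE)
}

#' Rank-biserial correlation for a two-group comparison
#'
#' The dominance form `r = (#(a > b) - #(a < b)) / (n_a * n_b)`, equivalent
#' to `2 * U_a / (n_a * n_b) - 1` with `U_a` the Mann-Whitney statistic of
#' `a` over `b` (ties counted half via mid-ranks). `r = 0` for no tendency,
#' `r = +1` when every `a` exceeds every `b`, `r = -1` for the reverse.
#'
#' @param a,b numeric samples (non-empty).
#' @return r in `[-1, 1]`.
#' @export
rank_biserial <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("rank_biserial needs non-empty samples")
  rk <- rank(c(a, b))
  u_a <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  2 * u_a / (na * nb) - 1
}

# Dunn's post hoc z statistics on pooled mid-ranks with tie correction.
dunn_pairs <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  rk <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  rbar <- tapply(rk, groups, mean)
  ns <- tapply(rk, groups, length)
  combs <- utils::combn(levels(groups), 2)
  out <- lapply(seq_len(ncol(combs)), function(k) {
    g1 <- combs[1, k]; g2 <- combs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ns[[g1]] + 1 / ns[[g2]]))
    z <- (rbar[[g1]] - rbar[[g2]]) / se
    data.frame(A = g1, B = g2, z = z,
               p_raw = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Bonferroni-corrected pairwise group comparisons with effect sizes
#'
#' All two-sided pairwise comparisons between groups. On the parametric
#' route these are pooled-variance t-tests with Cohen's d; on the
#' non-parametric route, Dunn's z tests on pooled mid-ranks (tie-corrected)
#' with the rank-biserial correlation. Raw p-values are multiplied by the
#' number of pairs and capped at 1. Pairs involving a group with fewer than
#' 2 observations are skipped with a message.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param route `"parametric"` or `"nonparametric"`.
#' @return data frame with one row per pair: `A`, `B`, `n_A`, `n_B`,
#'   `mean_A`, `sd_A`, `mean_B`, `sd_B`, `p_raw`, `p_corrected`,
#'   `effect_size`, `effect_kind`.
#' @export
pairwise_bonferroni <- function(values, groups,
                                route = c("parametric", "nonparametric")) {
  route <- match.arg(route)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  split_v <- split(values, groups)
  small <- names(split_v)[lengths(split_v) < 2L]
  if (length(small))
    message("group(s) skipped in pairwise comparisons (n < 2): ",
            paste(small, collapse = ", "))
  ok <- setdiff(levels(groups), small)
  combs <- utils::combn(ok, 2)
  m <- ncol(combs)
  dunn <- if (route == "nonparametric") {
    keep <- groups %in% ok
    dunn_pairs(values[keep], droplevels(groups[keep]))
  }
  rows <- lapply(seq_len(m), function(k) {
    g1 <- combs[1, k]; g2 <- combs[2, k]
    a <- split_v[[g1]]; b <- split_v[[g2]]
    if (route == "parametric") {
      p_raw <- t.test(a, b, var.equal = TRUE)$p.value
      eff <- cohen_d(a, b)$d
      kind <- "cohen_d"
    } else {
      p_raw <- dunn$p_raw[dunn$A == g1 & dunn$B == g2]
      eff <- rank_biserial(a, b)
      kind <- "rank_biserial"
    }
    data.frame(A = g1, B = g2, n_A = length(a), n_B = length(b),
               mean_A = mean(a), sd_A = sd(a),
               mean_B = mean(b), sd_B = sd(b),
               p_raw = p_raw, p_corrected = min(1, p_raw * m),
               effect_size = eff, effect_kind = kind,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full group comparison for one parameter
#'
#' Reproduces the comparison route for one extracted parameter: per-session
#' single-pass outlier trimming per group, assumption tests and route
#' choice, an omnibus test (mixed group x session ANOVA on the parametric
#' route, per-session Kruskal-Wallis with tie correction otherwise), and
#' Bonferroni-corrected pairwise comparisons with effect sizes per session.
#'
#' @param table long-format data frame with columns `subject_id`, `group`,
#'   `session`, `value` (one row per subject x session for this parameter).
#' @param alpha significance threshold (default 0.05).
#' @param trim apply the mean +/- 2 SD outlier rule per group x session.
#' @return object of class `group_comparison`: list with `route`,
#'   `assumptions`, `omnibus`, `pairwise` (data frame with a `session`
#'   column), `removed` (outlier bookkeeping).
#' @export
compare_groups <- function(table, alpha = 0.05, trim = TRUE) {
  need <- c("subject_id", "group", "session", "value")
  stopifnot(all(need %in% names(table)))
  d <- table[complete.cases(table[need]), need]
  if (length(unique(d$group)) < 2L)
    stop("group comparison needs at least 2 groups")
  removed <- list()
  if (trim) {
    keep <- rep(TRUE, nrow(d))
    for (key in split(seq_len(nrow(d)),
                      interaction(d$group, d$session, drop = TRUE))) {
      if (length(key) < 3L) next
      out <- suppressWarnings(remove_outliers(d$value[key]))
      if (length(out$removed)) {
        keep[key[out$removed]] <- FALSE
        removed[[length(removed) + 1L]] <-
          d[key[out$removed], c("subject_id", "group", "session")]
      }
    }
    d <- d[keep, ]
  }
  sessions <- sort(unique(d$session))
  ass <- lapply(setNames(sessions, sessions), function(s) {
    ds <- d[d$session == s, ]
    tryCatch(route_test(ds$value, ds$group, alpha),
             error = function(e) list(route = "nonparametric",
                                      shapiro_p = NA, levene_p = NA))
  })
  route <- if (any(vapply(ass, `[[`, "", "route") == "nonparametric"))
    "nonparametric" else "parametric"
  omnibus <- if (route == "parametric" && length(sessions) > 1L) {
    mixed_anova(d)
  } else {
    kw <- lapply(setNames(sessions, sessions), function(s) {
      ds <- d[d$session == s, ]
      k <- kruskal.test(ds$value, factor(ds$group))
      data.frame(session = s, statistic = unname(k$statistic),
                 df = unname(k$parameter), p = k$p.value)
    })
    do.call(rbind, kw)
  }
  pw <- lapply(sessions, function(s) {
    ds <- d[d$session == s, ]
    res <- pairwise_bonferroni(ds$value, ds$group, route)
    cbind(session = s, res)
  })
  structure(list(route = route, assumptions = ass, omnibus = omnibus,
                 pairwise = do.call(rbind, pw),
                 removed = if (length(removed)) do.call(rbind, removed)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (", x$route, " route)\n", sep = "")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
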