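# Cohort nonparametric comparisons of motion metrics between
# substructure groupings: Kruskal-Wallis with tie correction, Dunn's
# post-hoc test with Bonferroni adjustment, and the >= 4-of-8-metrics
# overall-significance rule.

#' Kruskal-Wallis rank-sum test
#'
#' H computed from pooled ranks with the standard tie correction
#' `1 - sum(t^3 - t) / (N^3 - N)`; when all observations are tied the
#' statistic is defined as 0. The p-value uses the chi-squared
#' approximation with `k - 1` degrees of freedom.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return List with `H`, `p`, `df`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("input error: need >= 2 groups", call. = FALSE)
  n_i <- lengths(groups)
  if (any(n_i == 0L))
    stop("input error: every group needs >= 1 observation", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- rank(x)
  g <- rep(seq_along(groups), n_i)
  R_i <- tapply(r, g, sum)
  H0 <- 12 / (N * (N + 1)) * sum(R_i^2 / n_i) - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- if (C <= 0) 0 else H0 / C
  df <- length(groups) - 1L
  list(H = H, p = pchisq(H, df, lower.tail = FALSE), df = df, n = N)
}

#' Dunn's post-hoc test on mean ranks
#'
#' Pairwise z statistics on pooled mean ranks with tie correction,
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1)))
#' (1/n_i + 1/n_j))`, two-sided p-values from the normal distribution,
#' adjusted over the number of pairs (Bonferroni by default; the
#' adjusted p caps at 1).
#'
#' @param groups named (or unnamed) list of >= 2 non-empty numeric
#'   vectors.
#' @param p_adjust adjustment method passed to [stats::p.adjust()]
#'   (default `"bonferroni"`).
#' @return data.frame with `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_posthoc <- function(groups, p_adjust = "bonferroni") {
  if (!is.list(groups) || length(groups) < 2L)
    stop("input error: need >= 2 groups", call. = FALSE)
  n_i <- lengths(groups)
  if (any(n_i == 0L))
    stop("input error: every group needs >= 1 observation", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- rank(x)
  g <- rep(seq_along(groups), n_i)
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  s2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(seq_along(groups), 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(s2 * (1 / n_i[i] + 1 / n_i[j]))
    z <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    c(z = unname(z), p = 2 * pnorm(-abs(unname(z))))
  })
  out <- data.frame(
    group1 = names(groups)[pairs[1, ]],
    group2 = names(groups)[pairs[2, ]],
    z = res["z", ], p = res["p", ],
    stringsAsFactors = FALSE)
  out$p_adj <- p.adjust(out$p, method = p_adjust)
  rownames(out) <- NULL
  out
}

#' Built-in substructure groupings
#'
#' The groupings used for cohort comparisons: the physiological classes
#' (coronary arteries, chambers, great vessels, whole heart), right vs
#' left heart, heart base vs apex, the right coronary artery vs the
#' right chambers, and the left coronary system vs the left chambers.
#'
#' @return Named list; each element is a named list of substructure
#'   label vectors (the groups to compare).
#' @export
substructure_groupings <- function() {
  list(
    physiological = list(
      coronary_arteries = c("RCA", "LMCA", "LADA", "LCX"),
      chambers = c("LV", "RV", "LA", "RA"),
      great_vessels = c("AA", "DA", "PA", "PVs", "IVC", "SVC"),
      whole_heart = "WH"),
    right_vs_left = list(
      right_heart = c("RCA", "RA", "RV"),
      left_heart = c("LADA", "LMCA", "LCX", "LV", "LA")),
    base_vs_apex = list(
      base = c("RCA", "LADA", "LMCA", "LCX", "AA", "DA", "PA", "PVs", "SVC"),
      apex = c("LV", "RV", "LA", "RA", "IVC")),
    rca_vs_right_chambers = list(
      rca = "RCA",
      right_chambers = c("RA", "RV")),
    lca_vs_left_chambers = list(
      lca = c("LMCA", "LADA", "LCX"),
      left_chambers = c("LV", "LA"))
  )
}

MOTION_METRICS <- c("rl", "ap", "si", "vector", "mean_face", "max_face",
                    "hd95", "mda")

#' Compare substructure groupings across the eight motion metrics
#'
#' For each grouping, motion type, and metric, runs [kruskal_wallis()]
#' across the groups (observations are the per-subject, per-substructure
#' metric values pooled within each group) followed by
#' [dunn_posthoc()] with Bonferroni adjustment over the pairwise
#' comparisons. A grouping/motion-type battery is flagged overall
#' significant when at least `min_significant` of the 8 metrics have
#' Kruskal-Wallis `p < alpha`; the 8 metrics are deliberately not
#' corrected across (the 4-of-8 rule plays that role).
#'
#' @param metric_table long-format table from [summarize_motion()]
#'   stacked over subjects (columns `subject`, `substructure`,
#'   `motion_type`, `metric`, `value_mm`).
#' @param groupings named list as returned by
#'   [substructure_groupings()].
#' @param motion_types motion types to test (default cardiac and
#'   respiratory).
#' @param alpha per-metric significance level (default 0.05).
#' @param min_significant metrics required for overall significance
#'   (default 4 of 8).
#' @return data.frame of class `grouping_comparison`: one row per
#'   (grouping, motion type) with `n_significant`,
#'   `overall_significant`, and a `tests` attribute holding the
#'   per-metric Kruskal-Wallis results and Dunn tables.
#' @export
compare_groupings <- function(metric_table,
                              groupings = substructure_groupings(),
                              motion_types = c("cardiac", "respiratory"),
                              alpha = 0.05, min_significant = 4) {
  rows <- list()
  details <- list()
  for (gname in names(groupings)) {
    grouping <- groupings[[gname]]
    known <- unique(metric_table$substructure)
    missing <- setdiff(unlist(grouping), known)
    if (length(missing) > 0)
      stop(sprintf("config error: grouping '%s' references substructures absent from the table: %s",
                   gname, paste(missing, collapse = ", ")), call. = FALSE)
    for (mt in motion_types) {
      tab <- metric_table[metric_table$motion_type == mt, ]
      nsig <- 0L
      mdetails <- list()
      for (metric in MOTION_METRICS) {
        vals <- tab[tab$metric == metric, ]
        if (nrow(vals) == 0L) next
        groups <- lapply(grouping, function(subs)
          vals$value_mm[vals$substructure %in% subs])
        if (any(lengths(groups) == 0L)) next
        kw <- kruskal_wallis(groups)
        dunn <- dunn_posthoc(groups)
        if (kw$p < alpha) nsig <- nsig + 1L
        mdetails[[metric]] <- list(kw = kw, dunn = dunn)
      }
      rows[[length(rows) + 1]] <- data.frame(
        grouping = gname, motion_type = mt,
        n_metrics = length(mdetails), n_significant = nsig,
        overall_significant = nsig >= min_significant,
        stringsAsFactors = FALSE)
      details[[paste(gname, mt, sep = ".")]] <- mdetails
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "tests") <- details
  class(out) <- c("grouping_comparison", "data.frame")
  out
}

#' Simulate a desk-scale cohort metric table
#'
#' Draws a long-format metric table directly (no mask rendering) for
#' statistical power and type-I-error studies: each (subject,
#' substructure) gets a latent 3D displacement `N(mean_disp,
#' between_sd^2)` per component, and the eight metrics are derived from
#' it with metric-level noise (`noise_sd`), so metrics are correlated
#' through the shared latent displacement but not identical — mimicking
#' how centroid, bounding-box, and surface-distance metrics co-vary in
#' real cohorts.
#'
#' @param substructure_means named list: substructure -> length-3 mean
#'   displacement (mm). All substructures share `between_sd`.
#' @param n_subjects number of subjects.
#' @param between_sd between-subject SD per displacement component, mm.
#' @param noise_sd metric-level measurement noise SD, mm.
#' @param motion_type label written into the table.
#' @param seed integer seed.
#' @return data.frame in the [summarize_motion()] long format.
#' @export
simulate_metric_table <- function(substructure_means, n_subjects = 10,
                                  between_sd = 1, noise_sd = 0.5,
                                  motion_type = "cardiac", seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_subjects)) {
    id <- sprintf("S%02d", i)
    for (sub in names(substructure_means)) {
      d <- substructure_means[[sub]] + rnorm(3, sd = between_sd)
      vec <- sqrt(sum(d^2))
      faces <- abs(rep(d, each = 2)) + abs(rnorm(6, sd = noise_sd))
      vals <- c(
        rl = d[1], ap = d[2], si = d[3], vector = vec,
        mean_face = mean(faces), max_face = max(faces),
        hd95 = vec * 1.1 + abs(rnorm(1, sd = noise_sd)),
        mda = vec * 0.6 + abs(rnorm(1, sd = noise_sd)))
      rows[[length(rows) + 1]] <- data.frame(
        subject = id, substructure = sub, motion_type = motion_type,
        metric = names(vals), value_mm = unname(vals),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
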