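shapiro_normal <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || sd(x) == 0) return(FALSE)
  if (length(x) > 5000) x <- sample(x, 5000)
  shapiro.test(x)$p.value >= alpha
}

#' Correlation matrix with p-values
#'
#' Pairwise-complete correlations between the numeric columns. With
#' `method = "auto"` the coefficient is Pearson when both columns pass a
#' Shapiro-Wilk normality check at `alpha`, Spearman otherwise (the
#' published convention). Cells with fewer than 3 complete pairs or a
#' constant column are `NA`.
#'
#' @param data tibble of numeric columns.
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @param alpha significance level of the normality gate.
#' @return A list of class `cor_result`: `r`, `p`, `method` (per-cell
#'   matrices).
#' @export
correlation_matrix <- function(data, method = c("auto", "pearson", "spearman"),
                               alpha = 0.05) {
  method <- match.arg(method)
  vars <- names(data)[vapply(data, is.numeric, logical(1))]
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  mm <- matrix(NA_character_, k, k, dimnames = list(vars, vars))
  normal <- vapply(vars, function(v) shapiro_normal(data[[v]], alpha),
                   logical(1))
  for (i in seq_len(k)) {
    r[i, i] <- 1
    p[i, i] <- 0
    for (j in seq_len(k)[-seq_len(i)]) {
      x <- data[[vars[i]]]
      y <- data[[vars[j]]]
      ok <- complete.cases(x, y)
      if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
      meth <- switch(method,
                     pearson = "pearson",
                     spearman = "spearman",
                     auto = if (normal[i] && normal[j]) "pearson" else "spearman")
      ct <- suppressWarnings(cor.test(x[ok], y[ok], method = meth))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
      mm[i, j] <- mm[j, i] <- meth
    }
  }
  structure(list(r = r, p = p, method = mm), class = "cor_result")
}

#' Two-group comparison with effect size
#'
#' Normality-gated test choice (Shapiro-Wilk at `alpha` on each group):
#' pooled-variance independent-samples t-test when both groups look normal
#' (Welch by flag), Mann-Whitney U otherwise. Cohen's d uses the
#' n-weighted pooled SD regardless of the test used.
#'
#' @param a,b numeric samples (each of length >= 2).
#' @param welch use Welch's t instead of the pooled-variance t.
#' @param alpha normality-gate level.
#' @param bonferroni_m number of comparisons in the family; the adjusted p
#'   is `min(1, p * m)`.
#' @return A one-row tibble: group means/SDs, `statistic`, `p`,
#'   `p_bonferroni`, `cohens_d`, `test_used`.
#' @export
#' @examples
#' compare_groups(rnorm(50, 10, 2), rnorm(50, 8, 2))
compare_groups <- function(a, b, welch = FALSE, alpha = 0.05,
                           bonferroni_m = 1) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) abort("each group needs >= 2 values.")
  pooled_sd <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                      (length(a) + length(b) - 2))
  d <- if (pooled_sd == 0) 0 else (mean(a) - mean(b)) / pooled_sd
  normal <- shapiro_normal(a, alpha) && shapiro_normal(b, alpha)
  if (normal) {
    tt <- t.test(a, b, var.equal = !welch)
    statistic <- unname(tt$statistic)
    pval <- tt$p.value
    test_used <- if (welch) "welch_t" else "t"
  } else {
    wt <- suppressWarnings(wilcox.test(a, b))
    statistic <- unname(wt$statistic)
    pval <- wt$p.value
    test_used <- "mann_whitney_u"
  }
  tibble(
    mean_a = mean(a), sd_a = sd(a), n_a = length(a),
    mean_b = mean(b), sd_b = sd(b), n_b = length(b),
    statistic = statistic, p = pval,
    p_bonferroni = min(1, pval * bonferroni_m),
    cohens_d = d, test_used = test_used
  )
}

#' One-way ANOVA across position groups
#'
#' One-way ANOVA F with Bonferroni-corrected pairwise t-tests (correction
#' factor = number of group pairs).
#'
#' @param values numeric outcome.
#' @param groups grouping factor (>= 2 groups of >= 2 values).
#' @return A list: `f`, `p`, `df`, `group_means` tibble, `pairwise` tibble
#'   of Bonferroni-adjusted pairwise p-values.
#' @export
position_anova <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) abort("need at least two groups.")
  fit <- aov(values ~ groups)
  s <- summary(fit)[[1]]
  pw <- pairwise.t.test(values, groups, p.adjust.method = "bonferroni",
                        pool.sd = TRUE)
  pw_tab <- as.data.frame(as.table(pw$p.value)) %>%
    dplyr::filter(!is.na(Freq)) %>%
    rename(group1 = Var1, group2 = Var2, p_bonferroni = Freq) %>%
    as_tibble()
  gm <- tibble(group = levels(groups)) %>%
    mutate(mean = vapply(group, function(g) mean(values[groups == g]), numeric(1)),
           sd = vapply(group, function(g) sd(values[groups == g]), numeric(1)),
           n = vapply(group, function(g) sum(groups == g), numeric(1)))
  list(f = s$`F value`[1], p = s$`Pr(>F)`[1],
       df = c(s$Df[1], s$Df[2]), group_means = gm, pairwise = pw_tab)
}

#' Session-level indicator table for correlation analysis
#'
#' Joins athlete heart-rate constants onto the session table, computes
#' TRIMP/sRPE per session, and optionally attaches the next morning's
#' LnRMSSD (the recovery marker responding to the session's load).
#'
#' @param sessions session tibble.
#' @param athletes athlete tibble.
#' @param morning optional morning tibble; when given, a `next_lnrmssd`
#'   column pairs each session with the following morning.
#' @return A tibble with one row per session.
#' @export
session_indicator_table <- function(sessions, athletes, morning = NULL) {
  out <- sessions %>%
    left_join(select(athletes, athlete_id, hr_rest, hr_max),
              by = "athlete_id") %>%
    mutate(
      trimp = compute_trimp(duration, pmin(pmax(hr_mean, hr_rest), hr_max),
                            hr_rest, hr_max),
      srpe = compute_srpe(rpe, duration)
    ) %>%
    select(athlete_id, day_index, session_type, total_distance, hsr_distance,
           sprint_distance, player_load, hr_mean, trimp, srpe)
  if (!is.null(morning)) {
    nxt <- morning %>%
      select(athlete_id, day_index, lnrmssd) %>%
      mutate(day_index = day_index - 1L) %>%
      rename(next_lnrmssd = lnrmssd)
    out <- left_join(out, nxt, by = c("athlete_id", "day_index"))
  }
  out
}

#' Write the report tables of a pipeline run
#'
#' Emits the descriptive and inferential summary files: training-vs-match
#' load descriptives, fatigued-vs-non-fatigued comparisons, the model
#' performance panel, the position ANOVA table, the indicator correlation
#' matrix, and a run manifest (seed, configuration hash, package version).
#'
#' @param results the list returned by [run_pipeline()] stages (needs
#'   `data`, `labels`, `assembled`, `metrics`).
#' @param out_dir output directory (created if needed).
#' @param seed,config_hash recorded in the manifest.
#' @return Invisibly, the vector of files written.
#' @export
render_report <- function(results, out_dir, seed = NA_integer_,
                          config_hash = NA_character_) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data <- results$data
  ses <- session_indicator_table(data$sessions, data$athletes, data$morning)

  load_vars <- c("total_distance", "hsr_distance", "sprint_distance",
                 "player_load", "hr_mean", "trimp", "srpe")
  t3 <- purrr::map_dfr(load_vars, function(v) {
    tr <- ses[[v]][ses$session_type == "training"]
    ma <- ses[[v]][ses$session_type == "match"]
    compare_groups(ma, tr, bonferroni_m = length(load_vars)) %>%
      mutate(variable = v, .before = 1) %>%
      rename(match_mean = mean_a, match_sd = sd_a, n_match = n_a,
             training_mean = mean_b, training_sd = sd_b, n_training = n_b)
  })
  readr::write_csv(t3, file.path(out_dir, "report_table3.csv"))

  lab <- results$labels$labels %>% filter(label != "unlabelable")
  t4dat <- results$assembled %>%
    inner_join(select(lab, athlete_id, day_index, label),
               by = c("athlete_id", "day_index"))
  t4_vars <- c("prev_total_distance", "prev_srpe", "weekly_total_distance",
               "acwr", "lnrmssd", "wellness_total")
  t4 <- purrr::map_dfr(t4_vars, function(v) {
    fa <- t4dat[[v]][t4dat$label == "fatigued"]
    nf <- t4dat[[v]][t4dat$label == "non_fatigued"]
    compare_groups(nf, fa, bonferroni_m = length(t4_vars)) %>%
      mutate(variable = v, .before = 1) %>%
      rename(non_fatigued_mean = mean_a, non_fatigued_sd = sd_a,
             n_non_fatigued = n_a, fatigued_mean = mean_b,
             fatigued_sd = sd_b, n_fatigued = n_b)
  })
  readr::write_csv(t4, file.path(out_dir, "report_table4.csv"))

  readr::write_csv(results$metrics, file.path(out_dir, "report_table5.csv"))

  pos <- ses %>%
    left_join(select(data$athletes, athlete_id, position), by = "athlete_id") %>%
    filter(session_type == "training", position != "GK") %>%
    group_by(athlete_id, position) %>%
    summarise(across(c(total_distance, hsr_distance, sprint_distance),
                     ~ mean(.x, na.rm = TRUE)), .groups = "drop")
  pos_dec <- data$sessions %>%
    left_join(select(data$athletes, athlete_id, position), by = "athlete_id") %>%
    filter(session_type == "training", position != "GK") %>%
    group_by(athlete_id, position) %>%
    summarise(decel_count = mean(decel_count, na.rm = TRUE), .groups = "drop")
  pos <- left_join(pos, pos_dec, by = c("athlete_id", "position"))
  pos_tab <- purrr::map_dfr(
    c("total_distance", "hsr_distance", "sprint_distance", "decel_count"),
    function(v) {
      an <- position_anova(pos[[v]], pos$position)
      an$group_means %>%
        tidyr::pivot_wider(names_from = group,
                           values_from = c(mean, sd, n)) %>%
        mutate(variable = v, f = an$f, p = an$p, .before = 1)
    })
  readr::write_csv(pos_tab, file.path(out_dir, "report_positions.csv"))

  cm <- correlation_matrix(
    select(ses, total_distance, hsr_distance, sprint_distance, player_load,
           hr_mean, trimp, srpe),
    method = "pearson"
  )
  cor_df <- as.data.frame(cm$r) %>%
    tibble::rownames_to_column("variable") %>%
    as_tibble()
  readr::write_csv(cor_df, file.path(out_dir, "correlations.csv"))

  manifest <- list(
    seed = seed,
    config_hash = config_hash,
    package_version = as.character(utils::packageVersion("fatiguelab")),
    n_athletes = nrow(data$athletes),
    n_sessions = nrow(data$sessions),
    n_person_days = nrow(data$morning),
    n_labeled = results$labels$summary$n_labeled,
    prevalence_pct = results$labels$summary$prevalence_pct
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list.files(out_dir))
}
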