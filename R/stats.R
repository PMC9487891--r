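# Statistical stage: log transform with a Shapiro-Wilk normality gate
# choosing between a parametric mixed ANOVA and an aligned-rank-transform
# (ART) mixed ANOVA, covariate adjustment by pooled within-group
# regression, Bonferroni post-hocs, and permutation-tested Pearson
# correlations with behaviour.

#' Log-transform values and gate the analysis route on normality
#'
#' Applies the natural log (metrics are strictly positive by construction;
#' nonpositive values are a data error), runs a Shapiro-Wilk test per cell
#' (default cells: group x condition) and routes to the aligned rank
#' transform if any cell rejects normality at `alpha`, else to the
#' parametric ANOVA. Cells with fewer than 3 values or zero variance are
#' flagged degenerate and do not influence the route.
#'
#' @param df Data frame holding the values and cell columns.
#' @param value Name of the value column.
#' @param cells Character vector of cell-defining columns.
#' @param alpha Gate level.
#' @param log_transform Apply the log before testing (default TRUE).
#' @return List with `route` (`"parametric"` or `"art"`), `shapiro`
#'   (per-cell tibble with `W`, `p`, `degenerate`) and `data` (the input
#'   with a `.value` column of transformed values).
#' @export
transform_and_gate <- function(df, value, cells = c("group", "condition"),
                               alpha = 0.05, log_transform = TRUE) {
  stopifnot(is.data.frame(df), value %in% names(df),
            all(cells %in% names(df)))
  v <- df[[value]]
  if (log_transform) {
    if (any(v <= 0)) {
      stop("nonpositive values under log transform in `", value, "`",
           call. = FALSE)
    }
    v <- log(v)
  }
  out <- df
  out$.value <- v
  cell_test <- function(v) {
    degen <- length(v) < 3 || stats::sd(v) == 0
    if (degen) {
      return(tibble::tibble(n = length(v), degenerate = TRUE,
                            W = NA_real_, p = NA_real_))
    }
    st <- stats::shapiro.test(v)
    tibble::tibble(n = length(v), degenerate = FALSE,
                   W = unname(st$statistic), p = st$p.value)
  }
  shapiro <- out |>
    dplyr::group_by(dplyr::across(dplyr::all_of(cells))) |>
    dplyr::group_modify(~ cell_test(.x$.value)) |>
    dplyr::ungroup()
  reject <- any(shapiro$p < alpha, na.rm = TRUE)
  list(route = if (reject) "art" else "parametric", shapiro = shapiro,
       data = out)
}

# covariate slopes estimated by pooled within-group regression (the model
# includes the design factors so group/condition differences are not
# absorbed into the slopes), then removed from the response
adjust_covariates <- function(df, value, covariates) {
  if (length(covariates) == 0) {
    df$.adj <- df[[value]]
    return(df)
  }
  stopifnot(all(covariates %in% names(df)))
  fml <- stats::reformulate(c("group * condition", covariates),
                            response = value)
  fit <- stats::lm(fml, data = df)
  qr_rank <- fit$rank
  if (qr_rank < length(stats::coef(fit))) {
    stop("rank-deficient covariates", call. = FALSE)
  }
  b <- stats::coef(fit)[covariates]
  df$.adj <- df[[value]] -
    as.matrix(df[, covariates, drop = FALSE]) %*% b
  df$.adj <- as.numeric(df$.adj)
  df
}

check_design <- function(df) {
  req <- c("subject_id", "group", "condition")
  stopifnot(all(req %in% names(df)))
  tab <- table(df$subject_id, df$condition)
  if (!all(tab == 1) || ncol(tab) != 2) {
    bad <- rownames(tab)[rowSums(tab) != 2]
    stop("unbalanced design: every subject needs one EC and one EO row",
         if (length(bad)) paste0(" (", paste(bad, collapse = ", "), ")"),
         call. = FALSE)
  }
  if (length(unique(df$group)) < 2) stop("need at least two groups", call. = FALSE)
  invisible(df)
}

# run aov(y ~ group*condition + Error(subject)) and pull F, dfs, p and
# partial eta squared for the three effects
mixed_aov_table <- function(df, y) {
  df$.y <- y
  df$subject_id <- factor(df$subject_id)
  df$group <- factor(df$group)
  df$condition <- factor(df$condition)
  fit <- stats::aov(.y ~ group * condition + Error(subject_id), data = df)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    rn <- trimws(rownames(tab))
    k <- match(term, rn)
    res <- match("Residuals", rn)
    tibble::tibble(
      effect = term,
      df1 = tab$Df[k], df2 = tab$Df[res],
      F = tab$`F value`[k], p = tab$`Pr(>F)`[k],
      eta2 = tab$`Sum Sq`[k] / (tab$`Sum Sq`[k] + tab$`Sum Sq`[res])
    )
  }
  dplyr::bind_rows(
    pull("Error: subject_id", "group"),
    pull("Error: Within", "condition"),
    pull("Error: Within", "group:condition")
  )
}

#' Parametric mixed ANOVA (condition within, group between)
#'
#' 2 (condition) x 3 (group) mixed-model ANOVA on covariate-adjusted
#' responses: covariate slopes (default age and IQ) are estimated by
#' pooled within-group regression and removed, then the factorial model
#' with a subject error stratum is fitted. Reports F, degrees of freedom,
#' p and partial eta squared for both main effects and the interaction.
#'
#' @param df Data frame with columns `subject_id`, `group`, `condition`,
#'   the response and any covariates; one EC and one EO row per subject.
#' @param value Response column name.
#' @param covariates Covariate column names (may be empty).
#' @return Object of class `mst_anova` (list with `table`, `route`,
#'   `value`); see [tidy.mst_anova()].
#' @export
mixed_anova <- function(df, value, covariates = c("age", "iq")) {
  check_design(df)
  stopifnot(value %in% names(df))
  df <- adjust_covariates(df, value, covariates)
  tab <- mixed_aov_table(df, df$.adj)
  structure(list(table = dplyr::mutate(tab, route = "parametric"),
                 route = "parametric", value = value,
                 n_subjects = length(unique(df$subject_id))),
            class = "mst_anova")
}

#' Aligned-rank-transform mixed ANOVA
#'
#' Nonparametric factorial ANOVA: for each effect (group, condition,
#' interaction) the covariate-adjusted responses are aligned by removing
#' the cell-mean estimates of all other effects, ranked across the full
#' dataset, and the mixed ANOVA of [mixed_anova()] is applied to the
#' ranks, keeping only that effect's row.
#'
#' @inheritParams mixed_anova
#' @return Object of class `mst_anova` with `route = "art"`.
#' @export
art_anova <- function(df, value, covariates = c("age", "iq")) {
  check_design(df)
  stopifnot(value %in% names(df))
  df <- adjust_covariates(df, value, covariates)
  cell <- df |>
    dplyr::group_by(.data$group, .data$condition) |>
    dplyr::summarise(m = mean(.data$.adj), .groups = "drop")
  mu <- mean(cell$m)
  a <- cell |> dplyr::group_by(.data$group) |>
    dplyr::summarise(a = mean(.data$m) - mu)
  b <- cell |> dplyr::group_by(.data$condition) |>
    dplyr::summarise(b = mean(.data$m) - mu)
  df <- df |>
    dplyr::left_join(cell, by = c("group", "condition")) |>
    dplyr::left_join(a, by = "group") |>
    dplyr::left_join(b, by = "condition")
  df$resid <- df$.adj - df$m
  df$ab <- df$m - mu - df$a - df$b
  effects <- list(
    group = df$resid + df$a,
    condition = df$resid + df$b,
    `group:condition` = df$resid + df$ab
  )
  rows <- purrr::imap(effects, function(aligned, eff) {
    tab <- mixed_aov_table(df, rank(aligned))
    tab[tab$effect == eff, ]
  })
  structure(list(table = dplyr::mutate(dplyr::bind_rows(rows), route = "art"),
                 route = "art", value = value,
                 n_subjects = length(unique(df$subject_id))),
            class = "mst_anova")
}

#' @export
print.mst_anova <- function(x, ...) {
  cat(sprintf("<mst_anova> %s route, response `%s`, %d subjects\n",
              x$route, x$value, x$n_subjects))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' Bonferroni-corrected pairwise group comparisons
#'
#' Within each condition, Welch t-tests between all group pairs on the
#' (optionally covariate-adjusted) response; corrected p is the raw p
#' times the family size (comparisons within the condition), capped at 1.
#'
#' @inheritParams mixed_anova
#' @return Tibble with columns `condition`, `group_1`, `group_2`,
#'   `estimate`, `p`, `p_bonferroni`, `family_size`.
#' @export
posthoc_bonferroni <- function(df, value, covariates = c("age", "iq")) {
  check_design(df)
  df <- adjust_covariates(df, value, covariates)
  groups <- sort(unique(df$group))
  if (length(groups) < 2) stop("empty comparison family", call. = FALSE)
  pairs <- utils::combn(groups, 2)
  rows <- purrr::map(unique(df$condition), function(cond) {
    sub <- df[df$condition == cond, ]
    fam <- ncol(pairs)
    purrr::map(seq_len(fam), function(k) {
      g1 <- pairs[1, k]; g2 <- pairs[2, k]
      tt <- stats::t.test(sub$.adj[sub$group == g1],
                          sub$.adj[sub$group == g2])
      tibble::tibble(condition = cond, group_1 = g1, group_2 = g2,
                     estimate = unname(tt$estimate[1] - tt$estimate[2]),
                     p = tt$p.value,
                     p_bonferroni = min(1, tt$p.value * fam),
                     family_size = fam)
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

#' Permutation-tested Pearson correlation
#'
#' Pearson r on the observed pairing; the two-sided permutation p-value is
#' `(1 + #(|r_perm| >= |r_obs|)) / (1 + n_perm)` under random relabelling
#' of `y`. Deterministic under `seed`.
#'
#' @param x,y Paired finite numeric vectors, length >= 4.
#' @param n_perm Number of permutations (default 5000).
#' @param seed Optional integer seed.
#' @return Object of class `perm_cor` (list with `r`, `p`, `n`, `n_perm`);
#'   see [tidy.perm_cor()].
#' @export
#' @examples
#' perm_correlation(1:10, (1:10)^2, n_perm = 200, seed = 1)
perm_correlation <- function(x, y, n_perm = 5000, seed = NULL) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  xc <- x - mean(x); yc <- y - mean(y)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  r_obs <- sum(xc * yc) / denom
  perm_idx <- replicate(n_perm, sample.int(n))
  r_perm <- colSums(xc * matrix(yc[perm_idx], nrow = n)) / denom
  p <- (1 + sum(abs(r_perm) >= abs(r_obs))) / (1 + n_perm)
  structure(list(r = r_obs, p = p, n = n, n_perm = n_perm),
            class = "perm_cor")
}

#' @export
print.perm_cor <- function(x, ...) {
  cat(sprintf("<perm_cor> r = %.3f, permutation p = %.4g (n = %d, %d permutations)\n",
              x$r, x$p, x$n, x$n_perm))
  invisible(x)
}

#' Levene homogeneity diagnostics per condition
#'
#' Brown-Forsythe/Levene test of variance homogeneity across groups within
#' each condition, reported as a diagnostic (non-blocking).
#'
#' @inheritParams mixed_anova
#' @return Tibble with `condition`, `F`, `df1`, `df2`, `p`.
#' @export
levene_homogeneity <- function(df, value) {
  stopifnot(value %in% names(df))
  if (!requireNamespace("car", quietly = TRUE)) {
    stop("the car package is required for Levene diagnostics", call. = FALSE)
  }
  rows <- purrr::map(unique(df$condition), function(cond) {
    sub <- df[df$condition == cond, ]
    lv <- car::leveneTest(sub[[value]], factor(sub$group))
    tibble::tibble(condition = cond, F = lv$`F value`[1],
                   df1 = lv$Df[1], df2 = lv$Df[2], p = lv$`Pr(>F)`[1])
  })
  dplyr::bind_rows(rows)
}

#' Permutation-tested behaviour correlations for a metric family
#'
#' Correlates each requested metric with the behavioural score within each
#' group (subjects relabelled within the group under permutation), with
#' Bonferroni correction across the metric family.
#'
#' @param df Subject-level table with one row per subject (e.g. the EC
#'   rows of one band), holding the metrics and the behaviour column.
#' @param metrics Character vector of metric columns (the correction
#'   family).
#' @param behavior Behaviour column name (default `"acc"`).
#' @param n_perm,seed Permutation settings.
#' @return Tibble with `group`, `metric`, `r`, `p_perm`, `p_bonferroni`,
#'   `n`.
#' @export
correlate_behavior <- function(df, metrics, behavior = "acc",
                               n_perm = 5000, seed = NULL) {
  stopifnot(all(c(metrics, behavior, "group") %in% names(df)))
  if (!is.null(seed)) set.seed(seed)
  fam <- length(metrics)
  rows <- purrr::map(sort(unique(df$group)), function(g) {
    sub <- df[df$group == g, ]
    purrr::map(metrics, function(mt) {
      pc <- tryCatch(
        perm_correlation(sub[[mt]], sub[[behavior]], n_perm = n_perm),
        error = function(e) list(r = NA_real_, p = NA_real_,
                                 n = nrow(sub))
      )
      tibble::tibble(group = g, metric = mt, r = pc$r, p_perm = pc$p,
                     p_bonferroni = min(1, pc$p * fam), n = pc$n)
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}
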