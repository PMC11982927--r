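#' Ordinary least squares with the usual inference summaries
#'
#' Fits `response ~ predictors` with an intercept by QR-based least squares
#' and returns the coefficient table (estimate, SE, t, two-sided p from the
#' t distribution on the error degrees of freedom), the model R-squared, and
#' the F statistic against the constant model. Engagement scores are treated
#' as a continuous response, following this literature's convention; p values
#' are unadjusted for multiple testing.
#'
#' @param data Data frame holding response and predictors.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor column names.
#' @return An object of class `"engage_ols"`: list with `coefficients`
#'   (data frame `term`, `estimate`, `se`, `t`, `p`), `r_squared`,
#'   `f_statistic`, `model_p`, `error_df`, `n`.
#' @export
fit_ols <- function(data, response, predictors) {
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  d <- data[, c(response, predictors), drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  k <- length(predictors)
  if (n <= k + 1L)
    stop("need more observations (", n, ") than parameters (", k + 1L, ")",
         call. = FALSE)
  X <- as.matrix(d[, predictors, drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < k + 1L) {
    piv <- qrX$pivot[seq_len(qrX$rank)]
    bad <- c("(Intercept)", predictors)[setdiff(seq_len(k + 1L), piv)]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fml <- stats::reformulate(sprintf("`%s`", predictors),
                            response = sprintf("`%s`", response))
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)
  ct <- sm$coefficients
  coefs <- data.frame(term = c("(Intercept)", predictors),
                      estimate = ct[, 1], se = ct[, 2], t = ct[, 3], p = ct[, 4],
                      row.names = NULL)
  fstat <- sm$fstatistic
  out <- list(coefficients = coefs,
              r_squared = unname(sm$r.squared),
              f_statistic = unname(fstat[1]),
              model_p = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                         lower.tail = FALSE)),
              error_df = unname(fit$df.residual),
              n = n)
  class(out) <- "engage_ols"
  out
}

#' @export
print.engage_ols <- function(x, ...) {
  cat(sprintf("Linear engagement model: n = %d, error df = %d\n", x$n, x$error_df))
  cat(sprintf("R^2 = %.4g, F vs constant = %.4g (p = %.4g)\n",
              x$r_squared, x$f_statistic, x$model_p))
  print(x$coefficients, digits = 5)
  cat("p values are unadjusted for multiple testing\n")
  invisible(x)
}

#' Individual-predictor and joint regression report
#'
#' The two-row-per-predictor report layout standard in this literature:
#' each predictor is fit alone (with intercept)
#' giving its individual coefficient, SE, R-squared and p value, and all
#' predictors are fit jointly giving the total coefficient, SE, t and p,
#' with a shared total R-squared, F statistic and error df.
#'
#' @inheritParams fit_ols
#' @return An object of class `"regression_report"`: data frame with one row
#'   per predictor and columns `individual_coef`, `individual_se`,
#'   `individual_r2`, `individual_p`, `total_coef`, `total_se`, `total_t`,
#'   `total_p`; attributes `total_r2`, `f_statistic`, `model_p`, `error_df`,
#'   `n`, and `total_fit` (the joint `engage_ols`).
#' @export
individual_and_total <- function(data, response, predictors) {
  total <- fit_ols(data, response, predictors)
  rows <- lapply(predictors, function(p) {
    f <- fit_ols(data, response, p)
    co <- f$coefficients[f$coefficients$term == p, ]
    data.frame(predictor = p,
               individual_coef = co$estimate, individual_se = co$se,
               individual_r2 = f$r_squared, individual_p = co$p)
  })
  rep_ <- do.call(rbind, rows)
  tc <- total$coefficients[match(predictors, total$coefficients$term), ]
  rep_$total_coef <- tc$estimate
  rep_$total_se <- tc$se
  rep_$total_t <- tc$t
  rep_$total_p <- tc$p
  attr(rep_, "total_r2") <- total$r_squared
  attr(rep_, "f_statistic") <- total$f_statistic
  attr(rep_, "model_p") <- total$model_p
  attr(rep_, "error_df") <- total$error_df
  attr(rep_, "n") <- total$n
  attr(rep_, "total_fit") <- total
  class(rep_) <- c("regression_report", "data.frame")
  rep_
}

#' Downsample score groups to a common size
#'
#' Reduces every group to the size of the smallest by seeded sampling
#' without replacement, so a one-way ANOVA compares balanced groups
#' (hosts differ widely in how many events they led).
#'
#' @param scores Numeric vector.
#' @param group Grouping vector, same length.
#' @param seed Integer seed; recorded on the result for provenance.
#' @return Data frame `score`, `group` with equal group sizes; attribute
#'   `seed`.
#' @export
downsample_equal <- function(scores, group, seed = 20260101L) {
  stopifnot(length(scores) == length(group))
  group <- as.character(group)
  sizes <- table(group)
  if (length(sizes) < 2L) stop("need at least two groups", call. = FALSE)
  m <- min(sizes)
  # local RNG: seeded draws must not disturb the caller's RNG stream
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  idx <- unlist(lapply(names(sizes), function(g) {
    gi <- which(group == g)
    if (length(gi) > m) sort(sample(gi, m)) else gi
  }))
  out <- data.frame(score = scores[idx], group = group[idx])
  attr(out, "seed") <- seed
  out
}

#' One-way ANOVA with eta-squared and Tukey HSD
#'
#' Tests whether group mean engagement differs across groups (e.g. hosts),
#' reporting the eta-squared effect size `SS_between / SS_total`, the F-test
#' p value, per-group means and sizes, and Tukey honestly-significant-
#' difference pairwise comparisons at the given confidence level.
#'
#' @param scores Numeric vector.
#' @param group Grouping vector, >= 2 groups with >= 2 observations each.
#' @param conf_level Tukey family-wise confidence level (default 0.95).
#' @return An object of class `"anova_report"`: list with `eta_squared`,
#'   `f_statistic`, `df`, `p_value`, `group_means`, `group_ns`, `tukey`
#'   (data frame `comparison`, `diff`, `lwr`, `upr`, `p_adj`, `significant`).
#' @export
anova_eta2 <- function(scores, group, conf_level = 0.95) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(group) < 2L))
    stop("every group needs at least two observations", call. = FALSE)
  if (stats::var(scores) == 0)
    stop("zero total variance: all scores identical", call. = FALSE)
  d <- data.frame(score = scores, group = group)
  fit <- stats::aov(score ~ group, data = d)
  tab <- summary(fit)[[1]]
  ssb <- tab["group", "Sum Sq"]
  sst <- sum(tab[, "Sum Sq"])
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$group
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < (1 - conf_level),
                      row.names = NULL)
  out <- list(eta_squared = ssb / sst,
              f_statistic = tab["group", "F value"],
              df = c(between = tab["group", "Df"],
                     within = tab["Residuals", "Df"]),
              p_value = tab["group", "Pr(>F)"],
              group_means = tapply(scores, group, mean),
              group_ns = as.integer(table(group)),
              tukey = tukey)
  class(out) <- "anova_report"
  out
}

#' @export
print.anova_report <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g, eta^2 = %.4g\n",
              x$df["between"], x$df["within"], x$f_statistic, x$p_value,
              x$eta_squared))
  cat("Group means:\n"); print(round(x$group_means, 4))
  cat("Tukey HSD:\n"); print(x$tukey, digits = 4)
  invisible(x)
}

#' Host-effect ANOVA with balanced downsampling
#'
#' Convenience wrapper for facilitator-effect comparisons: restrict to the
#' requested hosts, downsample every host's scores to the smallest host's
#' event count, then run [anova_eta2()] (typically once over all four
#' hosts and once over the three highest-volume hosts).
#'
#' @param events Event table with host indicator columns.
#' @param hosts Integer vector of host ids to compare (default 1:4).
#' @param rater 1 or 2: which rater's scores to use.
#' @param seed Downsampling seed.
#' @return An `"anova_report"` with attribute `seed`.
#' @export
host_anova <- function(events, hosts = 1:4, rater = 1, seed = 20260101L) {
  score_col <- if (rater == 1) "score_r1" else "score_r2"
  hid <- host_id(events)
  keep <- hid %in% hosts
  ds <- downsample_equal(events[[score_col]][keep], hid[keep], seed = seed)
  out <- anova_eta2(ds$score, ds$group)
  attr(out, "seed") <- seed
  out
}

#' Inter-rater percent agreement on Likert scores
#'
#' Percent of aligned score pairs agreeing exactly, percent differing by
#' exactly one point, and their sum (approximate agreement).
#'
#' @param scores_r1,scores_r2 Equal-length integer score vectors.
#' @return List `pct_exact`, `pct_within_one`, `pct_approx`, `n`.
#' @export
interrater_agreement <- function(scores_r1, scores_r2) {
  if (length(scores_r1) != length(scores_r2))
    stop("score vectors differ in length", call. = FALSE)
  ok <- !is.na(scores_r1) & !is.na(scores_r2)
  d <- abs(scores_r1[ok] - scores_r2[ok])
  n <- sum(ok)
  if (!n) stop("no aligned score pairs", call. = FALSE)
  exact <- 100 * mean(d == 0)
  within1 <- 100 * mean(d == 1)
  list(pct_exact = exact, pct_within_one = within1,
       pct_approx = exact + within1, n = n)
}

# Predictor sets for the engagement model families.
.model_predictors <- list(
  hosts = c("host1", "host2", "host3"),
  behaviors = c("social", "humor", "game", "cue", "affirm", "disclose",
                "correct", "nonverbal"),
  acoustic = paste0("d_", c("mean_pitch", "max_pitch", "min_pitch",
                            "mean_int", "max_int", "min_int")),
  time = c("host_time", "control_time", "participant_time",
           "participant_fraction", "silence_fraction"),
  general = c("social", "humor", "game", "cue", "affirm", "disclose",
              "correct", "nonverbal", "host1", "host2", "host3", "number",
              "participant_time", "host_time", "control_time",
              "participant_fraction", "silence_fraction")
)

#' Assemble the modelling table for a model family
#'
#' Joins the coded events with per-event time-budget (and, for the acoustic
#' family, entrainment proximity) features and returns the columns needed by
#' one of the model families: `hosts`, `behaviors`, `acoustic`, `time`,
#' `number`, or `general` (all predictors except the acoustic ones, which
#' are conventionally dropped from the general model as insignificant).
#'
#' @param events Event table.
#' @param time_features Optional output of [event_time_features()].
#' @param proximity Optional output of [event_proximity_table()]; required
#'   for `model = "acoustic"` (events without valid proximity are dropped
#'   by the fit through missing-value handling).
#' @param model Model family name.
#' @param rater 1 or 2.
#' @return List `data` (modelling frame with `score` column), `predictors`.
#' @export
engagement_design <- function(events, time_features = NULL, proximity = NULL,
                              model = c("general", "hosts", "behaviors",
                                        "acoustic", "time", "number"),
                              rater = 1) {
  model <- match.arg(model)
  score_col <- if (rater == 1) "score_r1" else "score_r2"
  if (!score_col %in% names(events))
    stop("events lack column ", score_col, call. = FALSE)
  d <- as.data.frame(events)
  d$score <- d[[score_col]]
  if (!is.null(time_features))
    d <- cbind(d, time_features[, c("host_time", "control_time",
                                    "participant_time", "participant_fraction",
                                    "silence_fraction")])
  if (!is.null(proximity))
    d <- cbind(d, proximity[, paste0("d_", .prox_cols)])
  predictors <- if (model == "number") "number" else .model_predictors[[model]]
  missing_cols <- setdiff(predictors, names(d))
  if (length(missing_cols))
    stop("modelling table lacks column(s): ",
         paste(missing_cols, collapse = ", "),
         " (supply time_features/proximity)", call. = FALSE)
  list(data = d[, c("score", predictors)], predictors = predictors)
}

#' Fit one of the engagement model families
#'
#' @inheritParams engagement_design
#' @return A `"regression_report"` from [individual_and_total()].
#' @export
fit_engagement_model <- function(events, time_features = NULL, proximity = NULL,
                                 model = c("general", "hosts", "behaviors",
                                           "acoustic", "time", "number"),
                                 rater = 1) {
  dz <- engagement_design(events, time_features, proximity, model, rater)
  individual_and_total(dz$data, "score", dz$predictors)
}
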