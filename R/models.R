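#' Cohen's f from an F statistic
#'
#' `f = sqrt(F * df_num / df_den)`, the effect size companion of a fixed
#' effect's F test.
#'
#' @param F_value F statistic (>= 0).
#' @param df_num,df_den Numerator and denominator degrees of freedom.
#' @return Cohen's f.
#' @examples
#' cohens_f_from_F(8.37, 1, 77)  # ~0.33
#' @export
cohens_f_from_F <- function(F_value, df_num, df_den) {
  if (any(df_num < 1) || any(df_den < 1))
    stop("degrees of freedom must be >= 1", call. = FALSE)
  if (any(F_value < 0)) stop("F must be non-negative", call. = FALSE)
  sqrt(F_value * df_num / df_den)
}

# deterministic coding: HC is the reference level when both labels occur
group_factor <- function(g) {
  lv <- unique(as.character(g))
  if (setequal(lv, c("HC", "aMCI"))) factor(g, c("HC", "aMCI"))
  else factor(g)
}

new_ol_model <- function(name, fit, coefficients, anova = NULL,
                         notes = character(0)) {
  structure(list(name = name, fit = fit, coefficients = coefficients,
                 anova = anova, notes = notes),
            class = "ol_model")
}

#' @export
print.ol_model <- function(x, digits = 3, ...) {
  cat("Model:", x$name, "\n")
  if (!is.null(x$anova)) {
    cat("F tests (Satterthwaite df):\n")
    print(x$anova, digits = digits, row.names = FALSE)
  }
  cat("Fixed effects:\n")
  print(x$coefficients, digits = digits, row.names = FALSE)
  for (nt in x$notes) cat("Note:", nt, "\n")
  invisible(x)
}

coef_table <- function(sm, or = FALSE) {
  ct <- as.data.frame(sm)
  names(ct)[1:2] <- c("estimate", "se")
  pcol <- grep("^Pr", names(ct))
  statcol <- grep("value$", names(ct))[1]
  out <- data.frame(term = rownames(ct), estimate = ct$estimate,
                    se = ct$se, statistic = ct[[statcol]],
                    p = ct[[pcol]])
  if (or) {
    out$or <- exp(out$estimate)
    out$or_low <- exp(out$estimate - 1.96 * out$se)
    out$or_high <- exp(out$estimate + 1.96 * out$se)
  }
  rownames(out) <- NULL
  out
}

prep_scores <- function(scores, covariates) {
  scores$group <- group_factor(scores$group)
  scores$cue <- factor(scores$cue)
  scores$participant_id <- factor(scores$participant_id)
  if (nlevels(scores$group) != 2L)
    stop("need exactly 2 groups, got ", nlevels(scores$group),
         call. = FALSE)
  if (nlevels(scores$cue) != 2L)
    stop("both cue conditions must be present", call. = FALSE)
  miss <- setdiff(covariates, names(scores))
  if (length(miss))
    stop("covariates not in scores: ", paste(miss, collapse = ", "),
         call. = FALSE)
  scores
}

anova_table <- function(fit) {
  a <- stats::anova(fit, type = 3)
  data.frame(term = rownames(a), df_num = a$NumDF, df_den = a$DenDF,
             F_value = a$`F value`, p = a$`Pr(>F)`,
             f = cohens_f_from_F(a$`F value`, a$NumDF, a$DenDF))
}

#' Linear mixed-effects ANOVA for recall error
#'
#' Fits `error ~ group * cue + covariates + (1 | participant)` with
#' REML and reports type-III F tests with Satterthwaite denominator
#' degrees of freedom, together with Cohen's f for each term.
#'
#' @param scores Per-trial score table from [score_cohort()].
#' @param response Name of the response column (default `"error"`;
#'   `"response_time_s"` gives the recall-time model).
#' @param covariates Optional character vector of additional fixed-effect
#'   terms (columns of `scores`, or interaction terms like `"age:gender"`).
#' @return An `ol_model` with `$anova` (term, df, F, p, f) and
#'   `$coefficients`.
#' @export
fit_error_mixed_anova <- function(scores, response = "error",
                                  covariates = NULL) {
  cov_cols <- unique(unlist(strsplit(covariates %||% character(0), ":")))
  scores <- prep_scores(scores, cov_cols)
  rhs <- paste(c("group * cue", covariates), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs,
                                 "+ (1 | participant_id)"))
  fit <- lmerTest::lmer(fml, data = scores)
  conv <- fit@optinfo$conv$lme4
  if (!is.null(conv$messages))
    warning("mixed model convergence: ",
            paste(conv$messages, collapse = "; "), call. = FALSE)
  new_ol_model(paste("mixed ANOVA:", response), fit,
               coef_table(stats::coef(summary(fit))),
               anova_table(fit))
}

#' Polynomial trial-course mixed model
#'
#' Extends the error model with orthogonal polynomial terms in the trial
#' index (default degree 2) and their interactions with group and cue,
#' to test improvement or deterioration across testing trials.
#'
#' @inheritParams fit_error_mixed_anova
#' @param degree Polynomial degree (>= 1); orthogonal coding.
#' @return An `ol_model`.
#' @export
fit_trial_polynomial_model <- function(scores, response = "error",
                                       degree = 2, covariates = NULL) {
  stopifnot(degree >= 1)
  scores <- prep_scores(scores, NULL)
  if (!"trial_index" %in% names(scores))
    stop("scores need a trial_index column", call. = FALSE)
  rhs <- paste(c(sprintf("group * cue * poly(trial_index, %d)", degree),
                 covariates), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs,
                                 "+ (1 | participant_id)"))
  fit <- lmerTest::lmer(fml, data = scores)
  new_ol_model(sprintf("trial-course polynomial (degree %d): %s",
                       degree, response),
               fit, coef_table(stats::coef(summary(fit))),
               anova_table(fit))
}

#' Switching-condition mixed ANOVA
#'
#' Group x switch-condition model of recall error over trials 2..n
#' (first trials carry no transition and are excluded).
#'
#' @inheritParams fit_error_mixed_anova
#' @return An `ol_model`.
#' @export
fit_switching_anova <- function(scores, response = "error",
                                covariates = NULL) {
  scores <- scores[scores$switch_label != "first_trial", ]
  scores$group <- group_factor(scores$group)
  scores$switch_label <- factor(scores$switch_label,
                                levels = c("no_switch", "ego_to_allo",
                                           "allo_to_ego"))
  scores$participant_id <- factor(scores$participant_id)
  rhs <- paste(c("group * switch_label", covariates), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs,
                                 "+ (1 | participant_id)"))
  fit <- lmerTest::lmer(fml, data = scores)
  new_ol_model(paste("switching ANOVA:", response), fit,
               coef_table(stats::coef(summary(fit))),
               anova_table(fit))
}

#' Attractor-index mixed model
#'
#' Fits one attractor index (landmark or centre) with group as the fixed
#' predictor and random intercepts for participants and objects.
#'
#' @inheritParams fit_error_mixed_anova
#' @param index `"landmark"` or `"center"`.
#' @return An `ol_model`.
#' @export
fit_attractor_model <- function(scores, index = c("landmark", "center")) {
  index <- match.arg(index)
  col <- paste0(index, "_index")
  scores$group <- group_factor(scores$group)
  scores$participant_id <- factor(scores$participant_id)
  scores$object_id <- factor(scores$object_id)
  fml <- stats::as.formula(paste(col, "~ group + (1 | participant_id)",
                                 "+ (1 | object_id)"))
  fit <- lmerTest::lmer(fml, data = scores)
  new_ol_model(paste(index, "attractor index model"), fit,
               coef_table(stats::coef(summary(fit))),
               anova_table(fit))
}

#' Poisson model of object-location binding errors
#'
#' Log-linear model of per-participant, per-cue binding counts with
#' group, cue and their interaction (plus optional covariates).
#'
#' @param counts Output of [binding_errors()].
#' @param covariates Optional additional fixed-effect terms.
#' @return An `ol_model`; coefficients carry rate ratios in `$or`.
#' @export
fit_binding_poisson <- function(counts, covariates = NULL) {
  counts$group <- group_factor(counts$group)
  counts$cue <- factor(counts$cue)
  rhs <- paste(c("group * cue", covariates), collapse = " + ")
  fml <- stats::as.formula(paste("binding_count ~", rhs))
  fit <- stats::glm(fml, family = stats::poisson(), data = counts)
  if (!fit$converged) stop("Poisson model did not converge", call. = FALSE)
  new_ol_model("Poisson binding model", fit,
               coef_table(stats::coef(summary(fit)), or = TRUE))
}

#' Logistic diagnosis model
#'
#' Models group membership from per-participant predictors (typically
#' per-cue or per-switch-condition mean errors, see
#' [participant_cue_means()]); reports coefficients, odds ratios and
#' Wald 95\% CIs. Perfect or quasi-perfect separation is detected and,
#' when `glmnet` is available, a ridge-penalised fallback fit is returned
#' and flagged in `$notes`; otherwise an error advises it.
#'
#' @param data Data frame of per-participant predictors including a
#'   `group` column.
#' @param predictors Character vector of predictor columns.
#' @param positive Group label modelled as the positive (diagnosed)
#'   class; defaults to `"aMCI"` when that label is present, otherwise
#'   the second factor level.
#' @return An `ol_model`.
#' @export
fit_logistic_diagnosis <- function(data, predictors,
                                   positive = NULL) {
  stopifnot(all(predictors %in% names(data)), "group" %in% names(data))
  g <- factor(data$group)
  if (nlevels(g) != 2L) stop("need exactly 2 groups", call. = FALSE)
  if (is.null(positive))
    positive <- if ("aMCI" %in% levels(g)) "aMCI" else levels(g)[2]
  data$.y <- as.integer(g == positive)
  fml <- stats::as.formula(paste(".y ~",
                                 paste(predictors, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = data))
  sep <- !fit$converged ||
    any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE) ||
    all(abs(fit$fitted.values - 0.5) > 0.5 - 1e-8)
  notes <- paste("positive class:", positive)
  if (sep) {
    if (!requireNamespace("glmnet", quietly = TRUE))
      stop("separation detected; install glmnet for the ridge-penalised ",
           "fallback", call. = FALSE)
    X <- stats::model.matrix(fml, data)[, -1, drop = FALSE]
    pnames <- colnames(X)
    if (ncol(X) == 1L) X <- cbind(X, .pad = 0)  # glmnet needs >= 2 cols
    gn <- glmnet::glmnet(X, data$.y, family = "binomial", alpha = 0,
                         lambda = 1e-3)
    beta <- c(`(Intercept)` = as.numeric(gn$a0),
              stats::setNames(as.numeric(gn$beta), rownames(gn$beta)))
    beta <- beta[c("(Intercept)", pnames)]
    ct <- data.frame(term = names(beta), estimate = beta,
                     se = NA_real_, statistic = NA_real_, p = NA_real_,
                     or = exp(beta), or_low = NA_real_, or_high = NA_real_)
    rownames(ct) <- NULL
    return(new_ol_model("logistic diagnosis model (ridge fallback)", gn,
                        ct, notes = c(notes,
                                      "separation detected: ridge-penalised fit, no Wald inference")))
  }
  new_ol_model("logistic diagnosis model", fit,
               coef_table(stats::coef(summary(fit)), or = TRUE),
               notes = notes)
}

#' ROC analysis with the Youden-index cutoff
#'
#' AUC by pairwise rank concordance (ties get half credit), and the
#' operating cutoff that maximises the Youden index
#' `J = sensitivity + specificity - 1`. A case is called positive when
#' `score >= cutoff`. When several cutoffs attain the maximal J, the
#' smallest is chosen and `tie` is set.
#'
#' @param scores Numeric classifier scores (higher = more positive-like).
#' @param labels Binary labels (logical, 0/1, or a 2-level factor whose
#'   second level is positive unless `positive` is given).
#' @param positive Label value treated as positive.
#' @return Object of class `roc_result`: `auc`, `optimal_cutoff`,
#'   `sensitivity`, `specificity`, `accuracy`, `youden`, `tie`, and the
#'   full `curve` (cutoff, sensitivity, specificity) table.
#' @examples
#' roc_youden(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc  # 0.75
#' @export
roc_youden <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  if (is.null(positive)) {
    f <- factor(labels)
    if (nlevels(f) != 2L)
      stop("labels must take exactly 2 values", call. = FALSE)
    y <- as.integer(f) == 2L
  } else y <- labels == positive
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  cuts <- sort(unique(scores))
  sens <- vapply(cuts, function(c) sum(y & scores >= c) / n1, 0)
  spec <- vapply(cuts, function(c) sum(!y & scores < c) / n0, 0)
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  i <- best[1L]
  structure(list(auc = auc, optimal_cutoff = cuts[i],
                 sensitivity = sens[i], specificity = spec[i],
                 accuracy = (sum(y & scores >= cuts[i]) +
                               sum(!y & scores < cuts[i])) / (n0 + n1),
                 youden = j[i], tie = length(best) > 1L,
                 curve = data.frame(cutoff = cuts, sensitivity = sens,
                                    specificity = spec, youden = j)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, digits = 3, ...) {
  cat("ROC analysis: AUC =", round(x$auc, digits), "\n")
  cat("Youden-optimal cutoff:", round(x$optimal_cutoff, digits),
      if (x$tie) "(tie: smallest of equal-J cutoffs)", "\n")
  cat("  sensitivity", round(x$sensitivity, digits),
      " specificity", round(x$specificity, digits),
      " accuracy", round(x$accuracy, digits), "\n")
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  o <- order(1 - x$curve$specificity, x$curve$sensitivity)
  graphics::plot(c(1, 1 - x$curve$specificity[o], 0),
                 c(1, x$curve$sensitivity[o], 0), type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("ROC (AUC = %.2f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
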