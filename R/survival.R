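# Prognostic analysis: univariate Cox screening, linear risk scores,
# mean-cutoff stratification, Kaplan-Meier curves, log-rank tests and
# group-wise expression comparisons. Model fitting is delegated to the
# survival package (Efron tie handling); the risk-score construction and
# stratification rule are implemented here.

align_covariate <- function(expr_vector, clinical) {
  if (!is.null(names(expr_vector))) {
    common <- intersect(clinical$sample_id, names(expr_vector))
    clinical <- filter(clinical, .data$sample_id %in% common)
    x <- expr_vector[clinical$sample_id]
  } else {
    if (length(expr_vector) != nrow(clinical)) {
      abort("unnamed covariate must align with the clinical table rows.")
    }
    x <- expr_vector
  }
  ok <- complete.cases(x, clinical$time, clinical$event)
  list(x = x[ok], clinical = clinical[ok, , drop = FALSE])
}

#' Univariate Cox proportional-hazards fit for one gene
#'
#' Maximises the Cox partial likelihood (Efron handling of tied event
#' times) for a single continuous covariate; reports the log hazard
#' ratio, `HR = exp(coef)`, a 95% Wald confidence interval and the Wald
#' p-value. Monotone-likelihood non-convergence is flagged via
#' `converged = FALSE` (infinite-HR marker) rather than an error.
#'
#' @param expr_vector Numeric covariate, named by `sample_id` (or aligned
#'   with `clinical` rows).
#' @param clinical Clinical tibble with `sample_id`, `time`, `event`.
#' @param gene_id Optional label for the output row.
#' @return One-row tibble: `gene_id`, `coef`, `hr`, `ci_low`, `ci_high`,
#'   `p`, `n_used`, `n_events`, `converged`.
#' @export
fit_cox_univariate <- function(expr_vector, clinical, gene_id = "x") {
  al <- align_covariate(expr_vector, clinical)
  x <- al$x; cl <- al$clinical
  if (sum(cl$event) < 2L) abort("need >= 2 observed events.")
  if (length(unique(x)) < 2L) abort("no information: constant covariate.")
  fit <- survival::coxph(survival::Surv(cl$time, cl$event) ~ x, ties = "efron")
  beta <- unname(coef(fit))
  se <- sqrt(diag(fit$var))[1]
  converged <- is.finite(beta) && is.finite(se) && abs(beta) < 15
  tibble(
    gene_id = gene_id,
    coef = beta,
    hr = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    p = 2 * stats::pnorm(-abs(beta / se)),
    n_used = fit$n,
    n_events = fit$nevent,
    converged = converged
  )
}

#' Univariate Cox screen over many genes
#'
#' Runs [fit_cox_univariate()] for each gene of an expression matrix;
#' genes that cannot be fitted (constant expression, too few events)
#' yield an `NA` row and a message instead of aborting the screen.
#'
#' @param expr Expression matrix (genes x samples).
#' @param clinical Clinical tibble.
#' @param genes Genes to screen (default: all rows of `expr`).
#' @return Tibble, one row per gene, broom-style.
#' @export
cox_screen <- function(expr, clinical, genes = rownames(expr)) {
  missing_g <- setdiff(genes, rownames(expr))
  if (length(missing_g)) {
    abort(sprintf("gene(s) absent from expression matrix: %s",
                  paste(head(missing_g, 5), collapse = ", ")))
  }
  out <- map(genes, function(g) {
    tryCatch(fit_cox_univariate(expr[g, ], clinical, gene_id = g),
             error = function(e) {
               tibble(gene_id = g, coef = NA_real_, hr = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                      n_used = NA_integer_, n_events = NA_integer_,
                      converged = NA)
             })
  })
  out <- list_rbind(out)
  if (anyNA(out$coef)) {
    inform(sprintf("%d gene(s) could not be fitted.", sum(is.na(out$coef))))
  }
  out
}

#' Linear risk score
#'
#' Per-sample score `sum_i r_i * Exp_i` over the model's genes, where
#' `r_i` are (Cox) regression coefficients. Samples missing expression
#' for any model gene are scored `NA` with a message.
#'
#' @param model Tibble with `gene_id` and `coef` (e.g. from
#'   [cox_screen()]), or a named numeric vector of coefficients.
#' @param expr Expression matrix containing every model gene.
#' @return Tibble with `sample_id`, `score`.
#' @export
risk_score <- function(model, expr) {
  if (is.numeric(model)) {
    model <- tibble(gene_id = names(model), coef = unname(model))
  }
  missing_g <- setdiff(model$gene_id, rownames(expr))
  if (length(missing_g)) {
    abort(sprintf("model gene(s) absent from expression: %s",
                  paste(head(missing_g, 5), collapse = ", ")))
  }
  sub <- expr[model$gene_id, , drop = FALSE]
  score <- as.vector(crossprod(sub, model$coef))
  if (anyNA(score)) {
    inform(sprintf("%d sample(s) scored NA (missing expression).", sum(is.na(score))))
  }
  tibble(sample_id = colnames(expr), score = score)
}

#' Stratify samples at the mean risk score
#'
#' Samples with score strictly greater than the mean are `high` risk;
#' the rest (including scores exactly at the mean) are `low`. All-equal
#' scores admit no split and raise an error.
#'
#' @param scores Tibble with `sample_id` and `score`, or a numeric vector.
#' @return Input tibble plus a `group` factor (`low`, `high`).
#' @export
stratify_by_mean <- function(scores) {
  if (is.numeric(scores)) {
    scores <- tibble(sample_id = names(scores) %||% as.character(seq_along(scores)),
                     score = unname(scores))
  }
  sc <- scores$score[!is.na(scores$score)]
  if (length(sc) < 2L) abort("need >= 2 scored samples.")
  if (diff(range(sc)) == 0) abort("all scores identical: no split possible.")
  cut <- mean(sc)
  scores$group <- factor(ifelse(scores$score > cut, "high", "low"),
                         levels = c("low", "high"))
  attr(scores, "cutoff") <- cut
  scores
}

#' Kaplan-Meier product-limit estimator
#'
#' @param time Follow-up times (>= 0).
#' @param event Event indicators (1 = observed, 0 = censored).
#' @param group Optional grouping factor for stratified curves.
#' @return Tibble of curve steps: `group` (if any), `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`. A `time = 0, surv = 1` anchor row is
#'   included per group.
#' @export
kaplan_meier <- function(time, event, group = NULL) {
  if (!length(time)) abort("empty cohort.")
  if (any(time < 0)) abort("times must be >= 0.")
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    groups <- factor(rep("all", length(fit$time)))
  } else {
    fit <- survival::survfit(survival::Surv(time, event) ~ group)
    groups <- factor(rep(sub("^group=", "", names(fit$strata)), fit$strata))
  }
  out <- tibble(group = groups, time = fit$time, n_risk = fit$n.risk,
                n_event = fit$n.event, n_censor = fit$n.censor, surv = fit$surv)
  anchors <- distinct(out, .data$group) |>
    mutate(time = 0, n_risk = NA_real_, n_event = 0, n_censor = 0, surv = 1)
  bind_rows(anchors, out) |> arrange(.data$group, .data$time)
}

#' Log-rank test between survival groups
#'
#' Standard observed-minus-expected statistic with hypergeometric
#' variance at each distinct event time; p from a chi-square with
#' `n_groups - 1` degrees of freedom.
#'
#' @param time,event Survival outcome.
#' @param group Group labels (>= 2 non-empty groups).
#' @return Tibble with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2L) abort("need >= 2 non-empty groups.")
  if (sum(event) < 1L) abort("need >= 1 observed event.")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  tibble(chisq = fit$chisq, df = df,
         p = pchisq(fit$chisq, df = df, lower.tail = FALSE))
}

#' Module prognosis: risk-score stratification of a gene set
#'
#' Implements the module survival procedure: fit a univariate Cox model
#' per module gene on the selected sample subset, combine the fitted
#' coefficients into a linear risk score, split the cohort at the mean
#' score, and compare the high- and low-risk groups by Kaplan-Meier /
#' log-rank.
#'
#' @param genes Character vector of module gene ids (present in `expr`).
#' @param expr Expression matrix (genes x samples).
#' @param clinical Clinical tibble (`sample_id`, `time`, `event`, ...).
#' @param ... Optional dplyr filter expressions applied to `clinical` to
#'   select the cohort subset (e.g. `subtype == "LumA"`).
#' @param coef_source Fit the per-gene Cox coefficients on the subset
#'   (default) or on the full cohort.
#' @return Object of class `stratified_cohort`: `cox` (per-gene fits),
#'   `scores` (with `group`), `km` (curve steps), `logrank`, `cutoff`.
#' @export
module_prognosis <- function(genes, expr, clinical, ...,
                             coef_source = c("subset", "full")) {
  coef_source <- match.arg(coef_source)
  dots <- enquos(...)
  subset_cl <- if (length(dots)) filter(clinical, !!!dots) else clinical
  if (nrow(subset_cl) == 0L) abort("subset filter matched zero samples.")
  subset_cl <- filter(subset_cl, .data$sample_id %in% colnames(expr))
  if (sum(subset_cl$event) < 2L) abort("subset has < 2 observed events.")
  fit_cl <- if (coef_source == "subset") subset_cl else clinical
  cox <- cox_screen(expr, fit_cl, genes = genes)
  usable <- filter(cox, !is.na(.data$coef))
  if (nrow(usable) == 0L) abort("no module gene could be fitted.")
  scores <- risk_score(usable, expr[, subset_cl$sample_id, drop = FALSE])
  strat <- stratify_by_mean(scores)
  dat <- inner_join(strat, subset_cl, by = "sample_id")
  km <- kaplan_meier(dat$time, dat$event, dat$group)
  lr <- logrank_test(dat$time, dat$event, dat$group)
  structure(list(cox = cox, scores = strat, km = km, logrank = lr,
                 cutoff = attr(strat, "cutoff"),
                 n = nrow(dat), n_events = sum(dat$event)),
            class = "stratified_cohort")
}

#' @export
print.stratified_cohort <- function(x, ...) {
  tab <- table(x$scores$group)
  cat(sprintf(
    "<stratified_cohort> %d samples (%d events): %d low / %d high risk; log-rank p = %.3g\n",
    x$n, x$n_events, tab[["low"]], tab[["high"]], x$logrank$p))
  invisible(x)
}

#' @export
tidy.stratified_cohort <- function(x, ...) x$km

#' @export
glance.stratified_cohort <- function(x, ...) {
  tab <- table(x$scores$group)
  tibble(n = x$n, n_events = x$n_events,
         n_low = tab[["low"]], n_high = tab[["high"]],
         cutoff = x$cutoff, chisq = x$logrank$chisq, p = x$logrank$p)
}

#' Two-group expression comparison
#'
#' Wilcoxon rank-sum by default (exact for small untied samples,
#' otherwise normal approximation with tie correction, the
#' [stats::wilcox.test()] policy); Welch t-test selectable. Both groups
#' need at least 3 samples.
#'
#' @param x Numeric expression values.
#' @param labels Two-level group labels aligned with `x`.
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @return Tibble with `statistic`, `p`, `method`, `n1`, `n2`.
#' @export
compare_expression_groups <- function(x, labels, method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2L) abort("labels must define exactly 2 groups.")
  n <- table(labels)
  if (any(n < 3L)) abort("both groups need >= 3 samples.")
  g1 <- x[labels == levels(labels)[1]]
  g2 <- x[labels == levels(labels)[2]]
  ht <- if (method == "wilcoxon") {
    suppressWarnings(wilcox.test(g1, g2))
  } else {
    t.test(g1, g2)
  }
  tibble(statistic = unname(ht$statistic), p = ht$p.value, method = method,
         n1 = unname(n[1]), n2 = unname(n[2]))
}
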