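# Evaluation layer: Spearman correlation, Mann-Whitney AUC, DeLong
# confidence intervals and paired tests, influence-function confidence
# intervals for cross-validated AUC, and exploratory association of
# principal components with clinical covariates.

#' Spearman correlation between predicted and actual RCB scores
#'
#' Rank correlation with mid-rank ties and the large-sample p-value
#' approximation.
#'
#' @param pred,y numeric vectors of equal length (>= 3).
#' @return list with `rho` and `p`.
#' @export
spearman_eval <- function(pred, y) {
  if (length(pred) != length(y) || length(y) < 3)
    stop("need two equal-length vectors of length >= 3")
  if (sd(pred) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant vector")
  ct <- suppressWarnings(cor.test(pred, y, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' @noRd
check_binary <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2)
    stop("both classes must be present")
  labels
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Equals the probability that a random positive's score exceeds a random
#' negative's, counting ties as one half. `direction = "lower"` declares
#' that lower scores indicate the positive class (the orientation used for
#' predicted RCB against responder/pCR endpoints) and is equivalent to
#' negating the scores.
#'
#' @param scores numeric vector.
#' @param labels binary vector (1 = positive class).
#' @param direction `"higher"` (default) or `"lower"`: which scores
#'   indicate the positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  labels <- check_binary(labels)
  if (direction == "lower") scores <- -scores
  r <- rank(scores)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# DeLong structural components: for each positive the fraction of negatives
# it beats (ties half), and symmetrically for negatives.
#' @noRd
delong_components <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)),
                numeric(1))
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)),
                numeric(1))
  list(auc = mean(v10), v10 = v10, v01 = v01,
       m = length(pos), n = length(neg))
}

#' DeLong confidence interval and paired AUC comparison
#'
#' Nonparametric AUC inference from DeLong's structural-components variance
#' estimator. With one score vector, returns the AUC and its 95% (or
#' `conf_level`) normal-approximation confidence interval clipped to
#' `[0, 1]`. With two score vectors on the same patients, additionally
#' performs the paired two-sided test of equal AUCs. If both models
#' separate perfectly (degenerate variance) the paired p-value is 1 when
#' the AUCs are equal, otherwise an error is raised.
#'
#' @param scores_a numeric scores of model A.
#' @param scores_b optional numeric scores of model B (same patients).
#' @param labels binary vector (1 = positive class).
#' @param direction score orientation, see [roc_auc()].
#' @param conf_level confidence level for the interval.
#' @return list with `auc`, `ci` (length 2), `se`, and — when `scores_b`
#'   is given — `auc_b`, `delta`, `p`.
#' @export
delong <- function(scores_a, scores_b = NULL, labels,
                   direction = c("higher", "lower"), conf_level = 0.95) {
  direction <- match.arg(direction)
  labels <- check_binary(labels)
  if (direction == "lower") {
    scores_a <- -scores_a
    if (!is.null(scores_b)) scores_b <- -scores_b
  }
  ca <- delong_components(scores_a, labels)
  var_a <- var(ca$v10) / ca$m + var(ca$v01) / ca$n
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, ca$auc + c(-1, 1) * z * sqrt(var_a)))
  out <- list(auc = ca$auc, ci = ci, se = sqrt(var_a))
  if (!is.null(scores_b)) {
    if (length(scores_b) != length(scores_a))
      stop("paired comparison requires scores on identical patients")
    cb <- delong_components(scores_b, labels)
    var_b <- var(cb$v10) / cb$m + var(cb$v01) / cb$n
    cov_ab <- cov(ca$v10, cb$v10) / ca$m + cov(ca$v01, cb$v01) / ca$n
    var_d <- var_a + var_b - 2 * cov_ab
    delta <- ca$auc - cb$auc
    if (var_d <= .Machine$double.eps) {
      if (abs(delta) < 1e-12) {
        p <- 1
      } else stop("degenerate DeLong variance with unequal AUCs")
    } else {
      p <- 2 * pnorm(-abs(delta) / sqrt(var_d))
    }
    out$auc_b <- cb$auc
    out$delta <- delta
    out$p <- p
  }
  out
}

#' Influence-function confidence interval for cross-validated AUC
#'
#' Pools the per-fold out-of-fold AUCs into their mean and estimates the
#' variance of the cross-validated AUC from the per-fold influence-function
#' (structural-components) variances: `var = sum(var_j) / J^2`. With a
#' single fold this reduces exactly to the DeLong interval. Folds
#' containing a single class are merged with the following fold (with a
#' warning), as is unavoidable at small n.
#'
#' @param scores list of numeric vectors, one per fold (out-of-fold scores).
#' @param labels list of binary vectors aligned with `scores`.
#' @param direction score orientation, see [roc_auc()].
#' @param conf_level confidence level.
#' @return list with `cvauc`, `ci`, `se` and the per-fold `fold_aucs`.
#' @export
cv_auc_ci <- function(scores, labels, direction = c("higher", "lower"),
                      conf_level = 0.95) {
  direction <- match.arg(direction)
  stopifnot(is.list(scores), is.list(labels),
            length(scores) == length(labels))
  if (direction == "lower") scores <- lapply(scores, function(s) -s)
  # merge single-class folds forward
  i <- 1
  while (i <= length(labels)) {
    if (length(unique(labels[[i]])) < 2) {
      if (length(labels) == 1)
        stop("both classes must be present overall")
      j <- if (i < length(labels)) i + 1 else i - 1
      warning("fold ", i, " contains a single class; merged with fold ", j)
      scores[[j]] <- c(scores[[j]], scores[[i]])
      labels[[j]] <- c(labels[[j]], labels[[i]])
      scores[[i]] <- NULL
      labels[[i]] <- NULL
    } else i <- i + 1
  }
  J <- length(scores)
  aucs <- numeric(J)
  vars <- numeric(J)
  for (j in seq_len(J)) {
    lab <- check_binary(labels[[j]])
    cj <- delong_components(scores[[j]], lab)
    aucs[j] <- cj$auc
    vars[j] <- var(cj$v10) / cj$m + var(cj$v01) / cj$n
  }
  cvauc <- mean(aucs)
  se <- sqrt(sum(vars)) / J
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, cvauc + c(-1, 1) * z * se))
  list(cvauc = cvauc, ci = ci, se = se, fold_aucs = aucs)
}

#' Association of principal components with clinical covariates
#'
#' Spearman correlation (with p-value) for continuous covariates and
#' Kruskal-Wallis tests (chi-square approximation, tie-corrected) for
#' categorical covariates, for every (component, covariate) pair.
#' Correlations with `|rho| >= 0.40` are flagged as moderate/strong.
#' p-values are reported unadjusted for multiple testing.
#'
#' @param pcs numeric matrix of components (rows = patients).
#' @param covariates data.frame aligned with `pcs`; numeric columns are
#'   treated as continuous, factors/characters as categorical.
#' @return data.frame with one row per pair: `component`, `covariate`,
#'   `type`, `statistic`, `p`, `flag`.
#' @export
pc_association <- function(pcs, covariates) {
  pcs <- as.matrix(pcs)
  if (nrow(pcs) != nrow(covariates)) stop("row mismatch")
  if (is.null(colnames(pcs))) colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
  rows <- list()
  for (cv in names(covariates)) {
    x <- covariates[[cv]]
    categorical <- is.factor(x) || is.character(x) || is.logical(x)
    if (categorical) {
      x <- factor(x)
      if (nlevels(droplevels(x)) < 2) {
        warning("covariate ", cv, " has a single level; skipped")
        next
      }
    }
    for (pc in colnames(pcs)) {
      if (categorical) {
        kt <- kruskal.test(pcs[, pc], x)
        rows[[length(rows) + 1]] <- data.frame(
          component = pc, covariate = cv, type = "categorical",
          statistic = unname(kt$statistic), p = kt$p.value, flag = NA,
          stringsAsFactors = FALSE)
      } else {
        ct <- suppressWarnings(cor.test(pcs[, pc], x, method = "spearman",
                                        exact = FALSE))
        rows[[length(rows) + 1]] <- data.frame(
          component = pc, covariate = cv, type = "continuous",
          statistic = unname(ct$estimate), p = ct$p.value,
          flag = abs(ct$estimate) >= 0.40, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Descriptive comparison of two cohort tables
#'
#' Per shared variable, the test follows the declared type: chi-square for
#' categorical variables, Student's t-test for normal continuous variables,
#' Mann-Whitney U otherwise. Missing values are excluded per variable.
#'
#' @param train,test data.frames with a shared column schema.
#' @param types named character vector declaring each variable as
#'   `"categorical"`, `"normal"` or `"continuous"`; undeclared variables
#'   default to `"categorical"` for factors/characters and `"continuous"`
#'   otherwise.
#' @return data.frame with `variable`, `test`, `statistic`, `p`.
#' @export
cohort_compare <- function(train, test, types = NULL) {
  shared <- intersect(names(train), names(test))
  if (length(shared) == 0) stop("no shared columns")
  rows <- list()
  for (v in shared) {
    a <- train[[v]]
    b <- test[[v]]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    if (length(a) == 0 || length(b) == 0) next
    ty <- if (!is.null(types) && v %in% names(types)) types[[v]]
          else if (is.numeric(a)) "continuous" else "categorical"
    res <- switch(ty,
      categorical = {
        tab <- table(group = rep(c("train", "test"), c(length(a), length(b))),
                     value = c(as.character(a), as.character(b)))
        ht <- suppressWarnings(chisq.test(tab))
        c(test = "chi-square", statistic = unname(ht$statistic),
          p = ht$p.value)
      },
      normal = {
        ht <- t.test(a, b)
        c(test = "t", statistic = unname(ht$statistic), p = ht$p.value)
      },
      continuous = {
        ht <- suppressWarnings(wilcox.test(a, b))
        c(test = "mann-whitney", statistic = unname(ht$statistic),
          p = ht$p.value)
      },
      stop("unknown type for ", v, ": ", ty))
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, test = res[["test"]],
      statistic = as.numeric(res[["statistic"]]),
      p = as.numeric(res[["p"]]), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Evaluation report across RCB prediction models
#'
#' For every model: Spearman correlation of predicted versus actual RCB
#' score, AUC for pCR versus non-pCR and for responder (RCB-0/I) versus
#' non-responder (RCB-II/III) with DeLong confidence intervals, and the
#' paired DeLong p-value against a reference model. Predicted RCB is
#' treated as a risk score: lower predictions indicate responder/pCR
#' (`direction = "lower"`), recorded in the output.
#'
#' @param predictions named list of numeric prediction vectors (one per
#'   model, same patients).
#' @param outcomes data.frame with `rcb_score`, `pcr`, `responder`.
#' @param reference name of the reference model for paired tests.
#' @return data.frame with one row per model (Table-style layout).
#' @export
evaluation_report <- function(predictions, outcomes, reference = NULL) {
  stopifnot(is.list(predictions), !is.null(names(predictions)))
  if (any(outcomes$pcr & !outcomes$responder))
    stop("inconsistent endpoints: pCR implies responder")
  if (is.null(reference)) reference <- names(predictions)[1]
  ref_pred <- predictions[[reference]]
  # degenerate endpoints (single class, constant predictions) at small n
  # yield NA entries rather than aborting the whole report
  safely <- function(expr, fallback) tryCatch(expr, error = function(e) fallback)
  na_delong <- list(auc = NA_real_, ci = c(NA_real_, NA_real_), p = NA_real_)
  rows <- lapply(names(predictions), function(nm) {
    pr <- predictions[[nm]]
    sp <- safely(spearman_eval(pr, outcomes$rcb_score),
                 list(rho = NA_real_, p = NA_real_))
    d_pcr <- safely(delong(pr, labels = as.integer(outcomes$pcr),
                           direction = "lower"), na_delong)
    d_rcb <- safely(delong(pr, labels = as.integer(outcomes$responder),
                           direction = "lower"), na_delong)
    p_pcr <- p_rcb <- NA_real_
    if (nm != reference) {
      p_pcr <- safely(delong(pr, ref_pred,
                             labels = as.integer(outcomes$pcr),
                             direction = "lower")$p, NA_real_)
      p_rcb <- safely(delong(pr, ref_pred,
                             labels = as.integer(outcomes$responder),
                             direction = "lower")$p, NA_real_)
    }
    data.frame(model = nm,
               auc_pcr = d_pcr$auc, auc_pcr_lo = d_pcr$ci[1],
               auc_pcr_hi = d_pcr$ci[2], p_vs_ref_pcr = p_pcr,
               auc_rcb = d_rcb$auc, auc_rcb_lo = d_rcb$ci[1],
               auc_rcb_hi = d_rcb$ci[2], p_vs_ref_rcb = p_rcb,
               spearman_rcb = sp$rho, n = length(pr),
               direction = "lower", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
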