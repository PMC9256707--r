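detect_covariates <- function(dat) {
  covs <- character(0)
  if ("sex" %in% names(dat) && length(unique(dat$sex)) > 1) covs <- c(covs, "sex")
  covs <- c(covs, grep("^PC[0-9]+$", names(dat), value = TRUE))
  if ("cohort" %in% names(dat) && length(unique(dat$cohort)) > 1)
    covs <- c(covs, "cohort")
  covs
}

check_full_rank <- function(dat, rhs_terms) {
  mm <- stats::model.matrix(stats::reformulate(rhs_terms), data = dat)
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    aliased <- colnames(mm)[q$pivot[(q$rank + 1):ncol(mm)]]
    stopf("covariate matrix is rank deficient; collinear column(s): %s",
          paste(aliased, collapse = ", "))
  }
  invisible(TRUE)
}

#' Test PRS-phenotype association
#'
#' Fits a logistic model of case status on the standardized PRS plus
#' covariates (sex, principal components `PC1..PCk`, and a cohort
#' indicator when more than one cohort is present — all picked up from the
#' phenotype table's columns). With `use_random_effect = TRUE` and family
#' ids present, a family-level random intercept is added
#' (logistic GLMM via Laplace approximation). When every family has a
#' single member the random intercept is unidentifiable for a binary
#' outcome, so the fit reduces to the plain logistic model (reported via
#' the `random_effect_dropped` flag). The returned effect is the
#' Wald estimate for the PRS term: log-odds per 1 standardized-PRS unit.
#'
#' Quasi- or complete separation is not silently reported as an estimate:
#' the result carries a `separation` flag raised when fitted probabilities
#' hit 0/1 numerically.
#'
#' @param pheno phenotype table: `sample_id`, `case` (0/1), optional
#'   `sex`, `PC1..PCk`, `cohort`, `family_id`.
#' @param prs standardized score table from [standardize_prs()].
#' @param use_random_effect add a `(1 | family_id)` random intercept.
#' @return object of class `prs_assoc`: list with `beta`, `se`, `z`,
#'   `p`, `model` (`"glm"`/`"glmm"`), `n`, `n_cases`, `label`,
#'   `separation`, `converged`.
#' @export
fit_prs_association <- function(pheno, prs, use_random_effect = FALSE) {
  pheno <- as.data.table(pheno)
  prs <- as.data.table(prs)
  if (!"standardized_score" %in% names(prs))
    stopf("prs must be standardized (see standardize_prs)")
  dat <- merge(pheno, prs[, .(sample_id, prs = standardized_score)],
               by = "sample_id")
  if (!all(dat$case %in% 0:1)) stopf("case status must be 0/1")
  if (length(unique(dat$case)) < 2) stopf("need at least one case and one control")
  covs <- detect_covariates(dat)
  rhs <- c("prs", covs)
  check_full_rank(dat, rhs)
  label <- if ("label" %in% names(prs)) prs$label[1] else "PRS"

  # a family random intercept is identifiable only if some family has > 1
  # member; with one Bernoulli observation per family the mixed model is
  # unidentifiable and correctly reduces to plain logistic regression
  fams <- dat$family_id
  has_structure <- "family_id" %in% names(dat) && !all(is.na(fams)) &&
    anyDuplicated(fams[!is.na(fams)]) > 0
  re_dropped <- isTRUE(use_random_effect) && !has_structure
  use_glmm <- isTRUE(use_random_effect) && has_structure
  separation <- FALSE
  if (use_glmm) {
    fm <- stats::as.formula(paste("case ~", paste(rhs, collapse = " + "),
                                  "+ (1 | family_id)"))
    fit <- suppressMessages(lme4::glmer(
      fm, data = dat, family = stats::binomial(),
      control = lme4::glmerControl(check.nobs.vs.nlev = "ignore",
                                   check.nobs.vs.nRE = "ignore",
                                   calc.derivs = FALSE)
    ))
    co <- summary(fit)$coefficients
    conv <- length(fit@optinfo$conv$lme4) == 0
    mu <- stats::fitted(fit)
    model <- "glmm"
  } else {
    fm <- stats::reformulate(rhs, response = "case")
    withCallingHandlers(
      fit <- stats::glm(fm, data = dat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    )
    co <- summary(fit)$coefficients
    conv <- fit$converged
    mu <- stats::fitted(fit)
    model <- "glm"
  }
  eps <- .Machine$double.eps
  if (any(mu < eps) || any(mu > 1 - eps)) separation <- TRUE
  structure(list(
    beta = unname(co["prs", 1]), se = unname(co["prs", 2]),
    z = unname(co["prs", 1] / co["prs", 2]),
    p = unname(2 * stats::pnorm(-abs(co["prs", 1] / co["prs", 2]))),
    model = model, n = nrow(dat), n_cases = sum(dat$case),
    label = label, separation = separation, converged = conv,
    random_effect_dropped = re_dropped
  ), class = "prs_assoc")
}

#' @export
print.prs_assoc <- function(x, ...) {
  cat(sprintf("%s association (%s, n = %d, %d cases): beta = %.4f, se = %.4f, p = %.3g%s\n",
              x$label, x$model, x$n, x$n_cases, x$beta, x$se, x$p,
              if (x$separation) " [separation flagged]" else ""))
  invisible(x)
}

#' Assign rank-based PRS deciles
#'
#' Orders samples by standardized score (ties broken by sample id, a
#' stable, reproducible rule) and cuts them into 10 contiguous groups
#' whose sizes differ by at most one; when the sample count is not a
#' multiple of 10 the extra samples go to the lowest deciles. Decile 1
#' holds the lowest scores. If every score is tied the assignment is
#' purely id-order and the result is flagged degenerate.
#'
#' @param prs standardized score table.
#' @return `data.table` with `sample_id`, `decile` (1-10); attribute
#'   `degenerate` when all scores are tied.
#' @export
decile_strata <- function(prs) {
  prs <- as.data.table(prs)
  n <- nrow(prs)
  if (n < 10) stopf("need at least 10 samples for deciles (got %d)", n)
  sc <- if ("standardized_score" %in% names(prs)) prs$standardized_score else prs$raw_score
  ord <- order(sc, prs$sample_id)
  sizes <- rep(n %/% 10L, 10L)
  r <- n %% 10L
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  lab <- rep.int(1:10, sizes)
  out <- data.table(sample_id = prs$sample_id[ord], decile = lab)
  out <- out[order(match(sample_id, prs$sample_id))]
  attr(out, "degenerate") <- length(unique(sc)) == 1L
  out
}

#' Per-decile case counts and rates
#'
#' @param pheno phenotype table with `sample_id`, `case`.
#' @param deciles output of [decile_strata()].
#' @return `data.table`: `decile`, `n`, `n_cases`, `case_rate`.
#' @export
decile_case_rates <- function(pheno, deciles) {
  dat <- merge(as.data.table(pheno)[, .(sample_id, case)],
               as.data.table(deciles), by = "sample_id")
  dat[, .(n = .N, n_cases = sum(case), case_rate = mean(case)),
      keyby = decile]
}

#' Decile odds ratios versus the bottom decile
#'
#' Logistic model of case status on decile indicators (decile 1 as the
#' reference) plus, when `adjust = TRUE`, the same covariates as
#' [fit_prs_association()]. Odds ratios are `exp(beta)` with Wald 95%
#' confidence intervals. A decile with no cases or no controls cannot
#' yield a stable estimate and is flagged, not silently reported.
#'
#' @param pheno phenotype table.
#' @param deciles output of [decile_strata()].
#' @param adjust include sex/PC/cohort covariates.
#' @param conf_level confidence level for the Wald interval.
#' @return `data.table`: `decile` (2-10), `or`, `ci_lower`, `ci_upper`,
#'   `p`, `n_cases`, `n_controls`, `unstable`.
#' @export
decile_or <- function(pheno, deciles, adjust = TRUE, conf_level = 0.95) {
  pheno <- as.data.table(pheno)
  dat <- merge(pheno, as.data.table(deciles), by = "sample_id")
  dat[, decile := factor(decile, levels = 1:10)]
  tab <- dat[, .(n_cases = sum(case), n_controls = sum(case == 0)), keyby = decile]
  if (tab[decile == 1, n_cases] == 0 || tab[decile == 1, n_controls] == 0)
    stopf("bottom decile must contain both cases and controls")
  covs <- if (adjust) detect_covariates(dat) else character(0)
  rhs <- c("decile", covs)
  fit <- suppressWarnings(stats::glm(stats::reformulate(rhs, response = "case"),
                                     data = dat, family = stats::binomial()))
  co <- summary(fit)$coefficients
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- paste0("decile", 2:10)
  b <- co[rows, 1]
  s <- co[rows, 2]
  out <- data.table(
    decile = 2:10,
    or = exp(b), ci_lower = exp(b - zq * s), ci_upper = exp(b + zq * s),
    p = 2 * stats::pnorm(-abs(b / s)),
    n_cases = tab[decile != 1, n_cases],
    n_controls = tab[decile != 1, n_controls]
  )
  out[, unstable := n_cases == 0 | n_controls == 0]
  out[]
}

#' Principal components of a dosage matrix
#'
#' Top-`k` principal components of the column-standardized dosage matrix,
#' the usual stand-in for genotype-based ancestry covariates. Constant
#' (zero-variance) variants are excluded before standardization; the sign
#' of each component is fixed deterministically so that its
#' largest-magnitude variant loading is positive.
#'
#' @param ds a [dosage_set()] or a plain samples x variants matrix.
#' @param k number of components.
#' @return samples x `k` matrix with columns `PC1..PCk`.
#' @export
compute_pcs <- function(ds, k = 10) {
  x <- if (inherits(ds, "dosage_set")) ds$dosages else as.matrix(ds)
  if (anyNA(x)) {
    cm <- colMeans(x, na.rm = TRUE)
    na_idx <- which(is.na(x), arr.ind = TRUE)
    x[na_idx] <- cm[na_idx[, 2]]
  }
  v <- apply(x, 2, stats::var)
  if (all(v == 0)) stopf("all variants have zero variance; PCs undefined")
  x <- x[, v > 0, drop = FALSE]
  if (k > min(dim(x)) - 1 || k < 1)
    stopf("k = %d exceeds the available rank (%d samples x %d variants)",
          k, nrow(x), ncol(x))
  pr <- stats::prcomp(x, center = TRUE, scale. = TRUE, rank. = k)
  if (ncol(pr$x) < k) stopf("k = %d exceeds the matrix rank", k)
  scores <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    ld <- pr$rotation[, j]
    if (ld[which.max(abs(ld))] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(x)
  scores
}
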