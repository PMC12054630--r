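# Gene-phenotype association: composite collagen score, Spearman
# associations against a clinical covariate panel, and the univariable ->
# multivariable linear regression cascade with backward elimination.

#' Composite collagen expression score
#'
#' Equal-weights mean of the three main cardiac collagen transcripts:
#' score = (Col1a1 + Col1a2 + Col3a1) / 3, each variant contributing one
#' third. Vectorized over equal-length inputs.
#'
#' @param col1a1,col1a2,col3a1 Relative-expression values, >= 0, on a
#'   common scale.
#' @return Numeric score(s).
#' @export
collagen_score <- function(col1a1, col1a2, col3a1) {
  n <- length(col1a1)
  if (length(col1a2) != n || length(col3a1) != n)
    stop_fmt("inputs must have equal length")
  vals <- cbind(col1a1, col1a2, col3a1)
  if (anyNA(vals)) stop_fmt("missing values are not allowed")
  if (any(vals < 0)) stop_fmt("relative expression must be >= 0")
  as.vector((col1a1 + col1a2 + col3a1) / 3)
}

clinical_covariates <- function(tbl, target, covariates = NULL) {
  if (!target %in% names(tbl))
    stop_fmt("target column '%s' not in table", target)
  if (is.null(covariates))
    covariates <- setdiff(names(tbl), c("subject_id", target))
  missing <- setdiff(covariates, names(tbl))
  if (length(missing))
    stop_fmt("covariate(s) not in table: %s", paste(missing, collapse = ", "))
  if (anyDuplicated(covariates)) stop_fmt("covariate names must be unique")
  covariates
}

#' Spearman association of each covariate with target expression
#'
#' Pairwise-complete Spearman rho and two-tailed p per covariate against
#' the target column, ordered by covariate name. A constant covariate is
#' flagged (`defined = FALSE`) with `NA` statistics rather than dropped.
#'
#' @param tbl Clinical data.frame.
#' @param target Name of the gene-expression column (default
#'   `"target_expr"`).
#' @param covariates Covariate column names; default all columns except
#'   `subject_id` and the target.
#' @param min_pairs Minimum non-missing pairs per covariate (default 5);
#'   fewer is an error.
#' @return data.frame with columns covariate, rho, p_two_tailed, n, defined.
#' @export
spearman_assoc <- function(tbl, target = "target_expr", covariates = NULL,
                           min_pairs = 5L) {
  covariates <- sort(clinical_covariates(tbl, target, covariates))
  y <- tbl[[target]]
  rows <- lapply(covariates, function(nm) {
    x <- tbl[[nm]]
    ok <- complete.cases(x, y)
    if (sum(ok) < min_pairs)
      stop_fmt("covariate '%s' has %d non-missing pairs; >= %d required",
               nm, sum(ok), min_pairs)
    st <- spearman_test(x[ok], y[ok])
    data.frame(covariate = nm, rho = st$rho, p_two_tailed = st$p,
               n = st$n, defined = !is.na(st$rho), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# expand factor/character covariates to one-hot dummies (first level as
# reference); numeric columns pass through
encode_covariates <- function(tbl, covariates) {
  cols <- list()
  for (nm in covariates) {
    x <- tbl[[nm]]
    if (is.numeric(x)) {
      cols[[nm]] <- x
    } else {
      f <- factor(x)
      for (lev in levels(f)[-1L])
        cols[[paste0(nm, "_", lev)]] <- as.numeric(f == lev)
    }
  }
  as.data.frame(cols, optional = TRUE, check.names = FALSE)
}

uni_fit <- function(x, y) {
  ok <- complete.cases(x, y)
  fit <- lm(y[ok] ~ x[ok])
  sm <- summary(fit)$coefficients
  if (nrow(sm) < 2L)   # constant covariate: slope not estimable
    return(c(slope = NA_real_, se = NA_real_, p = NA_real_, n = sum(ok)))
  c(slope = sm[2L, 1L], se = sm[2L, 2L], p = sm[2L, 4L], n = sum(ok))
}

#' Univariable-to-multivariable regression cascade
#'
#' Stage 1: ordinary least squares of target expression on each covariate
#' alone; covariates with two-sided slope p < `alpha` advance. Stage 2: all
#' advancing covariates are fit jointly and backward elimination removes,
#' one at a time, the covariate with the largest p >= `alpha` (ties broken
#' by covariate name) until every remaining covariate has p < `alpha` or
#' none remain. Listwise-complete cases are used within each fit. The full
#' elimination order is recorded. A rank-deficient stage-2 design is an
#' error naming the collinear columns. As an alternative to elimination,
#' `stage2 = "single_shot"` fits the joint model once and retains the
#' covariates with p < `alpha` without refitting.
#'
#' @param tbl Clinical data.frame.
#' @param target Gene-expression column name (default `"target_expr"`).
#' @param covariates Covariate columns; default all except `subject_id` and
#'   the target. Non-numeric covariates are one-hot encoded (first level
#'   reference).
#' @param alpha Significance threshold for both stages (default 0.05).
#' @param stage2 `"backward"` (default) or `"single_shot"`.
#' @return List of class `regression_report`: `univariable` (data.frame
#'   covariate, slope, se, p, n, significant), `retained` (data.frame
#'   covariate, coef, se, p), `audit` (character log of stage-2 steps),
#'   `alpha`.
#' @export
regression_cascade <- function(tbl, target = "target_expr",
                               covariates = NULL, alpha = 0.05,
                               stage2 = c("backward", "single_shot")) {
  stage2 <- match.arg(stage2)
  covariates <- clinical_covariates(tbl, target, covariates)
  enc <- encode_covariates(tbl, covariates)
  y <- tbl[[target]]

  uni <- t(vapply(names(enc), function(nm) uni_fit(enc[[nm]], y), numeric(4)))
  univariable <- data.frame(covariate = names(enc), uni,
                            stringsAsFactors = FALSE, row.names = NULL)
  univariable$significant <- !is.na(univariable$p) & univariable$p < alpha
  kept <- sort(univariable$covariate[univariable$significant])

  audit <- sprintf("stage1: %d of %d covariates significant at alpha = %g",
                   length(kept), nrow(univariable), alpha)
  empty_ret <- data.frame(covariate = character(), coef = numeric(),
                          se = numeric(), p = numeric(),
                          stringsAsFactors = FALSE)
  if (!length(kept)) {
    return(structure(list(univariable = univariable, retained = empty_ret,
                          audit = c(audit, "stage2: skipped (no candidates)"),
                          alpha = alpha),
                     class = "regression_report"))
  }
  if (nrow(tbl) <= length(kept) + 1L)
    stop_fmt("need more subjects (%d) than stage-1 covariates + 1 (%d)",
             nrow(tbl), length(kept) + 1L)

  joint <- function(vars) {
    dat <- cbind(.y = y, enc[vars])
    dat <- dat[complete.cases(dat), , drop = FALSE]
    fit <- lm(.y ~ ., data = dat)
    if (anyNA(coef(fit))) {
      bad <- names(coef(fit))[is.na(coef(fit))]
      al <- alias(fit)$Complete
      partners <- if (!is.null(al))
        unique(unlist(lapply(rownames(al), function(r)
          colnames(al)[al[r, ] != 0])))
      else character()
      cols <- unique(c(bad, partners))
      cols <- gsub("`", "", setdiff(cols, "(Intercept)"))
      stop_fmt("rank-deficient design: collinear column(s) %s",
               paste(sort(cols), collapse = ", "))
    }
    sm <- summary(fit)$coefficients
    sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
    rownames(sm) <- gsub("`", "", rownames(sm))
    sm
  }

  current <- kept
  repeat {
    sm <- joint(current)
    ps <- sm[current, 4L]
    if (stage2 == "single_shot") {
      current <- current[ps < alpha]
      audit <- c(audit, sprintf("stage2 single-shot: retained %d covariate(s)",
                                length(current)))
      if (length(current)) sm <- sm[current, , drop = FALSE]
      break
    }
    worst <- which(ps >= alpha)
    if (!length(worst)) {
      audit <- c(audit, sprintf("stage2: converged with %d covariate(s)",
                                length(current)))
      break
    }
    # drop the single covariate with the largest p; ties by name
    cand <- current[worst]
    drop_nm <- cand[order(-ps[worst], cand)][1L]
    audit <- c(audit, sprintf("stage2: removed %s (p = %.4g)",
                              drop_nm, ps[[match(drop_nm, current)]]))
    current <- setdiff(current, drop_nm)
    if (!length(current)) {
      audit <- c(audit, "stage2: all candidates eliminated")
      break
    }
  }

  retained <- if (length(current))
    data.frame(covariate = current, coef = sm[current, 1L],
               se = sm[current, 2L], p = sm[current, 4L],
               stringsAsFactors = FALSE, row.names = NULL)
  else empty_ret
  structure(list(univariable = univariable, retained = retained,
                 audit = audit, alpha = alpha),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("regression cascade (alpha = %g)\n", x$alpha))
  cat(sprintf("  stage 1: %d/%d covariates significant\n",
              sum(x$univariable$significant), nrow(x$univariable)))
  if (nrow(x$retained)) {
    cat("  retained:\n")
    print(x$retained, row.names = FALSE)
  } else cat("  retained: none\n")
  invisible(x)
}
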