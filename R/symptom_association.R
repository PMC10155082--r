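#' Ordinary least squares with explicit rank checking
#'
#' Fits `y = X b + e` by QR-based least squares (the design matrix must
#' already contain its intercept column) and returns the full coefficient
#' table with two-sided t-test p-values on `n - p` degrees of freedom. A
#' rank-deficient design is a fatal error naming the aliased columns,
#' rather than the silent coefficient-dropping `lm()` would do.
#'
#' @param y Numeric outcome vector.
#' @param X Numeric design matrix with named columns, including an
#'   intercept column.
#' @return Tibble `(term, b, se, t_stat, p_value)` with attributes `n`,
#'   `df`, `sigma` and `r_squared`.
#' @export
fit_linear_model <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) abort("y and X have different numbers of rows")
  if (n <= p) abort("need more observations than design columns")
  qx <- qr(X)
  if (qx$rank < p) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    abort(paste0(
      "rank-deficient design; aliased column(s): ",
      paste(aliased, collapse = ", ")
    ))
  }
  fit <- stats::lm.fit(X, y)
  b <- fit$coefficients
  res <- fit$residuals
  df <- n - p
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(sigma2 * diag(xtx_inv))
  t_stat <- b / se
  out <- tibble::tibble(
    term = colnames(X),
    b = unname(b),
    se = unname(se),
    t_stat = unname(t_stat),
    p_value = 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  )
  tss <- sum((y - mean(y))^2)
  attr(out, "n") <- n
  attr(out, "df") <- df
  attr(out, "sigma") <- sqrt(sigma2)
  attr(out, "r_squared") <- if (tss > 0) 1 - sum(res^2) / tss else NA_real_
  out
}

#' Squared bivariate correlation between outcome and one predictor
#'
#' The effect size reported alongside each adjusted coefficient: the
#' squared Pearson correlation of outcome and predictor alone, without
#' covariates. Invariant to affine rescaling of either variable.
#'
#' @param y,x Numeric vectors.
#' @return Squared correlation in `[0, 1]`.
#' @export
r2_bivariate <- function(y, x) {
  ok <- stats::complete.cases(y, x)
  cor(y[ok], x[ok])^2
}

#' Fit the symptom-association model suite
#'
#' Fits separate covariate-adjusted linear models of each symptom outcome
#' (PCL-5 PTSD severity, PHQ-9 depression severity) on each passive
#' feature. Full-cohort models adjust for employment, school enrollment
#' and shelter site; shelter-stratified entropy models adjust for
#' employment and school only. Reported `r2` is always the bivariate
#' (unadjusted) squared correlation. Cells whose stratum is too small to
#' estimate are reported as not estimable and the suite continues. A
#' Benjamini-Hochberg adjusted p-value column is appended as a clearly
#' supplementary quantity; the primary p-values are unadjusted.
#'
#' @param features Per-participant feature tibble containing at least the
#'   predictor columns used.
#' @param participants Metadata tibble with `employed`, `student`,
#'   `shelter`, `phq9_total`, `pcl5_total`.
#' @param predictors Feature columns to use as predictors.
#' @param stratify_predictors Predictors also fitted per shelter stratum.
#' @return Long-format tibble: `(outcome, predictor, stratum, n, b, se,
#'   t_stat, p_value, r2, p_bh_supplementary, note)`.
#' @export
run_association_suite <- function(features, participants,
                                  predictors = c(
                                    "entropy", "normalized_entropy",
                                    "n_clusters", "mean_daily_wifi_minutes"
                                  ),
                                  stratify_predictors = "entropy") {
  data <- dplyr::inner_join(features, participants, by = "participant_id")
  outcomes <- c(PCL5 = "pcl5_total", PHQ9 = "phq9_total")
  predictors <- intersect(predictors, names(data))

  cells <- dplyr::bind_rows(
    tidyr::expand_grid(
      outcome = names(outcomes), predictor = predictors, stratum = "all"
    ),
    tidyr::expand_grid(
      outcome = names(outcomes),
      predictor = intersect(stratify_predictors, predictors),
      stratum = paste0("shelter_", sort(unique(data$shelter)))
    )
  )

  rows <- purrr::pmap(cells, function(outcome, predictor, stratum) {
    fit_association_cell(
      data,
      outcome_col = outcomes[[outcome]], outcome = outcome,
      predictor = predictor, stratum = stratum
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_bh_supplementary <- p.adjust(out$p_value, method = "BH")
  out
}

fit_association_cell <- function(data, outcome_col, outcome, predictor, stratum) {
  covariates <- c("employed", "student", "shelter")
  if (stratum != "all") {
    data <- data[paste0("shelter_", data$shelter) == stratum, , drop = FALSE]
    covariates <- c("employed", "student")
  }
  skeleton <- tibble::tibble(
    outcome = outcome, predictor = predictor, stratum = stratum,
    n = NA_integer_, b = NA_real_, se = NA_real_, t_stat = NA_real_,
    p_value = NA_real_, r2 = NA_real_, note = NA_character_
  )
  cols <- c(outcome_col, predictor, covariates)
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]

  # covariates without variation in this cell carry no information and
  # would alias the intercept
  keep <- vapply(covariates, function(v) length(unique(d[[v]])) > 1, logical(1))
  covariates <- covariates[keep]

  X <- design_matrix(d, predictor, covariates)
  if (nrow(d) <= ncol(X)) {
    skeleton$n <- nrow(d)
    skeleton$note <- "not estimable (n <= p)"
    return(skeleton)
  }
  fit <- tryCatch(
    fit_linear_model(d[[outcome_col]], X),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    skeleton$n <- nrow(d)
    skeleton$note <- "not estimable (rank-deficient design)"
    return(skeleton)
  }
  row <- fit[fit$term == predictor, ]
  tibble::tibble(
    outcome = outcome, predictor = predictor, stratum = stratum,
    n = nrow(d), b = row$b, se = row$se, t_stat = row$t_stat,
    p_value = row$p_value,
    r2 = r2_bivariate(d[[outcome_col]], d[[predictor]]),
    note = NA_character_
  )
}

design_matrix <- function(d, predictor, covariates) {
  X <- cbind(`(Intercept)` = 1, as.matrix(d[predictor]))
  for (v in covariates) {
    col <- d[[v]]
    if (is.logical(col)) {
      X <- cbind(X, as.numeric(col))
      colnames(X)[ncol(X)] <- v
    } else {
      lev <- sort(unique(as.character(col)))
      for (l in lev[-1]) {
        X <- cbind(X, as.numeric(as.character(col) == l))
        colnames(X)[ncol(X)] <- paste0(v, l)
      }
    }
  }
  X
}

#' Severity bands for PHQ-9 and PCL-5 totals
#'
#' PHQ-9 depression totals (0-27) band at cuts 5, 10, 15 and 20 into
#' minimal, mild, moderate, moderately severe and severe (a score equal
#' to a cut enters the higher band). A PCL-5 total of 33 or higher flags
#' probable PTSD.
#'
#' @param phq9_total,pcl5_total Integer vectors of instrument totals.
#' @return Tibble `(phq9_band, pcl5_probable)`; `phq9_band` is an ordered
#'   factor.
#' @export
band_scores <- function(phq9_total, pcl5_total) {
  if (any(phq9_total < 0 | phq9_total > 27, na.rm = TRUE)) {
    abort("phq9_total outside 0-27")
  }
  if (any(pcl5_total < 0 | pcl5_total > 80, na.rm = TRUE)) {
    abort("pcl5_total outside 0-80")
  }
  bands <- c("minimal", "mild", "moderate", "moderately_severe", "severe")
  idx <- findInterval(phq9_total, c(0, 5, 10, 15, 20))
  tibble::tibble(
    phq9_band = factor(bands[idx], levels = bands, ordered = TRUE),
    pcl5_probable = pcl5_total >= 33
  )
}
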