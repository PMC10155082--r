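# Independent oracles used to verify the package's implementations.
# These deliberately share no code with the package internals.

# Brute-force density-based clustering by exhaustive reachability
# closure on the full distance matrix. Border points attach to the
# cluster of their lowest-index core neighbour (the documented policy).
dbscan_oracle <- function(lat, lon, eps_km, min_pts) {
  n <- length(lat)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- mobsense::haversine_km(lat[i], lon[i], lat[j], lon[j])
    }
  }
  within <- D <= eps_km
  core <- rowSums(within) >= min_pts

  # reachability closure over core points only
  A <- within & outer(core, core, `&`)
  diag(A) <- core
  repeat {
    A2 <- (A %*% A) > 0 | A
    if (identical(A2, A > 0 | A)) break
    A <- A2
  }
  labels <- rep(NA_integer_, n)
  next_label <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(labels[i])) next
    next_label <- next_label + 1L
    labels[which(A[i, ] > 0)] <- next_label
    labels[i] <- next_label
  }
  for (i in seq_len(n)) {
    if (core[i]) next
    cnb <- which(within[i, ] & core)
    if (length(cnb) > 0) labels[i] <- labels[min(cnb)]
  }
  labels
}

# TRUE when two label vectors describe the same partition (up to
# relabeling) with identical noise (NA) sets.
same_partition <- function(a, b) {
  if (!identical(is.na(a), is.na(b))) return(FALSE)
  ok <- !is.na(a)
  if (!any(ok)) return(TRUE)
  length(unique(paste(a[ok], b[ok]))) == length(unique(a[ok])) &&
    length(unique(a[ok])) == length(unique(b[ok]))
}

# Normal-equations OLS oracle: explicit pseudo-inverse, independent of
# the QR path used by the package.
ols_oracle <- function(y, X) {
  X <- as.matrix(X)
  xtx_inv <- solve(t(X) %*% X)
  b <- drop(xtx_inv %*% t(X) %*% y)
  res <- y - drop(X %*% b)
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(xtx_inv))
  t_stat <- b / se
  list(
    b = b, se = se, t_stat = t_stat,
    p_value = 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE),
    df = df
  )
}

# Partial-F p-value for dropping one column from the design.
partial_f_p <- function(y, X, col) {
  rss_full <- sum(stats::lm.fit(X, y)$residuals^2)
  rss_red <- sum(stats::lm.fit(X[, colnames(X) != col, drop = FALSE], y)$residuals^2)
  df2 <- length(y) - ncol(X)
  f <- (rss_red - rss_full) / (rss_full / df2)
  stats::pf(f, 1, df2, lower.tail = FALSE)
}

# Write a tibble as a temporary CSV, returning the path.
tmp_csv <- function(x, name = "x.csv") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  readr::write_csv(x, path)
  path
}

# A tiny three-anchor world reused across tests.
test_anchors <- function() {
  data.frame(lat = c(41.88, 41.93, 41.80), lon = c(-87.63, -87.70, -87.60))
}
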