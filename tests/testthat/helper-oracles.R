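# Independent brute-force oracles. These deliberately use naive loops (and
# lm() for the regressions) so they share no code path with the package.

# Stage-1 oracle: one lm() per time point of masked, demeaned data on the
# demeaned template matrix.
oracle_stage1 <- function(bold, templates) {
  d <- dim(bold$data)
  V <- prod(d[1:3])
  Y <- matrix(bold$data, V, d[4])
  Y <- Y - rowMeans(Y)
  X <- matrix(templates$maps, V, dim(templates$maps)[4])
  X <- sweep(X, 2, colMeans(X))
  t(sapply(seq_len(d[4]), function(t)
    unname(stats::coef(stats::lm(Y[, t] ~ X)))[-1]))
}

# Stage-2 oracle: one lm() per voxel on the given time courses; returns
# beta and t-statistic arrays.
oracle_stage2 <- function(bold, tc_values) {
  d <- dim(bold$data)
  V <- prod(d[1:3])
  p <- ncol(tc_values)
  Y <- matrix(bold$data, V, d[4])
  beta <- zmap <- matrix(0, V, p)
  for (v in seq_len(V)) {
    if (stats::sd(Y[v, ]) == 0) next
    fit <- summary(stats::lm(Y[v, ] ~ tc_values))
    beta[v, ] <- fit$coefficients[-1, "Estimate"]
    zmap[v, ] <- fit$coefficients[-1, "t value"]
  }
  list(beta = array(beta, c(d[1:3], p)), zmap = array(zmap, c(d[1:3], p)))
}

# ICC oracle: explicit cell-by-cell two-way ANOVA table built with loops.
oracle_icc31 <- function(y) {
  y <- as.matrix(y)
  n <- nrow(y); k <- ncol(y)
  grand <- mean(y)
  ss_subj <- 0
  for (i in seq_len(n)) ss_subj <- ss_subj + k * (mean(y[i, ]) - grand)^2
  ss_sess <- 0
  for (j in seq_len(k)) ss_sess <- ss_sess + n * (mean(y[, j]) - grand)^2
  ss_err <- 0
  for (i in seq_len(n))
    for (j in seq_len(k))
      ss_err <- ss_err +
        (y[i, j] - mean(y[i, ]) - mean(y[, j]) + grand)^2
  bms <- ss_subj / (n - 1)
  ems <- ss_err / ((n - 1) * (k - 1))
  list(bms = bms, ems = ems, jms = ss_sess / (k - 1),
       icc = (bms - ems) / (bms + (k - 1) * ems))
}
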