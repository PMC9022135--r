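# Shared fixtures and independent oracles used across the suite.

# Small, fast simulation config for unit tests: same optics, signal
# levels and noise model as the defaults, just fewer/smaller fields.
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(field_shape_px = c(256L, 256L), n_cells = 8L), list(...))
  do.call(simulation_config, args)
}

# Evaluation-scale config for recovery tests (matches the scaled-down
# conditions documented in the methods vignette).
eval_cfg <- function(...) {
  args <- utils::modifyList(
    list(field_shape_px = c(512L, 512L), n_cells = 30L), list(...))
  do.call(simulation_config, args)
}

# Memoised trained classifiers so several test files can share one
# (deterministic) training run.
.fixtures <- new.env(parent = emptyenv())
get_trained_models <- function() {
  if (is.null(.fixtures$models))
    .fixtures$models <- suppressMessages(
      train_spot_models(eval_cfg(), n_fields = 2L, seed = 999L))
  .fixtures$models
}

# ---- independent oracles ----------------------------------------------------

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# C(n1+n2, n1) group assignments of the pooled ranks (tie-free input).
enum_wilcox_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(ii) sum(r[ii])) - n1 * (n1 + 1) / 2
  p <- if (u_obs > n1 * n2 / 2) 2 * mean(us >= u_obs) else 2 * mean(us <= u_obs)
  min(p, 1)
}

# Pearson chi-square by direct sum over the four cells (no correction).
brute_chi2 <- function(a, b, c, d) {
  o <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  sum((o - e)^2 / e)
}

# Fisher-criterion direction by brute-force maximisation of
# J(w) = (w . dmu)^2 / (w' Sw w) over a grid of directions (degrees).
brute_fld_direction <- function(x1, x0, step_deg = 0.1) {
  mu1 <- colMeans(x1); mu0 <- colMeans(x0)
  sw <- crossprod(sweep(x1, 2, mu1)) + crossprod(sweep(x0, 2, mu0))
  th <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  w <- rbind(cos(th), sin(th))
  num <- (colSums(w * (mu1 - mu0)))^2
  den <- colSums(w * (sw %*% w))
  th[which.max(num / den)] * 180 / pi
}

# Angle (degrees, mod 180) of a 2D direction vector.
dir_angle <- function(v) (atan2(v[2], v[1]) * 180 / pi) %% 180

# Smallest angular distance between two axial directions (mod 180).
axial_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  min(d, 180 - d)
}

# Random tie-free sample pair of equal size n.
tie_free_pair <- function(n) {
  v <- sample(seq_len(100), 2 * n)
  list(x = v[seq_len(n)], y = v[n + seq_len(n)])
}
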