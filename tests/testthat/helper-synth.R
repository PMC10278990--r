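# Shared fixture builders. All synthetic data is generated in code at test
# time; sizes are kept small because the phenomena are scale-free.

small_cfg <- function(...) {
  defaults <- list(duration_s = 60, fs_raw = 5, fov = 48L, n_astro = 1L,
                   n_neuro_units = 0L, mean_quiet_s = 20, mean_run_s = 8,
                   paired_prob = 0, max_shift_px = 0L,
                   domain_radius_px = 14, soma_radius_px = 4, seed = 1L)
  do.call(scenario_config, utils::modifyList(defaults, list(...)))
}

# constructed single-pixel movie from a trace (H = W = 1)
trace_movie <- function(x, fs) {
  ca_movie(array(x, c(1, 1, length(x))), fs = fs, channel = "green")
}

# difference-of-exponentials kernel, peak 1
dexp_kernel <- function(fs, rise_s, decay_s, len_s = 8 * decay_s) {
  t <- seq(0, len_s, by = 1 / fs)
  k <- exp(-t / decay_s) - exp(-t / rise_s)
  k / max(k)
}

# greedy one-to-one matching of recovered units to ground-truth units by
# footprint Jaccard; returns matched Jaccard and trace correlation vectors
match_units <- function(units, truth_units, fs_ratio_len) {
  truth_fp <- lapply(truth_units, function(u) u$footprint > 0.2)
  tr <- sapply(truth_units, function(u)
    block_mean_resample(u$trace, fs_ratio_len))
  J <- outer(seq_along(units), seq_along(truth_fp), Vectorize(function(i, j)
    jaccard_logical(units[[i]]$footprint > 0, truth_fp[[j]])))
  C <- outer(seq_along(units), seq_len(ncol(tr)), Vectorize(function(i, j)
    stats::cor(units[[i]]$trace, tr[, j])))
  jac <- c(); cc <- c(); used <- integer(0)
  for (i in order(-apply(J, 1, max))) {
    j <- setdiff(order(-J[i, ]), used)[1]
    jac <- c(jac, J[i, j]); cc <- c(cc, C[i, j]); used <- c(used, j)
  }
  list(jaccard = jac, trace_cor = cc)
}

jaccard_logical <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}

block_mean_resample <- function(x, n) {
  g <- floor(seq_along(x) / (length(x) / n) - 1e-9)
  out <- as.numeric(tapply(x, g, mean))
  out[seq_len(n)]
}

# independent exhaustive minimiser of the Li cross-entropy criterion
exhaustive_li <- function(v) {
  xent <- function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) return(Inf)
    -sum(lo) * log(mean(lo)) - sum(hi) * log(mean(hi))
  }
  u <- sort(unique(v))
  cand <- (u[-length(u)] + u[-1]) / 2
  cand[which.min(vapply(cand, xent, 0))]
}
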