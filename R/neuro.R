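# Patch-based non-negative factorization of neuronal movies into activity
# units: per-patch decomposition, whole-frame refinement, Li-threshold
# footprint clipping, and Ward merging of temporal dynamics.

# Hierarchical alternating least squares for Y ~ A C with A, C >= 0.
# Monotone in the squared reconstruction error. A: P x k, C: k x T.
nmf_hals <- function(Y, A, C, n_iter = 100L, tol = 1e-6) {
  obj <- numeric(0)
  prev <- Inf
  for (it in seq_len(n_iter)) {
    # update A given C
    G <- tcrossprod(C)               # k x k
    YCt <- Y %*% t(C)                # P x k
    for (j in seq_len(ncol(A))) {
      g <- G[j, j]
      if (g <= .Machine$double.eps) { A[, j] <- 0; next }
      A[, j] <- pmax(0, A[, j] + (YCt[, j] - A %*% G[, j]) / g)
    }
    # update C given A
    H <- crossprod(A)                # k x k
    AtY <- crossprod(A, Y)           # k x T
    for (j in seq_len(nrow(C))) {
      hh <- H[j, j]
      if (hh <= .Machine$double.eps) { C[j, ] <- 0; next }
      C[j, ] <- pmax(0, C[j, ] + (AtY[j, ] - H[j, ] %*% C) / hh)
    }
    e <- sum((Y - A %*% C)^2)
    obj <- c(obj, e)
    if (is.finite(prev) && prev - e < tol * max(prev, 1)) break
    prev <- e
  }
  list(A = A, C = C, objective = obj)
}

# Deterministic non-negative initialisation from the truncated SVD
# (nndsvd-style: the dominant non-negative part of each component pair).
nndsvd_init <- function(Y, k) {
  sv <- trunc_svd(Y, k)
  P <- nrow(Y); Tn <- ncol(Y)
  A <- matrix(0, P, k); C <- matrix(0, k, Tn)
  A[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  C[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k > 1) for (j in 2:k) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    np <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nn <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (np >= nn && np > 0) {
      A[, j] <- sqrt(sv$d[j] * np) * up / sqrt(sum(up^2))
      C[j, ] <- sqrt(sv$d[j] * np) * vp / sqrt(sum(vp^2))
    } else if (nn > 0) {
      A[, j] <- sqrt(sv$d[j] * nn) * un / sqrt(sum(un^2))
      C[j, ] <- sqrt(sv$d[j] * nn) * vn / sqrt(sum(vn^2))
    }
  }
  list(A = A, C = C)
}

#' Patch-wise non-negative decomposition
#'
#' Splits the movie into overlapping square patches and factorizes each
#' patch's pixels-by-time matrix into `k_per_patch` non-negative spatial
#' and temporal components (plus one background component per patch, which
#' absorbs diffuse signal and is dropped from the output). There is no
#' temporal-kinetics constraint; spatial localization comes from the patch
#' structure. Components are tagged with their patch of origin.
#'
#' @param m a `dff_movie`, [ca_movie()], or non-negative `H x W x T` array.
#' @param patch patch side in pixels (default 100).
#' @param k_per_patch components per patch (default 12).
#' @param overlap patch overlap in pixels (default `patch / 2`).
#' @param n_iter HALS iterations per patch.
#' @return list of components, each with full-frame `footprint` (`H x W`),
#'   `trace`, `patch` origin, and the per-patch `objective` path.
#' @export
patch_decompose <- function(m, patch = 100L, k_per_patch = 12L,
                            overlap = NULL, n_iter = 100L) {
  X <- movie_array(m)
  d <- dim(X)
  patch <- as.integer(min(patch, d[1], d[2]))
  if (is.null(overlap)) overlap <- patch %/% 2L
  starts <- function(extent) {
    s <- seq(1L, max(extent - patch + 1L, 1L), by = patch - as.integer(overlap))
    unique(c(s, extent - patch + 1L))
  }
  comps <- list()
  for (y0 in starts(d[1])) for (x0 in starts(d[2])) {
    yi <- y0:(y0 + patch - 1L); xi <- x0:(x0 + patch - 1L)
    Y <- matrix(X[yi, xi, ], patch^2, d[3])
    if (max(Y) <= 0) next                       # degenerate patch
    k <- min(k_per_patch + 1L, patch^2, d[3])   # +1 background component
    init <- nndsvd_init(Y, k)
    fit <- nmf_hals(Y, init$A, init$C, n_iter = n_iter)
    for (j in seq_len(ncol(fit$A))) {
      if (max(fit$A[, j]) <= 0 || max(fit$C[j, ]) <= 0) next
      fp_patch <- matrix(fit$A[, j], patch, patch)
      # patch-spanning diffuse components are background: drop
      support_frac <- mean(fp_patch > 0.05 * max(fp_patch))
      if (support_frac > 0.5) next
      fp <- matrix(0, d[1], d[2])
      fp[yi, xi] <- fp_patch
      comps[[length(comps) + 1L]] <-
        list(footprint = fp, trace = fit$C[j, ],
             patch = c(y0, x0), objective = fit$objective)
    }
  }
  comps
}

movie_array <- function(m) {
  X <- if (inherits(m, "dff_movie")) m$dff
  else if (inherits(m, "ca_movie")) m$frames
  else m
  X[is.na(X)] <- 0
  X[X < 0] <- 0   # negative dF/F excursions are noise; factorization is
                  # non-negative
  X
}

#' Whole-frame refinement of patch components
#'
#' Re-runs the non-negative factorization on the entire frame with the
#' patch-based components as the initial condition. The HALS updates are
#' monotone, so the refined objective never exceeds the initial one.
#'
#' @param m movie as in [patch_decompose()].
#' @param comps components from [patch_decompose()].
#' @param n_iter HALS iterations.
#' @return refined components (same structure, plus the global `objective`).
#' @export
refine_global <- function(m, comps, n_iter = 50L) {
  if (!length(comps)) stop("no initial components")
  X <- movie_array(m)
  d <- dim(X)
  Y <- matrix(X, d[1] * d[2], d[3])
  A <- vapply(comps, function(cc) as.numeric(cc$footprint),
              numeric(d[1] * d[2]))
  C <- t(vapply(comps, function(cc) cc$trace, numeric(d[3])))
  fit <- nmf_hals(Y, A, C, n_iter = n_iter)
  out <- lapply(seq_along(comps), function(j) {
    list(footprint = matrix(fit$A[, j], d[1], d[2]),
         trace = fit$C[j, ], patch = comps[[j]]$patch,
         objective = fit$objective)
  })
  keep <- vapply(out, function(cc)
    max(cc$footprint) > 0 && max(cc$trace) > 0, logical(1))
  out[keep]
}

#' Li minimum cross-entropy threshold
#'
#' Iterative threshold of Li and Tam: starting from the sample mean, the
#' threshold is updated to `(mu_bg - mu_fg) / (log(mu_bg) - log(mu_fg))`
#' where `mu_bg`, `mu_fg` are the means of the values below/above the
#' current threshold, until convergence. Input values must be positive.
#'
#' The fixed point is then polished by discrete descent of the
#' cross-entropy criterion over the data-derived candidate thresholds
#' (midpoints of adjacent sorted values), so near-ties between neighbouring
#' candidates resolve to the better split.
#'
#' @param v positive numeric values (e.g. nonzero footprint weights).
#' @param tol convergence tolerance.
#' @return the threshold.
#' @export
li_threshold <- function(v, tol = 1e-8) {
  stopifnot(all(v > 0))
  t_cur <- mean(v)
  for (it in 1:200) {
    lo <- v[v <= t_cur]; hi <- v[v > t_cur]
    if (!length(lo) || !length(hi)) break
    m1 <- mean(lo); m2 <- mean(hi)
    if (abs(m1 - m2) < tol) break
    t_new <- (m1 - m2) / (log(m1) - log(m2))
    if (abs(t_new - t_cur) < tol) { t_cur <- t_new; break }
    t_cur <- t_new
  }
  u <- sort(unique(v))
  if (length(u) < 2L) return(t_cur)
  cand <- (u[-length(u)] + u[-1]) / 2
  i <- which.min(abs(cand - t_cur))
  repeat {
    left <- if (i > 1L) li_cross_entropy(v, cand[i - 1L]) else Inf
    right <- if (i < length(cand)) li_cross_entropy(v, cand[i + 1L]) else Inf
    here <- li_cross_entropy(v, cand[i])
    if (left < here && left <= right) i <- i - 1L
    else if (right < here) i <- i + 1L
    else break
  }
  cand[i]
}

# Li & Tam minimum cross-entropy criterion for a threshold t.
li_cross_entropy <- function(v, t) {
  lo <- v[v <= t]; hi <- v[v > t]
  if (!length(lo) || !length(hi)) return(Inf)
  -sum(lo) * log(mean(lo)) - sum(hi) * log(mean(hi))
}

#' Clip a footprint with Li's auto-threshold
#'
#' Computes Li's minimum cross-entropy threshold on the nonzero pixels of
#' the footprint and zeroes all weights below it, removing irregular
#' low-amplitude halo.
#'
#' @param footprint non-negative matrix.
#' @return the clipped footprint.
#' @export
clip_footprint_li <- function(footprint) {
  v <- footprint[footprint > 0]
  if (length(unique(v)) < 2L) {
    warning("footprint has < 2 distinct nonzero values; returned unchanged")
    return(footprint)
  }
  thr <- li_threshold(v)
  footprint[footprint < thr] <- 0
  footprint
}

#' Merge components into final activity units by Ward clustering
#'
#' Standardizes the temporal traces (z-score), clusters them by Ward
#' linkage on Euclidean distance, cuts at `n_final` clusters, and merges
#' each cluster into one activity unit: footprint = sum of member
#' footprints, trace = member traces averaged with footprint-mass weights.
#'
#' @param comps components (footprint + trace lists).
#' @param n_final number of final units (default 12).
#' @return list of units with `footprint`, `trace`, `members`.
#' @export
merge_units <- function(comps, n_final = 12L) {
  k <- length(comps)
  if (k < n_final) {
    warning("fewer components (", k, ") than requested units (", n_final,
            "); returning components unmerged")
    cl <- seq_len(k)
  } else if (k == n_final) {
    cl <- seq_len(k)
  } else {
    Z <- t(vapply(comps, function(cc) {
      x <- cc$trace
      s <- stats::sd(x)
      if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
    }, numeric(length(comps[[1]]$trace))))
    hc <- stats::hclust(stats::dist(Z), method = "ward.D2")
    cl <- stats::cutree(hc, k = n_final)
  }
  lapply(sort(unique(cl)), function(g) {
    idx <- which(cl == g)
    fp <- Reduce(`+`, lapply(comps[idx], `[[`, "footprint"))
    wts <- vapply(comps[idx], function(cc) sum(cc$footprint), 0)
    if (sum(wts) == 0) wts <- rep(1, length(idx))
    tr <- Reduce(`+`, Map(function(cc, w) w * cc$trace,
                          comps[idx], as.list(wts / sum(wts))))
    list(footprint = fp, trace = tr, members = idx)
  })
}

#' Classify activity units by locomotion coupling
#'
#' Labels each unit `locomotion_active` if its mean trace during locomotion
#' exceeds its mean during quiescence, else `quiescent_active`.
#'
#' @param units list of units (with `trace`).
#' @param episodes episode data.frame (`start_s`, `end_s`, `label`).
#' @param fs sampling rate of the traces, Hz.
#' @return character vector of labels (NA if either state is absent).
#' @export
unit_classification <- function(units, episodes, fs) {
  n <- length(units[[1]]$trace)
  tt <- (seq_len(n) - 1) / fs
  in_loco <- episode_indicator(tt, episodes, "locomotion")
  in_quiet <- episode_indicator(tt, episodes, "quiescence")
  if (!any(in_loco) || !any(in_quiet))
    return(rep(NA_character_, length(units)))
  vapply(units, function(u) {
    if (mean(u$trace[in_loco]) > mean(u$trace[in_quiet]))
      "locomotion_active" else "quiescent_active"
  }, character(1))
}

episode_indicator <- function(tt, episodes, label) {
  keep <- rep(FALSE, length(tt))
  e <- episodes[episodes$label == label, , drop = FALSE]
  for (i in seq_len(nrow(e)))
    keep <- keep | (tt >= e$start_s[i] & tt < e$end_s[i])
  keep
}

#' End-to-end neuronal segmentation
#'
#' Patch decomposition, whole-frame refinement, Li clipping of every
#' footprint, and Ward merging to `n_final` activity units.
#'
#' @inheritParams patch_decompose
#' @param n_final number of final units (default 12).
#' @param min_snr components whose trace peak falls below `min_snr` robust
#'   (MAD-based) noise SDs are discarded before merging, unless fewer than
#'   `n_final` would remain (default 6).
#' @return list of activity units.
#' @export
segment_neuro_movie <- function(m, patch = 100L, k_per_patch = 12L,
                                overlap = NULL, n_final = 12L,
                                n_iter = 100L, min_snr = 6) {
  comps <- patch_decompose(m, patch = patch, k_per_patch = k_per_patch,
                           overlap = overlap, n_iter = n_iter)
  if (!length(comps)) return(list())
  comps <- refine_global(m, comps, n_iter = max(25L, n_iter %/% 2L))
  comps <- lapply(comps, function(cc) {
    cc$footprint <- suppressWarnings(clip_footprint_li(cc$footprint))
    cc
  })
  comps <- Filter(function(cc) sum(cc$footprint) > 0, comps)
  snr <- vapply(comps, function(cc)
    max(cc$trace) / (1.4826 * stats::mad(cc$trace) + 1e-12), 0)
  keep <- comps[snr > min_snr]
  if (length(keep) >= n_final) comps <- keep
  merge_units(comps, n_final = n_final)
}
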