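# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG state seeded by `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Integer translation with replicated borders: content moves down by dy rows
# and right by dx columns.
translate_int <- function(img, dy, dx) {
  h <- nrow(img); w <- ncol(img)
  ri <- pmin(pmax(seq_len(h) - dy, 1L), h)
  ci <- pmin(pmax(seq_len(w) - dx, 1L), w)
  img[ri, ci, drop = FALSE]
}

# Truncated SVD of M keeping k components, via the smaller Gram matrix.
# Returns list(u, d, v) with u: nrow x k, v: ncol x k.
trunc_svd <- function(M, k) {
  n <- nrow(M); p <- ncol(M)
  k <- min(k, n, p)
  if (n <= p) {
    G <- tcrossprod(M)            # n x n
    e <- eigen(G, symmetric = TRUE)
    d <- sqrt(pmax(e$values[seq_len(k)], 0))
    u <- e$vectors[, seq_len(k), drop = FALSE]
    v <- crossprod(M, u)
    v <- sweep(v, 2, pmax(d, .Machine$double.eps), "/")
  } else {
    G <- crossprod(M)             # p x p
    e <- eigen(G, symmetric = TRUE)
    d <- sqrt(pmax(e$values[seq_len(k)], 0))
    v <- e$vectors[, seq_len(k), drop = FALSE]
    u <- M %*% v
    u <- sweep(u, 2, pmax(d, .Machine$double.eps), "/")
  }
  list(u = u, d = d, v = v)
}

# Gaussian smoothing along time (columns of X, P x T), kernel normalised
# within the record so edges are not biased toward zero.
gauss_smooth_time <- function(X, sigma_samples) {
  if (sigma_samples <= 0) return(X)
  Tn <- ncol(X)
  half <- min(Tn - 1L, max(1L, ceiling(3 * sigma_samples)))
  k <- exp(-0.5 * ((-half:half) / sigma_samples)^2)
  # T x T banded smoothing matrix with per-column renormalisation
  S <- matrix(0, Tn, Tn)
  for (j in seq_len(Tn)) {
    idx <- max(1L, j - half):min(Tn, j + half)
    w <- k[idx - j + half + 1L]
    S[idx, j] <- w / sum(w)
  }
  X %*% S
}

# Running minimum over a window of `w` samples along columns of X. The
# window is centered where possible and slides fully inside the record near
# the edges, so every position sees a full-length window and the negative
# bias of the minimum is uniform (removable by a constant offset).
running_min_time <- function(X, w) {
  w <- max(1L, as.integer(w))
  Tn <- ncol(X)
  w <- min(w, Tn)
  if (w == 1L) return(X)
  half <- w %/% 2L
  starts <- pmin(pmax(seq_len(Tn) - half, 1L), Tn - w + 1L)
  # van Herk: block prefix/suffix minima give any width-w window minimum as
  # min(suffix[start], prefix[start + w - 1]) in O(1) per sample
  nb <- ceiling(Tn / w)
  pad <- nb * w
  P <- cbind(X, matrix(Inf, nrow(X), pad - Tn))
  S <- P
  for (b in seq_len(nb)) {
    i0 <- (b - 1L) * w + 1L
    for (k in 1L:(w - 1L)) {
      P[, i0 + k] <- pmin(P[, i0 + k], P[, i0 + k - 1L])
      S[, i0 + w - 1L - k] <- pmin(S[, i0 + w - 1L - k], S[, i0 + w - k])
    }
  }
  pmin(S[, starts, drop = FALSE], P[, starts + w - 1L, drop = FALSE])
}

# 8-connected labelling of a logical matrix. Label propagation by iterated
# minimum over the 8 neighbour shifts; adequate for the compact clusters that
# arise from thresholded dF/F frames.
label_components8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(lab)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  big <- h * w + 1L
  labf <- matrix(big, h, w)
  labf[mask] <- lab[mask]
  repeat {
    new <- labf
    for (s in shifts) {
      sh <- translate_shift_pad(labf, s[1], s[2], big)
      new <- pmin(new, sh)
    }
    new[!mask] <- big
    if (identical(new, labf)) break
    labf <- new
  }
  lab[mask] <- labf[mask]
  # compact labels to 1..n
  u <- sort(unique(lab[mask]))
  lab[mask] <- match(lab[mask], u)
  lab
}

translate_shift_pad <- function(img, dy, dx, pad) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(pad, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys, xs] <- img[ys - dy, xs - dx]
  out
}

jaccard_index <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}
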