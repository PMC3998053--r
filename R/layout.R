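# 2D layouts of explored chemical space: linear projection of fingerprint
# space (PCA) and a stress-minimizing Kamada-Kawai embedding of the
# pairwise fingerprint-distance matrix.

#' PCA layout of fingerprint space
#'
#' Treats bit vectors as 0/1 coordinates, mean-centres them and projects
#' onto the top two principal directions. The sign of each axis is fixed by
#' making its largest-magnitude loading positive, so the layout is fully
#' deterministic.
#'
#' @param fps List of `mol_fp` objects of one kind.
#' @return Numeric matrix, one row per fingerprint, columns `x` and `y`.
#'   All-identical fingerprints yield all points at the origin.
#' @export
pca_layout <- function(fps) {
  stopifnot(length(fps) >= 2L)
  m <- do.call(rbind, lapply(fps, function(fp) {
    as.integer(rawToBits(fp$bits))[seq_len(fp$length)]
  }))
  m <- scale(m, center = TRUE, scale = FALSE)
  if (all(abs(m) < 1e-12)) {
    coords <- matrix(0, nrow = length(fps), ncol = 2L)
  } else {
    sv <- svd(m, nu = 0L, nv = 2L)
    v <- sv$v
    if (ncol(v) < 2L) v <- cbind(v, 0)
    # sign convention: largest-magnitude loading positive
    for (j in 1:2) {
      if (any(v[, j] != 0) && v[which.max(abs(v[, j])), j] < 0) {
        v[, j] <- -v[, j]
      }
    }
    coords <- m %*% v
  }
  colnames(coords) <- c("x", "y")
  coords
}

kk_energy <- function(coords, d, w) {
  dx <- outer(coords[, 1L], coords[, 1L], "-")
  dy <- outer(coords[, 2L], coords[, 2L], "-")
  e <- sqrt(dx^2 + dy^2)
  sum(w[upper.tri(w)] * (e[upper.tri(e)] - d[upper.tri(d)])^2)
}

#' Kamada-Kawai layout of a distance matrix
#'
#' Minimizes the layout energy
#' `E = sum_{i<j} (1/d_ij^2) (||x_i - x_j|| - d_ij)^2`
#' by node-wise Newton relaxation with step halving (so the energy is
#' non-increasing across accepted steps), starting from a seeded random
#' configuration. Off-diagonal zero distances (duplicate molecules) are
#' coalesced before layout and re-expanded to coincident points.
#'
#' @param d_matrix Symmetric distance matrix with zero diagonal.
#' @param max_iters Maximum number of node relaxation sweeps.
#' @param tol Stop when an entire sweep improves the energy by less than
#'   this.
#' @param seed Integer seed for the random start.
#' @return List of class `kk_layout`: `coords` (matrix with `x`, `y`),
#'   `energy`, and `d_matrix`.
#' @export
kk_layout <- function(d_matrix, max_iters = 200L, tol = 1e-10, seed = 1L) {
  d_matrix <- as.matrix(d_matrix)
  n_all <- nrow(d_matrix)
  stopifnot(n_all == ncol(d_matrix),
            max(abs(d_matrix - t(d_matrix))) < 1e-12,
            all(diag(d_matrix) == 0), all(d_matrix >= 0))

  # coalesce duplicate rows (off-diagonal zero distance)
  group <- seq_len(n_all)
  for (i in seq_len(n_all)) {
    z <- which(d_matrix[i, ] == 0 & seq_len(n_all) < i)
    if (length(z)) group[i] <- group[z[1L]]
  }
  reps <- unique(group)
  d <- d_matrix[reps, reps, drop = FALSE]
  n <- nrow(d)

  local_seed(seed)
  span <- if (n > 1) max(d) else 1
  coords <- matrix(stats::runif(2L * n, -span, span), ncol = 2L)
  if (n >= 2L) {
    w <- ifelse(d > 0, 1 / d^2, 0)
    diag(w) <- 0
    energy <- kk_energy(coords, d, w)
    for (sweep in seq_len(max_iters)) {
      e0 <- energy
      for (m in seq_len(n)) {
        dx <- coords[m, 1L] - coords[, 1L]
        dy <- coords[m, 2L] - coords[, 2L]
        dist_m <- sqrt(dx^2 + dy^2)
        ok <- seq_len(n) != m & dist_m > 1e-12
        if (!any(ok)) next
        # gradient of E wrt x_m
        coef <- 2 * w[m, ok] * (dist_m[ok] - d[m, ok]) / dist_m[ok]
        gx <- sum(coef * dx[ok]); gy <- sum(coef * dy[ok])
        gnorm <- sqrt(gx^2 + gy^2)
        if (gnorm < 1e-14) next
        step <- 0.25 / max(sum(w[m, ok]), 1e-12)  # scaled gradient step
        for (h in 1:20) {
          cand <- coords
          cand[m, ] <- coords[m, ] - step * c(gx, gy)
          e_cand <- kk_energy(cand, d, w)
          if (e_cand < energy) {
            coords <- cand; energy <- e_cand
            break
          }
          step <- step / 2
        }
      }
      if (e0 - energy < tol) break
    }
  } else {
    energy <- 0
  }
  out <- coords[match(group, reps), , drop = FALSE]
  colnames(out) <- c("x", "y")
  structure(list(coords = out, energy = energy, d_matrix = d_matrix),
            class = "kk_layout")
}

#' Lay out an exploration tree
#'
#' Computes 2D coordinates for every molecule currently in the tree, using
#' either the PCA projection of fingerprint space or the Kamada-Kawai
#' embedding of the pairwise fingerprint-distance matrix (the distances use
#' the job's fingerprint kind and similarity coefficient).
#'
#' @param job An `exploration`.
#' @param method `"pca"` or `"kk"`.
#' @param seed Seed for the Kamada-Kawai random start.
#' @return Data frame with columns `canonical`, `x`, `y`.
#' @export
layout_tree <- function(job, method = c("pca", "kk"), seed = 1L) {
  stopifnot(inherits(job, "exploration"))
  method <- match.arg(method)
  cans <- names(job$nodes)
  fps <- fingerprint_batch(lapply(job$nodes, `[[`, "graph"),
                           job$cfg$fp_kind)
  if (method == "pca") {
    coords <- pca_layout(fps)
  } else {
    n <- length(fps)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        d[i, j] <- d[j, i] <-
          1 - similarity(fps[[i]], fps[[j]], job$cfg$coeff)
      }
    }
    coords <- kk_layout(d, seed = seed)$coords
  }
  data.frame(canonical = cans, x = coords[, 1L], y = coords[, 2L],
             row.names = NULL, stringsAsFactors = FALSE)
}
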