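# Consensus (multiblock) PCA over user-defined ppm blocks, each with its own
# scaling and weight, yielding super scores, block scores and block loadings.
# The CPCA-W iteration used here is, per component, an exact power iteration
# on the concatenated weighted block matrix, so super scores coincide with
# plain PCA scores of that concatenation; the added value is the block-level
# decomposition (weights, scores, loadings, per-block variance).

#' Define a spectral block
#'
#' @param name Block name.
#' @param ppm_hi,ppm_lo Closed ppm interval (`ppm_hi > ppm_lo`).
#' @param scaling Per-block variable scaling: `"none"`, `"center"`, `"uv"`,
#'   `"pareto"`.
#' @param weight_rule `"inverse_sqrt_p"` (divide the block by the square root
#'   of its variable count, so small low-intensity regions are not swamped)
#'   or `"unit"`.
#' @return A `block_definition` list.
#' @export
block_definition <- function(name, ppm_hi, ppm_lo, scaling = "center",
                             weight_rule = c("inverse_sqrt_p", "unit")) {
  if (!(ppm_hi > ppm_lo)) stop("block must have ppm_hi > ppm_lo")
  structure(list(name = name, ppm_hi = ppm_hi, ppm_lo = ppm_lo,
                 scaling = match.arg(scaling, c("none", "center", "uv", "pareto")),
                 weight_rule = match.arg(weight_rule)),
            class = "block_definition")
}

#' Fit a consensus multiblock PCA
#'
#' Each block is the sub-matrix of grid columns inside its ppm interval,
#' preprocessed with its own scaling and multiplied by its weight
#' (`1/sqrt(p_b)` under `inverse_sqrt_p`). Per component, the CPCA-W loop
#' alternates block loadings `p_b = X_b' t_T / (t_T' t_T)` (normalized),
#' block scores `t_b = X_b p_b`, super weights `w_T = T_blk' t_T / (t_T' t_T)`
#' (normalized) and the super score `t_T = T_blk w_T` until the relative
#' change of `t_T` falls below `tol`; every block is then deflated by the
#' super score. Signs follow the PCA convention (largest-|loading| entry of
#' the concatenated deflation loading positive).
#'
#' @param m A [spectra_matrix].
#' @param blocks List of [block_definition]s; blocks must not overlap and
#'   each must contain at least 2 grid points.
#' @param n_components Number of consensus components.
#' @param tol,max_iter Convergence control of the CPCA-W loop.
#' @return An object of class `mbpca_model`: `super_scores` (n x A),
#'   `super_weights` (B x A, unit columns), per-block `block_scores`
#'   (n x A each), `block_loadings` (p_b x A each), `block_ppm`,
#'   `explained_variance` (per block and `overall`, fractions of the
#'   weighted, scaled SS), `blocks`, `sample_ids`.
#' @export
fit_mbpca <- function(m, blocks, n_components = 2, tol = 1e-12,
                      max_iter = 10000) {
  if (length(blocks) == 0) stop("at least one block required")
  idx <- lapply(blocks, function(b) which(m$ppm <= b$ppm_hi & m$ppm >= b$ppm_lo))
  for (k in seq_along(blocks)) {
    if (length(idx[[k]]) < 2L)
      stop(sprintf("block '%s' contains %d grid points; need >= 2",
                   blocks[[k]]$name, length(idx[[k]])))
  }
  all_idx <- unlist(idx)
  if (anyDuplicated(all_idx)) stop("blocks overlap on the ppm grid")
  n <- nrow(m$X)
  B <- length(blocks)
  Xb <- vector("list", B)
  weights <- numeric(B)
  for (k in seq_len(B)) {
    sub <- spectra_matrix(m$X[, idx[[k]], drop = FALSE], m$ppm[idx[[k]]],
                          sample_ids(m))
    sc <- scale_variables(sub, blocks[[k]]$scaling)
    if (length(sc$dropped_ppm) > 0)
      idx[[k]] <- idx[[k]][!(m$ppm[idx[[k]]] %in% sc$dropped_ppm)]
    weights[k] <- if (blocks[[k]]$weight_rule == "inverse_sqrt_p")
      1 / sqrt(ncol(sc$matrix$X)) else 1
    Xb[[k]] <- sc$matrix$X * weights[k]
  }
  block_ss <- vapply(Xb, function(x) sum(x^2), numeric(1))
  super_scores <- matrix(0, n, n_components)
  super_weights <- matrix(0, B, n_components)
  block_scores <- lapply(seq_len(B), function(k) matrix(0, n, n_components))
  block_loadings <- lapply(seq_len(B), function(k)
    matrix(0, length(idx[[k]]), n_components))
  expl <- matrix(0, B, n_components)
  for (a in seq_len(n_components)) {
    concat <- do.call(cbind, Xb)
    t_T <- concat[, which.max(colSums(concat^2))]
    if (sum(t_T^2) == 0) stop("no variance left for component ", a)
    p_list <- NULL; w_T <- NULL; T_blk <- NULL
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      T_blk <- matrix(0, n, B)
      p_list <- vector("list", B)
      for (k in seq_len(B)) {
        p_k <- drop(crossprod(Xb[[k]], t_T)) / sum(t_T^2)
        p_k <- p_k / sqrt(sum(p_k^2))
        p_list[[k]] <- p_k
        T_blk[, k] <- Xb[[k]] %*% p_k
      }
      w_T <- drop(crossprod(T_blk, t_T)) / sum(t_T^2)
      w_T <- w_T / sqrt(sum(w_T^2))
      t_new <- drop(T_blk %*% w_T)
      delta <- sqrt(sum((t_new - t_T)^2)) / sqrt(sum(t_new^2))
      t_T <- t_new
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
      warning(sprintf("CPCA-W component %d did not converge in %d iterations",
                      a, max_iter))
    # deflation loadings per block; concatenated vector fixes the sign
    defl <- lapply(Xb, function(x) drop(crossprod(x, t_T)) / sum(t_T^2))
    p_all <- unlist(defl)
    if (p_all[which.max(abs(p_all))] < 0) {
      t_T <- -t_T
      T_blk <- -T_blk
      p_list <- lapply(p_list, function(p) -p)
      defl <- lapply(defl, function(p) -p)
    }
    super_scores[, a] <- t_T
    super_weights[, a] <- w_T
    for (k in seq_len(B)) {
      block_scores[[k]][, a] <- T_blk[, k]
      block_loadings[[k]][, a] <- p_list[[k]]
      removed <- tcrossprod(t_T, defl[[k]])
      expl[k, a] <- sum(removed^2) / block_ss[k]
      Xb[[k]] <- Xb[[k]] - removed
    }
  }
  names(block_scores) <- names(block_loadings) <-
    vapply(blocks, `[[`, character(1), "name")
  rownames(super_scores) <- sample_ids(m)
  structure(list(super_scores = super_scores, super_weights = super_weights,
                 block_scores = block_scores, block_loadings = block_loadings,
                 block_ppm = lapply(idx, function(i) m$ppm[i]),
                 block_weights = weights,
                 explained_variance = list(
                   per_block = expl,
                   overall = colSums(expl * block_ss) / sum(block_ss)),
                 blocks = blocks, sample_ids = sample_ids(m)),
            class = "mbpca_model")
}

#' @export
print.mbpca_model <- function(x, ...) {
  cat(sprintf("<mbpca_model> %d block(s), %d component(s)\n",
              length(x$blocks), ncol(x$super_scores)))
  cat("overall explained variance:",
      paste(sprintf("%.3f", x$explained_variance$overall), collapse = " "), "\n")
  invisible(x)
}
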