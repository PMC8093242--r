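# Questionnaire preprocessing and data-driven measurement-model specification:
# delta scores, category aggregation, partial-correlation network by covariance
# selection (Gaussian graphical model, AIC-guided backward elimination), and
# item-level PCA on the partial correlation matrix.

#' Delta scores from paired questionnaire conditions
#'
#' Per subject and item, the high-load ("after") response minus the low-load
#' ("before") response; both on the 1–7 scale, so deltas lie in -6..6.
#'
#' @param responses data frame with `q*_before` and `q*_after` columns (and
#'   optionally an `id` column, carried through).
#' @param items item names; default the 14 items of [default_item_map()].
#' @return data frame of per-item delta columns (plus `id` if present).
#' @export
delta_scores <- function(responses, items = names(default_item_map())) {
  before <- paste0(items, "_before")
  after <- paste0(items, "_after")
  missing_cols <- setdiff(c(before, after), names(responses))
  if (length(missing_cols) > 0)
    stop_semscan(paste("missing questionnaire columns:",
                       paste(missing_cols, collapse = ", ")),
                 "semscan_validation_error")
  B <- as.matrix(responses[, before]); A <- as.matrix(responses[, after])
  bad <- which(!(B %in% 1:7) | !(A %in% 1:7))
  if (length(bad) > 0) {
    i <- ((bad[1] - 1) %% nrow(B)) + 1
    j <- ((bad[1] - 1) %/% nrow(B)) + 1
    stop_semscan(sprintf("Likert value outside 1..7 for subject %s, item %s",
                         if ("id" %in% names(responses)) responses$id[i] else i,
                         items[j]),
                 "semscan_validation_error")
  }
  out <- as.data.frame(A - B)
  names(out) <- items
  if ("id" %in% names(responses)) out <- cbind(id = responses$id, out)
  out
}

#' Category scores by item averaging
#'
#' @param deltas output of [delta_scores()].
#' @param item_map named vector mapping item id to category label.
#' @return data frame with one mean-score column per category (plus `id` if
#'   present in `deltas`).
#' @export
category_scores <- function(deltas, item_map = default_item_map()) {
  missing_cols <- setdiff(names(item_map), names(deltas))
  if (length(missing_cols) > 0)
    stop_semscan(paste("missing item columns:",
                       paste(missing_cols, collapse = ", ")),
                 "semscan_validation_error")
  cats <- unique(unname(item_map))
  out <- sapply(cats, function(cl) {
    rowMeans(as.matrix(deltas[, names(item_map)[item_map == cl], drop = FALSE]))
  })
  out <- as.data.frame(out)
  names(out) <- cats
  if ("id" %in% names(deltas)) out <- cbind(id = deltas$id, out)
  out
}

#' Pairwise partial correlations
#'
#' `rho_ij.rest = -Omega_ij / sqrt(Omega_ii * Omega_jj)` where `Omega` is the
#' inverse of the correlation matrix, equivalent to correlating the residuals
#' of each pair regressed on all remaining variables.
#'
#' @param data numeric data frame or matrix (subjects x variables).
#' @param ridge ridge constant added to the correlation diagonal if inversion
#'   fails (logged via a message); `NULL` disables the guard.
#' @return symmetric matrix of partial correlations with unit diagonal.
#' @export
partial_correlation_matrix <- function(data, ridge = 1e-6) {
  X <- as.matrix(data[, vapply(as.data.frame(data), is.numeric, TRUE),
                      drop = FALSE])
  if (nrow(X) <= ncol(X))
    stop_semscan("need more subjects than variables", "semscan_input_error")
  R <- cor(X)
  Om <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(Om)) {
    if (is.null(ridge))
      stop_semscan("singular correlation matrix; consider a ridge epsilon",
                   "semscan_numerical_error")
    message(sprintf("correlation matrix singular; ridge %g applied", ridge))
    Om <- solve(R + diag(ridge, ncol(R)))
  }
  D <- 1 / sqrt(diag(Om))
  P <- -Om * tcrossprod(D)
  diag(P) <- 1
  dimnames(P) <- dimnames(R)
  (P + t(P)) / 2
}

# Gaussian graphical model MLE under zero constraints on the precision matrix,
# by iterative proportional fitting over the edges (pairwise margins determine
# the Gaussian model, so edgewise IPF converges to the constrained MLE).
ggm_fit <- function(S, adjacency, tol = 1e-8, max_sweeps = 10000, K_start = NULL) {
  p <- ncol(S)
  K <- if (is.null(K_start)) diag(1 / diag(S)) else K_start
  edges <- which(upper.tri(adjacency) & adjacency != 0, arr.ind = TRUE)
  units <- c(lapply(seq_len(p), function(i) i),
             lapply(seq_len(nrow(edges)), function(r) as.integer(edges[r, ])))
  inv_S_cc <- lapply(units, function(cl) solve(S[cl, cl, drop = FALSE]))
  inv2 <- function(M) {  # explicit 2x2 inverse
    dt <- M[1] * M[4] - M[2] * M[3]
    matrix(c(M[4], -M[2], -M[3], M[1]), 2) / dt
  }
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    Sig <- chol2inv(chol(K))  # refresh to cancel Woodbury round-off drift
    for (u in seq_along(units)) {
      cl <- units[[u]]
      if (length(cl) == 1L) {
        upd <- inv_S_cc[[u]][1] - 1 / Sig[cl, cl] + K[cl, cl]
        D <- upd - K[cl, cl]
        delta <- max(delta, abs(D))
        if (abs(D) < tol * 1e-3) next
        K[cl, cl] <- upd
        scol <- Sig[, cl]
        Sig <- Sig - (D / (1 + D * Sig[cl, cl])) * tcrossprod(scol)
      } else {
        Scl <- Sig[cl, cl]
        upd <- inv_S_cc[[u]] - inv2(Scl) + K[cl, cl]
        D <- upd - K[cl, cl]
        dmax <- max(abs(D))
        delta <- max(delta, dmax)
        if (dmax < tol * 1e-3) next
        K[cl, cl] <- upd
        # rank-2 Woodbury update of Sigma = K^-1:
        # Sig' = Sig - Scol (I + D Scl)^-1 D Scol'
        Scol <- Sig[, cl]
        mid <- inv2(diag(2) + D %*% Scl) %*% D
        if (!all(is.finite(mid))) {
          Sig <- chol2inv(chol(K))
        } else {
          Sig <- Sig - Scol %*% mid %*% t(Scol)
        }
      }
    }
    if (delta < tol) {
      return(list(K = (K + t(K)) / 2, sweeps = sweep, converged = TRUE))
    }
  }
  stop_semscan(sprintf("IPF did not converge in %d sweeps (last delta %.3g)",
                       max_sweeps, delta), "semscan_numerical_error")
}

.ggm_loglik <- function(K, S, n) {
  p <- ncol(S)
  n / 2 * (determinant(K, logarithm = TRUE)$modulus - sum(K * S) -
             p * log(2 * pi))
}

.pcor_from_precision <- function(K) {
  D <- 1 / sqrt(diag(K))
  P <- -K * tcrossprod(D)
  diag(P) <- 1
  P
}

#' Covariance selection: Gaussian graphical model search by AIC
#'
#' Greedy backward elimination starting from the saturated graph: present
#' edges are examined in increasing order of absolute fitted partial
#' correlation; each candidate edge is tentatively removed and the model refit
#' by iterative proportional fitting under the zero constraints.  The first
#' removal that lowers `AIC = -2 loglik + 2 (free parameters)` is accepted and
#' the search restarts from the new model; the search stops when no single
#' removal lowers the AIC.  The accepted AIC sequence is strictly decreasing
#' by construction.
#'
#' @param S sample covariance (or correlation) matrix, positive definite.
#' @param n number of observations behind `S`.
#' @param tol IPF convergence tolerance.
#' @param penalty information-criterion penalty per free parameter; 2 is the
#'   AIC used throughout (log(n) would give BIC-type selection).
#' @return object of class `pcor_network`: `adjacency`, fitted `precision`,
#'   `pcor` (fitted partial correlations), `aic_trace` (AIC after each accepted
#'   state, starting with the saturated model) and `removed` edge list.
#' @export
covariance_selection <- function(S, n, tol = 1e-8, penalty = 2) {
  S <- as.matrix(S)
  p <- ncol(S)
  if (any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop_semscan("covariance matrix must be positive definite",
                 "semscan_input_error")
  adj <- matrix(1, p, p) - diag(p)
  dimnames(adj) <- dimnames(S)
  K <- solve(S)
  n_edges <- p * (p - 1) / 2
  aic <- -2 * .ggm_loglik(K, S, n) + penalty * (p + n_edges)
  aic_trace <- aic
  removed <- NULL
  try_fit <- function(adj_try) {
    # warm start: zero the dropped entry of the current precision if that
    # stays positive definite, else restart IPF from independence
    K0 <- K * (adj_try + diag(p))
    pd <- !inherits(tryCatch(chol(K0), error = identity), "error")
    ggm_fit(S, adj_try, tol = tol, K_start = if (pd) K0 else NULL)
  }
  repeat {
    cand <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
    if (nrow(cand) == 0) break
    P <- .pcor_from_precision(K)
    cand <- cand[order(abs(P[cand])), , drop = FALSE]
    accepted <- FALSE
    for (r in seq_len(nrow(cand))) {
      e <- cand[r, ]
      adj_try <- adj
      adj_try[e[1], e[2]] <- adj_try[e[2], e[1]] <- 0
      fit <- try_fit(adj_try)
      n_edges_try <- sum(adj_try[upper.tri(adj_try)] != 0)
      aic_try <- -2 * .ggm_loglik(fit$K, S, n) + penalty * (p + n_edges_try)
      if (aic_try < aic) {
        adj <- adj_try
        K <- fit$K
        aic <- aic_try
        aic_trace <- c(aic_trace, aic)
        removed <- rbind(removed, e)
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
  }
  structure(list(adjacency = adj, precision = K,
                 pcor = .pcor_from_precision(K),
                 aic_trace = aic_trace, removed = removed, n = n),
            class = "pcor_network")
}

#' @export
print.pcor_network <- function(x, ...) {
  p <- ncol(x$adjacency)
  cat("Partial correlation network:", p, "nodes,",
      sum(x$adjacency[upper.tri(x$adjacency)] != 0), "edges",
      sprintf("(of %d possible)\n", p * (p - 1) / 2))
  cat("  AIC:", sprintf("%.2f -> %.2f", x$aic_trace[1],
                        x$aic_trace[length(x$aic_trace)]),
      "in", length(x$aic_trace) - 1, "accepted removals\n")
  invisible(x)
}

#' Item-level PCA on a partial correlation matrix
#'
#' Eigendecomposition of the (symmetric) partial correlation matrix; item
#' coordinates on each component are the eigenvector entries scaled by the
#' square root of the eigenvalue.
#'
#' @param pcor symmetric partial correlation matrix.
#' @param n_components components to return coordinates for.
#' @return list: `eigenvalues`, `variance_share`, `coordinates` (items x
#'   components).
#' @export
item_pca <- function(pcor, n_components = 2L) {
  pcor <- as.matrix(pcor)
  if (max(abs(pcor - t(pcor))) > 1e-8)
    stop_semscan("matrix must be symmetric", "semscan_input_error")
  e <- eigen((pcor + t(pcor)) / 2, symmetric = TRUE)
  k <- min(n_components, ncol(pcor))
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
  rownames(coords) <- colnames(pcor)
  colnames(coords) <- paste0("PC", seq_len(k))
  list(eigenvalues = e$values,
       variance_share = e$values / sum(abs(e$values)),
       coordinates = coords)
}

#' Cliques in the thresholded partial-correlation graph
#'
#' Diagnostic for multi-factor structure: maximal cliques (Bron-Kerbosch via
#' igraph) among edges whose fitted |partial correlation| exceeds `threshold`.
#' A dense clique of strong edges suggests an additional latent factor.
#'
#' @param network a `pcor_network` from [covariance_selection()].
#' @param threshold minimum |partial correlation| for an edge to count.
#' @param min_size smallest clique size reported.
#' @return list of integer vectors (node indices), possibly empty.
#' @export
find_cliques <- function(network, threshold = 0.2, min_size = 3L) {
  A <- (network$adjacency != 0) & (abs(network$pcor) > threshold)
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  cl <- igraph::max_cliques(g, min = min_size)
  lapply(cl, as.integer)
}
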