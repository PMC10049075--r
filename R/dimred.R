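#' Principal-component embedding of samples
#'
#' Scores of the top-k principal components of the z-transformed feature
#' matrix (samples as observations). Sign convention: the largest-magnitude
#' entry of each score vector is positive.
#'
#' @param ft \code{feature_table} in \code{z} state.
#' @param k number of components (2 or 3).
#' @return An \code{embedding}: \code{coordinates} (n_samples x k),
#'   \code{explained_variance}, \code{method = "pca"}.
#' @export
pca_embedding <- function(ft, k = 2L) {
  if (ft$transform_state != "z")
    stop("state error: embeddings expect a z-state table")
  X <- t(ft$abundances)
  if (k > min(dim(X)))
    stop("configuration error: k exceeds min(n_samples, n_features)")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  scores <- fix_signs(scores)
  ev <- sv$d^2 / sum(sv$d^2)
  structure(list(sample_ids = rownames(X), coordinates = scores,
                 method = "pca", explained_variance = ev[seq_len(k)]),
            class = "embedding")
}

fix_signs <- function(scores) {
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  scores
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding (%s): %d samples x %d components\n", x$method,
              nrow(x$coordinates), ncol(x$coordinates)))
  invisible(x)
}

#' t-SNE embedding of samples
#'
#' Exact (dense) t-distributed stochastic neighbor embedding: per-point
#' bandwidths calibrated to the target perplexity by binary search,
#' symmetrized affinities, and gradient descent with early exaggeration and
#' momentum on the Student-t low-dimensional kernel. Quadratic in the
#' number of samples, which is adequate for cohort-scale tables. The
#' output is a visualization: reproducible under a fixed seed, with no
#' geometric guarantees.
#'
#' @param ft \code{feature_table} in \code{z} state.
#' @param seed RNG seed for the initial coordinates.
#' @param perplexity effective neighbor count; requires
#'   \code{n_samples > 3 * perplexity}.
#' @param n_iter gradient-descent iterations.
#' @return An \code{embedding} with 2-D \code{coordinates}.
#' @export
tsne_embedding <- function(ft, seed = 1L, perplexity = 15, n_iter = 400L) {
  if (ft$transform_state != "z")
    stop("state error: embeddings expect a z-state table")
  X <- t(ft$abundances)
  n <- nrow(X)
  if (n <= 3 * perplexity)
    stop("configuration error: perplexity too large for ", n, " samples")
  P <- tsne_affinities(X, perplexity)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  Y <- tsne_descent(P, Y, n_iter = n_iter)
  structure(list(sample_ids = rownames(X), coordinates = Y,
                 method = "tsne", explained_variance = NULL),
            class = "embedding")
}

tsne_affinities <- function(X, perplexity, tol = 1e-5) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { h <- 0; p[] <- 0 } else {
        p <- p / sp
        h <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      diff <- h - target
      if (abs(diff) < tol) break
      if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

tsne_descent <- function(P, Y, n_iter = 400L, eta = 200,
                         exaggeration = 4, exag_iter = 100L) {
  n <- nrow(Y)
  V <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= exag_iter) P * exaggeration else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pe - Q) * num
    G <- 4 * (diag(rowSums(W)) - W) %*% Y
    mom <- if (it <= 250) 0.5 else 0.8
    gains <- ifelse(sign(G) != sign(V), gains + 0.2, gains * 0.8)
    gains <- pmax(gains, 0.01)
    V <- mom * V - eta * gains * G
    Y <- Y + V
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' PLS-DA embedding of samples
#'
#' Partial least squares discriminant analysis: labels are one-hot encoded
#' and PLS2 latent variables extracted so that each successive direction
#' maximizes the covariance between the projected features and projected
#' labels (SVD-of-crossproduct with deflation, NIPALS-equivalent).
#' Supervised, so group separation here is descriptive, not inferential —
#' cross-validated classification is the inferential criterion.
#'
#' @param ft \code{feature_table} in \code{z} state.
#' @param y class labels, one per sample; >= 2 classes.
#' @param k number of latent variables.
#' @return An \code{embedding} with scores, per-component explained
#'   X-variance fractions and the class labels.
#' @export
plsda_embedding <- function(ft, y, k = 2L) {
  if (ft$transform_state != "z")
    stop("state error: embeddings expect a z-state table")
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2)
    stop("configuration error: need >= 2 classes")
  X <- t(ft$abundances)
  if (length(y) != nrow(X))
    stop("schema error: one label per sample required")
  Y <- stats::model.matrix(~ y - 1)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  n <- nrow(Xc)
  scores <- matrix(0, n, k, dimnames = list(rownames(X), paste0("LV", 1:k)))
  totvar <- sum(Xc^2)
  expl <- numeric(k)
  Xd <- Xc
  for (comp in seq_len(k)) {
    sv <- svd(crossprod(Xd, Yc), nu = 1, nv = 1)
    w <- sv$u[, 1]
    t_sc <- Xd %*% w
    scores[, comp] <- t_sc
    p <- crossprod(Xd, t_sc) / sum(t_sc^2)
    expl[comp] <- sum((t_sc %*% t(p))^2) / totvar
    Xd <- Xd - t_sc %*% t(p)
  }
  scores <- fix_signs(scores)
  structure(list(sample_ids = rownames(X), coordinates = scores,
                 method = "plsda", explained_variance = expl, labels = y),
            class = "embedding")
}

#' 95\% confidence ellipse of a 2-D point cloud
#'
#' Ellipse from the sample mean and covariance, scaled by the chi-square
#' quantile with 2 degrees of freedom at the requested level — the standard
#' construction behind the per-group ellipses drawn on score plots.
#'
#' @param points numeric m x 2 matrix, m >= 3.
#' @param level confidence level; default 0.95.
#' @return A list: \code{center}, \code{covariance}, \code{radii}
#'   (semi-axis lengths), \code{orientation} (unit axis directions),
#'   \code{level}, and \code{contains(points)} membership helper data via
#'   \code{\link{ellipse_contains}}.
#' @export
confidence_ellipse <- function(points, level = 0.95) {
  points <- as.matrix(points)
  if (nrow(points) < 3)
    stop("degenerate error: need >= 3 points for an ellipse")
  stopifnot(ncol(points) == 2, level > 0, level < 1)
  ctr <- colMeans(points)
  S <- stats::cov(points)
  e <- eigen(S, symmetric = TRUE)
  q <- stats::qchisq(level, df = 2)
  structure(list(center = ctr, covariance = S,
                 radii = sqrt(pmax(e$values, 0) * q),
                 orientation = e$vectors, level = level,
                 chisq_quantile = q),
            class = "confidence_ellipse")
}

#' Test which points fall inside a confidence ellipse
#'
#' @param ellipse a \code{confidence_ellipse}.
#' @param points m x 2 coordinates.
#' @return Logical vector: Mahalanobis distance squared <= the ellipse's
#'   chi-square quantile.
#' @export
ellipse_contains <- function(ellipse, points) {
  d2 <- stats::mahalanobis(as.matrix(points), ellipse$center,
                           ellipse$covariance)
  d2 <= ellipse$chisq_quantile
}

#' Per-group confidence ellipses on an embedding
#'
#' @param emb an \code{embedding} (first two coordinates used).
#' @param groups group label per sample.
#' @param level confidence level.
#' @return Named list of \code{confidence_ellipse} objects (groups with
#'   < 3 samples are skipped).
#' @export
group_ellipses <- function(emb, groups, level = 0.95) {
  co <- emb$coordinates[, 1:2, drop = FALSE]
  out <- list()
  for (g in unique(stats::na.omit(groups))) {
    idx <- which(!is.na(groups) & groups == g)
    if (length(idx) >= 3)
      out[[as.character(g)]] <- confidence_ellipse(co[idx, , drop = FALSE],
                                                   level)
  }
  out
}
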