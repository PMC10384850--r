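# Six dimensionality-reduction techniques, each implemented from its
# mathematical definition with fit-on-train / project-out-of-sample
# semantics. Every fitted object is a list of class "dimred_model" with a
# `kind` field; `project()` dispatches on it.

# deterministic sign convention: flip each component so its
# largest-magnitude loading is positive
fix_signs <- function(V) {
  s <- apply(V, 2, function(v) sign(v[which.max(abs(v))]))
  s[s == 0] <- 1
  sweep(V, 2, s, "*")
}

new_dimred_model <- function(kind, target_dim, fields) {
  structure(c(list(kind = kind, target_dim = as.integer(target_dim)),
              fields),
            class = "dimred_model")
}

#' Fit principal component analysis
#'
#' Classical PCA: centre the columns and keep the top `d` eigenvectors of
#' the sample covariance (descending explained variance, orthonormal
#' components, deterministic sign convention).
#'
#' @param X Numeric n x p training matrix.
#' @param d Target dimensionality.
#' @return A `"dimred_model"` of kind `"pca"` with fields `center`,
#'   `components` (p x d), `explained_variance`.
#' @export
fit_pca <- function(X, d) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n >= 2)
  d <- assert_count(d, "d")
  r <- min(n - 1L, p)
  if (d > r) {
    warning(sprintf("d = %d exceeds the data rank bound %d; truncating", d, r),
            call. = FALSE)
    d <- r
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = 0, nv = d)
  comps <- fix_signs(sv$v[, seq_len(d), drop = FALSE])
  ev <- sv$d[seq_len(d)]^2 / (n - 1)
  new_dimred_model("pca", d, list(center = ctr, components = comps,
                                  explained_variance = ev,
                                  input_dim = p))
}

rbf_kernel <- function(A, B, gamma, ...) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

sigmoid_kernel <- function(A, B, gamma, coef0, ...) {
  tanh(gamma * tcrossprod(A, B) + coef0)
}

linear_kernel <- function(A, B, ...) tcrossprod(A, B)

#' Fit kernel PCA
#'
#' Eigendecomposition of the double-centred training kernel matrix; dual
#' coefficients are the eigenvectors scaled by 1/sqrt(eigenvalue), so a
#' projection is the centred kernel row of a point against the training
#' set times the coefficients. Kernels: `"rbf"` K(x,y) =
#' exp(-gamma ||x-y||^2), `"sigmoid"` K(x,y) = tanh(gamma <x,y> + c0),
#' plus a `"linear"` test hook that reproduces PCA scores. Defaults
#' gamma = 1/p, c0 = 1. If fewer than `d` positive eigenvalues exist the
#' available components are returned with a warning.
#'
#' @param X Training matrix.
#' @param d Target dimensionality.
#' @param kernel `"rbf"`, `"sigmoid"` or `"linear"`.
#' @param gamma,coef0 Kernel parameters.
#' @return A `"dimred_model"` of kind `"kpca_rbf"`, `"kpca_sigmoid"` or
#'   `"kpca_linear"`.
#' @export
fit_kpca <- function(X, d, kernel = c("rbf", "sigmoid", "linear"),
                     gamma = NULL, coef0 = 1) {
  X <- as.matrix(X)
  kernel <- match.arg(kernel)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n >= 2)
  d <- assert_count(d, "d")
  if (is.null(gamma)) gamma <- 1 / p
  kfun <- switch(kernel, rbf = rbf_kernel, sigmoid = sigmoid_kernel,
                 linear = linear_kernel)
  K <- kfun(X, X, gamma = gamma, coef0 = coef0)
  ones <- matrix(1 / n, n, n)
  Kc <- K - ones %*% K - K %*% ones + ones %*% K %*% ones
  eg <- eigen((Kc + t(Kc)) / 2, symmetric = TRUE)
  # absolute cutoff: a vanishing kernel (e.g. rbf with gamma -> 0) has no
  # usable components and should degrade with a warning, not noise-fit
  pos <- which(eg$values > 1e-10)
  if (length(pos) < d) {
    warning(sprintf(
      "only %d positive kernel eigenvalues available (requested %d)",
      length(pos), d), call. = FALSE)
  }
  keep <- pos[seq_len(min(d, length(pos)))]
  lambda <- eg$values[keep]
  V <- fix_signs(eg$vectors[, keep, drop = FALSE])
  alpha <- sweep(V, 2, sqrt(lambda), "/")
  new_dimred_model(paste0("kpca_", kernel), length(keep),
                   list(X_train = X, kernel = kernel, gamma = gamma,
                        coef0 = coef0, alpha = alpha, lambda = lambda,
                        K_train = K, K_colmeans = colMeans(K),
                        K_mean = mean(K), input_dim = p))
}

#' Fit FastICA
#'
#' PCA-whitening to `d` dimensions followed by the parallel (symmetric)
#' fixed-point iteration with the logcosh contrast g(u) = tanh(u) and
#' symmetric decorrelation W <- (W W')^{-1/2} W, iterated until the
#' largest change in any component direction falls below `tol` or
#' `max_iter` is reached (non-convergence warns, not fails). With
#' `whiten_variant = "unit"` recovered components are rescaled to unit
#' sample variance; `"arbitrary"` leaves the whitened-scale components
#' as produced.
#'
#' @param X Training matrix.
#' @param d Number of independent components.
#' @param whiten_variant `"arbitrary"` (default) or `"unit"`.
#' @param max_iter Maximum fixed-point iterations (default 200).
#' @param tol Convergence tolerance (default 1e-4).
#' @param seed Seed for the random orthogonal initialisation.
#' @return A `"dimred_model"` of kind `"ica"` with the composite
#'   unmixing matrix in `unmixing` (d x p).
#' @export
fit_fastica <- function(X, d, whiten_variant = c("arbitrary", "unit"),
                        max_iter = 200L, tol = 1e-4, seed = 1L) {
  X <- as.matrix(X)
  whiten_variant <- match.arg(whiten_variant)
  n <- nrow(X); p <- ncol(X)
  d <- assert_count(d, "d")
  max_iter <- assert_count(max_iter, "max_iter")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = 0, nv = min(n - 1L, p))
  r <- sum(sv$d > 1e-10 * sv$d[1])
  if (d > r) stop(sprintf("d = %d exceeds data rank %d", d, r), call. = FALSE)
  # whitening matrix: rows of K map centred data to unit-variance PCs
  # population-variance whitening (unit variance with 1/n normalisation)
  K <- t(sv$v[, seq_len(d), drop = FALSE]) * sqrt(n) / sv$d[seq_len(d)]
  Z <- Xc %*% t(K)  # n x d, identity covariance
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)),
                       nrow = length(e$values)) %*%
      t(e$vectors) %*% W
  }
  W <- with_seed(seed, matrix(rnorm(d * d), d, d))
  W <- sym_decorrelate(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    U <- Z %*% t(W)           # n x d current sources
    G <- tanh(U)
    Gp <- 1 - G^2
    W_new <- crossprod(G, Z) / n - diag(colMeans(Gp), d) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("FastICA did not converge in %d iterations", max_iter),
            call. = FALSE)
  }
  unmix <- W %*% K  # d x p composite unmixing on centred data
  scale_sd <- rep(1, d)
  if (whiten_variant == "unit") {
    S <- Xc %*% t(unmix)
    scale_sd <- sqrt(colMeans(S^2) - colMeans(S)^2)  # population sd
  }
  new_dimred_model("ica", d,
                   list(center = ctr, unmixing = unmix,
                        whitening = K, W_rot = W,
                        whiten_variant = whiten_variant,
                        scale_sd = scale_sd, converged = converged,
                        n_iter = it, input_dim = p))
}

# k nearest neighbours of each row of A among rows of B (excluding exact
# self-index when `exclude_self`); ties broken by index order.
knn_index <- function(A, B, k, exclude_self = FALSE) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2 <- pmax(d2, 0)
  t(vapply(seq_len(nrow(A)), function(i) {
    o <- order(d2[i, ], seq_len(ncol(d2)))
    if (exclude_self) o <- o[o != i]
    o[seq_len(k)]
  }, integer(k)))
}

lle_weights <- function(x, neigh, reg) {
  Z <- sweep(neigh, 2, x)          # k x p differences
  C <- tcrossprod(Z)
  tr <- sum(diag(C))
  C <- C + diag(reg * (if (tr > 0) tr else 1), nrow(C))
  w <- solve(C, rep(1, nrow(C)))
  w / sum(w)
}

#' Fit locally linear embedding
#'
#' For each training point, barycentric reconstruction weights over its
#' `n_neighbors` Euclidean nearest neighbours are solved from the local
#' Gram matrix regularised by `reg * trace`, then normalised to sum to
#' one. The embedding is the bottom `d + 1` eigenvectors of
#' (I - W)'(I - W) with the constant eigenvector discarded. Out-of-sample
#' points are embedded as the weight-combination of their nearest
#' training points' embeddings.
#'
#' @param X Training matrix.
#' @param d Target dimensionality.
#' @param n_neighbors Neighbourhood size (must be < n).
#' @param reg Regularisation constant (default 1e-3).
#' @return A `"dimred_model"` of kind `"lle"`.
#' @export
fit_lle <- function(X, d, n_neighbors = 5L, reg = 1e-3) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- assert_count(d, "d")
  n_neighbors <- assert_count(n_neighbors, "n_neighbors")
  if (n_neighbors >= n) stop("n_neighbors must be smaller than n", call. = FALSE)
  if (reg <= 0) stop("reg must be positive", call. = FALSE)
  nbr <- knn_index(X, X, n_neighbors, exclude_self = TRUE)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    W[i, nbr[i, ]] <- lle_weights(X[i, ], X[nbr[i, ], , drop = FALSE], reg)
  }
  M <- crossprod(diag(n) - W)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  idx <- order(eg$values)[seq_len(d + 1L)]  # ascending; drop constant
  idx <- idx[-1L]
  Y <- fix_signs(eg$vectors[, idx, drop = FALSE])
  new_dimred_model("lle", d,
                   list(X_train = X, embedding = Y,
                        n_neighbors = n_neighbors, reg = reg,
                        bottom_eigenvalues = eg$values[order(eg$values)[seq_len(d + 1L)]],
                        input_dim = ncol(X)))
}

# iterative orthogonal-subspace (block power) eigensolver for the top-d
# eigenpairs of a symmetric matrix; `max_iter` caps the iterations, as
# iterative solvers expose. Deterministic start from the leading columns.
eigs_sym_iterative <- function(A, d, max_iter = 200L, tol = 1e-10) {
  n <- nrow(A)
  Q <- qr.Q(qr(A[, seq_len(d), drop = FALSE] +
                 diag(1e-8, n)[, seq_len(d), drop = FALSE]))
  vals_old <- rep(Inf, d)
  for (it in seq_len(max_iter)) {
    Z <- A %*% Q
    Q <- qr.Q(qr(Z))
    T_ <- crossprod(Q, A %*% Q)
    eg <- eigen((T_ + t(T_)) / 2, symmetric = TRUE)
    vals <- eg$values
    Q <- Q %*% eg$vectors
    if (max(abs(vals - vals_old)) < tol * max(abs(vals), 1)) break
    vals_old <- vals
  }
  list(values = vals, vectors = Q)
}

#' Fit isomap
#'
#' Builds the symmetrised k-nearest-neighbour graph with Euclidean edge
#' weights, computes all-pairs geodesic (shortest-path) distances, and
#' embeds by classical MDS: the top `d` eigenpairs of the double-centred
#' matrix -D^2/2, with coordinates eigenvector * sqrt(eigenvalue).
#' Out-of-sample points enter the graph through their `n_neighbors`
#' nearest training points (geodesic = min over neighbours of edge +
#' stored geodesic) and are placed by the Nystrom projection formula.
#'
#' @param X Training matrix.
#' @param d Target dimensionality.
#' @param n_neighbors Neighbourhood size for the graph.
#' @param eigen_solver `"lapack"` (dense `eigen`), `"arnoldi"` (the
#'   package's iterative subspace solver, capped at `max_iter`
#'   iterations) or `"auto"` (lapack below 500 points, else arnoldi).
#' @param max_iter Iteration cap for the iterative solver.
#' @return A `"dimred_model"` of kind `"isomap"`.
#' @export
fit_isomap <- function(X, d, n_neighbors = 5L,
                       eigen_solver = c("auto", "lapack", "arnoldi"),
                       max_iter = 200L) {
  X <- as.matrix(X)
  eigen_solver <- match.arg(eigen_solver)
  n <- nrow(X)
  d <- assert_count(d, "d")
  n_neighbors <- assert_count(n_neighbors, "n_neighbors")
  if (n_neighbors >= n) stop("n_neighbors must be smaller than n", call. = FALSE)
  nbr <- knn_index(X, X, n_neighbors, exclude_self = TRUE)
  edges <- cbind(rep(seq_len(n), each = n_neighbors), as.vector(t(nbr)))
  w <- sqrt(rowSums((X[edges[, 1], , drop = FALSE] -
                       X[edges[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = w)
  g <- igraph::simplify(g, edge.attr.comb = "min")
  comp <- igraph::components(g)
  if (comp$no > 1) {
    stop(sprintf(
      "k-nearest-neighbour graph is disconnected (component sizes: %s); increase n_neighbors",
      paste(comp$csize, collapse = ", ")), call. = FALSE)
  }
  D <- igraph::distances(g, algorithm = "dijkstra")
  D2 <- D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  B <- (B + t(B)) / 2
  if (eigen_solver == "auto") {
    eigen_solver <- if (n < 500) "lapack" else "arnoldi"
  }
  if (eigen_solver == "lapack") {
    eg <- eigen(B, symmetric = TRUE)
    vals <- eg$values[seq_len(d)]
    vecs <- eg$vectors[, seq_len(d), drop = FALSE]
  } else {
    eg <- eigs_sym_iterative(B, d, max_iter = max_iter)
    vals <- eg$values
    vecs <- eg$vectors
  }
  pos <- vals > 1e-10 * max(abs(vals))
  if (!all(pos)) {
    warning(sprintf("only %d positive geodesic-MDS eigenvalues (requested %d)",
                    sum(pos), d), call. = FALSE)
    vals <- vals[pos]; vecs <- vecs[, pos, drop = FALSE]
  }
  vecs <- fix_signs(vecs)
  Y <- sweep(vecs, 2, sqrt(vals), "*")
  new_dimred_model("isomap", length(vals),
                   list(X_train = X, embedding = Y, eigenvalues = vals,
                        eigenvectors = vecs, geodesics = D,
                        D2_colmeans = colMeans(D2),
                        n_neighbors = n_neighbors,
                        eigen_solver = eigen_solver,
                        input_dim = ncol(X)))
}

#' Geometric autoencoder layer sizing
#'
#' Layer sizes form a geometric series from the input dimension `D` down
#' to the latent (bottleneck) size `L` in `steps` steps and back up
#' symmetrically, every interior size rounded to the nearest whole
#' number: `[D, round(L r^(s-1)), ..., L, ..., round(L r^(s-1)), D]`
#' with common ratio `r = (D/L)^(1/s)`. One step gives the simplest
#' 3-layer autoencoder; five steps give 11 layers.
#'
#' @param D Input dimensionality (first and last layer size).
#' @param L Latent (bottleneck) size, `1 <= L < D`.
#' @param steps Number of layers between input and bottleneck.
#' @return An `"ae_architecture"`: list with `layer_sizes`,
#'   `steps_to_bottleneck`, `common_ratio`.
#' @export
ae_architecture <- function(D, L, steps) {
  D <- assert_count(D, "D"); L <- assert_count(L, "L")
  steps <- assert_count(steps, "steps")
  if (L >= D) stop("latent size must be smaller than input size", call. = FALSE)
  r <- (D / L)^(1 / steps)
  interior <- round(L * r^(seq_len(steps - 1L)))  # between bottleneck and D
  encoder <- c(D, rev(interior), L)
  sizes <- c(encoder, rev(encoder)[-1L])
  if (any(diff(sizes[seq_len(steps + 1L)]) >= 0)) {
    stop("rounded layer sizes are not strictly decreasing to the bottleneck",
         call. = FALSE)
  }
  structure(list(layer_sizes = sizes, steps_to_bottleneck = steps,
                 common_ratio = r),
            class = "ae_architecture")
}

#' Train an autoencoder reducer
#'
#' Feed-forward autoencoder with sigmoid activations in encoder neurons
#' and ReLU in decoder neurons, trained with Adam on mean squared
#' reconstruction error, shuffling the data between epochs. The fitted
#' model keeps only the encoder; projection is the bottleneck activation.
#'
#' @param X Training matrix (columns = `arch` input size).
#' @param arch An [ae_architecture()].
#' @param epochs Training epochs.
#' @param seed Seed (weight initialisation + shuffling).
#' @param batch_size,lr Adam minibatch size and learning rate.
#' @return A `"dimred_model"` of kind `"ae"`.
#' @export
ae_train <- function(X, arch, epochs, seed = 1L, batch_size = 32L,
                     lr = 1e-3) {
  stopifnot(inherits(arch, "ae_architecture"))
  X <- as.matrix(X)
  sizes <- arch$layer_sizes
  if (ncol(X) != sizes[1]) {
    stop("input dimension does not match the architecture", call. = FALSE)
  }
  epochs <- assert_count(epochs, "epochs")
  s <- arch$steps_to_bottleneck
  activations <- c(rep("sigmoid", s), rep("relu", s))
  net <- nn_init(sizes, activations, seed = seed)
  net <- nn_train(net, X, X, loss = "mse", epochs = epochs,
                  batch_size = batch_size, lr = lr, seed = seed,
                  trace_loss = TRUE)
  L <- sizes[s + 1L]
  new_dimred_model("ae", L,
                   list(net = net, encoder_layers = s,
                        arch = arch, loss_trace = net$loss_trace,
                        input_dim = sizes[1]))
}

#' Project data through a fitted dimensionality-reduction model
#'
#' Technique-appropriate out-of-sample mapping: centred rotation for PCA
#' and ICA; centred kernel row against the training set for kernel PCA;
#' encoder forward pass for the autoencoder; reconstruction-weight
#' combination of training embeddings for LLE; geodesic Nystrom formula
#' for isomap. Projecting the training matrix reproduces the fitted
#' embedding (exactly for pca/ica/ae and isomap, to numerical tolerance
#' for kpca, approximately for lle).
#'
#' @param model A `"dimred_model"`.
#' @param X Matrix with the model's fitted input dimension.
#' @return An `nrow(X)` x `target_dim` score matrix.
#' @export
project <- function(model, X) {
  stopifnot(inherits(model, "dimred_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$input_dim) {
    stop(sprintf("input has %d columns but the model was fitted on %d",
                 ncol(X), model$input_dim), call. = FALSE)
  }
  switch(sub("_.*", "", model$kind),
    pca = sweep(X, 2, model$center) %*% model$components,
    kpca = {
      kfun <- switch(model$kernel, rbf = rbf_kernel,
                     sigmoid = sigmoid_kernel, linear = linear_kernel)
      Kx <- kfun(X, model$X_train, gamma = model$gamma,
                 coef0 = model$coef0)
      n <- nrow(model$X_train)
      Kc <- Kx - matrix(rowMeans(Kx), nrow(Kx), n) -
        matrix(model$K_colmeans, nrow(Kx), n, byrow = TRUE) + model$K_mean
      Kc %*% model$alpha
    },
    ica = {
      S <- sweep(X, 2, model$center) %*% t(model$unmixing)
      sweep(S, 2, model$scale_sd, "/")
    },
    ae = {
      nn_forward(model$net, X, upto = model$encoder_layers)$out
    },
    lle = {
      k <- min(model$n_neighbors, nrow(model$X_train))
      nbr <- knn_index(X, model$X_train, k)
      out <- matrix(0, nrow(X), ncol(model$embedding))
      for (i in seq_len(nrow(X))) {
        w <- lle_weights(X[i, ], model$X_train[nbr[i, ], , drop = FALSE],
                         model$reg)
        out[i, ] <- w %*% model$embedding[nbr[i, ], , drop = FALSE]
      }
      out
    },
    isomap = {
      k <- min(model$n_neighbors, nrow(model$X_train))
      nbr <- knn_index(X, model$X_train, k)
      n <- nrow(model$X_train)
      out <- matrix(0, nrow(X), length(model$eigenvalues))
      for (i in seq_len(nrow(X))) {
        edge <- sqrt(colSums((t(model$X_train[nbr[i, ], , drop = FALSE]) -
                                X[i, ])^2))
        dgeo <- apply(model$geodesics[nbr[i, ], , drop = FALSE] + edge,
                      2, min)
        kc <- 0.5 * (model$D2_colmeans - dgeo^2)
        out[i, ] <- (kc %*% model$eigenvectors) / sqrt(model$eigenvalues)
      }
      out
    },
    stop("unknown model kind: ", model$kind, call. = FALSE))
}

#' Registry of reducer constructors by kind string
#'
#' Maps the seven benchmark kinds (`pca`, `kpca_rbf`, `kpca_sigmoid`,
#' `ica`, `ae`, `lle`, `isomap`) to fitting closures with a uniform
#' `(X, d, seed)` signature; technique hyperparameters are bound at
#' lookup. Neighbour counts and latent sizes beyond what the training
#' data supports are clamped with a warning.
#'
#' @param kind Kind string.
#' @param hyper Named list of technique hyperparameters (see the fit
#'   functions); missing entries fall back to the benchmark defaults
#'   (the grid-search optima at full scale).
#' @return A function `(X, d, seed)` returning a `"dimred_model"`.
#' @export
reducer <- function(kind, hyper = list()) {
  defaults <- reducer_defaults()[[kind]]
  if (is.null(defaults)) stop("unknown technique kind: ", kind, call. = FALSE)
  h <- utils::modifyList(defaults, hyper)
  force(kind)
  function(X, d, seed = 1L) {
    n <- nrow(X)
    clamp_k <- function(k) {
      if (k >= n) {
        warning(sprintf("n_neighbors = %d clamped to %d (training size %d)",
                        k, n - 1L, n), call. = FALSE)
        n - 1L
      } else k
    }
    switch(kind,
      pca = fit_pca(X, d),
      kpca_rbf = fit_kpca(X, d, kernel = "rbf", gamma = h$gamma),
      kpca_sigmoid = fit_kpca(X, d, kernel = "sigmoid", gamma = h$gamma,
                              coef0 = h$coef0),
      ica = fit_fastica(X, d, whiten_variant = h$whiten_variant,
                        max_iter = h$max_iter, seed = seed),
      ae = ae_train(X, ae_architecture(ncol(X), d, h$steps),
                    epochs = h$epochs, seed = seed,
                    batch_size = h$batch_size, lr = h$lr),
      lle = fit_lle(X, d, n_neighbors = clamp_k(h$n_neighbors),
                    reg = h$reg),
      isomap = fit_isomap(X, d, n_neighbors = clamp_k(h$n_neighbors),
                          eigen_solver = h$eigen_solver,
                          max_iter = h$max_iter))
  }
}

#' @rdname reducer
#' @export
reducer_defaults <- function() {
  list(
    pca = list(),
    kpca_rbf = list(gamma = NULL),
    kpca_sigmoid = list(gamma = NULL, coef0 = 1),
    # grid-search optima at full scale: arbitrary variance, 800 iterations
    ica = list(whiten_variant = "arbitrary", max_iter = 800L),
    # 320 epochs, one step to the bottleneck
    ae = list(epochs = 320L, steps = 1L, batch_size = 32L, lr = 1e-3),
    # regularisation 1e-6, 115 neighbours (clamped on small data)
    lle = list(reg = 1e-6, n_neighbors = 115L),
    # 65 neighbours, auto solver
    isomap = list(n_neighbors = 65L, eigen_solver = "auto",
                  max_iter = 200L))
}

#' @export
print.dimred_model <- function(x, ...) {
  cat(sprintf("<dimred_model %s, target_dim = %d, input_dim = %d>\n",
              x$kind, x$target_dim, x$input_dim))
  invisible(x)
}
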