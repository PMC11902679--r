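#' Kernel matrix of a feature set
#'
#' Encodes pairwise sample similarity as a symmetric positive semi-definite
#' matrix: the Gram matrix for the linear kernel, or
#' \code{exp(-||xi - xj||^2 / (2 sigma^2))} for the radial basis function
#' kernel (bandwidth defaulting to the median pairwise distance).
#'
#' @param features numeric n x d matrix (rows = samples), finite, n >= 2.
#' @param kind \code{"linear"} or \code{"rbf"}.
#' @param bandwidth RBF bandwidth sigma; default median pairwise distance.
#' @return object of class \code{kernel_matrix}: list with \code{values}
#'   (n x n), \code{kind}, \code{bandwidth}.
#' @export
compute_kernel <- function(features, kind = c("linear", "rbf"),
                           bandwidth = NULL) {
  kind <- match.arg(kind)
  x <- as.matrix(features)
  if (!all(is.finite(x))) stop("features must be finite")
  if (nrow(x) < 2) stop("need at least 2 samples")
  if (kind == "linear") {
    values <- tcrossprod(x)
  } else {
    d2 <- as.matrix(stats::dist(x))^2
    if (is.null(bandwidth)) {
      pos <- d2[upper.tri(d2)]
      bandwidth <- sqrt(stats::median(pos[pos > 0]))
      if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1
    }
    values <- exp(-d2 / (2 * bandwidth^2))
  }
  values <- (values + t(values)) / 2
  dimnames(values) <- NULL
  structure(list(values = values, kind = kind, bandwidth = bandwidth),
            class = "kernel_matrix")
}

.kernel_values <- function(K) {
  if (inherits(K, "kernel_matrix")) K$values else as.matrix(K)
}

#' Center a kernel matrix
#'
#' Double centering \code{H K H} with \code{H = I - (1/n) 11'}, so that the
#' row and column sums of the result vanish. Idempotent.
#'
#' @param K a \code{\link{compute_kernel}} result or a plain square matrix.
#' @return centered matrix of the same class as the input.
#' @export
center_kernel <- function(K) {
  V <- .kernel_values(K)
  stopifnot(nrow(V) == ncol(V))
  rm_ <- rowMeans(V)
  cm_ <- colMeans(V)
  centered <- V - outer(rm_, rep(1, ncol(V))) -
    outer(rep(1, nrow(V)), cm_) + mean(V)
  if (inherits(K, "kernel_matrix")) {
    K$values <- centered
    K
  } else centered
}

#' Empirical Centered Kernel Alignment
#'
#' The normalized Frobenius inner product of two centered kernel matrices,
#' \deqn{\rho(K_a, K_b) = \frac{\langle \bar K_a, \bar K_b \rangle_F}
#'   {\|\bar K_a\|_F \, \|\bar K_b\|_F},}
#' a symmetric similarity in \code{[0, 1]} between two representations of the
#' same samples; invariant to orthogonal rotation and isotropic scaling of
#' the features under the linear kernel.
#'
#' @param Ka,Kb kernel matrices (\code{\link{compute_kernel}} results or plain
#'   square matrices) of equal size.
#' @return alignment in \code{[0, 1]}.
#' @export
cka <- function(Ka, Kb) {
  A <- center_kernel(.kernel_values(Ka))
  B <- center_kernel(.kernel_values(Kb))
  if (!all(dim(A) == dim(B))) stop("kernel dimensions differ")
  na <- sqrt(sum(A * A))
  nb <- sqrt(sum(B * B))
  if (na < 1e-12 || nb < 1e-12)
    stop("alignment undefined: a centered kernel is identically zero ",
         "(constant features)")
  val <- sum(A * B) / (na * nb)
  min(max(val, 0), 1)
}

#' CKA alignment loss and its gradient with respect to the features
#'
#' For a feature matrix \code{X} under the linear kernel and a fixed target
#' kernel \code{Ky}, computes \code{1 - cka(XX', Ky)} and its analytic
#' gradient in \code{X}, used as a differentiable supervision term on the
#' autoencoder bottleneck. Writing \code{B} for the centered target kernel
#' and \code{A = H XX' H}, the alignment is \code{tr(XX' B) / (||A|| ||B||)}
#' and its gradient is
#' \code{2 B X / (||A|| ||B||) - 2 tr(XX' B) A X / (||A||^3 ||B||)}.
#'
#' @param X n x d feature matrix.
#' @param Ky fixed n x n target kernel (matrix or \code{kernel_matrix}).
#' @return list with \code{loss} (scalar \code{1 - rho}), \code{cka}
#'   (the alignment) and \code{grad} (n x d gradient of the loss).
#' @export
cka_loss_grad <- function(X, Ky) {
  X <- as.matrix(X)
  B <- center_kernel(.kernel_values(Ky))
  Kx <- tcrossprod(X)
  A <- center_kernel(Kx)
  na <- sqrt(sum(A * A))
  nb <- sqrt(sum(B * B))
  if (na < 1e-12 || nb < 1e-12)
    stop("alignment undefined: a centered kernel is identically zero")
  hsic <- sum(Kx * B)                 # = <A, B> since B is centered
  rho <- hsic / (na * nb)
  grad_rho <- 2 * (B %*% X) / (na * nb) -
    2 * hsic * (A %*% X) / (na^3 * nb)
  list(loss = 1 - rho, cka = rho, grad = -grad_rho)
}
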