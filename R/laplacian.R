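# Spherical-spline surface Laplacian (Perrin-style current source density).
#
# Potentials measured at unit-sphere electrode sites are interpolated with
# spherical splines of order m; the surface Laplacian of the spline is then
# evaluated at the electrode sites. Both kernels are Legendre expansions:
#   g(x) = sum_n (2n+1) / (n (n+1))^m     P_n(x) / (4 pi)
#   h(x) = -sum_n (2n+1) / (n (n+1))^(m-1) P_n(x) / (4 pi)
# The interpolation weights c solve (G + lambda I) c + c0 = v with
# sum(c) = 0; the Laplacian at the sites is H c. Everything is linear in
# v, so a single n x n transform matrix is precomputed per montage.

legendre_sum <- function(x, n_terms, coef) {
  p_prev <- matrix(1, nrow(x), ncol(x)) # P_0
  p_cur <- x                            # P_1
  acc <- coef(1) * p_cur
  for (n in 2:n_terms) {
    p_next <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
    acc <- acc + coef(n) * p_next
    p_prev <- p_cur
    p_cur <- p_next
  }
  acc
}

#' Precompute the spherical-spline surface Laplacian transform
#'
#' @param montage `fg_montage` (only scalp channels are used).
#' @param m spline stiffness order (4 = the common default).
#' @param lambda ridge regularization added to the spline system.
#' @param n_terms number of Legendre terms in the kernel expansions.
#' @return list with the transform matrix `L` (apply as `L %*% v`), the
#'   scalp `labels`, and the parameters. Output units are potential per
#'   squared head radius (micro-V/r^2 for micro-V input on a unit sphere).
#' @export
laplacian_transform <- function(montage, m = 4, lambda = 1e-5, n_terms = 50) {
  sc <- montage[montage$type == "scalp", ]
  fg_assert(nrow(sc) >= 16, "input",
            "need >= 16 scalp channels for the spherical spline")
  xyz <- as.matrix(sc[, c("x", "y", "z")])
  fg_assert(all(abs(sqrt(rowSums(xyz^2)) - 1) < 1e-6), "input",
            "scalp coordinates must lie on the unit sphere")
  cosang <- tcrossprod(xyz)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  dup <- which(cosang > 1 - 1e-10 & upper.tri(cosang), arr.ind = TRUE)
  if (nrow(dup) > 0) {
    fg_stop("geometry", "duplicate electrode positions: %s / %s",
            sc$label[dup[1, 1]], sc$label[dup[1, 2]])
  }
  G <- legendre_sum(cosang, n_terms,
                    function(n) (2 * n + 1) / (n * (n + 1))^m) / (4 * pi)
  H <- -legendre_sum(cosang, n_terms,
                     function(n) (2 * n + 1) / (n * (n + 1))^(m - 1)) / (4 * pi)
  n <- nrow(G)
  A <- rbind(cbind(G + lambda * diag(n), rep(1, n)), c(rep(1, n), 0))
  Ainv <- solve(A)
  L <- H %*% Ainv[seq_len(n), seq_len(n)]
  list(L = L, labels = sc$label, m = m, lambda = lambda, n_terms = n_terms)
}

#' Apply the spherical-spline surface Laplacian
#'
#' Reference-free by construction: adding any constant across channels
#' leaves the output unchanged, and a spatially constant potential maps to
#' zero everywhere.
#'
#' @param x numeric matrix channels x samples (rows in the order of
#'   `transform$labels`), or a 3-d array trials x channels x samples.
#' @param transform result of [laplacian_transform()].
#' @return object of the same shape in Laplacian units.
#' @export
spline_laplacian <- function(x, transform) {
  L <- transform$L
  if (is.matrix(x)) {
    fg_assert(nrow(x) == nrow(L), "input",
              "x has %d rows, transform expects %d", nrow(x), nrow(L))
    return(L %*% x)
  }
  if (length(dim(x)) == 3) {
    fg_assert(dim(x)[2] == nrow(L), "input",
              "x has %d channels, transform expects %d", dim(x)[2], nrow(L))
    out <- x
    for (i in seq_len(dim(x)[1])) out[i, , ] <- L %*% x[i, , ]
    return(out)
  }
  fg_stop("input", "x must be a channels x samples matrix or 3-d array")
}
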