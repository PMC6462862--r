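# Lawson-Hanson active-set non-negative least squares:
# minimise ||A x - b||_2 subject to x >= 0.
# Small dense problems only (96 x S here), so the unconstrained subproblems
# are solved by QR each pass.
nnls_solve <- function(A, b, tol = 1e-9, max_iter = 10 * ncol(A)) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      z[passive][is.na(z[passive])] <- 0
      if (all(z[passive] > tol)) {
        x <- z
        break
      }
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}
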