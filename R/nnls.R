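# Lawson-Hanson active-set non-negative least squares:
#   minimise || A x - b ||^2  subject to  x >= 0.
# Small dense problems only (detector refits, per-state rate fits).
nnls_fit <- function(A, b, tol = NULL) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- crossprod(A, b - A %*% x)
  tol <- tol %||% (10 * .Machine$double.eps * max(svd(A, nu = 0, nv = 0)$d) *
                     max(dim(A)))
  iter <- 0
  while (any(!passive) && max(w[!passive]) > tol && iter < 30 * n) {
    iter <- iter + 1
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      s <- numeric(n)
      s[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      s[P][is.na(s[P])] <- 0
      if (all(s[P] > tol)) break
      neg <- P[s[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
    }
    x <- s
    w <- crossprod(A, b - A %*% x)
  }
  as.numeric(x)
}
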