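# Independent oracles and small fixture builders shared across tests.

# Brute-force 2D convolution with zero padding: quadruple loop, written
# without reference to the package implementation.
brute_convolve <- function(A, kg) {
  K <- nrow(kg)
  h <- (K - 1) / 2
  nr <- nrow(A); nc <- ncol(A)
  D <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    acc <- 0
    for (i in seq_len(K)) for (j in seq_len(K)) {
      # true convolution: D[r,c] = sum_u k[u] * A[r - u_r, c - u_c]
      sr <- r - (i - (h + 1))
      sc <- cc - (j - (h + 1))
      if (sr >= 1 && sr <= nr && sc >= 1 && sc <= nc)
        acc <- acc + kg[i, j] * A[sr, sc]
    }
    D[r, cc] <- acc
  }
  D
}

# quick planar image / mask builders
img_of <- function(m, view = "anterior", duration_s = 1)
  planar_image(as.matrix(m), view = view, duration_s = duration_s)

mask_of <- function(m, label = "roi") organ_mask(as.matrix(m), label = label)

r_squared <- function(y, yhat) 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
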