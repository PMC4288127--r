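# shared small objects, built once per test run

fixture_dataset <- make_fixtures(seed = 42)     # 2 subjects x 4 directions

fixture_units <- lapply(fixture_dataset$trials, preprocess_trial)

fixture_decomp_pca <- lapply(fixture_units, decompose_trial, flavor = "pca")

# a standardized random channel matrix with a fixed seed
random_channels <- function(p = 7, n = 500, seed = 1) {
  set.seed(seed)
  matrix(rnorm(p * n), p, n, dimnames = list(emg_muscles()[seq_len(p)], NULL))
}

# minimal decomposition stand-in for pooling tests
fake_decomp <- function(id, loadings, flavor = "pca") {
  structure(list(loadings = loadings, flavor = flavor, trial_id = id,
                 condition = NULL),
            class = "emg_decomp")
}

# independent PCA oracle: SVD of the standardized matrix
pca_oracle <- function(x) {
  n <- ncol(x)
  z <- (x - rowMeans(x)) / sqrt(rowSums((x - rowMeans(x))^2) / n)
  sv <- svd(z / sqrt(n))
  lambda <- sv$d^2
  V <- sv$u
  flip <- apply(V * rep(sqrt(lambda), each = nrow(V)), 2,
                function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  list(eigenvalues = lambda,
       loadings = sweep(V * rep(sqrt(lambda), each = nrow(V)), 2, flip, "*"))
}

normalize_rows <- function(L) L / sqrt(rowSums(L^2))

random_orthogonal3 <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  q * sign(det(q))
}

# a hand-built clustering result for exercising the conflict rule
conflict_fixture <- function(labels, d_shared = NULL) {
  C <- rbind(c(10, 0, 0, 0, 0, 0, 0), c(0, 10, 0, 0, 0, 0, 0),
             c(0, 0, 10, 0, 0, 0, 0))
  X <- C[labels, , drop = FALSE]
  if (!is.null(d_shared))            # push vectors away from their centroid
    for (i in seq_along(d_shared)) X[i, 4] <- d_shared[i]
  km <- list(labels = labels, vectors = X, centroids = C,
             distances = sqrt(rowSums((X - C[labels, , drop = FALSE])^2)))
  prov <- data.frame(trial_id = "t1", rank = seq_along(labels),
                     flavor = "pca", stringsAsFactors = FALSE)
  list(km = km, prov = prov)
}

local_test_dir <- function() {
  d <- tempfile("emgsyn")
  dir.create(d)
  d
}

dominant_freq <- function(x, rate_hz) {
  x <- x - mean(x)
  spec <- Mod(fft(x))[seq_len(floor(length(x) / 2))]
  freqs <- (seq_along(spec) - 1) * rate_hz / length(x)
  freqs[which.max(spec[-1]) + 1]
}
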