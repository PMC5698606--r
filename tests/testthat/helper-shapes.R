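# geometric fixtures, built in code

disk_mask <- function(r, n = 2 * r + 11) {
  ctr <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
}

# solid ellipse with semi-axes a (x) and b (y), rotated by phi
ellipse_mask <- function(a, b, n = 100, phi = 0) {
  ctr <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(i, j) {
    x <- j - ctr; y <- i - ctr
    u <- cos(phi) * x + sin(phi) * y
    v <- -sin(phi) * x + cos(phi) * y
    (u / a)^2 + (v / b)^2 <= 1
  })
}

rect_mask <- function(h, w, n = max(h, w) + 20) {
  m <- matrix(FALSE, n, n)
  r0 <- (n - h) %/% 2; c0 <- (n - w) %/% 2
  m[r0 + seq_len(h), c0 + seq_len(w)] <- TRUE
  m
}

random_blob <- function(seed, aspect = c(1.15, 1.6), eps = c(0, 0.06),
                        harmonics = c(2, 4), area = c(700, 1600)) {
  # pi-symmetric blobs (even harmonics): principal axis defined modulo pi,
  # so alignment equivariance is testable under arbitrary rotations
  set.seed(seed)
  asp <- runif(1, aspect[1], aspect[2])
  ar <- runif(1, area[1], area[2])
  b <- sqrt(ar / (pi * asp))
  mod <- nucleus_model("normal", a = asp * b, b = b,
                       eps = runif(1, eps[1], eps[2]),
                       harmonics = harmonics,
                       phi = runif(1, -pi / 2, pi / 2))
  list(model = mod, mask = generate_mask(mod, seed = seed + 1000)$mask)
}

# feature table with planted signal columns: first n_signal columns carry
# a class effect, the rest are pure noise
signal_table <- function(n_per_class, n_signal, n_noise, effect, seed) {
  set.seed(seed)
  lab <- rep(c("normal", "HCC"), each = n_per_class)
  z <- ifelse(lab == "HCC", effect, 0)
  X <- cbind(
    if (n_signal > 0) sapply(seq_len(n_signal),
                             function(i) z + rnorm(2 * n_per_class)),
    if (n_noise > 0) sapply(seq_len(n_noise),
                            function(i) rnorm(2 * n_per_class)))
  colnames(X) <- sprintf("JI.c%03d", seq_len(n_signal + n_noise))
  data.frame(label = factor(lab, c("normal", "HCC")), X)
}

signal_ids <- function(tab, n_signal)
  sprintf("JI.c%03d", seq_len(n_signal))

canonical_angle_t <- function(theta) ((theta + pi / 2) %% pi) - pi / 2

shift_mask <- function(mask, dr, dc) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  idx <- which(mask, arr.ind = TRUE)
  idx[, 1] <- idx[, 1] + dr; idx[, 2] <- idx[, 2] + dc
  ok <- idx[, 1] >= 1 & idx[, 1] <= nrow(mask) &
        idx[, 2] >= 1 & idx[, 2] <= ncol(mask)
  out[idx[ok, , drop = FALSE]] <- TRUE
  out
}
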