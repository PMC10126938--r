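# Shared fixture builders (all generated in code, seeded).

# Gaussian epochs with a planted separable class-mean difference a %*% t(b).
make_planted_epochs <- function(n_per_class = 40, C = 6, T_ = 12,
                                strength = 1, noise_sd = 1, seed = 1) {
  stlfl:::with_seed(seed, {
    a <- rnorm(C); a <- a / sqrt(sum(a^2))
    b <- rnorm(T_); b <- b / sqrt(sum(b^2))
    n <- 2L * n_per_class
    arr <- array(rnorm(n * C * T_, sd = noise_sd), dim = c(n, C, T_))
    for (i in seq_len(n_per_class)) {
      arr[i, , ] <- arr[i, , ] + strength * (a %o% b)
    }
    list(epochs = epoch_set(arr, labels = rep(c(1L, 2L),
                                              each = n_per_class),
                            fs = 100),
         a = a, b = b)
  })
}

# A quick RCP session at a given SNR.
make_rcp_session <- function(n_characters = 5, n_repetitions = 15,
                             snr_db = 10, seed = 1, n_channels = 8,
                             latency_jitter_sd = 0.02,
                             amplitude_jitter_sd = 0.1) {
  p <- build_paradigm("RCP", n_repetitions = n_repetitions, seed = seed)
  cfg <- synth_config(n_channels = n_channels, n_characters = n_characters,
                      snr_db = snr_db, seed = seed,
                      latency_jitter_sd = latency_jitter_sd,
                      amplitude_jitter_sd = amplitude_jitter_sd)
  simulate_session(p, cfg)
}

# Random symmetric PSD matrix.
rand_psd <- function(d, seed, rank = d) {
  stlfl:::with_seed(seed, {
    A <- matrix(rnorm(d * rank), d, rank)
    tcrossprod(A) / rank
  })
}

# Random small DRBM parameter list.
rand_drbm_par <- function(d = 4, H = 3, K = 2, seed = 1, sd = 0.5) {
  stlfl:::with_seed(seed, list(
    W = matrix(rnorm(d * H, 0, sd), d, H),
    U = matrix(rnorm(K * H, 0, sd), K, H),
    b_v = rnorm(d, 0, sd), c_h = rnorm(H, 0, sd), d_y = rnorm(K, 0, sd)
  ))
}

# Brute-force DRBM posterior by enumerating all 2^H hidden states from the
# joint energy; independent of the package's closed form.
enum_drbm_posterior <- function(par, X) {
  H <- ncol(par$W); K <- length(par$d_y)
  configs <- as.matrix(expand.grid(rep(list(0:1), H)))
  t(apply(X, 1L, function(x) {
    un <- vapply(seq_len(K), function(y) {
      sum(vapply(seq_len(nrow(configs)), function(ci) {
        h <- configs[ci, ]
        exp(-(sum((x - par$b_v)^2) / 2 - sum(par$c_h * h) -
                sum(x * (par$W %*% h)) - par$d_y[y] - sum(h * par$U[y, ])))
      }, numeric(1L)))
    }, numeric(1L))
    un / sum(un)
  }))
}
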