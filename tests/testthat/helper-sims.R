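# Shared simulation builders for the selection / fusion / screening tests.

# 3 mutually independent informative features (the first dominant), one
# redundant copy of the dominant one, 16 noise columns
planted_mrmr_design <- function(seed, n = 500) {
  withr::with_seed(seed, {
    y <- rep(0:1, each = n / 2)
    X <- data.frame(matrix(rnorm(n * 16), n, 16))
    names(X) <- sprintf("noise%02d", 1:16)
    X$inf1 <- rnorm(n) + 1.4 * y
    X$inf2 <- rnorm(n) + y
    X$inf3 <- rnorm(n) + y
    X$red1 <- X$inf1 + 0.5 * rnorm(n)
    list(X = X, y = y)
  })
}

# two modality score sets sharing a latent signal with independent errors
latent_scores <- function(seed, n = 300, noise = 0.8, beta = 1.5) {
  withr::with_seed(seed, {
    z <- rnorm(n)
    labels <- rbinom(n, 1, plogis(beta * z)) == 1
    list(radiomics = plogis(z + noise * rnorm(n)),
         clinical = plogis(z + noise * rnorm(n)),
         labels = labels)
  })
}

# clinical-only cohort draw under a custom outcome model
clinical_cohort <- function(cfg, n, seed) {
  withr::with_seed(seed, {
    cl <- sample_clinical(cfg, n)
    cl$label <- sample_outcome(cl, cfg)
    cl
  })
}
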