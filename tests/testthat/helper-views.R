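# shared fixture builders: small z-normalized random views and a
# preprocessed three-view dataset built through the package's own chain

make_views <- function(n, p = c(1, 3, 3), seed = 1, shared = 0) {
  withr::with_seed(seed, {
    z <- rnorm(n)
    mk <- function(pk, prefix) {
      m <- matrix(rnorm(n * pk), n, pk) + shared * z
      colnames(m) <- paste0(prefix, seq_len(pk))
      zscore(m)
    }
    list(NL = mk(p[1], "nl"), UF = mk(p[2], "uf"), IW = mk(p[3], "iw"))
  })
}

# residualize -> zscore -> category PCA -> z-scored category scores,
# mirroring the pipeline's training preprocessing
preprocess_multiview <- function(dat) {
  covA <- expand_covariates(dat$covariates[, c("age", "gender", "pop_density")])
  covB <- expand_covariates(dat$covariates)
  nl <- zscore(residualize(dat$exposure, covA))
  uf <- zscore(residualize(dat$urban, covA))
  iw <- zscore(residualize(dat$wellbeing, covB))
  scz <- zscore(category_pca(uf, dat$category_map)$scores)
  list(NL = nl, UF = scz, IW = iw)
}

random_network <- function(p, seed) {
  withr::with_seed(seed, {
    w <- matrix(0, p, p)
    w[upper.tri(w)] <- runif(p * (p - 1) / 2, -0.4, 0.4) *
      rbinom(p * (p - 1) / 2, 1, 0.5)
    w <- w + t(w)
    colnames(w) <- rownames(w) <- paste0("n", seq_len(p))
    comm <- stats::setNames(sample(c("A", "B", "C"), p, replace = TRUE),
                            colnames(w))
    # make sure at least two communities are present
    comm[1] <- "A"; comm[2] <- "B"
    list(w = w, comm = comm)
  })
}
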