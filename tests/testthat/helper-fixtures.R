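# fixtures built in code: a minimal record builder and an independent
# brute-force logistic MLE used as the oracle for the IRLS path

# build a cohort from partial specifications; unspecified fields get benign
# defaults (healthy never-smoking reference participant)
make_cohort <- function(..., n = NULL) {
  spec <- list(...)
  n <- n %||% max(c(1L, vapply(spec, length, 1L)))
  base <- tibble::tibble(
    id = sprintf("T%04d", seq_len(n)),
    sex = "male",
    selfreport_diabetes = "no",
    fasting_glucose = 5.0,
    antidiabetic_medication = "no",
    mother_diabetes = "no",
    father_diabetes = "no",
    sibling_diabetes = "no",
    smoking = "never",
    leisure_pa = 2L,
    work_sedentary = 2L,
    height = 180,
    weight = 81,
    waist = 100,
    hip = 100,
    sad = 21
  )
  for (nm in names(spec)) base[[nm]] <- spec[[nm]]
  as_cohort(base, provenance = "test fixture")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent oracle: maximise the Bernoulli log-likelihood of an
# intercept + single-covariate logistic model by an iteratively refined
# two-dimensional grid search (no IRLS, no glm)
grid_mle_logistic <- function(x, y, iters = 40, span = 8) {
  loglik <- function(a, b) {
    eta <- a + b * x
    sum(y * eta - log1p(exp(eta)))
  }
  ctr <- c(0, 0)
  for (i in seq_len(iters)) {
    g0 <- seq(ctr[1] - span, ctr[1] + span, length.out = 21)
    g1 <- seq(ctr[2] - span, ctr[2] + span, length.out = 21)
    ll <- outer(g0, g1, Vectorize(loglik))
    best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    ctr <- c(g0[best[1]], g1[best[2]])
    span <- span * 0.4
  }
  ctr
}
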