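# Independent oracles and small fixture builders shared across test files.

# PLS1 regression coefficients via the Krylov-subspace (Helland) form:
# b_A is the least-squares coefficient restricted to the Krylov space
# K_A(X'X, X'y).  Algebraically equivalent to NIPALS PLS1 but computed by a
# different route (QR-orthonormalised Krylov basis, one linear solve).
oracle_pls1_coef <- function(X, y, A) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  s <- drop(crossprod(Xc, yc))
  C <- crossprod(Xc)
  K <- matrix(0, ncol(X), A)
  v <- s
  for (a in seq_len(A)) {
    K[, a] <- v
    v <- drop(C %*% v)
  }
  Q <- qr.Q(qr(K))
  drop(Q %*% solve(crossprod(Q, C %*% Q), drop(crossprod(Q, s))))
}

# Brute-force background leverages: explicit per-sample, per-factor loops
# over the defining formula (regress each score column on centered y, remove
# the analyte contribution, accumulate normalized squared residual scores).
oracle_h0 <- function(Tm, y) {
  yc <- y - mean(y)
  ssy <- sum(yc^2)
  h0 <- numeric(nrow(Tm))
  for (n in seq_len(nrow(Tm))) {
    for (a in seq_len(ncol(Tm))) {
      s_a <- if (ssy > 0) sum(Tm[, a] * yc) / ssy else 0
      t0 <- Tm[n, a] - yc[n] * s_a
      h0[n] <- h0[n] + t0^2 / sum(Tm[, a]^2)
    }
  }
  h0
}

# Minimal SpectraSet fixture: absorbance samples x wavenumbers on a small
# uniform grid inside the NIR range.
make_set <- function(absmat, conc = seq_len(nrow(absmat)) * 10,
                     role = "calibration",
                     wn = seq(6000, by = -8, length.out = ncol(absmat)),
                     group = paste0("g", seq_len(nrow(absmat)))) {
  SpectraSet(absmat, wn,
             data.frame(sample_id = paste0("s", seq_len(nrow(absmat))),
                        concentration = conc,
                        replicate_group = group,
                        role = role))
}

# Bare PLSModel with prescribed slots (for figure-of-merit unit tests).
make_model <- function(b, scores = NULL) {
  p <- length(b)
  A <- if (is.null(scores)) 1L else ncol(scores)
  if (is.null(scores)) scores <- matrix(seq_len(4), 4, 1)
  methods::new("PLSModel",
    xMean = numeric(p), yMean = 0,
    weights = matrix(1 / sqrt(p), p, A), scores = scores,
    xLoadings = matrix(1, p, A), yLoadings = numeric(A) + 1,
    coefficients = b, nFactors = A, wavenumbers = NA_real_)
}

# Session-level cache so expensive shared fixtures are built once.
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# The default-noise 52-point calibration run used by several files.
default_run <- function() cached("default_run", {
  sim <- generateSpectraSet(studyDesign(seed = 11L))
  avg <- averageReplicates(applyPlan(sim$spectra, preprocessPlan("reference")))
  cm <- crossValidate(avg, maxFactors = 8)
  model <- fitCalibration(avg, maxFactors = chosenFactors(cm))
  list(sim = sim, avg = avg, metrics = cm, model = model)
})
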