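# Shared fixtures: small cohorts and feature sets built in code.

small_cohort <- function(n_control = 30, n_patient = 30, seed = 1L,
                         missing_rates = numeric(0)) {
  generate_cohort(cohort_spec(n_control, n_patient,
                              missing_rates = missing_rates, seed = seed))
}

# labels as -1 (control) / +1 (patient) from a participant table
labels_of <- function(table) {
  ifelse(table$group == levels(table$group)[2], 1, -1)
}

# brute-force minimum of the EasyMKL QP objective over a grid on the
# product of two probability simplices (for 3 members per class)
grid_qp_min <- function(K, y, lam, step = 0.05) {
  stopifnot(sum(y > 0) == 3, sum(y < 0) == 3)
  s <- seq(0, 1, step)
  g2 <- expand.grid(a = s, b = s)
  g2 <- g2[g2$a + g2$b <= 1 + 1e-12, ]
  simplex <- cbind(g2$a, g2$b, 1 - g2$a - g2$b)
  pos <- which(y > 0); neg <- which(y < 0)
  Q <- K * tcrossprod(y)
  best <- Inf; best_g <- NULL
  for (i in seq_len(nrow(simplex))) {
    gpos <- simplex[i, ]
    # vectorize over the negative-class simplex
    g <- matrix(0, length(y), nrow(simplex))
    g[pos, ] <- gpos
    g[neg, ] <- t(simplex)
    obj <- (1 - lam) * colSums(g * (Q %*% g)) + lam * colSums(g^2)
    j <- which.min(obj)
    if (obj[j] < best) {
      best <- obj[j]
      best_g <- g[, j]
    }
  }
  list(objective = best, gamma = best_g)
}

easymkl_objective <- function(K, y, lam, gamma) {
  Q <- K * tcrossprod(y)
  (1 - lam) * drop(crossprod(gamma, Q %*% gamma)) + lam * sum(gamma^2)
}
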