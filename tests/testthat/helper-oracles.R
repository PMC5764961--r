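# Independent, deliberately naive reference implementations used to
# cross-check the package's statistics. Everything here is written with
# explicit element-wise loops and base formulas, sharing no code with R/.

naive_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# delta-Ct: mean over partners of SD of per-sample Ct differences
oracle_delta_ct <- function(m) {
  g <- nrow(m)
  vals <- numeric(g)
  for (j in 1:g) {
    sds <- c()
    for (k in 1:g) {
      if (k == j) next
      diffs <- numeric(ncol(m))
      for (s in 1:ncol(m)) diffs[s] <- m[j, s] - m[k, s]
      sds <- c(sds, naive_sd(diffs))
    }
    vals[j] <- sum(sds) / length(sds)
  }
  names(vals) <- rownames(m)
  vals
}

# geNorm M for a set of quantities (single pass, no exclusion)
oracle_genorm_m <- function(q) {
  g <- nrow(q)
  vals <- numeric(g)
  for (j in 1:g) {
    sds <- c()
    for (k in 1:g) {
      if (k == j) next
      lr <- numeric(ncol(q))
      for (s in 1:ncol(q)) lr[s] <- log2(q[j, s] / q[k, s])
      sds <- c(sds, naive_sd(lr))
    }
    vals[j] <- sum(sds) / length(sds)
  }
  names(vals) <- rownames(q)
  vals
}

# full iterative geNorm: returns list(exclusion_order, values per gene)
# tie rule mirrors the documented convention (larger variation to the
# current best gene goes first, residual ties lexicographic)
oracle_genorm_full <- function(q, tol = 1e-12) {
  remaining <- rownames(q)
  order_out <- c(); val_out <- c()
  while (length(remaining) > 2) {
    m <- oracle_genorm_m(q[remaining, , drop = FALSE])
    mx <- max(m)
    tied <- names(m)[m >= mx - tol]
    if (length(tied) > 1) {
      best <- names(m)[which.min(m)]
      vb <- sapply(tied, function(gn) {
        if (gn == best) return(-Inf)
        naive_sd(log2(q[gn, ] / q[best, ]))
      })
      worst <- tied[order(-vb, tied)][1]
    } else worst <- tied
    order_out <- c(order_out, worst)
    val_out <- c(val_out, m[[worst]])
    remaining <- setdiff(remaining, worst)
  }
  final_m <- oracle_genorm_m(q[remaining, , drop = FALSE])
  list(exclusion_order = order_out,
       m_at_exclusion = val_out,
       final_pair = sort(remaining),
       final_m = final_m)
}

# geNorm V series from a ranking (best gene first)
oracle_genorm_v <- function(q, ranked) {
  g <- nrow(q)
  sapply(2:(g - 1), function(n) {
    lr <- numeric(ncol(q))
    for (s in 1:ncol(q)) {
      nf_n <- prod(q[ranked[1:n], s])^(1 / n)
      nf_n1 <- prod(q[ranked[1:(n + 1)], s])^(1 / (n + 1))
      lr[s] <- log2(nf_n / nf_n1)
    }
    naive_sd(lr)
  })
}

# BestKeeper descriptives + correlation to the geometric-mean index
oracle_bestkeeper <- function(m) {
  g <- nrow(m); n <- ncol(m)
  index <- numeric(n)
  for (s in 1:n) index[s] <- prod(m[, s])^(1 / g)
  res <- data.frame(gene = rownames(m), am = NA_real_, mad = NA_real_,
                    cv = NA_real_, r = NA_real_, stringsAsFactors = FALSE)
  for (j in 1:g) {
    am <- sum(m[j, ]) / n
    mad_ <- sum(abs(m[j, ] - am)) / n
    res$am[j] <- am
    res$mad[j] <- mad_
    res$cv[j] <- mad_ / am * 100
    res$r[j] <- stats::cor(m[j, ], index)
  }
  res
}

# NormFinder: direct transcription of the variance-decontamination system
oracle_normfinder <- function(y, groups = NULL) {
  k <- nrow(y); n <- ncol(y)
  if (is.null(groups)) groups <- rep("all", n)
  r <- y
  for (s in 1:n) r[, s] <- y[, s] - sum(y[, s]) / k
  glev <- sort(unique(groups))
  sig2 <- matrix(0, k, length(glev), dimnames = list(rownames(y), glev))
  for (gi in seq_along(glev)) {
    cols <- which(groups == glev[gi])
    v <- numeric(k)
    for (j in 1:k) v[j] <- naive_sd(r[j, cols])^2
    s_g <- k / (k - 1) * sum(v)
    for (j in 1:k) sig2[j, gi] <- max(0, (v[j] - s_g / k^2) / (1 - 2 / k))
  }
  if (length(glev) == 1) return(sqrt(sig2[, 1]))
  overall <- apply(r, 1, mean)
  d <- matrix(0, k, length(glev), dimnames = list(rownames(y), glev))
  ng <- numeric(length(glev))
  for (gi in seq_along(glev)) {
    cols <- which(groups == glev[gi])
    ng[gi] <- length(cols)
    for (j in 1:k) d[j, gi] <- mean(r[j, cols]) - overall[j]
  }
  rho <- numeric(k)
  for (j in 1:k) {
    noise <- sig2[j, ] / ng
    gamma2 <- max(0, naive_sd(d[j, ])^2 - mean(noise))
    terms <- numeric(length(glev))
    for (gi in seq_along(glev)) {
      shr <- gamma2 / (gamma2 + noise[gi])
      terms[gi] <- abs(d[j, gi] * shr) + sqrt(noise[gi] * shr)
    }
    rho[j] <- mean(terms)
  }
  names(rho) <- rownames(y)
  rho
}

# OLS slope/intercept by the normal equations, no lm()
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}

# random positive gene x sample matrices for oracle sweeps
random_ct_matrix <- function(g, n, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(g * n, 15, 35), g, n,
              dimnames = list(paste0("g", seq_len(g)), paste0("s", seq_len(n))))
  m
}
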