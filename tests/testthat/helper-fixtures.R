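# Shared fixture builders and independent oracles. Everything is generated
# in code under fixed seeds; no stored data.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Dense-algebra restricted log-likelihood at a fixed variance ratio delta,
# computed by brute force (solve/determinant) — deliberately independent of
# the spectral path used by reml_solve(). Orthonormal-contrast convention.
dense_rll <- function(delta, yv, Xm, Zm, Km = NULL, wv = NULL) {
  if (is.null(Km)) Km <- diag(ncol(Zm))
  if (!is.null(wv)) {
    sw <- sqrt(wv); yv <- yv / sw; Xm <- Xm / sw; Zm <- Zm / sw
  }
  n <- length(yv); p <- qr(Xm)$rank
  V0 <- Zm %*% Km %*% t(Zm) + delta * diag(n)
  Vi <- solve(V0)
  XtViX <- t(Xm) %*% Vi %*% Xm
  beta <- solve(XtViX, t(Xm) %*% Vi %*% yv)
  r <- yv - Xm %*% beta
  ss <- drop(t(r) %*% Vi %*% r)
  s2 <- ss / (n - p)
  as.numeric(-0.5 * ((n - p) * log(2 * pi * s2) +
                       determinant(V0)$modulus +
                       determinant(XtViX)$modulus -
                       determinant(t(Xm) %*% Xm)$modulus + (n - p)))
}

# Profiled sigma2_u at delta, same dense route.
dense_s2u <- function(delta, yv, Xm, Zm, Km = NULL) {
  if (is.null(Km)) Km <- diag(ncol(Zm))
  n <- length(yv); p <- qr(Xm)$rank
  V0 <- Zm %*% Km %*% t(Zm) + delta * diag(n)
  Vi <- solve(V0)
  beta <- solve(t(Xm) %*% Vi %*% Xm, t(Xm) %*% Vi %*% yv)
  r <- yv - Xm %*% beta
  drop(t(r) %*% Vi %*% r) / (n - p)
}

# Random mixed-model instance with genuine signal in both components.
random_instance <- function(seed, n = NULL, q = NULL, with_K = FALSE) {
  withr::with_seed(seed, {
    n <- n %||% sample(10:30, 1)
    q <- q %||% sample(4:min(60, 3 * n), 1)
    X <- cbind(1, rnorm(n))
    Z <- matrix(rnorm(n * q), n, q)
    K <- NULL
    if (with_K) {
      A <- matrix(rnorm(q * q), q)
      K <- crossprod(A) / q + diag(q) * 0.1
    }
    su <- runif(1, 0.5, 2); se <- runif(1, 0.5, 2)
    u <- if (with_K) drop(chol(K) %*% rnorm(q)) * su else rnorm(q, 0, su)
    y <- drop(X %*% c(1, 0.5) + Z %*% u + rnorm(n, 0, se))
    list(y = y, X = X, Z = Z, K = K)
  })
}

# Tiny hand-specified marker matrix for QC boundary tests.
toy_marker_matrix <- function(calls) {
  marker_matrix(calls)
}

# A small inbred population bred from founders: `n_cross` crosses of
# `per_cross` lines each. Returns genotypes + cross map.
sim_population <- function(seed, n_founders = 30, n_markers = 400,
                           n_cross = 10, per_cross = 20, selfing = 6,
                           het = 0, config = NULL) {
  cfg <- config %||% sim_config(n_founders = n_founders,
                                n_markers = n_markers, seed = seed)
  f <- simulate_founders(cfg)
  withr::with_seed(seed + 17, {
    prs <- t(replicate(n_cross, sample(rownames(f), 2)))
    fams <- lapply(seq_len(n_cross), function(k) {
      derive_inbred_family(f, prs[k, 1], prs[k, 2], per_cross,
                           selfing_generations = selfing, seed = seed + k,
                           residual_het_rate = het,
                           cross_id = paste0("C", k),
                           prefix = paste0("C", k))
    })
    geno <- marker_matrix(do.call(rbind,
                                  lapply(fams, function(x)
                                    unclass(x$genotypes))),
                          map = attr(f, "map"))
    list(geno = geno,
         pedigree = dplyr::bind_rows(lapply(fams, function(x) x$pedigree)),
         founders = f, config = cfg)
  })
}

# Cohort of independent inbred lines drawn at given allele frequencies —
# fast stand-in population when family structure is not needed.
sim_cohort <- function(seed, n = 300, m = 400, maf = c(0.1, 0.5)) {
  withr::with_seed(seed, {
    p <- runif(m, maf[1], maf[2])
    calls <- matrix(2L * rbinom(n * m, 1, rep(p, each = n)), nrow = n,
                    dimnames = list(sprintf("L%04d", seq_len(n)),
                                    sprintf("M%04d", seq_len(m))))
    marker_matrix(calls)
  })
}

# Phenotypes y = mu + TBV + N(0, s2e) for a genotype matrix, with TBV built
# from `n_qtl` random marker effects scaled to var_g.
sim_pheno <- function(geno, seed, h2 = 0.5, var_g = 0.25, n_qtl = 100,
                      mu = 5.5) {
  withr::with_seed(seed, {
    m <- ncol(geno)
    qtl <- sample(m, min(n_qtl, m))
    a <- rnorm(length(qtl))
    tbv <- drop(unclass(geno)[, qtl, drop = FALSE] %*% a)
    if (sd(tbv) > 0) tbv <- tbv * sqrt(var_g) / sd(tbv)
    s2e <- if (h2 > 0) var_g * (1 - h2) / h2 else var_g
    if (h2 == 0) tbv <- tbv * 0
    y <- mu + tbv + rnorm(nrow(geno), 0, sqrt(s2e))
    list(pheno = tibble::tibble(line = rownames(geno), value = y),
         tbv = tibble::tibble(line = rownames(geno), tbv = tbv))
  })
}
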