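# Small in-code fixtures and independent brute-force oracles.

tiny_obs <- function() {
  tibble::tibble(
    station_id = c("A", "A", "A", "B"),
    wcz = "Z1",
    date = as.Date(c("2000-01-01", "2000-01-01", "2000-02-01", "2000-01-01")),
    species_id = c("sp1", "sp2", "sp1", "sp1"),
    group = c("diatom", "dinoflagellate", "diatom", "diatom"),
    abundance = c(9, 1, 4, 2),
    cell_biovolume = c(100, 10000, 120, 300)
  )
}

# Observation table with one species per row spec: build from vectors
make_obs <- function(station, date, species, abundance, biovolume,
                     group = "diatom", wcz = "Z1") {
  tibble::tibble(station_id = station, wcz = wcz,
                 date = as.Date(paste0(date, "-01")),
                 species_id = species, group = group,
                 abundance = abundance, cell_biovolume = biovolume)
}

# --- independent oracles ---------------------------------------------------

# OLS slope/p via explicit normal equations and the t distribution.
ols_oracle <- function(t, y) {
  X <- cbind(1, t)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  n <- length(y)
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  tt <- beta[2] / se
  list(intercept = beta[1], slope = beta[2], se = se,
       p = 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE))
}

# Textbook BH step-up: q_(i) = min_{j >= i} m p_(j) / j, input order restored.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# ANOSIM R for one labelling (mid-ranked dissimilarities).
anosim_r_oracle <- function(m, groups) {
  lt <- lower.tri(m)
  r <- rank(m[lt])
  same <- outer(groups, groups, "==")[lt]
  n <- nrow(m)
  (mean(r[!same]) - mean(r[same])) / (n * (n - 1) / 4)
}

# Exact ANOSIM p by enumerating every distinct assignment of labels.
anosim_p_enumeration <- function(m, groups) {
  n <- length(groups)
  r_obs <- anosim_r_oracle(m, groups)
  perms <- combinat_permutations(n)
  r_all <- apply(perms, 1, function(ix) anosim_r_oracle(m, groups[ix]))
  mean(r_all >= r_obs - 1e-12)
}

combinat_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Brute-force partition of community mean-size change from the definitions.
partition_oracle <- function(obs0, obs1) {
  stats_of <- function(o) {
    sp <- sort(unique(o$species_id))
    tot <- sum(o$abundance)
    p <- vapply(sp, function(s) sum(o$abundance[o$species_id == s]) / tot,
                numeric(1))
    v <- vapply(sp, function(s) {
      rows <- o$species_id == s
      sum(o$abundance[rows] * o$cell_biovolume[rows]) /
        sum(o$abundance[rows])
    }, numeric(1))
    list(sp = sp, p = p, v = v)
  }
  s0 <- stats_of(obs0); s1 <- stats_of(obs1)
  sp <- union(s0$sp, s1$sp)
  p0 <- ifelse(sp %in% s0$sp, s0$p[match(sp, s0$sp)], 0)
  p1 <- ifelse(sp %in% s1$sp, s1$p[match(sp, s1$sp)], 0)
  v0 <- ifelse(sp %in% s0$sp, s0$v[match(sp, s0$sp)],
               s1$v[match(sp, s1$sp)])
  v1 <- ifelse(sp %in% s1$sp, s1$v[match(sp, s1$sp)],
               s0$v[match(sp, s0$sp)])
  list(delta = sum(p1 * v1) - sum(p0 * v0),
       within = sum((p0 + p1) / 2 * (v1 - v0)),
       composition = sum((v0 + v1) / 2 * (p1 - p0)))
}

# Random two-window observation pair over a shared species pool.
random_partition_instance <- function(n_species = 8, seed = 1) {
  set.seed(seed)
  sp <- sprintf("sp%02d", seq_len(n_species))
  draw <- function(t, keep_frac = 1) {
    keep <- runif(n_species) <= keep_frac
    keep[1] <- TRUE
    make_obs("A", t, sp[keep],
             abundance = rlnorm(sum(keep), 3, 1),
             biovolume = rlnorm(sum(keep), 6, 1.5))
  }
  list(w0 = draw("2000-01", 0.8), w1 = draw("2010-01", 0.8))
}

# Brute-force exact Shapley values by direct coalition enumeration,
# structured independently of the package implementation.
shapley_oracle <- function(f, x, background) {
  p <- ncol(x)
  n <- nrow(x)
  subsets <- lapply(0:(2^p - 1), function(mask) {
    which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
  })
  vfun <- function(S, xi) {
    z <- background
    for (j in S) z[, j] <- xi[j]
    mean(f(z))
  }
  phi <- matrix(0, n, p)
  for (i in seq_len(n)) {
    for (j in seq_len(p)) {
      for (S in subsets) {
        if (j %in% S) next
        w <- factorial(length(S)) * factorial(p - length(S) - 1) /
          factorial(p)
        phi[i, j] <- phi[i, j] +
          w * (vfun(c(S, j), x[i, ]) - vfun(S, x[i, ]))
      }
    }
  }
  colnames(phi) <- colnames(x)
  phi
}
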