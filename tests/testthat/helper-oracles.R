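# Independent brute-force / hand-rolled oracles.  These deliberately use
# naive loops and direct formulas, separate from the package's code
# paths.

# Minimum cross-entropy criterion, naive scan over every admissible edge.
li_bruteforce <- function(hist) {
  centers <- (hist$edges[-1L] + hist$edges[-length(hist$edges)]) / 2
  counts <- hist$counts
  nonempty <- which(counts > 0)
  ks <- (nonempty[1L] + 1L):nonempty[length(nonempty)]
  best_eta <- Inf
  best_k <- NA_integer_
  for (k in ks) {
    below <- seq_len(k - 1L)
    above <- k:length(counts)
    m1 <- sum(centers[below] * counts[below])
    n1 <- sum(counts[below])
    m2 <- sum(centers[above] * counts[above])
    n2 <- sum(counts[above])
    eta <- -(m1 * log(m1 / n1) + m2 * log(m2 / n2))
    if (eta < best_eta) {
      best_eta <- eta
      best_k <- k
    }
  }
  hist$edges[best_k]
}

# Kapur maximum-entropy criterion, naive scan.
kapur_bruteforce <- function(hist) {
  counts <- hist$counts
  nonempty <- which(counts > 0)
  ks <- (nonempty[1L] + 1L):nonempty[length(nonempty)]
  p <- counts / sum(counts)
  # sum of the normalized within-class entropies; algebraically equal to
  # Kapur's log(P1*P2) + H1/P1 + H2/P2 form
  ent <- function(q) {
    q <- q[q > 0]
    q <- q / sum(q)
    -sum(q * log(q))
  }
  best_psi <- -Inf
  best_k <- NA_integer_
  for (k in ks) {
    psi <- ent(p[seq_len(k - 1L)]) + ent(p[k:length(p)])
    if (psi > best_psi) {
      best_psi <- psi
      best_k <- k
    }
  }
  hist$edges[best_k]
}

# Exact two-sided rank-sum p by full enumeration of group assignments,
# using the same tail-doubling rule as the exact Mann-Whitney
# distribution (symmetric under no ties).
wilcoxon_enum_p <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  p <- if (u_obs > nx * ny / 2) mean(us >= u_obs) else mean(us <= u_obs)
  min(1, 2 * p)
}

# Naive weighted survival test (independent second implementation).
survtest_oracle <- function(ta, ea, tb, eb, gehan = FALSE) {
  time <- c(ta, tb)
  event <- c(ea, eb)
  g <- rep(c(TRUE, FALSE), c(length(ta), length(tb)))
  ut <- sort(unique(time[event == 1]))
  num <- 0
  den <- 0
  for (t in ut) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & g)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g)
    w <- if (gehan) n else 1
    num <- num + w * (d1 - d * n1 / n)
    if (n > 1) {
      den <- den + w^2 * d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  chi2 <- num^2 / den
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

# Greedy Ward agglomeration by explicit within-cluster sum-of-squares;
# returns the sequence of merge heights sqrt(2 * delta SS), which is the
# height scale of hclust's ward.D2 for Euclidean input.
ward_heights_oracle <- function(m) {
  clusters <- lapply(seq_len(nrow(m)), identity)
  ss <- function(idx) {
    if (length(idx) == 1L) return(0)
    x <- m[idx, , drop = FALSE]
    sum(sweep(x, 2, colMeans(x))^2)
  }
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- list(dss = Inf, i = NA, j = NA)
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        dss <- ss(c(clusters[[i]], clusters[[j]])) -
          ss(clusters[[i]]) - ss(clusters[[j]])
        if (dss < best$dss) best <- list(dss = dss, i = i, j = j)
      }
    }
    heights <- c(heights, sqrt(2 * best$dss))
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  heights
}

# Exact rank-product pfp for k case samples over n genes: the null rank
# product is the geometric mean of k iid uniform ranks on 1..n, whose
# distribution is enumerated exhaustively (n^k tuples).
pfp_exact_oracle <- function(rp_obs, n, k) {
  tuples <- as.matrix(do.call(expand.grid, rep(list(seq_len(n)), k)))
  null_rp <- exp(rowMeans(log(tuples)))
  e_false <- n * vapply(rp_obs, function(x) mean(null_rp <= x), 0)
  raw <- e_false / rank(rp_obs, ties.method = "max")
  ord <- order(rp_obs)
  out <- numeric(length(raw))
  out[ord] <- rev(cummin(rev(raw[ord])))  # same step-up smoothing
  out
}

# Random bimodal OD histogram for threshold-oracle checks.
random_mixture_hist <- function(seed) {
  set.seed(seed)
  n1 <- sample(200:2000, 1)
  n2 <- sample(50:1000, 1)
  v <- abs(c(rnorm(n1, runif(1, 0.02, 0.4), runif(1, 0.01, 0.1)),
             rnorm(n2, runif(1, 0.5, 1.5), runif(1, 0.02, 0.2))))
  od_histogram(v, bins = sample(c(64L, 128L, 256L), 1))
}
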