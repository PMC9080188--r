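# Independent oracle implementations used to verify the package's statistics.
# These are deliberately written from the textbook definitions (loops,
# enumeration, grids), not by calling the code under test.

# Benjamini-Hochberg step-up from the definition:
# adj_(i) = min_{j >= i} m * p_(j) / j, clipped at 1, restored to input order.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Pearson r from the covariance/sigma definition, p from the t transform.
brute_pearson <- function(x, y) {
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# Two-group log-rank chi-square from explicit 2x2 tables at each event time.
# Times are assumed untied when used for permutations (d = 1 per time), but
# the loop handles ties too.
brute_logrank2 <- function(time, event, g1) {
  ut <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ut) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Fast vectorized 2-group log-rank chi-square for permutation tests
# (untied times only).
fast_logrank2 <- function(time, event, g1) {
  ord <- order(time)
  e <- event[ord]; g <- g1[ord]
  n <- length(time)
  n_risk <- n - seq_len(n) + 1L
  n1_risk <- rev(cumsum(rev(g)))
  f <- n1_risk / n_risk
  ev <- e == 1
  O1 <- sum(g[ev])
  E1 <- sum(f[ev])
  V <- sum((f * (1 - f))[ev])
  (O1 - E1)^2 / V
}

# Betweenness by exhaustive shortest-path enumeration (graphs of <= ~10
# nodes). adj: symmetric logical adjacency matrix with node names.
brute_betweenness <- function(adj) {
  ids <- rownames(adj)
  n <- length(ids)
  # BFS distances
  dist <- matrix(Inf, n, n, dimnames = list(ids, ids))
  for (s in seq_len(n)) {
    dist[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ])) {
          if (dist[s, w] > d) { dist[s, w] <- d; nxt <- c(nxt, w) }
        }
      }
      frontier <- unique(nxt)
    }
  }
  # enumerate all shortest s-t paths by DFS down the distance gradient
  count_through <- stats::setNames(numeric(n), ids)
  n_paths_through <- function(s, t) {
    paths <- list()
    walk <- function(v, acc) {
      if (v == t) { paths[[length(paths) + 1L]] <<- acc; return() }
      for (w in which(adj[v, ]))
        if (dist[w, t] == dist[v, t] - 1) walk(w, c(acc, w))
    }
    walk(s, integer(0))
    paths
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(dist[s, t]) || dist[s, t] < 2) next
    paths <- n_paths_through(s, t)
    tot <- length(paths)
    for (p in paths) {
      inner <- p[-length(p)]          # interior nodes (s excluded by start)
      for (v in inner) count_through[v] <- count_through[v] + 1 / tot
    }
  }
  count_through
}

# Exhaustive cutpoint scan with per-split recomputation of the standardized
# log-rank score statistic (guards the minprop / tie-breaking logic).
brute_cutpoint <- function(x, time, event, minprop = 0.1) {
  n <- length(x)
  # per-subject log-rank scores, recomputed longhand
  a <- numeric(n)
  ut <- sort(unique(time[event == 1]))
  for (i in seq_len(n)) {
    H <- 0
    for (t in ut) {
      if (t > time[i]) break
      H <- H + sum(time == t & event == 1) / sum(time >= t)
    }
    a[i] <- event[i] - H
  }
  abar <- mean(a)
  va <- sum((a - abar)^2)
  best <- NULL
  for (c in sort(unique(x))) {
    m <- sum(x <= c)
    if (m == 0 || m == n) next
    if (m / n < minprop - 1e-9 || (n - m) / n < minprop - 1e-9) next
    S <- sum(a[x <= c])
    z <- (S - m * abar) / sqrt(m * (n - m) / (n * (n - 1)) * va)
    if (is.null(best) || abs(z) > abs(best$z) + 1e-12)
      best <- list(cut = c, z = z)
  }
  best
}

# Exact Cox partial log-likelihood for untied event times.
brute_cox_loglik <- function(beta, x, time, event) {
  eta <- x * beta
  ll <- 0
  for (i in which(event == 1))
    ll <- ll + eta[i] - log(sum(exp(eta[time >= time[i]])))
  ll
}

# All layer-respecting lncRNA -> mRNA -> GO -> hallmark paths by triple loop.
brute_path_counts <- function(lnc_mrna, mrna_go, go_hallmark, lncrna) {
  counts <- list()
  for (i in seq_len(nrow(lnc_mrna))) {
    if (lnc_mrna$lncRNA[i] != lncrna) next
    m <- lnc_mrna$mRNA[i]
    for (j in seq_len(nrow(mrna_go))) {
      if (mrna_go$gene_id[j] != m) next
      go <- mrna_go$go_id[j]
      for (k in seq_len(nrow(go_hallmark))) {
        if (go_hallmark$go_id[k] != go) next
        h <- go_hallmark$hallmark[k]
        key <- paste(m, go, sep = "\r")
        counts[[h]] <- union(counts[[h]], key)
      }
    }
  }
  out <- vapply(counts, length, integer(1))
  out[order(-out, names(out))]
}
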