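# Independent brute-force oracles used to check the vectorized implementations.

# Mutual ranks by explicit per-row / per-column sorting.
bf_mutual_rank <- function(scc, orientation) {
  s <- if (orientation == "positive") -scc else scc
  out <- matrix(NA_real_, nrow(scc), ncol(scc), dimnames = dimnames(scc))
  for (i in seq_len(nrow(scc))) {
    for (j in seq_len(ncol(scc))) {
      r_row <- rank(s[i, ])[j]
      r_col <- rank(s[, j])[i]
      out[i, j] <- sqrt(r_row * r_col)
    }
  }
  out
}

# Association index as plain Pearson of 0/1 indicator vectors.
bf_indicator_pearson <- function(set_x, set_y, universe) {
  vx <- as.numeric(universe %in% set_x)
  vy <- as.numeric(universe %in% set_y)
  cor(vx, vy)
}

# Closed-form simple OLS of y on x with slope p-value.
bf_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  tval <- slope / se
  list(slope = slope, intercept = intercept,
       p_value = 2 * pt(abs(tval), df = n - 2, lower.tail = FALSE),
       r_squared = 1 - sum(resid^2) / sum((y - mean(y))^2))
}

# Normalized betweenness by enumeration of all shortest paths (BFS).
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s >= t) next
      # enumerate all paths from s to t of minimal length via DFS
      paths <- list()
      best <- Inf
      stack <- list(s)
      walk <- function(path) {
        v <- path[length(path)]
        if (length(path) - 1 > best) return()
        if (v == t) {
          if (length(path) - 1 < best) { best <<- length(path) - 1; paths <<- list() }
          if (length(path) - 1 == best) paths[[length(paths) + 1]] <<- path
          return()
        }
        for (w in which(adj[v, ] == 1)) {
          if (!w %in% path) walk(c(path, w))
        }
      }
      walk(s)
      if (!length(paths)) next
      thru <- table(unlist(lapply(paths, function(p) setdiff(p, c(s, t)))))
      for (v in names(thru)) {
        btw[as.integer(v)] <- btw[as.integer(v)] + thru[[v]] / length(paths)
      }
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

# Log partial likelihood (Breslow form; exact for untied data) for a single
# covariate, and its maximiser found by grid search.
bf_cox_loglik <- function(beta, x, times, events) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

bf_cox_grid <- function(x, times, events, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, bf_cox_loglik, numeric(1), x = x, times = times, events = events)
  grid[which.max(ll)]
}

# Two-group log-rank statistic from the hypergeometric O-E sums.
bf_logrank <- function(groups, times, events) {
  g <- as.integer(as.factor(groups))
  o_e <- 0; v <- 0
  for (t0 in sort(unique(times[events == 1]))) {
    at_risk <- times >= t0
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(times == t0 & events == 1)
    d1 <- sum(times == t0 & events == 1 & g == 1)
    o_e <- o_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_e^2 / v
}

# Mann-Whitney pair-counting AUC among cases (time <= t, event) vs controls
# (time > t); valid without censoring.
bf_pair_auc <- function(scores, times, events, t0) {
  ca <- scores[times <= t0 & events == 1]
  co <- scores[times > t0]
  m <- outer(ca, co, function(a, b) (a > b) + 0.5 * (a == b))
  mean(m)
}

# Kaplan-Meier by hand (product-limit over event times).
bf_km <- function(times, events, at) {
  s <- 1
  for (t0 in sort(unique(times[events == 1]))) {
    if (t0 > at) break
    n_risk <- sum(times >= t0)
    d <- sum(times == t0 & events == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}
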