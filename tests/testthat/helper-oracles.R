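# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: enumeration, closed forms, and normal equations.

# maximum spanning-tree total |weight| by exhaustive enumeration of all
# (n-1)-edge acyclic subsets; edges is a data.frame(u, v, weight)
enum_mst_weight <- function(nodes, edges) {
  n <- length(nodes)
  m <- nrow(edges)
  stopifnot(m >= n - 1)
  combos <- utils::combn(m, n - 1)
  ui <- match(edges$u, nodes)
  vi <- match(edges$v, nodes)
  w <- abs(edges$weight)
  best <- -Inf
  for (c_ in seq_len(ncol(combos))) {
    sel <- combos[, c_]
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (e in sel) {
      ra <- find(ui[e]); rb <- find(vi[e])
      if (ra == rb) { ok <- FALSE; break }
      parent[ra] <- rb
    }
    if (ok) best <- max(best, sum(w[sel]))
  }
  best
}

# random connected graph on n nodes with at most max_edges edges
random_connected_graph <- function(n, p = 0.4, max_edges = 14) {
  repeat {
    all_pairs <- t(utils::combn(n, 2))
    keep <- runif(nrow(all_pairs)) < p
    # always keep a random spanning path so the graph is connected
    perm <- sample(n)
    path <- cbind(perm[-n], perm[-1])
    edges <- unique(rbind(all_pairs[keep, , drop = FALSE],
                          t(apply(path, 1, sort))))
    if (nrow(edges) <= max_edges && nrow(edges) >= n - 1) {
      return(data.frame(u = paste0("v", edges[, 1]), v = paste0("v", edges[, 2]),
                        weight = round(runif(nrow(edges), -1, 1), 3)))
    }
  }
}

# eigenvalues of a symmetric 3x3 matrix by the closed-form trigonometric
# solution of the characteristic cubic (no LAPACK involved)
eigen3_closed_form <- function(A) {
  stopifnot(all(dim(A) == c(3, 3)))
  p1 <- A[1, 2]^2 + A[1, 3]^2 + A[2, 3]^2
  q <- sum(diag(A)) / 3
  p2 <- sum((diag(A) - q)^2) + 2 * p1
  p <- sqrt(p2 / 6)
  if (p < 1e-14) return(rep(q, 3))
  B <- (A - q * diag(3)) / p
  r <- det(B) / 2
  r <- min(max(r, -1), 1)
  phi <- acos(r) / 3
  eig1 <- q + 2 * p * cos(phi)
  eig3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  sort(c(eig1, 3 * q - eig1 - eig3, eig3), decreasing = TRUE)
}

# largest control subset (by size) whose Welch t-test against `case_ages`
# gives p > alpha, by enumerating every subset of the eligible ages
brute_force_max_balanced <- function(case_ages, eligible_ages, alpha = 0.05) {
  m <- length(eligible_ages)
  stopifnot(m <= 12)
  best <- 0
  for (mask in seq_len(2^m - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    if (length(sel) <= best || length(sel) < 2) next
    y <- eligible_ages[sel]
    p <- if (sd(case_ages) == 0 && sd(y) == 0) {
      if (isTRUE(all.equal(mean(case_ages), mean(y)))) 1 else 0
    } else t.test(case_ages, y)$p.value
    if (!is.na(p) && p > alpha) best <- length(sel)
  }
  best
}

# minimal-total-distance injective assignment of references to candidates
# by enumerating all ordered candidate subsets
brute_force_assignment <- function(d) {
  refs <- seq_len(nrow(d)); cands <- seq_len(ncol(d))
  stopifnot(nrow(d) <= 4, ncol(d) <= 7)
  perms <- function(v, k) {
    if (k == 0) return(list(integer(0)))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i], k - 1))
        out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  best <- Inf; best_map <- NULL
  for (map in perms(cands, length(refs))) {
    tot <- sum(d[cbind(refs, map)])
    if (tot < best) { best <- tot; best_map <- map }
  }
  list(total = best, map = best_map)
}

# weighted modularity of a node partition (absolute weights)
partition_modularity <- function(assignment, edges, nodes) {
  w <- abs(edges$weight)
  m <- sum(w)
  if (m == 0) return(0)
  comm <- assignment[nodes]
  cu <- assignment[edges$u]; cv <- assignment[edges$v]
  q <- 0
  for (c_ in unique(comm)) {
    w_in <- sum(w[cu == c_ & cv == c_])
    strength <- sum(w[cu == c_]) + sum(w[cv == c_])
    q <- q + w_in / m - (strength / (2 * m))^2
  }
  q
}

# all partitions of a small set via restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(s, maxv) {
    if (length(s) == n) { out[[length(out) + 1]] <<- s; return(invisible()) }
    for (v in seq_len(maxv + 1)) rec(c(s, v), max(maxv, v))
  }
  rec(integer(0), 0)
  out
}

# adjusted Rand computed by the contingency-table formula, written
# independently of the package's implementation
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(tab * (tab - 1) / 2)
  ai <- sum(rowSums(tab) * (rowSums(tab) - 1) / 2)
  bj <- sum(colSums(tab) * (colSums(tab) - 1) / 2)
  ntot <- length(a) * (length(a) - 1) / 2
  (nij - ai * bj / ntot) / ((ai + bj) / 2 - ai * bj / ntot)
}
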