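`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force oracles.  These deliberately avoid the code
# paths (and vectorization) of the implementation: plain double/triple
# loops over an adjacency matrix and location sets.

oracle_tom <- function(A) {
  n <- nrow(A)
  k <- rowSums(A)
  S <- diag(1, n)
  dimnames(S) <- dimnames(A)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- A[i, j]
    for (u in seq_len(n)) {
      if (u != i && u != j) num <- num + A[i, u] * A[u, j]
    }
    S[i, j] <- num / (min(k[i], k[j]) + 1 - A[i, j])
  }
  S
}

# sets: named list protein -> character vector of locations
oracle_ltom <- function(A, sets) {
  n <- nrow(A)
  ids <- rownames(A)
  k <- rowSums(A)
  has_common <- function(ps) {
    common <- sets[[ps[1]]]
    if (is.null(common)) return(FALSE)
    for (p in ps[-1]) {
      common <- intersect(common, sets[[p]] %||% character())
    }
    length(common) > 0
  }
  S <- diag(1, n)
  dimnames(S) <- dimnames(A)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- A[i, j] * has_common(c(ids[i], ids[j]))
    for (u in seq_len(n)) {
      if (u != i && u != j) {
        num <- num + A[i, u] * A[u, j] * has_common(c(ids[i], ids[u], ids[j]))
      }
    }
    S[i, j] <- num / (min(k[i], k[j]) + 1 - A[i, j])
  }
  S
}

# all-pairs shortest paths by Floyd-Warshall on a 0/1 adjacency matrix
oracle_path_length <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (m in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, m] + D[m, j] < D[i, j]) D[i, j] <- D[i, m] + D[m, j]
  }
  vals <- D[upper.tri(D)]
  mean(vals[is.finite(vals)])
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] == 1)
    d <- length(nb)
    if (d < 2) { cc[v] <- 0; next }
    links <- 0
    for (a in nb) for (b in nb) if (a < b && A[a, b] == 1) links <- links + 1
    cc[v] <- 2 * links / (d * (d - 1))
  }
  mean(cc)
}

oracle_sn_ppv_acc <- function(pred, ref) {
  r <- length(pred); s <- length(ref)
  tt <- matrix(0, r, s)
  for (i in seq_len(r)) for (j in seq_len(s)) {
    tt[i, j] <- length(intersect(pred[[i]], ref[[j]]))
  }
  sn <- sum(apply(tt, 2, max)) / sum(lengths(ref))
  ppv <- if (sum(tt) == 0) 0 else sum(apply(tt, 1, max)) / sum(tt)
  c(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

# step-up BH written from the definition, independent of p.adjust
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# exhaustive upper-tail hypergeometric by summing the pmf terms
oracle_hyper <- function(t, n, T, N) {
  total <- 0
  for (i in t:n) {
    if (i > T || n - i > N - T) next
    total <- total + choose(T, i) * choose(N - T, n - i)
  }
  total / choose(N, n)
}

# random simple undirected graph as a ppi_network + adjacency
random_net <- function(n, p_edge, prefix = "N") {
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  pairs <- which(upper.tri(A), arr.ind = TRUE)
  on <- stats::runif(nrow(pairs)) < p_edge
  A[pairs[on, , drop = FALSE]] <- 1
  A <- A + t(A)
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  net <- as_ppi_network(
    data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]]),
    nodes = ids
  )
  list(net = net, A = A, ids = ids)
}

random_locs <- function(ids, max_labels = 3) {
  sets <- lapply(ids, function(p) {
    sample(loctom::major_locations, sample.int(max_labels, 1))
  })
  names(sets) <- ids
  loc <- localization_table(data.frame(
    protein = rep(ids, lengths(sets)),
    location = unlist(sets)
  ))
  list(loc = loc, sets = sets)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
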