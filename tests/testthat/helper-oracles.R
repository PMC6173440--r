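# independent brute-force oracles used across the suite

# direct transcription of the signed quality function: explicit double loop
# over ordered node pairs
oracle_signed_Q <- function(w, membership, resolution = 1) {
  diag(w) <- 0
  wp <- pmax(w, 0); wn <- pmax(-w, 0)
  vp <- sum(wp); vn <- sum(wn)
  sp <- rowSums(wp); sn <- rowSums(wn)
  n <- nrow(w)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (membership[i] != membership[j]) next
    q <- q + (wp[i, j] - resolution * sp[i] * sp[j] / vp) / vp
    if (vn > 0)
      q <- q - (wn[i, j] - resolution * sn[i] * sn[j] / vn) / (vp + vn)
  }
  q
}

# all set partitions of 1..n as membership vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1))
      rec(c(prefix, lab), max(maxlab, lab))
  }
  rec(integer(0), 0)
  out
}

# exhaustive maximum of the signed quality over every partition
oracle_best_partition <- function(w, resolution = 1) {
  parts <- all_partitions(nrow(w))
  qs <- vapply(parts, function(p) oracle_signed_Q(w, p, resolution),
               numeric(1))
  list(Q = max(qs), membership = parts[[which.max(qs)]])
}

# scalar-loop weighted Pearson correlation of two vectors
oracle_weighted_cor <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  sxy <- sum(w * (x - mx) * (y - my))
  sxx <- sum(w * (x - mx)^2)
  syy <- sum(w * (y - my)^2)
  sxy / sqrt(sxx * syy)
}

# exhaustive ECDF sup-difference evaluated at every sample point
oracle_ks <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(p) mean(a <= p) - mean(b <= p), numeric(1))))
}

# adjusted Rand index between two labelings
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- si * sj / n
  (sij - expected) / ((si + sj) / 2 - expected)
}

# small modular connectome shared by several tests
toy_connectome <- function(n_nodes = 30, seed = 7, ...) {
  generate_connectome(synthetic_connectome_spec(n_nodes = n_nodes,
                                                seed = seed, ...))
}
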