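# Brute-force enumeration oracles, independent of the package's
# implementations (different permutation algorithm, direct definitional
# sums). Used by the rank-test and Spearman exactness checks.

# all permutations of 1..n by Heap's algorithm
heap_perms <- function(n) {
  out <- list()
  a <- seq_len(n)
  gen <- function(k) {
    if (k == 1L) { out[[length(out) + 1L]] <<- a; return(invisible()) }
    for (i in seq_len(k)) {
      gen(k - 1L)
      j <- if (k %% 2L) 1L else i
      tmp <- a[j]; a[j] <<- a[k]; a[k] <<- tmp
    }
  }
  gen(n)
  do.call(rbind, out)
}

brute_spearman_p <- function(x, y) {
  r_obs <- cor(rank(x), rank(y))
  P <- heap_perms(length(y))
  rs <- apply(P, 1, function(p) cor(rank(x), rank(y)[p]))
  mean(abs(rs) >= abs(r_obs) - 1e-12)
}

brute_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  idx <- utils::combn(length(pooled), n1)
  ws <- apply(idx, 2, function(i) sum(r[i]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.numeric(signs %*% r)
  mu <- n * (n + 1) / 4
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}
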