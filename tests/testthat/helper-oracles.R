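# Fixture builders and independent brute-force oracles used across tests.

tiny_probe <- function(n = 8, cols = 2) make_probe(n, cols, 18, 22)

# Hand-built template set from a list of T x C waveform matrices.
manual_templates <- function(waves, sampling_rate = 32000, probe = NULL) {
  tlen <- nrow(waves[[1]])
  n_ch <- ncol(waves[[1]])
  if (is.null(probe)) probe <- make_probe(n_ch, 1, 18, 22)
  arr <- array(0, dim = c(length(waves), tlen, n_ch))
  for (u in seq_along(waves)) arr[u, , ] <- waves[[u]]
  structure(
    list(
      waveforms = arr,
      sampling_rate = sampling_rate,
      unit_positions = tibble::tibble(
        unit_id = seq_along(waves),
        x = 0, y = 0, z = 20
      ),
      probe = probe
    ),
    class = "template_set"
  )
}

# A fabricated similarity matrix with the right class/dimnames.
manual_similarity <- function(m, ids = seq_len(nrow(m))) {
  dimnames(m) <- list(as.character(ids), as.character(ids))
  class(m) <- c("similarity_matrix", class(m))
  m
}

spike_tbl <- function(unit_id, time, duration) {
  as_spike_trains(data.frame(unit_id = unit_id, time = time), duration = duration)
}

# Sequential keep-the-earlier refractory scan, the reference implementation.
seq_prune <- function(times, refractory_ms) {
  r <- refractory_ms / 1000
  kept <- numeric(0)
  last <- -Inf
  for (t in times) {
    if (t - last >= r) {
      kept <- c(kept, t)
      last <- t
    }
  }
  kept
}

# Maximum one-to-one matching size between two spike trains under |dt| <=
# delta, via augmenting paths on the bipartite compatibility graph (Kuhn's
# algorithm). Independent of the package's two-pointer greedy.
bf_max_matching <- function(a, b, delta) {
  na <- length(a)
  nb <- length(b)
  if (na == 0 || nb == 0) return(0L)
  adj <- lapply(seq_len(na), function(i) which(abs(b - a[i]) <= delta))
  match_b <- rep(0L, nb)
  aug <- function(i, seen) {
    for (j in adj[[i]]) {
      if (!seen$v[j]) {
        seen$v[j] <- TRUE
        if (match_b[j] == 0L || aug(match_b[j], seen)) {
          match_b[j] <<- i
          return(TRUE)
        }
      }
    }
    FALSE
  }
  n <- 0L
  for (i in seq_len(na)) {
    seen <- new.env()
    seen$v <- rep(FALSE, nb)
    if (aug(i, seen)) n <- n + 1L
  }
  n
}

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1)
    }
  }
  out
}

# Brute-force best one-to-one assignment total on a score matrix.
bf_best_assignment <- function(s) {
  n <- nrow(s)
  m <- ncol(s)
  transposed <- n > m
  if (transposed) s <- t(s)
  n <- nrow(s)
  m <- ncol(s)
  best <- 0
  for (p in all_perms(m)) {
    tot <- sum(s[cbind(seq_len(n), p[seq_len(n)])])
    if (tot > best) best <- tot
  }
  best
}

# Brute-force O(n^2) correlogram oracle: counts of tj - ti in (lo, hi] bins.
bf_ccg <- function(ti, tj, edges_ms) {
  d <- as.vector(outer(tj, ti, "-")) * 1000
  counts <- integer(length(edges_ms) - 1)
  for (k in seq_len(length(edges_ms) - 1)) {
    counts[k] <- sum(d > edges_ms[k] & d <= edges_ms[k + 1])
  }
  counts
}
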