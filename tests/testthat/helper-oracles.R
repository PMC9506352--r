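# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths wherever they check one.

# dense grid search for the maximum of the double-exponential transient
grid_argmax_transient <- function(rise_tau, decay_tau, resolution = 1e-3) {
  dt <- seq(0, 20 * decay_tau, by = resolution)
  f <- exp(-dt / decay_tau) - exp(-dt / rise_tau)
  dt[which.max(f)]
}

# high-resolution trapezoid integral of an arbitrary function (oracle for
# closed-form AUCs)
numeric_integral <- function(f, from, to, n = 2e5) {
  x <- seq(from, to, length.out = n)
  y <- f(x)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Brute-force verification of a compact letter display against a
# significance matrix: two groups share a letter iff non-significant.
cld_consistent <- function(letters_vec, sig_matrix) {
  m <- length(letters_vec)
  sets <- strsplit(letters_vec, "")
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      share <- length(intersect(sets[[i]], sets[[j]])) > 0
      if (share == sig_matrix[i, j]) return(FALSE)  # share xor non-sig
    }
  }
  TRUE
}

# Brute-force minimal clique cover of the non-significance graph (adjacency
# = !sig, diag TRUE), by exhaustive search over clique subsets; feasible for
# <= 6 groups. Returns the minimal number of cliques needed to cover all
# non-significant edges and isolated vertices.
min_clique_cover_size <- function(sig_matrix) {
  m <- nrow(sig_matrix)
  adj <- !sig_matrix
  diag(adj) <- TRUE
  subsets <- lapply(seq_len(2^m - 1), function(code) {
    which(bitwAnd(code, 2^(seq_len(m) - 1)) > 0)
  })
  is_clique <- vapply(subsets, function(s) all(adj[s, s, drop = FALSE]),
                      logical(1))
  cliques <- subsets[is_clique]
  # edges (and lone vertices) to cover
  need <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  for (size in 1:m) {
    combos <- utils::combn(length(cliques), size, simplify = FALSE)
    for (cb in combos) {
      cover <- cliques[cb]
      verts_ok <- all(seq_len(m) %in% unlist(cover))
      edges_ok <- all(apply(need, 1, function(e) {
        any(vapply(cover, function(s) all(e %in% s), logical(1)))
      }))
      if (nrow(need) == 0) edges_ok <- TRUE
      if (verts_ok && edges_ok) return(size)
    }
  }
  m
}

# flat calcium trace at a constant (resting-range) level
new_ca_trace_for_test <- function(times, ca) {
  make_ca_trajectory(ca_kinetics(baseline = ca), times)
}

# default acquisition used by round-trip tests
roundtrip_config <- function(run_duration = 2000, discharge_time = 1900) {
  plate_run_config(run_duration = run_duration,
                   discharge_time = discharge_time)
}
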