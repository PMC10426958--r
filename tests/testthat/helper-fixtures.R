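# Small fixtures built in code.

# symmetric toy connectome with explicit numbers
toy_connectome <- function() {
  w <- matrix(c(0, 2, 1,
                2, 0, 3,
                1, 3, 0), 3, 3)
  l <- matrix(c(0, 20, 35,
                20, 0, 50,
                35, 50, 0), 3, 3)
  structural_connectome(w, l, c("ctx_a", "ctx_b", "th_a"),
                        c("cortical", "cortical", "thalamic"),
                        subject_id = "toy")
}

# random valid connectome with a driver group
random_connectome <- function(n = 8, n_driver = 2, seed = 1) {
  set.seed(seed)
  n_total <- n
  w <- matrix(0, n_total, n_total)
  w[upper.tri(w)] <- stats::rexp(n_total * (n_total - 1) / 2)
  w <- w + t(w)
  l <- matrix(0, n_total, n_total)
  l[upper.tri(l)] <- stats::runif(n_total * (n_total - 1) / 2, 10, 150)
  l <- l + t(l)
  l[w == 0] <- 0
  roles <- c(rep("cortical", n_total - n_driver), rep("thalamic", n_driver))
  structural_connectome(w, l, sprintf("r%02d", seq_len(n_total)), roles,
                        subject_id = sprintf("rand%d", seed))
}

# isolated single-node connectome (uncoupled column)
single_node <- function(role = "cortical") {
  structural_connectome(matrix(0, 1, 1), matrix(0, 1, 1), "node_1", role)
}

# n uncoupled nodes (diagonal-free zero matrix)
uncoupled_nodes <- function(n, role = "cortical") {
  structural_connectome(matrix(0, n, n), matrix(0, n, n),
                        sprintf("node_%d", seq_len(n)), rep(role, n))
}
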