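# Shared test fixtures and independent oracles.

# Random descriptor-like table with non-degenerate continuous columns.
random_table <- function(n, seed) {
  set.seed(seed)
  data.frame(agent_id = as.character(seq_len(n)),
             log_p = rnorm(n, 2.5, 0.6),
             psa = runif(n, 40, 120),
             n_atoms = sample(10:25, n, replace = TRUE),
             fw = runif(n, 150, 450),
             n_on = sample(2:8, n, replace = TRUE),
             n_ohnh = sample(0:4, n, replace = TRUE),
             n_rot = sample(0:10, n, replace = TRUE),
             volume = runif(n, 120, 380),
             stringsAsFactors = FALSE)
}

# Brute-force O(n^3) single-linkage agglomeration on a distance matrix.
# Ties broken by the lexicographically smallest pair of active cluster
# indices. Returns per-merge member sets (sorted) and heights.
single_linkage_oracle <- function(dmat, labels) {
  clusters <- lapply(seq_along(labels), function(i) labels[i])
  active <- seq_along(labels)
  idx <- lapply(seq_along(labels), function(i) i)
  merges <- list()
  while (length(active) > 1L) {
    best <- NULL
    for (ai in seq_along(active)) {
      for (bi in seq_along(active)) {
        if (bi <= ai) next
        a <- active[ai]; b <- active[bi]
        h <- min(dmat[idx[[a]], idx[[b]]])
        if (is.null(best) || h < best$h) best <- list(a = a, b = b, h = h)
      }
    }
    merged_members <- sort(c(clusters[[best$a]], clusters[[best$b]]))
    merges[[length(merges) + 1L]] <- list(members = merged_members, height = best$h)
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    idx[[best$a]] <- c(idx[[best$a]], idx[[best$b]])
    active <- setdiff(active, best$b)
  }
  merges
}

# Normal-equation OLS (independent of lm).
ols_oracle <- function(y, X) {
  X1 <- cbind(1, as.matrix(X))
  beta <- solve(t(X1) %*% X1, t(X1) %*% y)
  fitted <- drop(X1 %*% beta)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(beta = drop(beta), r_squared = 1 - ss_res / ss_tot)
}

lomustine_smiles <- "ClCCN(N=O)C(=O)NC1CCCCC1"

# element / bond-order multisets for canonicalization round-trip checks
atom_multiset <- function(m) sort(paste0(m$atoms$element, "H", m$atoms$n_h))
bond_multiset <- function(m) sort(m$bonds$order)
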