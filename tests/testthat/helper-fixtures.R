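# Shared fixtures built in code.

# Small protein matrix with a known missingness pattern and flags.
make_pm <- function(n_prot = 8, n_samp = 6, seed = 42, flags = NULL,
                    meta = NULL) {
  set.seed(seed)
  samp <- if (is.null(meta)) sprintf("S%d", seq_len(n_samp)) else meta$sample
  vals <- matrix(rnorm(n_prot * n_samp, mean = 25, sd = 2), n_prot, n_samp,
                 dimnames = list(sprintf("P%03d", seq_len(n_prot)), samp))
  protein_matrix(vals, meta = meta, flags = flags)
}

# Replicated-line metadata: n_lines lines x n_rep replicates.
make_line_meta <- function(n_lines, n_rep = 3, groups = NULL) {
  lines <- sprintf("L%02d", seq_len(n_lines))
  data.frame(sample = as.vector(t(outer(lines, seq_len(n_rep),
                                        function(l, r) sprintf("%s_R%d", l, r)))),
             line = rep(lines, each = n_rep),
             replicate = rep(seq_len(n_rep), times = n_lines),
             group = if (is.null(groups)) NA else rep(groups, each = n_rep),
             stringsAsFactors = FALSE)
}

# Dense least-squares oracle for profile reconstruction: solve the
# overdetermined incidence system with qr.solve, anchored at node 1,
# then renormalize to the observed total.
oracle_profile <- function(samples, edges, totals) {
  m <- length(samples)
  A <- matrix(0, nrow(edges), m)
  for (k in seq_len(nrow(edges))) {
    A[k, match(edges$a[k], samples)] <- 1
    A[k, match(edges$b[k], samples)] <- -1
  }
  # minimise ||A x - r|| with the gauge x[1] = 0
  x <- c(0, qr.solve(A[, -1, drop = FALSE], edges$log2_ratio))
  x + log2(sum(totals) / sum(2^x))
}

# Exhaustive two-sided Fisher p: sum of probabilities of all tables with
# the observed margins whose probability does not exceed the observed
# table's (up to a relative tolerance, as in the standard convention).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Step-up Benjamini-Hochberg by the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}
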