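# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library code never perturbs user-level reproducibility.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Row-wise mean/variance over a matrix with NAs, without matrixStats.
row_stats <- function(x) {
  n <- rowSums(!is.na(x))
  s <- rowSums(x, na.rm = TRUE)
  m <- ifelse(n > 0, s / n, NA_real_)
  ss <- rowSums(x^2, na.rm = TRUE)
  v <- ifelse(n > 1, (ss - n * m^2) / (n - 1), NA_real_)
  v[v < 0] <- 0  # guard against tiny negative round-off
  list(n = n, mean = m, var = v)
}

# Connected components of an undirected graph on `nodes` given an edge list
# (two character vectors a, b). Returns an integer component id per node.
graph_components <- function(nodes, a, b) {
  comp <- stats::setNames(seq_along(nodes), nodes)
  # union-find with path compression
  find <- function(i) {
    while (comp[[i]] != i) {
      comp[[i]] <<- comp[[comp[[i]]]]
      i <- comp[[i]]
    }
    i
  }
  ia <- match(a, nodes); ib <- match(b, nodes)
  for (k in seq_along(ia)) {
    ra <- find(ia[k]); rb <- find(ib[k])
    if (ra != rb) comp[[rb]] <- ra
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  match(roots, unique(roots))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x) && x >= min
}
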