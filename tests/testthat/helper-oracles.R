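# Independent oracles and small fixture builders shared across tests.
# The oracles re-derive each quantity from first principles (enumeration,
# naive definitions) and deliberately share no code with the package.

# Inverse-variance fixed-effect combination, written out longhand.
oracle_fixed <- function(theta, v) {
  num <- 0; den <- 0
  for (i in seq_along(theta)) {
    num <- num + theta[i] / v[i]
    den <- den + 1 / v[i]
  }
  mu <- num / den
  se <- sqrt(1 / den)
  list(effect = mu, se = se, p = 2 * pnorm(-abs(mu / se)))
}

# Cochran's Q / df / ISq from the printed formula.
oracle_het <- function(theta, v) {
  mu <- oracle_fixed(theta, v)$effect
  Q <- 0
  for (i in seq_along(theta)) Q <- Q + (theta[i] - mu)^2 / v[i]
  df <- length(theta) - 1
  list(Q = Q, df = df, ISq = if (Q > df) 100 * (Q - df) / Q else 0)
}

# DerSimonian-Laird moment estimator and re-weighted combination.
oracle_dl <- function(theta, v) {
  het <- oracle_het(theta, v)
  w <- 1 / v
  C <- sum(w) - sum(w * w) / sum(w)
  tau2 <- max(0, (het$Q - het$df) / C)
  ws <- 1 / (v + tau2)
  mu <- sum(ws * theta) / sum(ws)
  se <- sqrt(1 / sum(ws))
  list(effect = mu, se = se, p = 2 * pnorm(-abs(mu / se)), tau2 = tau2)
}

# Closed-form chi-square survival function for df in 1..4, derived from
# the recurrence P(X_k > Q) = P(X_{k-2} > Q) + (Q/2)^(k/2-1) e^(-Q/2) / Gamma(k/2);
# tail-accurate, unlike 1 - CDF.
oracle_chisq_upper <- function(Q, df) {
  switch(df,
         2 * pnorm(-sqrt(Q)),
         exp(-Q / 2),
         2 * pnorm(-sqrt(Q)) + sqrt(2 * Q / pi) * exp(-Q / 2),
         exp(-Q / 2) * (1 + Q / 2),
         stop("oracle covers df 1..4 only"))
}

# Exact upper-tail hypergeometric by enumeration of all C(N, n) draws.
# Feasible for N <= 12; returns P(overlap >= k).
oracle_hyper_enum <- function(N, K, n, k) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  draws <- combn(N, n)
  hits <- 0
  for (j in seq_len(ncol(draws)))
    if (sum(draws[, j] <= K) >= k) hits <- hits + 1
  hits / ncol(draws)
}

# Naive O(m^2) Benjamini-Hochberg: q_i = min over thresholds t = p_j with
# p_j >= p_i of m * t / #{p <= t}, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- p[p >= p[i]]
    vals <- vapply(cand, function(t) m * t / sum(p <= t), 0)
    q[i] <- min(1, vals)
  }
  q
}

# All unordered gene pairs co-occurring in passing overlaps, counted by
# direct double loop.
oracle_ggi <- function(overlaps) {
  counts <- list()
  for (ov in overlaps) {
    g <- sort(unique(ov))
    if (length(g) < 2) next
    for (a in seq_len(length(g) - 1)) for (b in (a + 1):length(g)) {
      key <- paste(g[a], g[b], sep = "\r")
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  if (length(counts) == 0)
    return(data.frame(gene_a = character(), gene_b = character(),
                      shared = integer(), stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(names(counts), "\r", fixed = TRUE))
  out <- data.frame(gene_a = parts[, 1], gene_b = parts[, 2],
                    shared = unlist(counts, use.names = FALSE),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), ]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A tiny handmade two-group dataset used across I/O and effect tests.
tiny_dataset <- function(id = "DS1") {
  m <- rbind(g1 = c(5, 7, 4, 4.5),
             g2 = c(3, 3, 2, 2),
             g3 = c(1, 2, 3, 4))
  colnames(m) <- c("c1", "c2", "k1", "k2")
  expression_dataset(id, m, c("case", "case", "control", "control"),
                     dataset_meta(id, n_control = 2, n_case = 2,
                                  country = "Sweden", study_age = 5))
}

# Random per-study effect instances for oracle-equivalence loops.
random_instance <- function(k = sample(2:5, 1)) {
  list(theta = rnorm(k, 0, 2), v = runif(k, 0.05, 2))
}
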