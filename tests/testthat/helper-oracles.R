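# Independent brute-force oracles used across the suite. These deliberately
# restate each definition in the most literal (slow) form.

# literal risk-table log-rank: loop over distinct event times
brute_logrank <- function(time, event, group) {
  et <- sort(unique(time[event == 1]))
  OmE <- 0; V <- 0; O1 <- 0; E1 <- 0
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- (O1 - E1)^2 / V
  list(o_minus_e = O1 - E1, variance = V, chi_square = chi,
       p_value = pchisq(chi, 1, lower.tail = FALSE))
}

# literal BH step-up on the sorted vector, mapped back
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(pmin(m * ps[i:m] / (i:m), 1))
  out <- numeric(m)
  out[ord] <- q
  out
}

# tie-corrected Mann-Whitney AUC: P(responder score < non-responder score)
# + half ties (low scores predict response)
brute_auc_mw <- function(scores, labels) {
  sp <- scores[labels]
  sn <- scores[!labels]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a < b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# literal single-sample enrichment running sum
brute_ssgsea <- function(x, set_genes, alpha) {
  n <- length(x)
  ord <- order(x, decreasing = TRUE)
  r <- rank(x)
  genes <- names(x)[ord]
  inset <- genes %in% set_genes
  w <- r[ord]^alpha
  p_in <- 0; p_out <- 0; es <- 0
  win <- sum(w[inset])
  for (i in seq_len(n)) {
    if (inset[i]) p_in <- p_in + w[i] / win else p_out <- p_out + 1 / (n - sum(inset))
    es <- es + (p_in - p_out)
  }
  unname(es)
}

# Mann-Whitney U of x over y with half-credit ties
brute_u <- function(x, y) {
  u <- 0
  for (a in x) for (b in y) u <- u + (a > b) + 0.5 * (a == b)
  u
}

# small expression fixture: g genes x s samples, positive values, seeded
rand_expr <- function(g, s, seed = 1) {
  set.seed(seed)
  m <- matrix(rexp(g * s) + 0.01, nrow = g,
              dimnames = list(sprintf("g%02d", seq_len(g)),
                              sprintf("s%02d", seq_len(s))))
  m
}

# random strictly increasing transform per sample (distinct per column)
monotone_distort <- function(expr, seed = 1) {
  set.seed(seed)
  out <- expr
  fns <- list(function(x) x^2, function(x) log1p(x), function(x) 5 * x + 2,
              function(x) exp(x / max(x)), function(x) rank(x) / length(x))
  for (j in seq_len(ncol(expr))) {
    f <- fns[[(j - 1) %% length(fns) + 1]]
    out[, j] <- f(expr[, j])
  }
  out
}

# exponential survival with a binary-covariate planted log-hazard
sim_surv <- function(n, log_hr, seed, base = 0.05, cens = 0.02) {
  set.seed(seed)
  g <- rbinom(n, 1, 0.5)
  t <- rexp(n, rate = base * exp(log_hr * g))
  cns <- rexp(n, rate = cens)
  list(time = pmin(t, cns), event = as.integer(t <= cns), group = g)
}
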