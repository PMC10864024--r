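# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately use brute-force / direct-formula routes that share
# no code with the implementation they check.

cfg0 <- protocol_config()

ts0 <- function(x) as.POSIXct(x, tz = "UTC")

# quick bout stream from offsets (seconds) relative to a base time
make_stream <- function(offsets_s, durations_s, masses_g,
                        base = ts0("2024-01-01 06:30:00"),
                        id = "m1", window = NULL) {
  bout_stream(tibble::tibble(t_start = base + offsets_s,
                             duration_s = durations_s,
                             mass_g = masses_g),
              animal_id = id, window = window)
}

# random small stream with a mix of short and long gaps
random_stream <- function(n_bouts, base = ts0("2024-01-01 06:30:00")) {
  durations <- stats::runif(n_bouts, 1, 60)
  gaps <- ifelse(stats::runif(n_bouts - 1) < 0.6,
                 stats::runif(n_bouts - 1, 0, 400),
                 stats::runif(n_bouts - 1, 400, 5000))
  offsets <- cumsum(c(0, durations[-n_bouts] + gaps))
  make_stream(offsets, durations, stats::runif(n_bouts, 0.001, 0.08),
              base = base)
}

# O(n^2) brute-force partition: bout j shares a cluster with bout i iff
# every consecutive end-to-start gap between them is below the threshold
oracle_partition <- function(t_start_s, duration_s, thr) {
  n <- length(t_start_s)
  if (!n) return(integer())
  lab <- seq_len(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    gaps <- t_start_s[(i + 1):j] - (t_start_s[i:(j - 1)] + duration_s[i:(j - 1)])
    if (all(gaps < thr)) lab[j] <- lab[i]
  }
  match(lab, unique(lab))
}

# direct-formula Tukey-Kramer adjusted p for every group pair
oracle_tukey <- function(y, g) {
  g <- factor(g)
  k <- nlevels(g)
  N <- length(y)
  ni <- tapply(y, g, length)
  mi <- tapply(y, g, mean)
  mse <- sum((y - stats::ave(y, g))^2) / (N - k)
  prs <- utils::combn(levels(g), 2, simplify = FALSE)
  out <- lapply(prs, function(pr) {
    se <- sqrt(mse / 2 * (1 / ni[[pr[1]]] + 1 / ni[[pr[2]]]))
    q <- abs(mi[[pr[1]]] - mi[[pr[2]]]) / se
    data.frame(contrast = paste(pr[2], pr[1], sep = "-"),
               diff = mi[[pr[2]]] - mi[[pr[1]]],
               p_adj = stats::ptukey(q, k, N - k, lower.tail = FALSE))
  })
  do.call(rbind, out)
}

# direct-formula Grubbs two-sided test
oracle_grubbs <- function(x, alpha = 0.05) {
  n <- length(x)
  G <- max(abs(x - mean(x))) / stats::sd(x)
  tcrit <- stats::qt(alpha / (2 * n), n - 2, lower.tail = FALSE)
  crit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  list(G = G, critical = crit, flagged = G > crit)
}
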