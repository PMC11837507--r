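# Independent oracles and small fixture builders shared across tests.

# Brute-force classical Passing-Bablok: explicit enumeration of all pairwise
# slopes and the shifted-median rule, written independently of the package's
# vectorized estimator.
pb_brute_force <- function(x, y) {
  n <- length(x)
  s <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dx <- x[j] - x[i]
      dy <- y[j] - y[i]
      if (dx == 0) next
      v <- dy / dx
      if (v == -1) next
      s <- c(s, v)
    }
  }
  if (length(s) == 0) return(c(slope = NA_real_, intercept = NA_real_))
  s <- sort(s)
  n_s <- length(s)
  k <- sum(s < -1)
  idx <- if (n_s %% 2 == 1) {
    min((n_s + 1) %/% 2 + k, n_s)
  } else {
    NA
  }
  slope <- if (n_s %% 2 == 1) {
    s[idx]
  } else {
    i1 <- min(n_s %/% 2 + k, n_s)
    i2 <- min(n_s %/% 2 + 1 + k, n_s)
    (s[i1] + s[i2]) / 2
  }
  c(slope = slope, intercept = median(y - slope * x))
}

# Closed-form one-way ANOVA for two groups (sum-of-squares arithmetic).
anova_two_group_oracle <- function(a, b) {
  gm <- mean(c(a, b))
  ssb <- length(a) * (mean(a) - gm)^2 + length(b) * (mean(b) - gm)^2
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  df2 <- length(a) + length(b) - 2
  f <- ssb / (ssw / df2)
  c(F = f, p = pf(f, 1, df2, lower.tail = FALSE))
}

# A small hand-built experiment: n_plots plots at each of two sites, one
# control + field + lab tube per plot, n_frac fractions per tube, counts for
# named genera placed with simple per-tube profiles.
toy_samples <- function(n_plots = 2, sites = c("Valley", "Ridge")) {
  do.call(rbind, lapply(sites, function(s) {
    do.call(rbind, lapply(seq_len(n_plots), function(p) {
      data.frame(
        sample_id = paste0(s, "_P", p, c("_pre", "_field", "_lab")),
        site = s, method = c("none", "field", "lab"), plot = p,
        label = c("unlabeled", "labeled", "labeled"),
        stringsAsFactors = FALSE)
    }))
  }))
}

toy_fractions <- function(samples, densities = c(1.68, 1.70, 1.72),
                          total_copies = 100) {
  do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
    tid <- paste0("T_", samples$sample_id[i])
    data.frame(tube_id = tid, sample_id = samples$sample_id[i],
               fraction_id = paste0(tid, "_F", seq_along(densities)),
               density = densities, total_copies = total_copies,
               stringsAsFactors = FALSE)
  }))
}
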