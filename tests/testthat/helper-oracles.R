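# Independent brute-force oracles, written against the textbook definitions
# and kept structurally separate from the package's implementations.

# Kruskal-Wallis H via explicit mid-ranks and explicit tie correction:
# H = [12 / (n(n+1))] * sum n_i (Rbar_i - (n+1)/2)^2, divided by
# 1 - sum(t^3 - t) / (n^3 - n) over tie groups.
oracle_kw_h <- function(x, g) {
  n <- length(x)
  # mid-ranks by hand
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i])
    eq <- sum(x == x[i])
    r[i] <- less + (eq + 1) / 2
  }
  num <- 0
  for (lev in unique(g)) {
    ri <- r[g == lev]
    num <- num + length(ri) * (mean(ri) - (n + 1) / 2)^2
  }
  h <- 12 / (n * (n + 1)) * num
  tie_term <- 0
  for (v in unique(x)) {
    t <- sum(x == v)
    tie_term <- tie_term + t^3 - t
  }
  corr <- 1 - tie_term / (n^3 - n)
  if (corr == 0) 0 else h / corr
}

# Top-k Kendall distance with penalty p: exhaustive enumeration over every
# unordered pair of elements of the union, one if/else per case.
oracle_topk_kendall <- function(a, b, p = 0.5) {
  k <- length(a)
  u <- union(a, b)
  total <- 0
  if (length(u) >= 2) {
    for (ii in 1:(length(u) - 1)) {
      for (jj in (ii + 1):length(u)) {
        i <- u[ii]; j <- u[jj]
        ia <- match(i, a); ja <- match(j, a)
        ib <- match(i, b); jb <- match(j, b)
        in_a <- !is.na(ia) && !is.na(ja)
        in_b <- !is.na(ib) && !is.na(jb)
        if (in_a && in_b) {
          # both lists order the pair
          if (sign(ia - ja) != sign(ib - jb)) total <- total + 1
        } else if (in_a && (!is.na(ib) || !is.na(jb))) {
          # both in a, exactly one in b: penalize if a ranks the b-absent
          # element ahead of the b-present one
          present_b <- if (!is.na(ib)) i else j
          pos_present <- if (present_b == i) ia else ja
          pos_absent <- if (present_b == i) ja else ia
          if (pos_absent < pos_present) total <- total + 1
        } else if (in_b && (!is.na(ia) || !is.na(ja))) {
          present_a <- if (!is.na(ia)) i else j
          pos_present <- if (present_a == i) ib else jb
          pos_absent <- if (present_a == i) jb else ib
          if (pos_absent < pos_present) total <- total + 1
        } else if ((!is.na(ia) && !is.na(jb)) || (!is.na(ja) && !is.na(ib))) {
          # one element exclusive to each list
          total <- total + 1
        } else {
          # both elements confined to the same single list
          total <- total + p
        }
      }
    }
  }
  total / (k^2 + 2 * p * choose(k, 2))
}

# Two-sided Fisher exact p by hypergeometric enumeration: sum of the
# probabilities of all tables (fixed margins) no more probable than the
# observed one.
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_obs <- tab[1, 1]
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(a_range, c1, n - c1, r1)
  p_obs <- dhyper(a_obs, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small deterministic feature matrix + labels for split/selection tests
make_toy_matrix <- function(n = 30, m = 40, n_signal = 4, shift = 2,
                            seed = 42) {
  set.seed(seed)
  labels <- rep(c(TRUE, FALSE), length.out = n)
  x <- matrix(rnorm(n * m), n, m,
              dimnames = list(NULL, sprintf("v%03d", seq_len(m))))
  if (n_signal > 0) {
    x[labels, seq_len(n_signal)] <- x[labels, seq_len(n_signal)] + shift
  }
  list(x = x, labels = labels)
}

# Hand-built two-session fixture with known per-zone values
make_manual_session <- function(id, speed, posted = rep(45, length(speed)),
                                zones, rate = 10,
                                events = data.frame(t_sec = numeric(),
                                                    type = character(),
                                                    zone_id = character())) {
  n <- length(speed)
  replay_session(
    session_id = id, sample_rate_hz = rate,
    channels = data.frame(
      speed_mph = speed,
      posted_speed_mph = posted,
      lane_offset_m = seq(-0.1, 0.1, length.out = n),
      center_offset_m = rep(1, n) + seq_len(n) * 1e-3,
      heading_deg = rep(90, n),
      road_heading_deg = rep(90, n),
      steering_frac = sin(seq_len(n))
    ),
    zone_track = zones, events = events
  )
}
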