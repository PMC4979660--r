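# Independent oracles: literal scalar-loop transcriptions of the published
# formulas, kept deliberately separate from the package's vectorized
# implementations, plus a brute-force urn sampler.

oracle_beta <- function(name, x, y, ness_m = 10) {
  S <- length(x)
  X <- 0; Y <- 0
  for (i in 1:S) { X <- X + x[i]; Y <- Y + y[i] }
  a <- 0; b <- 0; cc <- 0
  for (i in 1:S) {
    if (x[i] > 0 && y[i] > 0) a <- a + 1
    else if (x[i] > 0) b <- b + 1
    else if (y[i] > 0) cc <- cc + 1
  }
  W <- 0; AD <- 0; MX <- 0
  for (i in 1:S) {
    W <- W + min(x[i], y[i])
    AD <- AD + abs(x[i] - y[i])
    MX <- MX + max(x[i], y[i])
  }
  H <- function(p) { h <- 0; for (v in p) if (v > 0) h <- h - v * log(v); h }
  p <- x / X; q <- y / Y
  clamp <- function(v) max(0, min(1, v))
  switch(name,
    sim = if (min(b, cc) + a == 0) 0 else min(b, cc) / (min(b, cc) + a),
    classic_sorensen = (b + cc) / (2 * a + b + cc),
    classic_jaccard = (b + cc) / (a + b + cc),
    bray_curtis = AD / (X + Y),
    ruzicka = AD / MX,
    renkonen = { s <- 0; for (i in 1:S) s <- s + min(p[i], q[i]); clamp(1 - s) },
    kulczynski = clamp(1 - (W / X + W / Y) / 2),
    morisita = {
      num <- 0; for (i in 1:S) num <- num + x[i] * y[i]
      num <- 2 * num
      if (num == 0) 1
      else if (X <= 1 || Y <= 1) NA_real_
      else {
        l1 <- 0; l2 <- 0
        for (i in 1:S) { l1 <- l1 + x[i] * (x[i] - 1); l2 <- l2 + y[i] * (y[i] - 1) }
        den <- (l1 / (X * (X - 1)) + l2 / (Y * (Y - 1))) * X * Y
        if (den <= 0) NA_real_ else clamp(1 - num / den)
      }
    },
    morisita_horn = {
      num <- 0; d1 <- 0; d2 <- 0
      for (i in 1:S) { num <- num + p[i] * q[i]; d1 <- d1 + p[i]^2; d2 <- d2 + q[i]^2 }
      clamp(1 - 2 * num / (d1 + d2))
    },
    horn = {
      s <- 0
      for (i in 1:S) {
        z <- p[i] + q[i]
        if (z > 0) s <- s + z * log(z)
        if (p[i] > 0) s <- s - p[i] * log(p[i])
        if (q[i] > 0) s <- s - q[i] * log(q[i])
      }
      clamp(1 - s / (2 * log(2)))
    },
    jost_shannon = max(exp(H((p + q) / 2) - (H(p) + H(q)) / 2) - 1, 0),
    jost_simpson = {
      sm <- 0; d1 <- 0; d2 <- 0
      for (i in 1:S) { sm <- sm + ((p[i] + q[i]) / 2)^2; d1 <- d1 + p[i]^2; d2 <- d2 + q[i]^2 }
      clamp((1 / sm) / (2 / (d1 + d2)) - 1)
    },
    lande_shannon = max(H((x + y) / (X + Y)) - (H(p) + H(q)) / 2, 0),
    lande_simpson = {
      gs <- function(v) { s <- 0; for (u in v) s <- s + u^2; 1 - s }
      max(gs((x + y) / (X + Y)) - (gs(p) + gs(q)) / 2, 0)
    },
    canberra = {
      s <- 0; n <- 0
      for (i in 1:S) if (x[i] + y[i] > 0) {
        s <- s + abs(x[i] - y[i]) / (x[i] + y[i]); n <- n + 1
      }
      s / n
    },
    gower = { s <- 0; for (i in 1:S) if (x[i] != y[i]) s <- s + 1; s / S },
    alt_gower = {
      n <- 0; for (i in 1:S) if (x[i] + y[i] > 0) n <- n + 1
      AD / n
    },
    manhattan = AD,
    euclidean = { s <- 0; for (i in 1:S) s <- s + (x[i] - y[i])^2; sqrt(s) },
    av_euclidean = {
      s <- 0; n <- 0
      for (i in 1:S) { s <- s + (x[i] - y[i])^2; if (x[i] + y[i] > 0) n <- n + 1 }
      sqrt(s / n)
    },
    binomial = {
      s <- 0
      for (i in 1:S) {
        n <- x[i] + y[i]
        if (n > 0) {
          tx <- if (x[i] > 0) x[i] * log(x[i] / n) else 0
          ty <- if (y[i] > 0) y[i] * log(y[i] / n) else 0
          s <- s + (tx + ty + n * log(2)) / n
        }
      }
      s
    },
    cyd = {
      s <- 0; n <- 0
      for (i in 1:S) if (x[i] + y[i] > 0) {
        xi <- if (x[i] == 0) 0.1 else x[i]
        yi <- if (y[i] == 0) 0.1 else y[i]
        ni <- xi + yi
        s <- s + log(ni / 2) - (xi * log(yi) + yi * log(xi)) / ni
        n <- n + 1
      }
      s / n
    },
    ness = {
      if (X < ness_m || Y < ness_m) return(NA_real_)
      pr <- function(tot, ab) {
        if (tot - ab < ness_m) 1 else
          1 - exp(lchoose(tot - ab, ness_m) - lchoose(tot, ness_m))
      }
      eab <- 0; eaa <- 0; ebb <- 0
      for (i in 1:S) {
        pa <- pr(X, x[i]); pb <- pr(Y, y[i])
        eab <- eab + pa * pb; eaa <- eaa + pa^2; ebb <- ebb + pb^2
      }
      clamp(1 - 2 * eab / (eaa + ebb))
    },
    chao_sorensen = {
      uv <- oracle_chao_uv(x, y)
      if (uv[1] + uv[2] == 0) 1 else
        clamp(1 - 2 * uv[1] * uv[2] / (uv[1] + uv[2]))
    },
    chao_jaccard = {
      uv <- oracle_chao_uv(x, y)
      if (uv[1] + uv[2] == 0) 1 else
        clamp(1 - uv[1] * uv[2] / (uv[1] + uv[2] - uv[1] * uv[2]))
    },
    baselga_bc_turn = {
      bb <- X - W; cb <- Y - W; m <- min(bb, cb)
      if (m == 0) 0 else m / (W + m)
    },
    baselga_r_turn = {
      bb <- X - W; cb <- Y - W; m <- min(bb, cb)
      if (m == 0) 0 else 2 * m / (W + 2 * m)
    },
    podani_bc_turn = 2 * min(X - W, Y - W) / (X + Y),
    podani_r_turn = 2 * min(X - W, Y - W) / (W + AD),
    stop("oracle has no formula for ", name))
}

oracle_chao_uv <- function(x, y) {
  X <- sum(x); Y <- sum(y)
  U <- 0; V <- 0; f1y <- 0; f2y <- 0; f1x <- 0; f2x <- 0
  u1 <- 0; v1 <- 0
  for (i in seq_along(x)) {
    if (x[i] > 0 && y[i] > 0) {
      U <- U + x[i] / X
      V <- V + y[i] / Y
      if (y[i] == 1) { f1y <- f1y + 1; u1 <- u1 + x[i] / X }
      if (y[i] == 2) f2y <- f2y + 1
      if (x[i] == 1) { f1x <- f1x + 1; v1 <- v1 + y[i] / Y }
      if (x[i] == 2) f2x <- f2x + 1
    }
  }
  U <- U + (Y - 1) / Y * f1y / (2 * max(f2y, 1)) * u1
  V <- V + (X - 1) / X * f1x / (2 * max(f2x, 1)) * v1
  c(min(U, 1), min(V, 1))
}

# brute-force urn sampler: draw n individuals one at a time without
# replacement from an abundance vector
urn_subsample <- function(abundances, n) {
  urn <- rep(seq_along(abundances), times = abundances)
  picked <- sample(urn, n, replace = FALSE)
  tabulate(picked, nbins = length(abundances))
}

# random small abundance pair for oracle comparisons
random_small_pair <- function(max_S = 10, max_count = 20) {
  S <- sample(2:max_S, 1)
  repeat {
    x <- sample(0:max_count, S, replace = TRUE)
    y <- sample(0:max_count, S, replace = TRUE)
    keep <- x > 0 | y > 0
    if (sum(x) > 1 && sum(y) > 1) return(list(x = x[keep], y = y[keep]))
  }
}
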