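# Independent brute-force oracles used to validate the fast implementations.
# These deliberately re-derive every quantity with naive loops.

# --- SSIM oracle -----------------------------------------------------------

reflect_index <- function(i, n) {
  # half-sample symmetric reflection (edge repeated)
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

naive_window <- function(m, r, c, k) {
  vals <- numeric((2 * k + 1)^2)
  t <- 0
  for (dr in -k:k) {
    for (dc in -k:k) {
      t <- t + 1
      vals[t] <- m[reflect_index(r + dr, nrow(m)),
                   reflect_index(c + dc, ncol(m))]
    }
  }
  vals
}

naive_ssim <- function(x, y, cfg) {
  k <- (cfg$window - 1L) %/% 2L
  h <- nrow(x); w <- ncol(x)
  l <- cc <- s <- dd <- matrix(0, h, w)
  for (r in 1:h) {
    for (c in 1:w) {
      wx <- naive_window(x, r, c, k)
      wy <- naive_window(y, r, c, k)
      mx <- mean(wx); my <- mean(wy)
      vx <- mean((wx - mx)^2); vy <- mean((wy - my)^2)
      cxy <- mean((wx - mx) * (wy - my))
      sx <- sqrt(vx); sy <- sqrt(vy)
      l[r, c] <- (2 * mx * my + cfg$C1) / (mx^2 + my^2 + cfg$C1)
      cc[r, c] <- (2 * sx * sy + cfg$C2) / (sx^2 + sy^2 + cfg$C2)
      s[r, c] <- (cxy + cfg$C3) / (sx * sy + cfg$C3)
      dd[r, c] <- abs(x[r, c] - y[r, c])
    }
  }
  list(dd = dd, luminance = l, contrast = cc, structure = s,
       ssim = l^cfg$alpha * cc^cfg$beta * s^cfg$gamma)
}

# --- texture-matrix oracles ------------------------------------------------

ORACLE_OFFSETS <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))

oracle_glcm <- function(lv, ng) {
  out <- array(0, c(ng, ng, 4))
  h <- nrow(lv); w <- ncol(lv)
  for (a in 1:4) {
    off <- ORACLE_OFFSETS[[a]]
    for (r in 1:h) {
      for (c in 1:w) {
        r2 <- r + off[1]; c2 <- c + off[2]
        if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
          i <- lv[r, c]; j <- lv[r2, c2]
          out[i, j, a] <- out[i, j, a] + 1
          out[j, i, a] <- out[j, i, a] + 1
        }
      }
    }
  }
  out
}

oracle_glrlm <- function(lv, ng) {
  h <- nrow(lv); w <- ncol(lv)
  maxrun <- max(h, w)
  out <- array(0, c(ng, maxrun, 4))
  dirs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  for (a in 1:4) {
    d <- dirs[[a]]
    for (r0 in 1:h) {
      for (c0 in 1:w) {
        pr <- r0 - d[1]; pc <- c0 - d[2]
        if (pr >= 1 && pr <= h && pc >= 1 && pc <= w) next # not a line start
        r <- r0; c <- c0; g <- -1; run <- 0
        while (r >= 1 && r <= h && c >= 1 && c <= w) {
          if (lv[r, c] == g) run <- run + 1
          else {
            if (g > 0) out[g, run, a] <- out[g, run, a] + 1
            g <- lv[r, c]; run <- 1
          }
          r <- r + d[1]; c <- c + d[2]
        }
        out[g, run, a] <- out[g, run, a] + 1
      }
    }
  }
  out
}

oracle_glszm <- function(lv, ng) {
  h <- nrow(lv); w <- ncol(lv)
  seen <- matrix(FALSE, h, w)
  zones <- list()
  for (r0 in 1:h) {
    for (c0 in 1:w) {
      if (seen[r0, c0]) next
      g <- lv[r0, c0]
      queue <- list(c(r0, c0))
      seen[r0, c0] <- TRUE
      size <- 0
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        size <- size + 1
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          r <- p[1] + dr; c <- p[2] + dc
          if (r >= 1 && r <= h && c >= 1 && c <= w && !seen[r, c] &&
              lv[r, c] == g) {
            seen[r, c] <- TRUE
            queue <- c(queue, list(c(r, c)))
          }
        }
      }
      zones[[length(zones) + 1]] <- c(g, size)
    }
  }
  zm <- do.call(rbind, zones)
  out <- matrix(0, ng, max(zm[, 2]))
  for (z in seq_len(nrow(zm))) out[zm[z, 1], zm[z, 2]] <-
      out[zm[z, 1], zm[z, 2]] + 1
  out
}

oracle_gldm <- function(lv, ng, alpha = 0) {
  h <- nrow(lv); w <- ncol(lv)
  out <- matrix(0, ng, 9)
  for (r in 1:h) {
    for (c in 1:w) {
      dep <- 0
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w &&
            abs(lv[r2, c2] - lv[r, c]) <= alpha) dep <- dep + 1
      }
      out[lv[r, c], dep + 1] <- out[lv[r, c], dep + 1] + 1
    }
  }
  out
}

oracle_ngtdm <- function(lv, ng) {
  h <- nrow(lv); w <- ncol(lv)
  out <- matrix(0, ng, 2)
  for (r in 1:h) {
    for (c in 1:w) {
      nb <- c()
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w)
          nb <- c(nb, lv[r2, c2])
      }
      g <- lv[r, c]
      out[g, 1] <- out[g, 1] + 1
      out[g, 2] <- out[g, 2] + abs(g - mean(nb))
    }
  }
  out
}

# --- AUC oracle ------------------------------------------------------------

# Mann-Whitney concordance probability by exhaustive pair counting.
oracle_auc <- function(scores, truth, positive = TRUE) {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}
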