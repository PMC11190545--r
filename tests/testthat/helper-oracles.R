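# Independent oracle implementations used by the equivalence tests.
# Deliberately written as plain per-element loops, sharing no code with
# the package internals they check.

# One full optimizer iteration, individual by individual, straight from
# the update equations: prey selection, the two-branch exploration move,
# bound clipping, greedy acceptance, then the multiplicative pursuit
# perturbation with greedy acceptance. `draws` carries every random
# quantity (k, I, step matrix, r2 matrix); `radius` is the pursuit
# radius (baseline schedule value or chaotic state).
oracle_iteration <- function(Z, P, f, lower, upper, radius, draws) {
  n <- nrow(Z); m <- ncol(Z)
  Z0 <- Z; P0 <- P # exploration works against the phase-entry snapshot
  for (i in seq_len(n)) {
    k <- draws$k[i]
    cand <- numeric(m)
    for (j in seq_len(m)) {
      if (P0[k] < P0[i]) {
        cand[j] <- Z0[i, j] + draws$step[i, j] *
          (Z0[k, j] - draws$I[i] * Z0[i, j])
      } else {
        cand[j] <- Z0[i, j] + draws$step[i, j] * (Z0[i, j] - Z0[k, j])
      }
      cand[j] <- min(max(cand[j], lower[j]), upper[j])
    }
    pc <- f(cand)
    if (pc < P[i]) { Z[i, ] <- cand; P[i] <- pc }
  }
  for (i in seq_len(n)) {
    cand <- numeric(m)
    for (j in seq_len(m)) {
      cand[j] <- Z[i, j] + radius * (2 * draws$r2[i, j] - 1) * Z[i, j]
      cand[j] <- min(max(cand[j], lower[j]), upper[j])
    }
    pc <- f(cand)
    if (pc < P[i]) { Z[i, ] <- cand; P[i] <- pc }
  }
  list(Z = Z, P = P)
}

# Scalar-loop GRU forward pass for a single sequence (T x D matrix):
# every dot product written out as an explicit accumulation loop.
oracle_gru_forward <- function(w, seq_mat) {
  H <- w$spec$hidden_size; D <- w$spec$input_size
  sig <- function(a) 1 / (1 + exp(-a))
  h <- rep(0, H)
  for (t in seq_len(nrow(seq_mat))) {
    x <- seq_mat[t, ]
    hx <- c(h, x)
    i <- z <- r <- numeric(H)
    for (u in 1:H) {
      ai <- w$bi[u]; az <- w$bz[u]; ar <- w$br[u]
      for (v in seq_along(hx)) {
        ai <- ai + w$Wi[u, v] * hx[v]
        az <- az + w$Wz[u, v] * hx[v]
        ar <- ar + w$Wr[u, v] * hx[v]
      }
      i[u] <- sig(ai); z[u] <- sig(az); r[u] <- sig(ar)
    }
    hn <- numeric(H)
    for (u in 1:H) {
      a <- w$b[u]
      for (v in 1:H) a <- a + w$W[u, v] * (r[v] * h[v])
      xa <- 0
      for (v in 1:D) xa <- xa + w$W[u, H + v] * x[v]
      a <- a + i[u] * xa
      hn[u] <- z[u] * h[u] + (1 - z[u]) * tanh(a)
    }
    h <- hn
  }
  out <- w$b_out
  for (u in 1:H) out <- out + w$w_out[u] * h[u]
  sig(out)
}

# Per-sample tally of a confusion table.
oracle_confusion <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1L
    if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1L
    if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1L
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

# Tiny flat raster helpers for preprocessing tests.
tiny_gray <- function(h = 4, w = 4, value = 0.5) matrix(value, h, w)

tiny_set <- function(n_pos, n_neg, h = 4, w = 4) {
  imgs <- c(
    lapply(seq_len(n_pos), function(i) tiny_gray(h, w, i / (n_pos + 1))),
    lapply(seq_len(n_neg), function(i) tiny_gray(h, w, 1 - i / (n_neg + 1)))
  )
  image_set(imgs, c(rep("cancerous", n_pos), rep("non-cancerous", n_neg)))
}

random_gru_weights <- function(spec, seed) {
  withr::with_seed(seed, gru_decode(spec, stats::runif(spec$n_weights, -1, 1)))
}
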