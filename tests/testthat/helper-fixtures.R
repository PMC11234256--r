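# Shared builders and independent oracles for the test suite.

# 3 + 3 + 3 layout used throughout (optionally with unused channels).
tiny_layout <- function(n_unused = 0L) {
  ch <- c(paste0("WT_", 1:3), paste0("VAR_", 1:3), paste0("CTRL_", 1:3))
  roles <- rep(c("WT_BAIT", "VARIANT_BAIT", "NEGATIVE_CONTROL"), each = 3L)
  reps <- rep(1:3, times = 3L)
  if (n_unused > 0L) {
    ch <- c(ch, paste0("X_", seq_len(n_unused)))
    roles <- c(roles, rep("UNUSED", n_unused))
    reps <- c(reps, seq_len(n_unused))
  }
  plex_layout(ch, roles, reps)
}

# Abundance matrix from a per-protein list of 9 values (WT1-3, VAR1-3, CTRL1-3);
# a bait row of all 1000s is appended unless already present.
tiny_matrix <- function(rows, bait_id = "BAIT") {
  if (!bait_id %in% names(rows)) rows[[bait_id]] <- rep(1000, 9L)
  vals <- do.call(rbind, rows)
  colnames(vals) <- c(paste0("WT_", 1:3), paste0("VAR_", 1:3), paste0("CTRL_", 1:3))
  abundance_matrix(vals, bait_id = bait_id)
}

# Closed-form pooled-variance two-sample t-test (independent of stats::t.test).
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Closed-form Welch test with Satterthwaite degrees of freedom.
oracle_welch_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v1 <- stats::var(a) / n1; v2 <- stats::var(b) / n2
  t <- (mean(a) - mean(b)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Quadratic-time brute-force BH step-up adjustment.
oracle_bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (r in seq_len(m)) {
    adj[r] <- min(1, min(ps[r:m] * m / (r:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Independent re-derivation of the two-stage step-up rejection decisions.
oracle_bky_rejected <- function(p, q) {
  m <- length(p)
  qp <- q / (1 + q)
  o <- order(p)
  ps <- p[o]
  count <- function(denom) {
    k <- seq_len(m)
    w <- which(ps <= k * qp / denom)
    if (length(w)) max(w) else 0L
  }
  r1 <- count(m)
  n_rej <- if (r1 == 0L) 0L else if (r1 == m) m else count(m - r1)
  rej <- logical(m)
  if (n_rej > 0L) rej[o[seq_len(n_rej)]] <- TRUE
  rej
}

# Full grid-scan q-values: smallest level on the grid where each hypothesis
# is rejected, by exhaustively sweeping every level.
oracle_q_grid_scan <- function(p, grid) {
  G <- round(1 / grid)
  qv <- rep(1, length(p))
  for (g in seq_len(G - 1L)) {
    rej <- oracle_bky_rejected(p, g / G)
    new <- rej & qv == 1
    qv[new] <- g / G
    if (all(qv < 1)) break
  }
  qv
}

# Write a small delimited abundance fixture and return its path.
write_abundance_fixture <- function(sep = "\t", drop_channel = NULL,
                                    blank_cell = NULL, negative_cell = NULL) {
  ch <- c(paste0("WT_", 1:3), paste0("VAR_", 1:3), paste0("CTRL_", 1:3))
  vals <- matrix(seq(10, 10 * 27, by = 10), nrow = 3,
                 dimnames = list(NULL, ch))
  df <- data.frame(Accession = c("BAIT", "P1", "P2"),
                   Gene = c("COL2A1", "G1", "G2"),
                   vals, check.names = FALSE)
  if (!is.null(drop_channel)) df[[drop_channel]] <- NULL
  mat <- vapply(df, as.character, character(nrow(df)))
  if (!is.null(blank_cell)) mat[blank_cell[1L], blank_cell[2L] + 2L] <- ""
  if (!is.null(negative_cell)) mat[negative_cell[1L], negative_cell[2L] + 2L] <- "-5"
  path <- tempfile(fileext = if (sep == "\t") ".tsv" else ".csv")
  writeLines(c(paste(colnames(df), collapse = sep),
               apply(mat, 1L, paste, collapse = sep)), path)
  path
}
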