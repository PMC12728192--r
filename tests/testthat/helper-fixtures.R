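# Shared helpers: ad-hoc structures, alignment enumeration oracle,
# Markov-chain variance oracle.

# Build a one-chain structure from an n x 3 coordinate matrix.
mk_points <- function(x, name = "CA", element = "C", res_name = "GLY",
                      chain = "A", res_seq = NULL, hetero = FALSE) {
  n <- nrow(x)
  if (is.null(res_seq)) res_seq <- seq_len(n)
  new_structure(data.frame(
    serial = seq_len(n), name = name, element = element, alt_loc = "",
    res_name = res_name, chain_id = chain, res_seq = res_seq, i_code = "",
    x = x[, 1], y = x[, 2], z = x[, 3], occupancy = 1, b_factor = 0,
    model_index = 1L, is_hetero = hetero, stringsAsFactors = FALSE))
}

# Build a polypeptide-like structure from a per-atom spec data frame.
mk_atoms <- function(df) {
  defaults <- list(element = NA, alt_loc = "", res_name = "GLY",
                   chain_id = "A", i_code = "", occupancy = 1, b_factor = 0,
                   model_index = 1L, is_hetero = FALSE)
  for (nm in names(defaults))
    if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  if (all(is.na(df$element))) df$element <- substr(df$name, 1, 1)
  df$serial <- seq_len(nrow(df))
  new_structure(df)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Exhaustive global-alignment oracle: enumerates all alignments recursively
# and returns the maximal score (match +1 / mismatch -1 / gap -2).
align_score_oracle <- function(a, b) {
  if (length(a) == 0) return(-2 * length(b))
  if (length(b) == 0) return(-2 * length(a))
  s <- if (a[1] == b[1]) 1 else -1
  max(s + align_score_oracle(a[-1], b[-1]),
      -2 + align_score_oracle(a[-1], b),
      -2 + align_score_oracle(a, b[-1]))
}

# Score of an alignment given as paired index columns.
align_score_of <- function(al, a, b) {
  matches <- sum(a[al$i] == b[al$j])
  mismatches <- nrow(al) - matches
  gaps <- (length(a) - nrow(al)) + (length(b) - nrow(al))
  matches - mismatches - 2 * gaps
}

# Asymptotic standard error of the sample mean of f(X_t) for a stationary
# finite Markov chain: sqrt((gamma0 + 2*sum_k gamma_k) / n).
markov_mean_se <- function(P, f, n, kmax = 500) {
  pi0 <- stationary_distribution(P)
  mu <- sum(pi0 * f)
  gamma0 <- sum(pi0 * (f - mu)^2)
  acc <- gamma0
  Pk <- diag(nrow(P))
  for (k in seq_len(kmax)) {
    Pk <- Pk %*% P
    gk <- sum(pi0 * (f - mu) * as.numeric(Pk %*% (f - mu)))
    acc <- acc + 2 * gk
    if (abs(gk) < 1e-12 * gamma0) break
  }
  sqrt(max(acc, 0) / n)
}

# Constructed N-H...O=C geometry: donor at origin, hydrogen 1.0 A along +x,
# acceptor at distance d from the donor with the D-H...A axis bent by `dev`
# degrees from linear; the carbonyl C sits behind the acceptor.
hb_geometry <- function(d_da = 2.9, dev = 10) {
  th <- dev * pi / 180
  acc <- c(d_da * cos(th), d_da * sin(th), 0)
  cpos <- acc + c(1.0, 0.8, 0)
  mk_atoms(data.frame(
    name = c("N", "H", "CA", "O", "C", "CA"),
    res_name = "GLY",
    chain_id = c("A", "A", "A", "B", "B", "B"),
    res_seq = c(1, 1, 1, 2, 2, 2),
    x = c(0, 1, -1.2, acc[1], cpos[1], cpos[1] + 1.2),
    y = c(0, 0, 0.6, acc[2], cpos[2], cpos[2] + 0.6),
    z = 0))
}
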