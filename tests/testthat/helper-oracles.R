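# Independent oracles and fixture builders. These deliberately re-derive
# results with different code paths (plain set operations, exhaustive
# enumeration, closed forms) so they can check the package implementations.

make_membership <- function(sets) {
  structure(list(
    extracts = names(sets),
    scaffolds_of = lapply(sets, function(s) sort(unique(as.integer(s)))),
    universe = sort(unique(as.integer(unlist(sets))))),
    class = "membership_map")
}

make_activity <- function(ids, activity = NA_real_, hit = NA) {
  structure(data.frame(extract_id = ids, activity = activity, hit = hit),
            class = c("activity_table", "data.frame"))
}

make_quant <- function(ab, mz = NULL, rt = NULL, blanks = character(0)) {
  n <- nrow(ab)
  if (is.null(mz)) mz <- seq(200, by = 1, length.out = n)
  if (is.null(rt)) rt <- seq(1, by = 0.5, length.out = n)
  rownames(ab) <- as.character(seq_len(n))
  structure(list(
    features = data.frame(feature_id = seq_len(n), mz = mz, rt = rt),
    abundance = ab,
    sample_columns = setdiff(colnames(ab), blanks),
    blank_columns = blanks),
    class = "quant_matrix")
}

# a random extract -> scaffold instance as a plain named list of integer sets
random_instance <- function(n_extracts, n_scaffolds, max_set = 8) {
  sets <- lapply(seq_len(n_extracts), function(i)
    sample.int(n_scaffolds, sample.int(min(n_scaffolds, max_set), 1)))
  names(sets) <- sprintf("E%02d", seq_len(n_extracts))
  sets
}

# naive greedy: rescans every remaining extract each step with plain setdiff
naive_greedy <- function(sets, target = 1) {
  universe <- unique(unlist(sets))
  covered <- integer(0)
  picked <- character(0)
  gains <- integer(0)
  repeat {
    remaining <- setdiff(names(sets), picked)
    if (!length(remaining)) break
    gain <- vapply(remaining, function(e)
      length(setdiff(sets[[e]], covered)), integer(1))
    if (max(gain) == 0) break
    pick <- sort(remaining[gain == max(gain)])[1]  # lexicographic tie-break
    covered <- union(covered, sets[[pick]])
    picked <- c(picked, pick)
    gains <- c(gains, max(gain))
    if (length(covered) / length(universe) >= target) break
  }
  list(order = picked, new_covered = unname(gains),
       cumulative_fraction = cumsum(gains) / length(universe))
}

# exact minimum set-cover size by exhaustive subset search (tiny instances)
exact_min_cover_size <- function(sets) {
  universe <- sort(unique(unlist(sets)))
  n <- length(sets)
  for (k in seq_len(n)) {
    for (cc in utils::combn(n, k, simplify = FALSE)) {
      if (setequal(unique(unlist(sets[cc])), universe)) return(k)
    }
  }
  stop("no cover exists")  # unreachable: the full set always covers
}

# all permutations of 1..n as a matrix (rows)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Spearman rho re-derived as the product-moment correlation of average ranks
spearman_rho_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# exact two-sided permutation-null p for Spearman rho (n <= 7)
spearman_p_exact <- function(x, y) {
  n <- length(x)
  obs <- abs(spearman_rho_oracle(x, y))
  P <- all_perms(n)
  rhos <- apply(P, 1, function(idx) spearman_rho_oracle(x, y[idx]))
  mean(abs(rhos) >= obs - 1e-12)
}

# Benjamini-Hochberg by hand: step-up over the sorted raw p values
bh_manual <- function(p) {
  m <- length(p)
  o <- order(p)
  stepped <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(stepped)))
  pmin(adj, 1)[order(o)]
}

# expected coverage fraction at k from the hypergeometric closed form
hypergeom_coverage <- function(sets, k) {
  n <- length(sets)
  universe <- sort(unique(unlist(sets)))
  m_s <- vapply(universe, function(s)
    sum(vapply(sets, function(ss) s %in% ss, logical(1))), numeric(1))
  vapply(k, function(kk)
    sum(1 - choose(n - m_s, kk) / choose(n, kk)) / length(universe),
    numeric(1))
}
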