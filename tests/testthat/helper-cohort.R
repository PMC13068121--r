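# shared fixtures, built in code

# mirror a cohort: swap every left/right measurement, negate SVV trials and
# the true side
mirror_cohort <- function(df) {
  swap <- function(a, b) {
    tmp <- df[[a]]
    df[[a]] <<- df[[b]]
    df[[b]] <<- tmp
  }
  swap("ll", "rl"); swap("la", "ra"); swap("lp", "rp")
  swap("cvemp_left", "cvemp_right")
  swap("ovemp_left", "ovemp_right")
  swap("caloric_left_cold", "caloric_right_cold")
  swap("caloric_left_warm", "caloric_right_warm")
  for (k in 1:6) df[[paste0("svv_", k)]] <- -df[[paste0("svv_", k)]]
  df$true_side <- -df$true_side
  df
}

# small complete canonical-scale metric matrix with a single informative
# column (separation `delta` on `informative`), remaining columns noise
make_feature_matrix <- function(n = 20, p = 3, delta = 0, seed = 1,
                                informative = 1) {
  set.seed(seed)
  y <- rep(c(1, -1), length.out = n)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(sprintf("P%02d", seq_len(n)),
                              paste0("m", seq_len(p))))
  X[, informative] <- X[, informative] + delta * y
  list(X = X, y = y)
}

# independent midrank concordance oracle (exhaustive double loop)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# independent 1-NN oracle implementing the package's documented distance
# (Euclidean over shared columns scaled by sqrt(p/m)) and tie-break
# (smallest training-row index; nearer donors first, skipping donors that
# do not observe the needed column)
oracle_impute <- function(queries, donors) {
  p <- ncol(queries)
  for (i in seq_len(nrow(queries))) {
    q <- queries[i, ]
    d <- numeric(nrow(donors))
    for (t in seq_len(nrow(donors))) {
      shared <- which(!is.na(q) & !is.na(donors[t, ]))
      d[t] <- if (length(shared) == 0L) Inf else
        sqrt(sum((q[shared] - donors[t, shared])^2) * p / length(shared))
    }
    ord <- order(d, seq_along(d))
    for (j in which(is.na(q))) {
      for (t in ord) {
        if (is.infinite(d[t])) break
        if (!is.na(donors[t, j])) {
          queries[i, j] <- donors[t, j]
          break
        }
      }
    }
  }
  queries
}
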