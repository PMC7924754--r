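# Independent brute-force oracles used to check the package implementation.

# Union-find connected components over an explicit edge list.
uf_components <- function(ids, from, to) {
  parent <- setNames(seq_along(ids), ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(from)) {
    ra <- find(match(from[k], ids))
    rb <- find(match(to[k], ids))
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_along(ids), find, numeric(1))
  setNames(match(roots, unique(roots)), ids)
}

# Enumerate every candidate co-elution edge by a naive double loop.
naive_edges <- function(features, rt_window = 0.04, r_min = 0.8) {
  cols <- setdiff(names(features), c("feature_id", "mz", "rt"))
  x <- as.matrix(features[, cols])
  n <- nrow(features)
  from <- to <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(features$rt[i] - features$rt[j]) > rt_window) next
      if (sd(x[i, ]) == 0 || sd(x[j, ]) == 0) next
      if (cor(x[i, ], x[j, ]) > r_min) {
        from <- c(from, features$feature_id[i])
        to <- c(to, features$feature_id[j])
      }
    }
  }
  list(from = from, to = to)
}

# Textbook pooled-variance two-sample t test from the t CDF.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tval <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = tval, p_value = 2 * pt(-abs(tval), df = na + nb - 2))
}

# Classical balanced two-way ANOVA from the explicit sums-of-squares
# decomposition.
anova_ss_oracle <- function(y, f1, f2) {
  f1 <- factor(f1); f2 <- factor(f2)
  gm <- mean(y)
  n_cell <- table(f1, f2)
  stopifnot(length(unique(n_cell)) == 1)
  m1 <- tapply(y, f1, mean); m2 <- tapply(y, f2, mean)
  m12 <- tapply(y, interaction(f1, f2), mean)
  nc <- n_cell[1, 1]
  ss_a <- sum(table(f1) * (m1 - gm)^2)
  ss_b <- sum(table(f2) * (m2 - gm)^2)
  cell_means <- outer(levels(f1), levels(f2), Vectorize(function(i, j) {
    mean(y[f1 == i & f2 == j])
  }))
  ss_ab <- nc * sum((cell_means - outer(m1 - gm, m2 - gm, `+`) - gm)^2)
  fitted <- cell_means[cbind(as.integer(f1), as.integer(f2))]
  ss_e <- sum((y - fitted)^2)
  df_a <- nlevels(f1) - 1; df_b <- nlevels(f2) - 1
  df_ab <- df_a * df_b
  df_e <- length(y) - nlevels(f1) * nlevels(f2)
  f_stat <- c(ss_a / df_a, ss_b / df_b, ss_ab / df_ab) / (ss_e / df_e)
  list(F_value = f_stat,
       p_value = pf(f_stat, c(df_a, df_b, df_ab), df_e, lower.tail = FALSE))
}

# Exhaustive Wilcoxon signed-rank p-value by iterating over sign bitmasks
# (coded independently of the package's subset-sum doubling).
wilcox_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
  }, numeric(1))
  min(1, 2 * min(mean(vs <= v + 1e-9), mean(vs >= v - 1e-9)))
}

# All permutations of 1..n as a list, by recursion over the first element.
perm_list <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (first in seq_len(n)) {
    rest <- perm_list(n - 1L)
    for (p in rest) {
      out[[length(out) + 1]] <- c(first, setdiff(seq_len(n), first)[p])
    }
  }
  out
}

# Exact two-sided Spearman permutation p-value by full enumeration.
spearman_perm_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  rhos <- vapply(perm_list(length(y)), function(p) cor(rx, ry[p]), numeric(1))
  mean(abs(rhos) >= abs(rho) - 1e-12)
}

# Tie-corrected Kruskal-Wallis H from the textbook formula.
kruskal_h_oracle <- function(y, g) {
  g <- factor(g)
  n <- length(y)
  r <- rank(y)
  h <- 12 / (n * (n + 1)) * sum(tapply(r, g, sum)^2 / table(g)) - 3 * (n + 1)
  ties <- table(y)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Canonical string signature of a partition (list of member vectors), for
# order-insensitive comparisons.
partition_canon <- function(members_by_group) {
  unname(sort(vapply(members_by_group,
                     function(x) paste(sort(x), collapse = ","), "")))
}

# Small hand-built feature table: n_compounds with `frags` co-eluting,
# correlated fragments each, well separated in retention time.
make_grouped_table <- function(n_compounds = 10, frags = 3, n_samples = 8,
                               seed = 1) {
  set.seed(seed)
  rows <- list()
  for (c_i in seq_len(n_compounds)) {
    latent <- exp(rnorm(n_samples, log(1e4), 0.5))
    rt0 <- 0.5 + c_i * 0.5
    for (f_i in seq_len(frags)) {
      intens <- latent * exp(rnorm(1, 0, 0.5)) * exp(rnorm(n_samples, 0, 0.02))
      rows[[length(rows) + 1]] <- c(
        list(feature_id = sprintf("C%02dF%d", c_i, f_i),
             mz = 100 + c_i * 10 + f_i * 0.1,
             rt = rt0 + f_i * 0.01),
        setNames(as.list(intens), paste0("s", seq_len(n_samples)))
      )
    }
  }
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}

# Random small feature table with clumped retention times so that edges are
# plentiful; used for grouping-oracle equivalence checks.
random_feature_table <- function(seed, n_max = 50, n_samples = 6) {
  set.seed(seed)
  n <- sample(5:n_max, 1)
  base <- matrix(rlnorm(n * n_samples, log(1e4), 1), n, n_samples)
  # make some rows correlated copies of earlier rows
  for (i in seq_len(n)) {
    if (i > 1 && runif(1) < 0.4) {
      j <- sample(i - 1, 1)
      base[i, ] <- base[j, ] * exp(rnorm(n_samples, 0, 0.05))
    }
  }
  colnames(base) <- paste0("s", seq_len(n_samples))
  dplyr::bind_cols(
    tibble::tibble(feature_id = sprintf("f%03d", seq_len(n)),
                   mz = runif(n, 100, 1200),
                   rt = sample(seq(1, 1.2, by = 0.01), n, replace = TRUE)),
    tibble::as_tibble(base)
  )
}
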