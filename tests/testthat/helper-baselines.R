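# shared fixture: 6 features with known structure
baseline_table <- function(seed = 23, n = 60) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.5)
  data.frame(
    s1 = y + rnorm(n, sd = 0.6),          # strong signal
    s2 = y + rnorm(n, sd = 1.2),          # weaker signal
    n1 = rnorm(n),
    n2 = rnorm(n),
    n3 = rnorm(n),
    n4 = rnorm(n),
    class = y)
}

# independent stepwise re-implementation of every greedy criterion
brute_greedy <- function(df, method, K, beta = 1, bins = 4) {
  ft <- as_feature_table(df, label = "class")
  p <- ncol(ft$X)
  bx <- lapply(seq_len(p), function(j) discretize_ef(ft$X[, j], bins))
  y <- ft$y
  sel <- integer(0)
  for (step in seq_len(K)) {
    rem <- setdiff(seq_len(p), sel)
    sc <- sapply(rem, function(k) {
      relk <- entropy_mi(bx[[k]], y)
      if (!length(sel)) return(relk)
      switch(method,
        mim = relk,
        mifs = relk - beta * sum(sapply(sel, function(j)
          entropy_mi(bx[[k]], bx[[j]]))),
        mrmr = relk - mean(sapply(sel, function(j)
          entropy_mi(bx[[k]], bx[[j]]))),
        jmi = sum(sapply(sel, function(j)
          entropy_mi(paste(bx[[k]], bx[[j]]), y))),
        cmim = min(sapply(sel, function(j)
          entropy_mi(paste(bx[[k]], bx[[j]]), y) - entropy_mi(bx[[j]], y))))
    })
    sel <- c(sel, rem[order(-sc, rem)[1]])
  }
  ft$feature_names[sel]
}

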