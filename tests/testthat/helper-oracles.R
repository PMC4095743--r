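# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles with naive loops and literal formulas,
# sharing no code path with the package implementation.

# domain instances of one protein, straight off the annotation table
oracleInstances <- function(proteins, p) {
  dm <- proteins@domains
  dm$domain_id[dm$protein_id == p]
}

# does the unordered protein pair (pi, pj) support domain pair (dm, dn)?
oracleSupports <- function(proteins, pi, pj, dm, dn) {
  A <- unique(oracleInstances(proteins, pi))
  B <- unique(oracleInstances(proteins, pj))
  (dm %in% A && dn %in% B) || (dn %in% A && dm %in% B)
}

# brute-force association scores over every domain pair of the universe
oracleScores <- function(dataset, method = c("assoc", "asnm", "apm")) {
  method <- match.arg(method)
  ps <- dataset@proteins
  doms <- sort(unique(ps@domains$domain_id))
  pr <- dataset@pairs
  out <- list()
  for (a in seq_along(doms)) for (b in a:length(doms)) {
    dm <- doms[a]; dn <- doms[b]
    vals <- c()
    for (r in seq_len(nrow(pr))) {
      if (oracleSupports(ps, pr$protein_a[r], pr$protein_b[r], dm, dn)) {
        rho <- pr$strength[r]
        v <- switch(method,
          assoc = as.numeric(rho == 1),
          asnm = rho,
          apm = {
            ni <- length(oracleInstances(ps, pr$protein_a[r]))
            nj <- length(oracleInstances(ps, pr$protein_b[r]))
            1 - (1 - rho)^(1 / (ni * nj))
          })
        vals <- c(vals, v)
      }
    }
    if (length(vals))
      out[[paste(dm, dn, sep = "|")]] <- c(score = mean(vals),
                                           support = length(vals))
  }
  out
}

# literal noisy-OR combination over domain instance pairs
oraclePredict <- function(proteins, pa, pb, scores) {
  A <- oracleInstances(proteins, pa)
  B <- oracleInstances(proteins, pb)
  prod_term <- 1
  for (dm in A) for (dn in B) {
    key <- paste(min(dm, dn), max(dm, dn), sep = "|")
    if (!key %in% names(scores)) stop("oracle: missing score for ", key)
    prod_term <- prod_term * (1 - scores[[key]])
  }
  1 - prod_term
}

# dictionary-based k-spectrum kernel of two raw strings over the
# 21-letter alphabet (independent of kmerCounts)
oracleSpectrum <- function(s1, s2, k) {
  mapChar <- function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    ch[!ch %in% aa20] <- "x"
    paste(ch, collapse = "")
  }
  dict <- function(s) {
    s <- mapChar(s)
    n <- nchar(s)
    if (n < k) return(table(character(0)))
    words <- vapply(seq_len(n - k + 1), function(i) substr(s, i, i + k - 1), "")
    table(words)
  }
  d1 <- dict(s1); d2 <- dict(s2)
  common <- intersect(names(d1), names(d2))
  sum(as.numeric(d1[common]) * as.numeric(d2[common]))
}

# exact maximiser of the epsilon-SVR dual by active-set enumeration:
#   max  y'beta - eps ||beta||_1 - 0.5 beta' K beta
#   s.t. sum(beta) = 0, |beta_i| <= C
# Each point is in one of 5 states (0, interior +/-, bound +/-); for
# every assignment the stationarity system is solved and KKT feasibility
# checked. Only viable for a handful of points.
oracleSvrDual <- function(K, y, C, eps, tol = 1e-9) {
  n <- length(y)
  states <- expand.grid(rep(list(1:5), n))  # 1=zero 2=int+ 3=C 4=int- 5=-C
  best <- -Inf
  obj <- function(beta) {
    sum(y * beta) - eps * sum(abs(beta)) - 0.5 * sum(beta * (K %*% beta))
  }
  for (r in seq_len(nrow(states))) {
    st <- as.integer(states[r, ])
    beta <- numeric(n)
    beta[st == 3] <- C
    beta[st == 5] <- -C
    I <- which(st == 2 | st == 4)
    sI <- ifelse(st[I] == 2, 1, -1)
    Fx <- which(st == 3 | st == 5)
    if (length(I)) {
      A <- rbind(cbind(K[I, I, drop = FALSE], 1), c(rep(1, length(I)), 0))
      rhs <- c(y[I] - eps * sI -
                 if (length(Fx)) K[I, Fx, drop = FALSE] %*% beta[Fx] else 0,
               -sum(beta[Fx]))
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      bI <- sol[seq_along(I)]
      lambda <- sol[length(sol)]
      if (any(st[I] == 2 & (bI <= tol | bI >= C - tol))) next
      if (any(st[I] == 4 & (bI >= -tol | bI <= -C + tol))) next
      beta[I] <- bI
    } else {
      if (abs(sum(beta)) > tol) next
      # lambda only constrained by inequalities; find a feasible value
      f <- as.numeric(K %*% beta)
      lo <- -Inf; hi <- Inf
      for (i in seq_len(n)) {
        g <- y[i] - f[i]
        if (st[i] == 1) { lo <- max(lo, g - eps); hi <- min(hi, g + eps) }
        if (st[i] == 3) hi <- min(hi, g - eps)
        if (st[i] == 5) lo <- max(lo, g + eps)
      }
      if (lo > hi + tol) next
      lambda <- mean(c(max(lo, min(hi, 0)), min(hi, max(lo, 0))))
    }
    # remaining KKT inequalities
    f <- as.numeric(K %*% beta)
    ok <- TRUE
    for (i in seq_len(n)) {
      g <- y[i] - f[i] - lambda
      if (st[i] == 1 && abs(g) > eps + tol) ok <- FALSE
      if (st[i] == 3 && g < eps - tol) ok <- FALSE
      if (st[i] == 5 && g > -eps + tol) ok <- FALSE
    }
    if (!ok) next
    best <- max(best, obj(beta))
  }
  best
}
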